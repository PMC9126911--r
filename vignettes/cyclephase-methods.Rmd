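---
title: "Inferring a circular transcriptional phase from spliced and unspliced counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a circular transcriptional phase from spliced and unspliced counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cyclephase)
```

## The problem and the model

Single-cell RNA-seq captures each cell at an unknown point of its cell
cycle. For a cycling gene, the joint dynamics of unspliced (nascent) and
spliced (mature) reads contain directional information: transcription
turns on, the unspliced pool fills first, the spliced pool follows, and
both decay when transcription turns off. Over one cycle a cycling gene
therefore traces a closed loop in the (spliced, unspliced) plane, with an
"off" attractor and an "on" attractor joined by an activation branch
(unspliced leading) and a deactivation branch (unspliced lagging).

`cyclephase` compresses this structure into one circular latent variable,
the *transcriptional phase* $\theta \in [0,1)$, with a small
circular-bottleneck autoencoder:

* the encoder maps the per-gene standardized vector
  $x = (z(s_1),\dots,z(s_N),\, z(u_1),\dots,z(u_N))$, concatenated with
  $(\cos a, \sin a)$ of a seed angle, through two leaky-ReLU hidden layers
  of width $4N$ to one real number;
* a circularize layer maps that number to $(\cos\theta, \sin\theta)$, so
  the latent space is topologically a circle;
* the decoder expands $(\cos\theta, \sin\theta)$ back to the $2N$-vector.

The seed angle $a_c = \mathrm{atan2}(z(u), z(s))$ of a single robustly
cycling gene already orders cells coarsely around the cycle, because one
loop traversal advances this angle by one turn. Training is therefore done
in two steps: step 1 fits the encoder alone to the seed angles (as a
cos/sin pair -- regressing the raw angle across its wrap point is
ill-posed); step 2 trains encoder and decoder end-to-end on reconstruction
mean squared error. Both steps use Adam, minibatches of 5 cells, a 17%
validation split, early stopping (patience 20, best weights restored) and
plateau learning-rate decay (factor 0.8, patience 5, floor $10^{-5}$).
Gaussian noise (default sd 0.1 in z-units) is injected into training
inputs as a regularizer; validation inputs are clean. The epoch cap is
1000 per step; early stopping halts training long before on all
populations we simulate.

Cells are then mapped onto the cycle by decoding 50 bin-center phases into
expression space and assigning each cell to the nearest decoded vector in
Euclidean distance over the standardized $2N$ coordinates, ties toward
the lower bin. Because assignment uses the decoder only, held-out cells
(for example a quiescent subpopulation excluded from training) can be
mapped with a trained model.

### Constant-speed parameterization of the latent circle

The decoder may traverse the expression loop at an arbitrary speed in
$\theta$: two parameterizations that differ by a monotone circular warp
reconstruct equally well. Left uncorrected, this warp concentrates many
bins on a short stretch of the cycle and stretches others, which distorts
bin occupancies and any phase-resolved statistic. After training we
therefore re-parameterize the circle at constant arc length of the decoded
trajectory in z-space (1000-point discretization), so equal phase
differences correspond to equal amounts of transcriptional change. This is
a pure relabeling of the circle -- monotone, bijective, and applied
consistently to decoding and assignment.

## Cycling-gene selection

Cycling genes are detected per gene from the smoothed (s, u) cloud:

1. a two-component bivariate Gaussian mixture (EM, 5 restarts with
   kmeans++-style seeding, tolerance $10^{-6}$, at most 500 iterations)
   finds the two candidate attractors; fits with a component weight below
   $10^{-3}$ or covariance condition number above $10^8$ are flagged
   degenerate;
2. a two-sample Hotelling $T^2$ test on the hard-assigned groups asks
   whether the attractors are significantly distinct; p-values are
   Benjamini-Hochberg adjusted across genes with a default threshold of
   0.01 (the mixture is a descriptive device here; the test is the
   standard closed-form two-sample statistic, which also gives us an
   independent oracle to test against);
3. a branch count asks whether the attractors are joined by *two*
   high-density paths (a loop) rather than one (a ridge) or none. The
   point density is turned into a potential $V = -\log(\hat f +
   \varepsilon)$, the corridor between the attractors (excluding one
   Mahalanobis unit around each mean, capped at a quarter of the axis) is
   sliced perpendicular to the inter-mean axis, and the density ridge
   peaks in each slice are located on the interpolated potential. A peak
   only counts where actual cells sit under it (at least one point within
   the slice strip and ~1.5 bandwidths of the peak), which prevents the
   blurred tails of two isolated clusters from reading as a connecting
   ridge. The branch count is the largest number of peaks that coexist
   over a sustained contiguous window (a quarter of the corridor);
   branches merge near the attractors, so chains are not required to span
   the corridor end to end.

A gene is selected if the fit is non-degenerate, the adjusted p-value
passes, and at least two branches join the attractors. Selection runs on
smoothed counts: raw UMI counts (a few per gene per cell) are far too
sparse for per-cell loop structure. Smoothing is the usual first-order
kNN moment: log1p of total-count-normalized spliced counts, PCA (30
components), Euclidean 30-nearest-neighbor graph (self included),
arithmetic mean of raw spliced and unspliced counts over neighbors.

The autoencoder is trained on the selected genes, strongest Hotelling
separations first, capped at 40 genes by default; beyond that the added
genes are increasingly redundant while the hidden layers (width $4N$) grow
quadratically in cost.

## Phase annotation

The latent circle has arbitrary orientation and origin. Both are fixed
from marker programs and RNA content, per 50-bin tables of: the S and G2M
scores (per-cell means of per-gene z-scores over marker lists, averaged
per bin), a cyclin-E score (CCNE1/CCNE2), and mean total UMI counts.

* **Orientation**: in the biological direction the programs peak in the
  order cyclin E, then S, then G2M. If, going forward from the cyclin-E
  peak, the G2M peak comes first, the circle is reflected. Peak positions
  are used rather than the transition bins themselves because they are
  robust: score crossings in the reversed orientation can land in
  artifactual but internally consistent places.
* **M/G1**: mitosis is the sharp drop in per-cell RNA content. The
  largest circularly contiguous decrease of the 3-bin-smoothed counts
  locates the division region; the steepest single-bin drop of the raw
  series inside it marks the boundary. (The start of the smoothed run
  systematically precedes the cliff by a few bins -- nearest-bin
  assignment mixes mother and daughter cells around division, and the
  3-bin smoothing rounds the shoulder.)
* **G1/S** is the bin after the cyclin-E score peaks; **S/G2** is the
  first bin, forward from G1/S, where the G2M score exceeds the S score.

Phases are then rotated by a whole number of bins so mitosis sits at
$\theta = 1$; transitions are reported at bin left boundaries so that the
rotation is exact and re-running the alignment on an aligned assignment
is the identity. Alignment is an isometry of the circle: pairwise
circular distances between cells are untouched. Discrete labels follow:
G1 $= [0, \theta_{G1S})$, S $= [\theta_{G1S}, \theta_{SG2})$, G2M
$= [\theta_{SG2}, 1)$.

**RNA fold change.** The ratio of RNA content just before versus just
after mitosis should be the per-cycle growth factor (2 for a doubling,
symmetrically dividing population). The default estimator fits
$\log_2(\text{mean counts per bin})$ against phase over the interior of
the cycle (excluding 3 bins on each side of mitosis) and reports
$2^{\text{slope}}$. A direct ratio of the 3-bin flanks is also available
(`method = "flank"`), but it is biased toward 1 whenever the division
drop is smeared over more than one bin by assignment noise -- the flank
windows then sit partly inside the mixing zone. The trend estimator
extrapolates the two plateaus to the boundary from bins that mixing
cannot reach, at the cost of assuming log-linear (exponential-like)
growth of RNA content across the cycle, which holds for cycling
populations by construction of volume growth.

## Motif activities

Transcription-factor motif activities across the cycle follow the ISMARA
linear model: per phase bin $c$, promoter-level expression is explained by
site counts, $E_{pc} \approx \sum_m N_{pm} A_{mc}$, with an L2 penalty on
$A$. $N_{pm}$ sums Motevo-style binding posteriors of motif $m$ within
TSS $\pm$ 1 kb of gene $p$. We fit to binned *unspliced* expression
(per-bin mean of log1p smoothed unspliced counts, per-gene centered),
because nascent transcription reflects regulator activity without mRNA
stability effects. The ridge strength is chosen by 10 repeats of random
80/20 cross-validation over promoters -- promoters are the model's
generalization unit -- minimizing held-out error on a log-spaced grid
($10^{-4}$ to $10^2$), and the per-repeat optima are combined by
geometric mean (arithmetic averaging on a log grid over-weights large
values). One shared strength is used across bins. Solutions are computed
through the SVD of the centered site-count matrix; significance z-scores
use the ridge sandwich covariance with a per-bin residual variance.
Activities fit on binned profiles rather than per cell; per-cell fitting
is a possible extension but adds noise without changing the estimand.

## High-density paths and branch comparison

For branch-level questions (which genes differ between cycle progression
and cycle exit), cell density in a 2-D embedding is turned into the same
$-\log$ density potential (Gaussian KDE, Scott's-rule bandwidths per
axis, floor $\varepsilon = 10^{-6} \max \hat f$). Coarse paths connect
two endpoints by slicing perpendicular to their segment, taking per-slice
potential minima, and chaining nearest minima across slices; the chain
with the lowest mean potential is kept, anchored at the endpoints.

Paths are refined with a viscous nudged elastic band: each interior image
feels the perpendicular component of $-\nabla V$ (bilinear interpolation
of the gridded potential) plus a tangential spring force
$k(\lVert x_{j+1}-x_j\rVert - \lVert x_j-x_{j-1}\rVert)$, velocities are
damped multiplicatively by $(1-\eta)$ per step, and endpoints never move.
Iteration stops when the largest image displacement stays below the
tolerance for three consecutive steps (a one-step criterion can trigger
spuriously before the damped velocities develop). Defaults: 30 images,
$k = 1$, $\eta = 0.1$, $dt = 0.1\times$ grid spacing, tolerance
$10^{-3}\times$ grid spacing, 5000 iterations. On rapidly varying
analytic potentials a larger step (for example $dt = 0.3$, $\eta = 0.3$)
converges faster and tighter; both are exposed.

Expression along a path is the Gaussian-distance-weighted mean of
smoothed spliced counts of cells within a radius of each image (kernel
scale radius/2); branches are compared by the per-gene log2 ratio of the
two path means with a pseudocount.

## The simulator and what passing tests mean

The built-in generator draws populations from the
transcription-splicing-degradation model
$du/dt = \alpha(\theta) - \beta u$, $ds/dt = \beta u - \gamma s$ with a
smooth periodic transcription bump
$\alpha(\theta) = a_0 + a_1 e^{\kappa(\cos 2\pi(\theta-\phi) - 1)}$,
solved to its periodic orbit by cycling the ODE until successive cycles
agree to $10^{-8}$. Cell volume grows as $2^\theta$ over a 20 h cycle and
resets at division; molecule numbers scale with volume; observed UMIs are
Poisson with a 20% capture efficiency. Defaults: 2000 cells, 80 cycling
genes with peak phases on an even grid, 120 constitutive genes; basal and
peak rates 0.5-2 and 5-15 molecules/h, bump concentration $\kappa$ 3-8,
splicing rates 0.5-1.2/h (effective processing times around an hour, the
scale at which unspliced reads are informative), degradation rates
0.2-0.6/h (mRNA half-lives of 1-3.5 h, at the fast end of the mammalian
range where cycle-resolved expression is possible at all). These rates
put the phase lag between unspliced and spliced signals --
$\arctan(\omega/\beta) + \arctan(\omega/\gamma)$ at cycle frequency
$\omega$ -- around 0.1 cycles, so cycling genes show open loops, which is
precisely the regime the method (and its gene filter) is designed for:
genes whose turnover is much faster than the cycle collapse onto a line
in (s, u) and are correctly not selected. Ages are uniform by default
(growth-biased $p(\theta) \propto 2^{1-\theta}$ optional); an optional
arrested subpopulation sits at a fixed mid-G1-like phase with a
configurable set of constitutive marker genes up-scaled. The planted
peak phases stored for evaluation are the phases at which the
volume-scaled expectations peak (`phi_s`, `phi_u`): these lag the
transcription peak by the kinetic response times and are the quantity an
expression-based method can actually see.

The simulator does *not* model transcriptional bursting, gene-length or
sequence biases, doublets, batch effects, checkpoint arrest dynamics or
negative-binomial overdispersion. Tests passing on these populations
demonstrate the machinery is correct and self-consistent under the
model's own assumptions -- circular (u, s) dynamics, Poisson capture,
volume doubling -- not that every real dataset will reach the same
recovery; on real data, marker lists, the seed gene and the selection
threshold remain the user's scientific choices.

Problem sizes used in the shipped tests: the reference population above
for end-to-end checks; 400-1200 cells and 70-100 genes for module-level
checks; 200 promoters x 20 motifs x 50 bins for activity recovery.

## Numerical choices and degenerate inputs

* z-scores use the population standard deviation; zero-variance genes map
  to all-zero z-scores rather than NaN, and a zero-variance seed gene is
  rejected with a pointer to choose another.
* Cells with zero total counts are rejected at load; explicit filtering
  is the caller's job.
* EM covariances carry a $10^{-10}$ trace ridge; a singular pooled
  covariance in the Hotelling test is regularized by $10^{-8}$ of its
  mean diagonal with a warning.
* Empty phase bins are carried as missing values: interpolated circularly
  for transition detection, excluded per bin from the activity solve.
* Assignment distance ties break toward the lower bin index; all
  stochastic steps (simulation, EM restarts, validation split, batch
  order, input noise, CV splits) are seeded, and the network trainer uses
  its own counter-based generator so results do not depend on R's global
  RNG state.

## Known limitations

* The transcriptional phase is not clock time: equal phase steps are
  equal amounts of transcriptional change, not equal durations. Mapping
  to wall-clock time needs external anchors (e.g. phase durations).
* Orientation detection needs informative S/G2M/cyclin-E marker sets; on
  species or cell types where those programs are weak the orientation
  should be checked manually.
* The two-Gaussian mixture is descriptive; genes with more than two
  expression states are outside its scope.
* The branch counter and path finder operate in 2-D projections;
  structure orthogonal to the chosen plane is invisible to them.
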