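#' Per-bin marker score
#'
#' For each cell, the mean of the per-gene z-scores (smoothed spliced
#' expression, z-scored across cells) over the markers present in the
#' dataset; then averaged per phase bin. This is the standard per-cell
#' signature score used to place S-phase, G2/M and cyclin-E programs on the
#' inferred cycle.
#'
#' @param ds an \code{ExpressionDataset} with smoothed layers.
#' @param assignment a \code{PhaseAssignment} for the same cells.
#' @param genes character vector of marker symbols (absent ones are dropped
#'   with a message; none present is an error).
#' @return numeric vector of length \code{n_bins} (NA for empty bins) with
#'   the per-cell scores in \code{attr(, "per_cell")}.
#' @export
marker_score <- function(ds, assignment, genes) {
  stopifnot(is(ds, "ExpressionDataset"), is(assignment, "PhaseAssignment"))
  if (is.null(ds$S_smooth)) stop("run knn_smooth() first")
  present <- intersect(genes, ds$gene_ids)
  if (length(present) == 0L) stop("no marker genes present in the dataset")
  if (length(present) < length(genes)) {
    message(sprintf("%d of %d marker genes absent from the dataset",
                    length(genes) - length(present), length(genes)))
  }
  Z <- apply(ds$S_smooth[, present, drop = FALSE], 2L, zscore_per_gene)
  per_cell <- rowMeans(Z)
  per_bin <- rep(NA_real_, assignment$n_bins)
  agg <- tapply(per_cell, assignment$bin, mean)
  per_bin[as.integer(names(agg)) + 1L] <- agg
  attr(per_bin, "per_cell") <- per_cell
  per_bin
}

#' Per-bin score table for transition detection
#'
#' Assembles the S, G2M and cyclin-E marker scores and the mean total RNA
#' counts per phase bin, the inputs of \code{\link{detect_transitions}}.
#'
#' @inheritParams marker_score
#' @param s_genes,g2m_genes,cyclin_e_genes marker gene lists.
#' @return data.frame with columns \code{bin} (0-based), \code{S_score},
#'   \code{G2M_score}, \code{CyclinE_score}, \code{mean_total_counts},
#'   \code{n_cells}.
#' @export
build_score_table <- function(ds, assignment, s_genes, g2m_genes,
                              cyclin_e_genes) {
  n_bins <- assignment$n_bins
  counts <- rep(NA_real_, n_bins)
  agg <- tapply(ds$total_counts, assignment$bin, mean)
  counts[as.integer(names(agg)) + 1L] <- agg
  occ <- rep(0L, n_bins)
  tab <- table(assignment$bin)
  occ[as.integer(names(tab)) + 1L] <- as.integer(tab)
  data.frame(bin = seq_len(n_bins) - 1L,
             S_score = as.numeric(marker_score(ds, assignment, s_genes)),
             G2M_score = as.numeric(marker_score(ds, assignment, g2m_genes)),
             CyclinE_score = as.numeric(
               marker_score(ds, assignment, cyclin_e_genes)),
             mean_total_counts = counts,
             n_cells = occ)
}

# fill NA bins by circular linear interpolation
fill_circular_na <- function(x) {
  n <- length(x)
  if (!anyNA(x)) return(x)
  if (all(is.na(x))) stop("all bins are empty")
  idx <- which(!is.na(x))
  xx <- c(idx, idx + n)
  yy <- c(x[idx], x[idx])
  out <- x
  for (i in which(is.na(x))) {
    out[i] <- stats::approx(xx, yy, xout = if (i < idx[1L]) i + n else i)$y
  }
  out
}

#' Detect the G1/S, S/G2 and M/G1 transitions from per-bin scores
#'
#' Applies the three rules: M/G1 is the first bin at which the per-cell RNA
#' content drops, operationalized as the start of the largest circularly
#' contiguous decrease of the 3-bin moving-averaged mean total counts; G1/S
#' is the bin after the cyclin-E score reaches its maximum; S/G2 is the
#' first bin, searching forward from G1/S, where the G2M score exceeds the
#' S score.
#'
#' @param score_table as built by \code{\link{build_score_table}} (empty
#'   bins are interpolated circularly).
#' @return a \code{TransitionMap}: 0-based bins \code{bin_G1S},
#'   \code{bin_SG2}, \code{bin_MG1}; their phase coordinates
#'   \code{theta_G1S}, \code{theta_SG2}, \code{theta_MG1} (left bin
#'   boundaries in cycles); flags \code{orientation_flipped},
#'   \code{rotation_applied}; and the score table.
#' @export
detect_transitions <- function(score_table) {
  need <- c("S_score", "G2M_score", "CyclinE_score", "mean_total_counts")
  stopifnot(all(need %in% names(score_table)))
  n <- nrow(score_table)
  S <- fill_circular_na(score_table$S_score)
  G2M <- fill_circular_na(score_table$G2M_score)
  CycE <- fill_circular_na(score_table$CyclinE_score)
  counts <- fill_circular_na(score_table$mean_total_counts)

  # M/G1: the bin where the RNA content has sharply dropped. The largest
  # circularly contiguous decrease of the 3-bin smoothed series locates
  # the division region; within it, the steepest single-bin drop of the
  # raw series marks the mitosis boundary (the smoothed run start rounds
  # off several bins before the cliff).
  m <- circular_ma3(counts)
  d <- m[c(seq(2L, n), 1L)] - m                    # d[k] = m[k+1] - m[k]
  neg <- d < 0
  if (!any(neg)) stop("total counts never decrease; cannot place mitosis")
  runs <- circular_runs(neg)
  drop_sums <- vapply(runs, function(r) sum(d[r]), 0)
  best <- runs[[which.min(drop_sums)]]
  d_raw <- counts[c(seq(2L, n), 1L)] - counts
  k_star <- best[which.min(d_raw[best])]
  bin_MG1 <- k_star %% n
  # d[k] is the step from 0-based bin k-1 to bin k, so the first bin on
  # the low side of the steepest step is 0-based bin k_star
  bin_G1S <- (which.max(CycE)) %% n                 # bin after the argmax
  diffGS <- G2M - S
  if (all(diffGS > 0) || all(diffGS <= 0)) {
    stop("G2M and S scores never cross; phase inference did not capture the cycle")
  }
  order_from_g1s <- ((bin_G1S + seq_len(n) - 1L)) %% n
  hit <- order_from_g1s[which(diffGS[order_from_g1s + 1L] > 0)[1L]]
  if (is.na(hit)) stop("no bin with G2M score above S score")
  bin_SG2 <- hit

  structure(list(bin_G1S = bin_G1S, bin_SG2 = bin_SG2, bin_MG1 = bin_MG1,
                 theta_G1S = bin_G1S / n,
                 theta_SG2 = bin_SG2 / n,
                 theta_MG1 = if (bin_MG1 == 0L) 1 else bin_MG1 / n,
                 n_bins = n,
                 orientation_flipped = FALSE, rotation_applied = 0,
                 score_table = score_table),
            class = "TransitionMap")
}

# maximal runs of TRUE in a circular logical vector; returns 1-based index
# vectors (possibly wrapping past n, reduced mod n by callers)
circular_runs <- function(flag) {
  n <- length(flag)
  if (all(flag)) return(list(seq_len(n)))
  # rotate so the vector starts with FALSE, then take ordinary runs
  start <- which(!flag)[1L]
  rot <- flag[((seq_len(n) + start - 2L) %% n) + 1L]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    span <- seq(ends[i] - r$lengths[i] + 1L, ends[i])
    out[[length(out) + 1L]] <- ((span + start - 2L) %% n) + 1L
  }
  out
}

#' @export
print.TransitionMap <- function(x, ...) {
  cat(sprintf(
    "TransitionMap: G1/S at %.3f, S/G2 at %.3f, M/G1 at %.3f (%d bins)\n",
    x$theta_G1S, x$theta_SG2, x$theta_MG1, x$n_bins))
  invisible(x)
}

# flip a score table to the theta -> 1 - theta orientation
flip_score_table <- function(tab) {
  out <- tab[rev(seq_len(nrow(tab))), , drop = FALSE]
  out$bin <- seq_len(nrow(tab)) - 1L
  rownames(out) <- NULL
  out
}

#' Normalize and align a phase assignment to the cell cycle
#'
#' Fixes the orientation of the circle so that the cycle runs G1 -> S ->
#' G2/M (the cyclin-E peak must precede the G2M/S crossing which must
#' precede mitosis in increasing theta; if not, theta is reflected), then
#' rotates all phases so mitosis sits exactly at theta = 1. The rotation is
#' a whole number of bins, so bin centers stay on the bin grid and pairwise
#' circular distances between cells are untouched.
#'
#' @param assignment a \code{PhaseAssignment}.
#' @param transitions the \code{TransitionMap} detected on this assignment.
#' @return the normalized \code{PhaseAssignment} with \code{normalized} and
#'   \code{oriented} set and the re-expressed \code{TransitionMap} in
#'   \code{$transitions}; after alignment \code{theta_G1S < theta_SG2 < 1}.
#' @export
normalize_and_align <- function(assignment, transitions) {
  stopifnot(is(assignment, "PhaseAssignment"), is(transitions, "TransitionMap"))
  n <- assignment$n_bins
  stopifnot(n == transitions$n_bins)

  # orientation: in the biological direction the marker programs peak in
  # the order cyclin E -> S -> G2M; going forward from the cyclin-E peak,
  # the S peak must come before the G2M peak
  peak_order_ok <- function(tab) {
    cyce <- which.max(fill_circular_na(tab$CyclinE_score)) - 1L
    s_pk <- which.max(fill_circular_na(tab$S_score)) - 1L
    g_pk <- which.max(fill_circular_na(tab$G2M_score)) - 1L
    ((s_pk - cyce) %% n) < ((g_pk - cyce) %% n)
  }
  flipped <- FALSE
  tr <- transitions
  if (!peak_order_ok(tr$score_table)) {
    flipped <- TRUE
    flipped_tab <- flip_score_table(transitions$score_table)
    if (!peak_order_ok(flipped_tab)) {
      stop("transition ordering unsatisfiable in both orientations")
    }
    tr <- detect_transitions(flipped_tab)
    assignment$bin <- (n - 1L) - assignment$bin
    assignment$theta <- (assignment$bin + 0.5) / n
  }

  shift <- (n - tr$bin_MG1) %% n
  assignment$bin <- (assignment$bin + shift) %% n
  assignment$theta <- (assignment$bin + 0.5) / n
  assignment$normalized <- TRUE
  assignment$oriented <- TRUE

  tab <- tr$score_table
  new_bin <- (tab$bin + shift) %% n
  tab <- tab[order(new_bin), , drop = FALSE]
  tab$bin <- sort(new_bin)
  rownames(tab) <- NULL

  rot <- function(b) (b + shift) %% n
  out <- structure(list(
    bin_G1S = rot(tr$bin_G1S), bin_SG2 = rot(tr$bin_SG2),
    bin_MG1 = 0L,
    theta_G1S = rot(tr$bin_G1S) / n,
    theta_SG2 = rot(tr$bin_SG2) / n,
    theta_MG1 = 1,
    n_bins = n,
    orientation_flipped = flipped,
    rotation_applied = shift / n,
    score_table = tab), class = "TransitionMap")
  if (!(out$theta_G1S < out$theta_SG2 && out$theta_SG2 < 1)) {
    stop("transition ordering violated after alignment")
  }
  assignment$transitions <- out
  assignment
}

#' RNA-content fold change across mitosis
#'
#' Estimates how much the total RNA content of a cell grows over one cycle,
#' i.e. the ratio of mean total UMI counts just before mitosis (theta = 1)
#' to just after it. Two estimators are available. The default,
#' \code{"trend"}, fits \eqn{\log_2} of the per-bin mean counts against
#' phase over the interior of the cycle (excluding \code{window} bins on
#' each side of mitosis, where nearest-bin assignment mixes mother and
#' daughter cells) and reports \eqn{2^{slope}}; it extrapolates the two
#' plateaus to the division boundary and is robust to that mixing.
#' \code{"flank"} is the direct ratio of the mean counts in the
#' \code{window} bins immediately before mitosis to the \code{window} bins
#' immediately after, which is biased toward 1 when the division drop is
#' smeared over several bins. In a population doubling its RNA content and
#' dividing symmetrically the true value is 2 by conservation.
#'
#' @param ds the \code{ExpressionDataset} (full gene set, for total counts).
#' @param assignment a normalized \code{PhaseAssignment}.
#' @param window flanking/exclusion window in bins (default 3; widened with
#'   a warning if a flank is empty).
#' @param method "trend" (default) or "flank".
#' @return the fold change (single number).
#' @export
rna_fold_change <- function(ds, assignment, window = 3L,
                            method = c("trend", "flank")) {
  method <- match.arg(method)
  stopifnot(is(ds, "ExpressionDataset"), is(assignment, "PhaseAssignment"))
  if (!isTRUE(assignment$normalized)) {
    stop("assignment must be normalized (mitosis at theta = 1) first")
  }
  n <- assignment$n_bins
  per_bin <- tapply(ds$total_counts, assignment$bin, mean)
  counts <- rep(NA_real_, n)
  counts[as.integer(names(per_bin)) + 1L] <- per_bin

  if (method == "trend") {
    bins <- seq_len(n) - 1L
    keep <- bins >= window & bins < n - window & !is.na(counts)
    if (sum(keep) < 5L) stop("too few occupied bins for the trend fit")
    theta <- (bins[keep] + 0.5) / n
    fit <- stats::lm(log2(counts[keep]) ~ theta)
    return(as.numeric(2^stats::coef(fit)[2L]))
  }

  w <- window
  repeat {
    pre_bins <- (n - seq_len(w)) %% n
    post_bins <- seq_len(w) - 1L
    pre <- assignment$bin %in% pre_bins
    post <- assignment$bin %in% post_bins
    if (any(pre) && any(post)) break
    w <- w + 1L
    if (w > n %/% 4) stop("no cells near mitosis in either flank")
    warning(sprintf("empty mitosis flank; widening window to %d bins", w))
  }
  mean(ds$total_counts[pre]) / mean(ds$total_counts[post])
}

#' Discrete cell-cycle phase labels from a normalized assignment
#'
#' G1 spans \code{[0, theta_G1S)}, S spans \code{[theta_G1S, theta_SG2)}
#' and G2M spans \code{[theta_SG2, 1)}.
#'
#' @param assignment a normalized \code{PhaseAssignment} with transitions.
#' @return factor of per-cell labels in \code{c("G1", "S", "G2M")}.
#' @export
assign_cell_cycle_phase <- function(assignment) {
  stopifnot(is(assignment, "PhaseAssignment"),
            !is.null(assignment$transitions))
  tr <- assignment$transitions
  th <- assignment$theta
  lab <- ifelse(th < tr$theta_G1S, "G1",
                ifelse(th < tr$theta_SG2, "S", "G2M"))
  factor(lab, levels = c("G1", "S", "G2M"))
}

#' Build a phase assignment from known phases
#'
#' Bins a vector of phases (cycles, mitosis at 1) onto the phase grid.
#' Mainly useful to evaluate annotation operations against a simulation's
#' ground truth, independently of the inference pipeline.
#'
#' @param theta per-cell phases in cycles, \code{[0, 1)}.
#' @param cell_ids cell identifiers.
#' @param n_bins number of bins (default 50).
#' @param normalized whether the phases are already mitosis-aligned
#'   (default TRUE).
#' @return a \code{PhaseAssignment}.
#' @export
assignment_from_phase <- function(theta, cell_ids = NULL, n_bins = 50L,
                                  normalized = TRUE) {
  stopifnot(all(theta >= 0 & theta < 1))
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%04d", seq_along(theta))
  bin <- pmin(floor(theta * n_bins), n_bins - 1L)
  structure(list(cell_ids = cell_ids,
                 theta = (bin + 0.5) / n_bins,
                 bin = as.integer(bin),
                 n_bins = as.integer(n_bins),
                 normalized = normalized, oriented = normalized),
            class = "PhaseAssignment")
}
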