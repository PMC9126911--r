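#' Configuration for the kinetic cell-cycle simulator
#'
#' The simulator draws cells from a transcription-splicing-degradation model
#' in which each cycling gene's transcription rate is a smooth periodic bump
#' \deqn{\alpha(\theta) = a_0 + a_1 \exp(\kappa \cos(2\pi(\theta-\phi)))/e^{\kappa},}
#' pre-mRNA follows \eqn{du/dt = \alpha - \beta u} and mature mRNA
#' \eqn{ds/dt = \beta u - \gamma s}. Cell volume grows as
#' \eqn{V(\theta) = g^{\theta}} over the cycle (fold \eqn{g} per cycle,
#' resetting at division), molecule numbers scale with volume, and observed
#' UMI counts are Poisson thinned by the capture efficiency. Per-gene kinetic
#' parameters are drawn uniformly from the ranges below; peak phases
#' \eqn{\phi_g} are laid out on an even grid over the cycle.
#'
#' Default rates are in events per hour with a 20 h cycle, giving mRNA
#' lifetimes (40 min - 2 h) and splicing times (20 - 60 min) in the range
#' reported for mammalian cells, and a capture efficiency of 0.2 typical of
#' droplet protocols.
#'
#' @param n_cells number of cells (default 2000).
#' @param n_cycling_genes,n_flat_genes number of periodically transcribed and
#'   constitutive genes (defaults 80 and 120).
#' @param a0_range,a1_range basal and peak transcription rates
#'   (molecules/hour, per unit volume).
#' @param kappa_range von-Mises-style bump concentration (larger = sharper).
#' @param beta_range,gamma_range splicing and degradation rates (1/hour).
#' @param flat_alpha_range transcription rates for flat genes.
#' @param period cycle period T in hours.
#' @param growth_factor per-cycle volume fold (2 = symmetric division).
#' @param capture_efficiency fraction of molecules captured as UMIs, in (0,1].
#' @param age_distribution "uniform" (default) or "growth-biased"
#'   (\eqn{p(\theta) \propto 2^{1-\theta}}, as in an exponentially growing
#'   culture).
#' @param arrested_fraction fraction of cells arrested out of the cycle
#'   (default 0 = none).
#' @param arrested_phase phase at which arrested cells sit (mid-G1-like).
#' @param arrested_scale fold up-scaling of arrest marker genes in arrested
#'   cells.
#' @param n_arrest_markers number of flat genes acting as arrest markers.
#' @param n_grid phase-grid resolution for the periodic ODE solution.
#' @param seed integer RNG seed; identical configs give identical datasets.
#' @return a \code{SimulationConfig} list.
#' @export
sim_config <- function(n_cells = 2000L,
                       n_cycling_genes = 80L,
                       n_flat_genes = 120L,
                       a0_range = c(0.5, 2),
                       a1_range = c(5, 15),
                       kappa_range = c(3, 8),
                       beta_range = c(0.5, 1.2),
                       gamma_range = c(0.2, 0.6),
                       flat_alpha_range = c(2, 8),
                       period = 20,
                       growth_factor = 2,
                       capture_efficiency = 0.2,
                       age_distribution = c("uniform", "growth-biased"),
                       arrested_fraction = 0,
                       arrested_phase = 0.35,
                       arrested_scale = 4,
                       n_arrest_markers = 10L,
                       n_grid = 200L,
                       seed = 0L) {
  age_distribution <- match.arg(age_distribution)
  cfg <- list(n_cells = as.integer(n_cells),
              n_cycling_genes = as.integer(n_cycling_genes),
              n_flat_genes = as.integer(n_flat_genes),
              a0_range = a0_range, a1_range = a1_range,
              kappa_range = kappa_range,
              beta_range = beta_range, gamma_range = gamma_range,
              flat_alpha_range = flat_alpha_range,
              period = period, growth_factor = growth_factor,
              capture_efficiency = capture_efficiency,
              age_distribution = age_distribution,
              arrested_fraction = arrested_fraction,
              arrested_phase = arrested_phase,
              arrested_scale = arrested_scale,
              n_arrest_markers = as.integer(n_arrest_markers),
              n_grid = as.integer(n_grid),
              seed = as.integer(seed))
  stopifnot(cfg$n_cells >= 1L,
            all(c(cfg$a0_range, cfg$a1_range, cfg$beta_range,
                  cfg$gamma_range, cfg$flat_alpha_range) > 0),
            cfg$period > 0, cfg$growth_factor >= 1,
            cfg$capture_efficiency > 0, cfg$capture_efficiency <= 1,
            cfg$arrested_fraction >= 0, cfg$arrested_fraction < 1,
            cfg$arrested_phase >= 0, cfg$arrested_phase < 1,
            cfg$n_grid >= 8L)
  if (cfg$n_cycling_genes + cfg$n_flat_genes == 0L) {
    stop("at least one gene (cycling or flat) is required")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Periodic solution of the transcription-splicing-degradation ODE
#'
#' Integrates \eqn{du/dt = \alpha(\theta) - \beta u},
#' \eqn{ds/dt = \beta u - \gamma s} with \eqn{\theta = t/T} over repeated
#' cycles until successive cycles agree to \code{1e-8} in sup-norm, and
#' returns the unique periodic orbit sampled on a uniform phase grid.
#'
#' @param alpha function mapping phase in \code{[0,1)} to a transcription
#'   rate (must be periodic and vectorized).
#' @param beta,gamma splicing and degradation rates (> 0).
#' @param T_period cycle period in the same time units as the rates.
#' @param n_grid number of phase grid points (>= 8).
#' @param tol sup-norm convergence tolerance between cycles.
#' @param max_cycles integration budget before giving up.
#' @return list with \code{theta} (grid in \code{[0,1)}), \code{u}, \code{s}
#'   (non-negative), all of length \code{n_grid}.
#' @export
periodic_kinetics <- function(alpha, beta, gamma, T_period, n_grid = 200L,
                              tol = 1e-8, max_cycles = 200L) {
  stopifnot(is.function(alpha), beta > 0, gamma > 0, T_period > 0,
            n_grid >= 8L)
  times <- seq(0, T_period, length.out = n_grid + 1L)
  rhs <- function(t, y, parms) {
    a <- alpha(wrap_phase(t / T_period))
    list(c(a - beta * y[1L], beta * y[1L] - gamma * y[2L]))
  }
  y0 <- c(u = alpha(0) / beta, s = alpha(0) / gamma)
  prev <- NULL
  for (cyc in seq_len(max_cycles)) {
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    traj <- sol[, c("u", "s"), drop = FALSE]
    if (!is.null(prev) && max(abs(traj - prev)) < tol) {
      out <- list(theta = times[-length(times)] / T_period,
                  u = pmax(traj[-nrow(traj), "u"], 0),
                  s = pmax(traj[-nrow(traj), "s"], 0))
      return(out)
    }
    prev <- traj
    y0 <- traj[nrow(traj), ]
  }
  stop(sprintf(
    "periodic solution did not converge in %d cycles (residual %.3g)",
    max_cycles, max(abs(traj - prev))))
}

# periodic bump transcription rate, normalized so the peak value is a0 + a1
bump_alpha <- function(a0, a1, kappa, phi) {
  force(a0); force(a1); force(kappa); force(phi)
  function(theta) a0 + a1 * exp(kappa * (cos(2 * pi * (theta - phi)) - 1))
}

# inverse-cdf sampler for the growth-biased age distribution
# p(theta) proportional to 2^(1 - theta) on [0, 1)
sample_age <- function(n, distribution) {
  v <- runif(n)
  if (distribution == "uniform") return(v)
  # CDF F(t) = 2 (1 - 2^-t); invert for inverse-cdf sampling
  -log2(1 - v / 2)
}

#' Simulate a cell population with ground-truth phases
#'
#' Draws a cell population from the kinetic model described in
#' \code{\link{sim_config}}. Each cycling cell gets an age \eqn{\theta} from
#' the configured age distribution; expected molecule numbers are the
#' periodic-orbit concentrations times the volume \eqn{V(\theta)}; observed
#' counts are Poisson with mean \code{capture_efficiency} times the
#' expectation. Arrested cells (if any) sit at \code{arrested_phase} with
#' their arrest marker genes up-scaled.
#'
#' The planted per-gene parameters, including the phases \code{phi_s} and
#' \code{phi_u} at which the volume-scaled spliced and unspliced
#' expectations peak (these lag the transcription peak \code{phi} by the
#' kinetic response times), are attached as \code{attr(ds, "sim_params")}.
#'
#' @param cfg a \code{\link{sim_config}} object.
#' @return an \code{\link{ExpressionDataset}} with \code{true_phase} and
#'   \code{true_labels} filled in.
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  n_cyc <- cfg$n_cycling_genes
  n_flat <- cfg$n_flat_genes
  n_genes <- n_cyc + n_flat
  gene_ids <- c(sprintf("CYC%03d", seq_len(n_cyc)),
                sprintf("FLAT%03d", seq_len(n_flat)))

  runif2 <- function(n, r) runif(n, r[1L], r[2L])
  params <- data.frame(
    gene = gene_ids,
    type = rep(c("cycling", "flat"), c(n_cyc, n_flat)),
    a0 = c(runif2(n_cyc, cfg$a0_range), runif2(n_flat, cfg$flat_alpha_range)),
    a1 = c(runif2(n_cyc, cfg$a1_range), rep(0, n_flat)),
    kappa = c(runif2(n_cyc, cfg$kappa_range), rep(0, n_flat)),
    phi = c(if (n_cyc > 0) (seq_len(n_cyc) - 1) / n_cyc else numeric(0),
            rep(NA_real_, n_flat)),
    beta = c(runif2(n_cyc, cfg$beta_range), runif2(n_flat, cfg$beta_range)),
    gamma = c(runif2(n_cyc, cfg$gamma_range), runif2(n_flat, cfg$gamma_range)),
    stringsAsFactors = FALSE)

  grid <- (seq_len(cfg$n_grid) - 1L) / cfg$n_grid
  Vgrid <- cfg$growth_factor^grid
  U_curve <- matrix(0, cfg$n_grid, n_genes)
  S_curve <- matrix(0, cfg$n_grid, n_genes)
  for (g in seq_len(n_genes)) {
    if (params$type[g] == "cycling") {
      orb <- periodic_kinetics(
        bump_alpha(params$a0[g], params$a1[g], params$kappa[g], params$phi[g]),
        params$beta[g], params$gamma[g], cfg$period, cfg$n_grid)
      U_curve[, g] <- orb$u
      S_curve[, g] <- orb$s
    } else {
      U_curve[, g] <- params$a0[g] / params$beta[g]
      S_curve[, g] <- params$a0[g] / params$gamma[g]
    }
  }
  # phases where the observable (volume-scaled) expectations peak
  params$phi_u <- grid[apply(U_curve * Vgrid, 2L, which.max)]
  params$phi_s <- grid[apply(S_curve * Vgrid, 2L, which.max)]
  params$phi_u[params$type == "flat"] <- NA_real_
  params$phi_s[params$type == "flat"] <- NA_real_

  n_arr <- round(cfg$arrested_fraction * cfg$n_cells)
  n_cycling_cells <- cfg$n_cells - n_arr
  theta <- c(sample_age(n_cycling_cells, cfg$age_distribution),
             rep(cfg$arrested_phase, n_arr))
  labels <- rep(c("cycling", "arrested"), c(n_cycling_cells, n_arr))

  # interpolate the periodic curves at each cell's phase (circular)
  interp_circ <- function(curve, th) {
    pos <- th * cfg$n_grid
    i0 <- floor(pos) %% cfg$n_grid
    i1 <- (i0 + 1L) %% cfg$n_grid
    w <- pos - floor(pos)
    curve[i0 + 1L, , drop = FALSE] * (1 - w) +
      curve[i1 + 1L, , drop = FALSE] * w
  }
  EU <- interp_circ(U_curve, theta)
  ES <- interp_circ(S_curve, theta)
  V <- cfg$growth_factor^theta
  lamU <- cfg$capture_efficiency * EU * V
  lamS <- cfg$capture_efficiency * ES * V

  markers <- character(0)
  if (n_arr > 0L && cfg$n_arrest_markers > 0L) {
    markers <- gene_ids[params$type == "flat"]
    markers <- utils::head(markers, cfg$n_arrest_markers)
    mcols <- match(markers, gene_ids)
    arr <- labels == "arrested"
    lamU[arr, mcols] <- lamU[arr, mcols] * cfg$arrested_scale
    lamS[arr, mcols] <- lamS[arr, mcols] * cfg$arrested_scale
  }

  U <- matrix(rpois(length(lamU), lamU), nrow = cfg$n_cells)
  S <- matrix(rpois(length(lamS), lamS), nrow = cfg$n_cells)
  total <- rowSums(S) + rowSums(U)
  if (any(total == 0)) {
    # resample empty droplets once; with realistic rates this is vanishing
    for (i in which(total == 0)) {
      U[i, ] <- rpois(n_genes, lamU[i, ])
      S[i, ] <- rpois(n_genes, lamS[i, ])
      if (sum(U[i, ]) + sum(S[i, ]) == 0) S[i, which.max(lamS[i, ])] <- 1L
    }
  }
  ds <- ExpressionDataset(S, U,
                          cell_ids = sprintf("cell%04d", seq_len(cfg$n_cells)),
                          gene_ids = gene_ids,
                          true_phase = wrap_phase(theta),
                          true_labels = labels)
  attr(ds, "sim_params") <- params
  attr(ds, "sim_config") <- cfg
  attr(ds, "arrest_markers") <- markers
  ds
}

#' Marker gene lists derived from planted peak phases
#'
#' For simulated datasets, returns S-like, G2M-like and cyclin-E-like marker
#' lists by selecting cycling genes whose volume-scaled spliced expectation
#' peaks inside phase windows placed where the corresponding real marker
#' programs peak (S markers mid-cycle, G2M markers late, cyclin E just before
#' S entry), with mitosis at \eqn{\theta = 1} by construction of the
#' simulator (division resets volume at \eqn{\theta = 1}).
#'
#' @param ds a simulated \code{ExpressionDataset}.
#' @param s_window,g2m_window,cyclin_e_window phase windows in cycles.
#' @return list with \code{s_genes}, \code{g2m_genes}, \code{cyclin_e_genes}.
#' @export
sim_marker_lists <- function(ds,
                             s_window = c(0.45, 0.65),
                             g2m_window = c(0.75, 0.95),
                             cyclin_e_window = c(0.33, 0.45)) {
  par <- attr(ds, "sim_params")
  if (is.null(par)) stop("dataset carries no planted simulation parameters")
  cyc <- par[par$type == "cycling", ]
  inside <- function(w) cyc$gene[cyc$phi_s >= w[1L] & cyc$phi_s < w[2L]]
  out <- list(s_genes = inside(s_window),
              g2m_genes = inside(g2m_window),
              cyclin_e_genes = inside(cyclin_e_window))
  if (any(lengths(out) == 0L)) {
    warning("some marker windows contain no planted genes")
  }
  out
}
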