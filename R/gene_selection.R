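#' Fit a two-component bivariate Gaussian mixture by EM
#'
#' Cycling genes show two attractors in the spliced-unspliced plane (an
#' active and an inactive expression state). This fits a mixture of two
#' bivariate Gaussians with full covariances by expectation-maximization,
#' taking the best of \code{n_init} restarts with kmeans++-style seeding.
#'
#' @param points n x 2 matrix of (s, u) values, n >= 10.
#' @param n_init number of EM restarts (default 5).
#' @param max_iter EM iteration cap per restart (default 500).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @param seed RNG seed for the restarts; results are deterministic given it.
#' @return a \code{MixtureFit}: \code{weights}, \code{means} (2 x 2, rows =
#'   components), \code{covariances} (list of two 2 x 2 matrices),
#'   \code{log_likelihood}, \code{responsibilities} (n x 2), and a
#'   \code{degenerate} flag set when a component collapses (weight below
#'   1e-3 or covariance condition number above 1e8).
#' @export
fit_two_gaussian_mixture <- function(points, n_init = 5L, max_iter = 500L,
                                     tol = 1e-6, seed = 0L) {
  points <- as.matrix(points)
  if (nrow(points) < 10L) {
    stop(sprintf("need at least 10 points, got %d", nrow(points)))
  }
  stopifnot(ncol(points) == 2L, all(is.finite(points)))
  n <- nrow(points)

  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  for (init in seq_len(n_init)) {
    # kmeans++-style seeding: second center drawn with prob ~ squared distance
    c1 <- points[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(points, 2L, c1)^2)
    if (all(d2 == 0)) d2 <- rep(1, n)
    c2 <- points[sample.int(n, 1L, prob = d2), ]
    assign1 <- rowSums(sweep(points, 2L, c1)^2) <=
      rowSums(sweep(points, 2L, c2)^2)
    fit <- em_gmm2(points, assign1, max_iter, tol)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  best$degenerate <- min(best$weights) < 1e-3 ||
    any(vapply(best$covariances, function(S) kappa(S, exact = TRUE), 0) > 1e8)
  class(best) <- "MixtureFit"
  best
}

# EM core for a 2-component bivariate Gaussian mixture from a hard split
em_gmm2 <- function(X, assign1, max_iter, tol) {
  n <- nrow(X)
  R <- cbind(as.numeric(assign1), as.numeric(!assign1))
  # guard a one-sided initial split
  if (sum(R[, 1L]) < 2 || sum(R[, 2L]) < 2) R <- matrix(0.5, n, 2L)
  ridge <- 1e-10 * sum(diag(stats::cov(X)))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-10
  ll_old <- -Inf
  w <- c(0.5, 0.5); mu <- list(); S <- list()
  for (iter in seq_len(max_iter)) {
    # M step
    nk <- colSums(R)
    w <- nk / n
    for (k in 1:2) {
      mu[[k]] <- colSums(X * R[, k]) / nk[k]
      Xc <- sweep(X, 2L, mu[[k]])
      S[[k]] <- crossprod(Xc * R[, k], Xc) / nk[k] + diag(ridge, 2L)
    }
    # E step
    logd <- vapply(1:2, function(k) {
      dmvnorm2_log(X, mu[[k]], S[[k]]) + log(w[k])
    }, numeric(n))
    m <- pmax(logd[, 1L], logd[, 2L])
    lse <- m + log(exp(logd[, 1L] - m) + exp(logd[, 2L] - m))
    R <- exp(logd - lse)
    ll <- sum(lse)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = w,
       means = rbind(mu[[1L]], mu[[2L]]),
       covariances = S,
       log_likelihood = ll,
       responsibilities = R,
       n_iter = iter)
}

# log-density of a bivariate normal, stable via Cholesky
dmvnorm2_log <- function(X, mu, S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    S <- S + diag(1e-8 * sum(diag(S)) / 2, 2L)
    ch <- chol(S)
  }
  Xc <- sweep(X, 2L, mu)
  z <- backsolve(ch, t(Xc), transpose = TRUE)
  -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Two-sample Hotelling T-squared separation of the mixture components
#'
#' Hard-assigns points to components by maximum responsibility and computes
#' the two-sample Hotelling statistic
#' \deqn{T^2 = \frac{n_1 n_2}{n_1+n_2}
#'       (\bar x_1-\bar x_2)^\top S_{pooled}^{-1} (\bar x_1-\bar x_2)}
#' with its F-transform p-value (dimension 2). Used to keep only genes whose
#' two expression attractors are significantly distinct.
#'
#' @param fit a \code{MixtureFit}.
#' @param points the n x 2 matrix the mixture was fitted to.
#' @return the fit with \code{T2}, \code{p_value} and \code{assignment}
#'   fields added.
#' @export
hotelling_separation <- function(fit, points) {
  points <- as.matrix(points)
  g1 <- fit$responsibilities[, 1L] >= fit$responsibilities[, 2L]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (min(n1, n2) < 3L) {
    stop(sprintf("component group sizes %d/%d; need >= 3 each", n1, n2))
  }
  X1 <- points[g1, , drop = FALSE]
  X2 <- points[!g1, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  Sp <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  if (!is.finite(rcond_2x2(Sp)) || rcond_2x2(Sp) < 1e-12) {
    warning("singular pooled covariance; regularizing")
    Sp <- Sp + diag(1e-8 * sum(diag(Sp)) / 2, 2L)
  }
  d <- m1 - m2
  T2 <- as.numeric(n1 * n2 / (n1 + n2) * crossprod(d, solve(Sp, d)))
  p <- 2
  df2 <- n1 + n2 - p - 1
  Fstat <- T2 * df2 / (p * (n1 + n2 - 2))
  pval <- stats::pf(Fstat, p, df2, lower.tail = FALSE)
  fit$T2 <- T2
  fit$p_value <- pval
  fit$assignment <- ifelse(g1, 1L, 2L)
  fit
}

rcond_2x2 <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Count high-density branches connecting the two mixture attractors
#'
#' A cycling gene traverses its two expression states along two distinct
#' branches (activation and deactivation), forming a loop in the (s, u)
#' plane; a gene that merely spreads along one axis has a single branch.
#' The point density is turned into a landscape
#' (\code{\link{build_landscape}}), sliced perpendicular to the segment
#' joining the two component means, density ridge peaks are located in each
#' slice of the corridor between the attractor neighborhoods (1 Mahalanobis
#' unit around each mean), and peaks are chained across adjacent slices.
#' The number of disjoint chains spanning the corridor is returned.
#'
#' @param points n x 2 matrix of (s, u) values.
#' @param fit a non-degenerate \code{MixtureFit} for these points.
#' @param n_slices number of corridor slices (default 20).
#' @return integer branch count (0, 1, 2, ...).
#' @export
count_branches <- function(points, fit, n_slices = 20L) {
  points <- as.matrix(points)
  if (isTRUE(fit$degenerate)) stop("branch counting requires a non-degenerate fit")
  chains <- trace_density_chains(points, fit$means[1L, ], fit$means[2L, ],
                                 n_slices = n_slices,
                                 cov1 = fit$covariances[[1L]],
                                 cov2 = fit$covariances[[2L]])
  chains$n_spanning
}

# Shared slicing machinery: build a density landscape over the points,
# slice the corridor between the attractors perpendicular to the a->b
# axis, find per-slice local minima of V (density ridge peaks), and chain
# them across slices by nearest neighbor with a small gap tolerance.
trace_density_chains <- function(points, a, b, n_slices = 20L,
                                 cov1 = NULL, cov2 = NULL, L = NULL) {
  axis <- b - a
  len <- sqrt(sum(axis^2))
  empty <- list(n_spanning = 0L, chains = list(), slice_centers = numeric(0))
  if (len == 0) return(empty)
  if (is.null(L)) {
    L <- tryCatch(build_landscape(points, grid_size = 80L),
                  error = function(e) NULL)
    if (is.null(L)) return(empty)
  }
  e1 <- axis / len
  e2 <- c(-e1[2L], e1[1L])

  # corridor: exclude up to 1 Mahalanobis unit (capped at a quarter of the
  # axis) around each attractor, where the branches merge
  mah_extent <- function(S) {
    if (is.null(S)) return(0.05 * len)
    sqrt(max(as.numeric(crossprod(e1, S %*% e1)), 0))
  }
  t_lo <- min(mah_extent(cov1) / len, 0.25)
  t_hi <- 1 - min(mah_extent(cov2) / len, 0.25)
  if (t_hi <= t_lo) return(empty)

  centers <- seq(t_lo, t_hi, length.out = n_slices)
  diag_len <- sqrt(diff(range(L$x))^2 + diff(range(L$y))^2)
  w_grid <- seq(-diag_len / 2, diag_len / 2, length.out = 201L)
  v_cut <- -log(0.02 * max(L$dens) + L$eps)   # density >= 2% of the mode

  # projected point coordinates, for the data-support requirement: a KDE
  # ridge only counts as a branch where actual cells sit under it
  tt <- as.numeric(sweep(points, 2L, a) %*% e1) / len
  ww <- as.numeric(sweep(points, 2L, a) %*% e2)
  half_strip <- if (n_slices > 1L) (centers[2L] - centers[1L]) else 0.5
  support_w <- max(1.5 * mean(L$bandwidth), half_strip * len)

  peaks <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    centre <- a + centers[i] * len * e1
    pts <- cbind(centre[1L] + w_grid * e2[1L], centre[2L] + w_grid * e2[2L])
    inside <- pts[, 1L] >= min(L$x) & pts[, 1L] <= max(L$x) &
      pts[, 2L] >= min(L$y) & pts[, 2L] <= max(L$y)
    if (sum(inside) < 3L) next
    v <- landscape_potential(L, pts[inside, , drop = FALSE])
    w <- w_grid[inside]
    is_min <- v < c(Inf, v[-length(v)]) & v <= c(v[-1L], Inf) & v < v_cut
    if (!any(is_min)) next
    in_strip <- abs(tt - centers[i]) <= half_strip
    wk <- w[is_min]
    supported <- vapply(wk, function(w0) {
      any(in_strip & abs(ww - w0) <= support_w)
    }, logical(1L))
    if (any(supported)) peaks[[i]] <- wk[supported]
  }
  informative <- !vapply(peaks, is.null, logical(1L))
  inf_idx <- which(informative)
  if (length(inf_idx) < 3L) {
    warning("fewer than 3 informative slices; returning 0 branches")
    return(list(n_spanning = 0L, chains = list(), slice_centers = centers))
  }

  max_jump <- 3 * mean(L$bandwidth) + 0.02 * diag_len
  max_gap <- 2L            # a chain may skip up to 2 slices
  chains <- lapply(peaks[[inf_idx[1L]]], function(w0) {
    list(slice = inf_idx[1L], w = w0)
  })
  for (j in seq_along(inf_idx)[-1L]) {
    i <- inf_idx[j]
    pk <- peaks[[i]]
    taken <- rep(FALSE, length(pk))
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      last <- ch$slice[length(ch$slice)]
      if (i - last > max_gap + 1L || length(pk) == 0L) next
      dists <- abs(pk - ch$w[length(ch$w)])
      dists[taken] <- Inf
      best <- which.min(dists)
      if (is.finite(dists[best]) && dists[best] <= max_jump) {
        chains[[ci]]$slice <- c(ch$slice, i)
        chains[[ci]]$w <- c(ch$w, pk[best])
        taken[best] <- TRUE
      }
    }
    for (k in which(!taken)) {
      chains[[length(chains) + 1L]] <- list(slice = i, w = pk[k])
    }
  }
  # branch count: the maximal number of ridge peaks that coexist over a
  # sustained contiguous stretch of slices spanning the corridor midpoint.
  # Branches merge near the attractors, so chains are not required to span
  # the whole corridor, but paths that connect the two attractors must
  # cross the middle -- ridges confined to an attractor flank (e.g. the
  # blurred tails of two isolated clusters) do not count.
  n_inf <- length(inf_idx)
  npk_full <- lengths(peaks)
  win <- max(4L, ceiling(0.25 * n_inf))
  win <- min(win, n_slices)
  n_branches <- 0L
  for (j in seq_len(n_slices - win + 1L)) {
    idx <- j:(j + win - 1L)
    n_branches <- max(n_branches, min(npk_full[idx]))
  }
  spans <- vapply(chains, function(ch) {
    length(ch$slice) >= win
  }, logical(1L))
  coords <- lapply(chains, function(ch) {
    t_abs <- centers[ch$slice]
    cbind(a[1L] + t_abs * len * e1[1L] + ch$w * e2[1L],
          a[2L] + t_abs * len * e1[2L] + ch$w * e2[2L])
  })
  list(n_spanning = n_branches, chains = coords[spans],
       all_chains = coords, slice_centers = centers)
}

#' Scan a dataset for cycling genes
#'
#' Runs the mixture fit, Hotelling separation test and branch count on the
#' smoothed (s, u) values of every requested gene. A gene is selected when
#' the fit is non-degenerate, the Benjamini-Hochberg adjusted p-value is
#' below \code{alpha_level}, and at least two branches connect the
#' attractors. Per-gene failures are recorded as flags; the scan never
#' aborts on a single gene.
#'
#' @param ds an \code{ExpressionDataset} with smoothed layers.
#' @param gene_list optional restriction (e.g. a cell-cycle GO list);
#'   default all genes.
#' @param alpha_level FDR threshold on adjusted p-values (default 0.01).
#' @param n_slices slices for branch counting.
#' @param exclude optional genes to drop before scanning (supervised
#'   filtering hook).
#' @param seed seed for the EM restarts.
#' @return data.frame with columns \code{gene}, \code{T2}, \code{p},
#'   \code{q}, \code{n_branches}, \code{degenerate}, \code{failed},
#'   \code{selected}, sorted by \code{T2} descending. The per-gene fits are
#'   attached as \code{attr(, "fits")}.
#' @export
select_cycling_genes <- function(ds, gene_list = NULL, alpha_level = 0.01,
                                 n_slices = 20L, exclude = NULL, seed = 0L) {
  stopifnot(is(ds, "ExpressionDataset"))
  if (is.null(ds$S_smooth)) stop("run knn_smooth() before gene selection")
  genes <- if (is.null(gene_list)) ds$gene_ids else
    intersect(ds$gene_ids, gene_list)
  genes <- setdiff(genes, exclude)
  if (length(genes) == 0L) stop("no genes to scan")

  res <- data.frame(gene = genes, T2 = NA_real_, p = NA_real_,
                    n_branches = NA_integer_, degenerate = FALSE,
                    failed = FALSE, stringsAsFactors = FALSE)
  fits <- vector("list", length(genes))
  names(fits) <- genes
  for (i in seq_along(genes)) {
    g <- genes[i]
    pts <- cbind(ds$S_smooth[, g], ds$U_smooth[, g])
    fit <- tryCatch({
      f <- fit_two_gaussian_mixture(pts, seed = seed + i)
      f <- hotelling_separation(f, pts)
      f
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      res$failed[i] <- TRUE
      next
    }
    res$T2[i] <- fit$T2
    res$p[i] <- fit$p_value
    res$degenerate[i] <- fit$degenerate
    fits[[i]] <- fit
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  # branch counting only where the separation already passes (it is the
  # expensive step and cannot rescue a non-significant gene)
  for (i in seq_along(genes)) {
    fit <- fits[[i]]
    if (is.null(fit) || res$degenerate[i] || is.na(res$q[i]) ||
        res$q[i] >= alpha_level) next
    pts <- cbind(ds$S_smooth[, genes[i]], ds$U_smooth[, genes[i]])
    nb <- tryCatch(
      suppressWarnings(count_branches(pts, fit, n_slices = n_slices)),
      error = function(e) NA_integer_)
    res$n_branches[i] <- nb
  }
  res$selected <- !res$failed & !res$degenerate &
    !is.na(res$q) & res$q < alpha_level &
    !is.na(res$n_branches) & res$n_branches >= 2L
  res <- res[order(-res$T2, res$gene), ]
  rownames(res) <- NULL
  attr(res, "fits") <- fits
  res
}
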