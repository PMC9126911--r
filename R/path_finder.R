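#' Build a density landscape over a 2-D embedding
#'
#' Gaussian kernel density estimate on a regular grid, converted to the
#' potential \eqn{V = -\log(\hat f + \epsilon)} with
#' \eqn{\epsilon = 10^{-6} \max \hat f}. High-density ridges of the cells
#' become valleys of \eqn{V}, so minimum-energy-path methods apply
#' directly. Bandwidths default to Scott's rule per axis.
#'
#' @param points n x 2 matrix (n >= 20).
#' @param grid_size number of grid nodes per axis (default 100).
#' @param bandwidth length-2 kernel standard deviations; Scott's rule
#'   (\eqn{\sigma_j n^{-1/6}}) when NULL.
#' @param pad fractional padding of the data range (default 0.1).
#' @return a \code{Landscape}: grid vectors \code{x}, \code{y}, potential
#'   matrix \code{V} (rows = x), density \code{dens}, \code{bandwidth},
#'   \code{eps}, and precomputed gradient arrays.
#' @export
build_landscape <- function(points, grid_size = 100L, bandwidth = NULL,
                            pad = 0.1) {
  points <- as.matrix(points)
  if (nrow(points) < 20L) {
    stop(sprintf("need at least 20 points for a landscape, got %d",
                 nrow(points)))
  }
  stopifnot(ncol(points) == 2L, all(is.finite(points)))
  sds <- apply(points, 2L, stats::sd)
  if (any(sds == 0)) stop("degenerate point cloud: zero variance along an axis")
  if (is.null(bandwidth)) {
    bandwidth <- sds * nrow(points)^(-1 / 6)   # Scott's rule, d = 2
  }
  rng_x <- range(points[, 1L]); rng_y <- range(points[, 2L])
  ex <- pad * diff(rng_x); ey <- pad * diff(rng_y)
  # MASS::kde2d uses h/4 as the gaussian sd, so scale accordingly
  kd <- MASS::kde2d(points[, 1L], points[, 2L],
                    h = 4 * bandwidth, n = grid_size,
                    lims = c(rng_x[1L] - ex, rng_x[2L] + ex,
                             rng_y[1L] - ey, rng_y[2L] + ey))
  eps <- 1e-6 * max(kd$z)
  V <- -log(kd$z + eps)
  dx <- kd$x[2L] - kd$x[1L]
  dy <- kd$y[2L] - kd$y[1L]
  grad_x <- (rbind(V[-1L, ], V[nrow(V), ]) -
             rbind(V[1L, ], V[-nrow(V), ])) /
    matrix(c(dx, rep(2 * dx, nrow(V) - 2L), dx), nrow(V), ncol(V))
  grad_y <- (cbind(V[, -1L], V[, ncol(V)]) -
             cbind(V[, 1L], V[, -ncol(V)])) /
    matrix(rep(c(dy, rep(2 * dy, ncol(V) - 2L), dy), each = nrow(V)),
           nrow(V), ncol(V))
  structure(list(x = kd$x, y = kd$y, V = V, dens = kd$z,
                 bandwidth = bandwidth, eps = eps,
                 grad_x = grad_x, grad_y = grad_y,
                 spacing = c(dx, dy)),
            class = "Landscape")
}

#' @export
print.Landscape <- function(x, ...) {
  cat(sprintf("Landscape: %d x %d grid, V in [%.2f, %.2f]\n",
              length(x$x), length(x$y), min(x$V), max(x$V)))
  invisible(x)
}

# bilinear interpolation of a grid matrix at K x 2 points (clamped)
interp_grid <- function(gx, gy, M, pts) {
  ix <- findInterval(pts[, 1L], gx, all.inside = TRUE)
  iy <- findInterval(pts[, 2L], gy, all.inside = TRUE)
  x0 <- gx[ix]; x1 <- gx[ix + 1L]
  y0 <- gy[iy]; y1 <- gy[iy + 1L]
  tx <- pmin(pmax((pts[, 1L] - x0) / (x1 - x0), 0), 1)
  ty <- pmin(pmax((pts[, 2L] - y0) / (y1 - y0), 0), 1)
  M[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    M[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    M[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    M[cbind(ix + 1L, iy + 1L)] * tx * ty
}

#' Evaluate the landscape potential at arbitrary points
#' @param L a \code{Landscape}.
#' @param pts K x 2 matrix of coordinates (clamped to the grid).
#' @return numeric vector of potential values.
#' @export
landscape_potential <- function(L, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  interp_grid(L$x, L$y, L$V, pts)
}

landscape_gradient <- function(L, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  cbind(interp_grid(L$x, L$y, L$grad_x, pts),
        interp_grid(L$x, L$y, L$grad_y, pts))
}

#' Coarse high-density path between two endpoints
#'
#' Slices the landscape perpendicular to the segment joining \code{a} and
#' \code{b}, locates the density ridge peaks in each slice, chains them
#' across adjacent slices by nearest neighbor, and returns the chain with
#' the lowest mean potential, anchored at \code{a} and \code{b}. All
#' candidate chains are attached for branch inspection. Slices without an
#' interior peak are interpolated through with a warning.
#'
#' @param L a \code{Landscape}.
#' @param a,b endpoints (length-2 coordinates inside the grid).
#' @param n_slices number of slices (default 30).
#' @return a \code{PathCurve}: \code{images} (K x 2), \code{fixed_endpoints},
#'   \code{converged} (NA until refined), per-image \code{V}; candidate
#'   chains in \code{attr(, "chains")}. When no chain reaches both anchors
#'   the result has zero interior images and \code{attr(, "no_path")}.
#' @export
coarse_path <- function(L, a, b, n_slices = 30L) {
  a <- as.numeric(a); b <- as.numeric(b)
  in_grid <- function(p) p[1L] >= min(L$x) && p[1L] <= max(L$x) &&
    p[2L] >= min(L$y) && p[2L] <= max(L$y)
  if (!in_grid(a) || !in_grid(b)) stop("endpoints must lie inside the grid")

  axis <- b - a
  len <- sqrt(sum(axis^2))
  if (len == 0) stop("endpoints coincide")
  e1 <- axis / len
  e2 <- c(-e1[2L], e1[1L])
  # perpendicular extent: cover the whole grid
  diag_len <- sqrt(diff(range(L$x))^2 + diff(range(L$y))^2)
  w_grid <- seq(-diag_len / 2, diag_len / 2, length.out = 201L)

  t_centers <- (seq_len(n_slices) - 0.5) / n_slices
  peaks <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    centre <- a + t_centers[i] * len * e1
    pts <- cbind(centre[1L] + w_grid * e2[1L], centre[2L] + w_grid * e2[2L])
    inside <- pts[, 1L] >= min(L$x) & pts[, 1L] <= max(L$x) &
      pts[, 2L] >= min(L$y) & pts[, 2L] <= max(L$y)
    if (sum(inside) < 3L) next
    v <- landscape_potential(L, pts[inside, , drop = FALSE])
    w <- w_grid[inside]
    is_min <- v < c(Inf, v[-length(v)]) & v <= c(v[-1L], Inf)
    # keep minima carrying meaningful density (>= 2% of the mode)
    is_min <- is_min & v < -log(0.02 * max(L$dens) + L$eps)
    if (any(is_min)) {
      peaks[[i]] <- data.frame(w = w[is_min], V = v[is_min])
    }
  }

  have <- !vapply(peaks, is.null, logical(1L))
  if (!any(have)) {
    out <- structure(list(images = rbind(a, b), fixed_endpoints = TRUE,
                          converged = NA, V = landscape_potential(L, rbind(a, b))),
                     class = "PathCurve")
    attr(out, "no_path") <- TRUE
    warning("no slice contains an interior density peak; no path found")
    return(out)
  }
  if (any(!have)) {
    warning(sprintf("%d slice(s) without interior peaks; interpolating through",
                    sum(!have)))
  }

  # chain peaks across informative slices (nearest neighbor in w)
  inf_idx <- which(have)
  w_scale <- diag_len / 6
  chains <- lapply(seq_len(nrow(peaks[[inf_idx[1L]]])), function(r) {
    list(slice = inf_idx[1L], w = peaks[[inf_idx[1L]]]$w[r],
         V = peaks[[inf_idx[1L]]]$V[r])
  })
  for (j in seq_along(inf_idx)[-1L]) {
    i <- inf_idx[j]
    pk <- peaks[[i]]
    taken <- rep(FALSE, nrow(pk))
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      # allow a chain to bridge up to 2 missing slices
      if (i - ch$slice[length(ch$slice)] > 3L) next
      dists <- abs(pk$w - ch$w[length(ch$w)])
      dists[taken] <- Inf
      best_k <- which.min(dists)
      if (is.finite(dists[best_k]) && dists[best_k] <= w_scale) {
        chains[[ci]]$slice <- c(ch$slice, i)
        chains[[ci]]$w <- c(ch$w, pk$w[best_k])
        chains[[ci]]$V <- c(ch$V, pk$V[best_k])
        taken[best_k] <- TRUE
      }
    }
    for (k in which(!taken)) {
      chains[[length(chains) + 1L]] <-
        list(slice = i, w = pk$w[k], V = pk$V[k])
    }
  }

  spans <- vapply(chains, function(ch) {
    ch$slice[1L] == inf_idx[1L] &&
      ch$slice[length(ch$slice)] == inf_idx[length(inf_idx)]
  }, logical(1L))
  to_xy <- function(ch) {
    t_abs <- t_centers[ch$slice] * len
    cbind(a[1L] + t_abs * e1[1L] + ch$w * e2[1L],
          a[2L] + t_abs * e1[2L] + ch$w * e2[2L])
  }
  all_xy <- lapply(chains, to_xy)
  if (!any(spans)) {
    out <- structure(list(images = rbind(a, b), fixed_endpoints = TRUE,
                          converged = NA,
                          V = landscape_potential(L, rbind(a, b))),
                     class = "PathCurve")
    attr(out, "no_path") <- TRUE
    attr(out, "chains") <- all_xy
    warning("no peak chain connects both anchors; no path found")
    return(out)
  }
  mean_v <- vapply(chains, function(ch) mean(ch$V), 0)
  mean_v[!spans] <- Inf
  best_chain <- chains[[which.min(mean_v)]]
  images <- rbind(a, to_xy(best_chain), b)
  structure(list(images = unname(images), fixed_endpoints = TRUE,
                 converged = NA,
                 V = landscape_potential(L, images)),
            class = "PathCurve",
            chains = all_xy)
}

#' @export
print.PathCurve <- function(x, ...) {
  cat(sprintf("PathCurve: %d images, mean V = %.3f%s\n",
              nrow(x$images), mean(x$V),
              if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

#' Refine a path with the viscous nudged elastic band
#'
#' Damped chain-of-images dynamics on the landscape: each interior image
#' feels the component of \eqn{-\nabla V} perpendicular to the path
#' tangent plus a tangential spring force
#' \eqn{k (\lVert x_{j+1}-x_j \rVert - \lVert x_j-x_{j-1} \rVert)}, and
#' velocities are damped by the viscosity factor \eqn{(1-\eta)} each step.
#' Endpoints never move. Iteration stops when the largest image
#' displacement in a step falls below \code{tol}.
#'
#' @param path a \code{PathCurve} with K >= 3 images.
#' @param L the \code{Landscape} the path lives on.
#' @param k_spring spring constant (default 1).
#' @param eta viscosity in (0, 1) (default 0.1).
#' @param dt time step; default 0.1 x grid spacing.
#' @param tol convergence threshold on displacement; default 1e-3 x grid
#'   spacing.
#' @param max_iter iteration cap (default 5000).
#' @return the refined \code{PathCurve} with \code{converged} set and the
#'   mean-potential history in \code{attr(, "meanV_history")}.
#' @export
vneb_refine <- function(path, L, k_spring = 1, eta = 0.1,
                        dt = NULL, tol = NULL, max_iter = 5000L) {
  stopifnot(is(path, "PathCurve"), is(L, "Landscape"))
  X <- path$images
  K <- nrow(X)
  if (K < 3L) stop("need at least 3 images to refine")
  h <- min(L$spacing)
  if (is.null(dt)) dt <- 0.1 * h
  if (is.null(tol)) tol <- 1e-3 * h
  vel <- matrix(0, K, 2L)
  xr <- range(L$x); yr <- range(L$y)
  meanV <- numeric(0)
  converged <- FALSE
  clamped_warned <- FALSE
  still <- 0L   # consecutive sub-tol steps; guards against stopping before
                # the damped velocities have developed

  for (iter in seq_len(max_iter)) {
    Xold <- X
    interior <- 2:(K - 1L)
    tangent <- X[interior + 1L, , drop = FALSE] -
      X[interior - 1L, , drop = FALSE]
    tnorm <- sqrt(rowSums(tangent^2))
    tnorm[tnorm == 0] <- 1
    tangent <- tangent / tnorm
    g <- landscape_gradient(L, X[interior, , drop = FALSE])
    if (any(!is.finite(g))) stop("non-finite landscape gradient")
    gpar <- rowSums(g * tangent)
    f_perp <- -(g - gpar * tangent)
    d_fwd <- sqrt(rowSums((X[interior + 1L, , drop = FALSE] -
                             X[interior, , drop = FALSE])^2))
    d_bwd <- sqrt(rowSums((X[interior, , drop = FALSE] -
                             X[interior - 1L, , drop = FALSE])^2))
    f_spring <- k_spring * (d_fwd - d_bwd) * tangent
    force <- f_perp + f_spring
    if (any(!is.finite(force))) stop("non-finite NEB force")
    vel[interior, ] <- (1 - eta) * vel[interior, ] + force * dt
    X[interior, ] <- X[interior, ] + vel[interior, ] * dt
    out_x <- X[, 1L] < xr[1L] | X[, 1L] > xr[2L]
    out_y <- X[, 2L] < yr[1L] | X[, 2L] > yr[2L]
    if (any(out_x | out_y)) {
      if (!clamped_warned) {
        warning("image left the grid; clamping to the boundary")
        clamped_warned <- TRUE
      }
      X[, 1L] <- pmin(pmax(X[, 1L], xr[1L]), xr[2L])
      X[, 2L] <- pmin(pmax(X[, 2L], yr[1L]), yr[2L])
    }
    meanV <- c(meanV, mean(landscape_potential(L, X)))
    still <- if (max(abs(X - Xold)) < tol) still + 1L else 0L
    if (still >= 3L && iter >= 10L) {
      converged <- TRUE
      break
    }
  }
  out <- structure(list(images = X, fixed_endpoints = TRUE,
                        converged = converged,
                        V = landscape_potential(L, X)),
                   class = "PathCurve")
  attr(out, "meanV_history") <- meanV
  out
}

#' Compare gene expression along two branch paths
#'
#' Computes a per-gene expression profile along each path (a
#' Gaussian-distance-weighted mean of smoothed spliced counts of cells
#' within \code{radius} of each image, kernel scale \code{radius/2}), then
#' the per-gene log2 fold change of the path means (blue over red, with a
#' pseudocount). Used to contrast the G1-to-S branch against the
#' cycle-exit branch.
#'
#' @param ds an \code{ExpressionDataset} with smoothed layers.
#' @param embedding n_cells x 2 matrix of per-cell coordinates in the same
#'   space as the paths.
#' @param paths named list with \code{PathCurve}s \code{red} and
#'   \code{blue}.
#' @param radius cell-capture radius around each image.
#' @param genes optional gene subset; absent genes are dropped and listed
#'   in \code{attr(, "missing_genes")}.
#' @param pseudocount added to both means before the log ratio.
#' @return data.frame with \code{gene}, \code{mean_red}, \code{mean_blue},
#'   \code{lfc}, sorted by decreasing \code{abs(lfc)}.
#' @export
compare_paths <- function(ds, embedding, paths, radius,
                          genes = NULL, pseudocount = 0.01) {
  stopifnot(is(ds, "ExpressionDataset"),
            all(c("red", "blue") %in% names(paths)))
  if (is.null(ds$S_smooth)) stop("run knn_smooth() first")
  embedding <- as.matrix(embedding)
  stopifnot(nrow(embedding) == length(ds$cell_ids), ncol(embedding) == 2L)
  missing_genes <- character(0)
  if (is.null(genes)) {
    genes <- ds$gene_ids
  } else {
    missing_genes <- setdiff(genes, ds$gene_ids)
    genes <- intersect(genes, ds$gene_ids)
    if (length(genes) == 0L) stop("none of the requested genes are present")
  }
  S <- ds$S_smooth[, genes, drop = FALSE]
  kernel_scale <- radius / 2

  path_profile <- function(path) {
    imgs <- path$images
    covered <- 0L
    acc <- numeric(length(genes))
    wsum <- 0
    for (j in seq_len(nrow(imgs))) {
      d <- sqrt((embedding[, 1L] - imgs[j, 1L])^2 +
                  (embedding[, 2L] - imgs[j, 2L])^2)
      near <- d <= radius
      if (!any(near)) next
      covered <- covered + 1L
      w <- exp(-0.5 * (d[near] / kernel_scale)^2)
      acc <- acc + colSums(S[near, , drop = FALSE] * w)
      wsum <- wsum + sum(w)
    }
    if (covered < nrow(imgs) / 2) {
      stop("path has cells near fewer than half of its images")
    }
    acc / wsum
  }
  prof_red <- path_profile(paths$red)
  prof_blue <- path_profile(paths$blue)
  lfc <- log2((prof_blue + pseudocount) / (prof_red + pseudocount))
  out <- data.frame(gene = genes, mean_red = prof_red,
                    mean_blue = prof_blue, lfc = lfc,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$lfc), out$gene), ]
  rownames(out) <- NULL
  attr(out, "missing_genes") <- missing_genes
  out
}

#' Build a Landscape from an explicit potential matrix
#'
#' Wraps a precomputed potential on a regular grid in the same structure
#' that \code{\link{build_landscape}} produces, so path operations can run
#' on analytic test potentials as well as on density landscapes.
#'
#' @param x,y increasing grid coordinate vectors.
#' @param V potential matrix with \code{dim = c(length(x), length(y))}.
#' @return a \code{Landscape}.
#' @export
as_landscape <- function(x, y, V) {
  stopifnot(nrow(V) == length(x), ncol(V) == length(y),
            all(diff(x) > 0), all(diff(y) > 0), all(is.finite(V)))
  dx <- x[2L] - x[1L]; dy <- y[2L] - y[1L]
  grad_x <- (rbind(V[-1L, ], V[nrow(V), ]) -
             rbind(V[1L, ], V[-nrow(V), ])) /
    matrix(c(dx, rep(2 * dx, nrow(V) - 2L), dx), nrow(V), ncol(V))
  grad_y <- (cbind(V[, -1L], V[, ncol(V)]) -
             cbind(V[, 1L], V[, -ncol(V)])) /
    matrix(rep(c(dy, rep(2 * dy, ncol(V) - 2L), dy), each = nrow(V)),
           nrow(V), ncol(V))
  dens <- exp(-V)
  structure(list(x = x, y = y, V = V, dens = dens,
                 bandwidth = c(dx, dy), eps = min(dens),
                 grad_x = grad_x, grad_y = grad_y,
                 spacing = c(dx, dy)),
            class = "Landscape")
}

#' Build an initial path as a straight chain of images
#'
#' @param a,b endpoints (length-2).
#' @param n_images total number of images including the endpoints (>= 3).
#' @return a \code{PathCurve} with equally spaced images on the segment.
#' @export
straight_path <- function(a, b, n_images = 30L) {
  stopifnot(n_images >= 3L)
  tt <- seq(0, 1, length.out = n_images)
  images <- cbind(a[1L] + tt * (b[1L] - a[1L]),
                  a[2L] + tt * (b[2L] - a[2L]))
  structure(list(images = images, fixed_endpoints = TRUE,
                 converged = NA, V = rep(NA_real_, n_images)),
            class = "PathCurve")
}
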