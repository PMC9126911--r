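#' @keywords internal
"_PACKAGE"

#' @useDynLib cyclephase, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats prcomp rnorm runif rpois sd density approx
#'   pf p.adjust setNames median
#' @importFrom utils read.table write.table head
#' @importFrom methods is
NULL

# population standard deviation (divides by n, not n-1)
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Z-score a per-cell expression vector for one gene
#'
#' Centers to mean zero and scales to unit population standard deviation
#' (dividing by n). Constant vectors map to all zeros rather than NaN, so
#' zero-variance genes never propagate non-finite values downstream.
#'
#' @param values numeric vector of per-cell values for a single gene.
#' @return numeric vector of z-scores with `mean(out) == 0`.
#' @export
zscore_per_gene <- function(values) {
  if (length(values) < 1L) stop("zscore_per_gene: empty input vector")
  if (!all(is.finite(values))) stop("zscore_per_gene: non-finite values")
  m <- mean(values)
  s <- pop_sd(values)
  if (s == 0) return(rep(0, length(values)))
  (values - m) / s
}

# column-wise z-scoring of a cells x genes matrix; returns list(z, mu, sd)
# with zero-sd columns mapped to 0 (sd recorded as 1 so reuse is a no-op)
zscore_matrix <- function(X) {
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)
  sdv[sdv < .Machine$double.eps] <- NA_real_
  Z <- sweep(X, 2L, mu, "-")
  Z <- sweep(Z, 2L, ifelse(is.na(sdv), 1, sdv), "/")
  Z[, is.na(sdv)] <- 0
  list(z = Z, mu = mu, sd = ifelse(is.na(sdv), 1, sdv))
}

# wrap a phase (in cycles) into [0, 1)
wrap_phase <- function(theta) theta - floor(theta)

# circular difference a - b wrapped to (-0.5, 0.5]
circ_diff <- function(a, b) {
  d <- wrap_phase(a - b)
  ifelse(d > 0.5, d - 1, d)
}

#' Circular correlation between two phase variables
#'
#' Fisher-Lee circular correlation coefficient for phases expressed in
#' cycles on \code{[0, 1)}. The statistic is invariant to rotations of
#' either variable and changes sign under reflection, so
#' \code{abs(circular_correlation(x, y))} measures agreement up to an
#' arbitrary rotation and orientation of the circle.
#'
#' @param x,y numeric vectors of phases in cycles.
#' @return correlation in \code{[-1, 1]}.
#' @export
circular_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  a <- 2 * pi * x
  b <- 2 * pi * y
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  num <- 2 * (sum(sa * sb) * sum(ca * cb) - sum(sa * cb) * sum(ca * sb))
  n <- length(x)
  den_a <- (n^2 - sum(cos(2 * a))^2 - sum(sin(2 * a))^2) / 2
  den_b <- (n^2 - sum(cos(2 * b))^2 - sum(sin(2 * b))^2) / 2
  if (den_a <= 0 || den_b <= 0) return(NA_real_)
  num / sqrt(den_a * den_b)
}

# shoelace area of the closed polygon through the rows of a K x 2 matrix
polygon_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

# circular 3-bin moving average of a per-bin series
circular_ma3 <- function(x) {
  n <- length(x)
  (x + x[c(n, seq_len(n - 1L))] + x[c(seq(2L, n), 1L)]) / 3
}
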