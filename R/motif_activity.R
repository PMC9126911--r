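#' Build a promoter x motif site-count matrix
#'
#' Sums the posterior probabilities of predicted transcription-factor
#' binding sites falling inside each gene's promoter window (TSS +/-
#' \code{window_bp}), motif by motif: \eqn{N_{pm} = \sum posteriors} of
#' motif \eqn{m} sites overlapping promoter \eqn{p}. Site predictions in
#' the SwissRegulon GFF layout (score = posterior, motif name in the
#' attributes) are supported directly.
#'
#' @param sites a GFF file path (imported with \pkg{rtracklayer}), a
#'   \code{GRanges}, or a data.frame with columns \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive), \code{motif},
#'   \code{posterior}.
#' @param tss a data.frame (or TSV path) with columns \code{gene},
#'   \code{chrom}, \code{pos} (1-based TSS position), \code{strand}.
#' @param window_bp promoter half-width in bp (default 1000).
#' @return a \code{SiteCountMatrix}: dense matrix \code{N} (promoters x
#'   motifs, non-negative), \code{promoter_ids}, \code{motif_ids},
#'   \code{window_bp}. Genes without sites keep zero rows.
#' @export
build_site_counts <- function(sites, tss, window_bp = 1000L) {
  if (is.character(tss)) {
    tss <- read.table(tss, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "chrom", "pos", "strand") %in% names(tss)))

  site_df <- normalize_sites(sites)
  bad <- !is.finite(site_df$posterior) | is.na(site_df$motif) |
    site_df$motif == "" | site_df$start > site_df$end
  if (any(bad)) {
    message(sprintf("skipping %d malformed site record(s)", sum(bad)))
    site_df <- site_df[!bad, , drop = FALSE]
  }
  if (nrow(site_df) == 0L) stop("no usable site records")
  if (any(site_df$posterior < 0 | site_df$posterior > 1)) {
    stop("site posteriors must lie in [0, 1]")
  }
  if (!any(site_df$chrom %in% tss$chrom)) {
    stop(sprintf(
      "no shared chromosome names between sites (e.g. %s) and TSS table (e.g. %s)",
      paste(utils::head(unique(site_df$chrom), 3L), collapse = ","),
      paste(utils::head(unique(tss$chrom), 3L), collapse = ",")))
  }

  prom <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = pmax(tss$pos - window_bp, 1L),
                              end = tss$pos + window_bp))
  sgr <- GenomicRanges::GRanges(
    seqnames = site_df$chrom,
    ranges = IRanges::IRanges(start = site_df$start, end = site_df$end))
  hits <- GenomicRanges::findOverlaps(prom, sgr)

  motifs <- sort(unique(site_df$motif))
  N <- matrix(0, nrow(tss), length(motifs),
              dimnames = list(tss$gene, motifs))
  if (length(hits) > 0L) {
    p <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    m <- match(site_df$motif[s], motifs)
    for (k in seq_along(p)) {
      N[p[k], m[k]] <- N[p[k], m[k]] + site_df$posterior[s[k]]
    }
  }
  structure(list(N = N, promoter_ids = tss$gene, motif_ids = motifs,
                 window_bp = window_bp),
            class = "SiteCountMatrix")
}

# accept GFF path / GRanges / data.frame and return a canonical site table
normalize_sites <- function(sites) {
  if (is.character(sites)) {
    sites <- rtracklayer::import(sites)
  }
  if (is(sites, "GRanges")) {
    mc <- S4Vectors::mcols(sites)
    motif_col <- intersect(c("motif", "Motif", "Name", "name", "ID"),
                           colnames(mc))[1L]
    if (is.na(motif_col)) stop("cannot find a motif name column in the sites")
    data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
               start = GenomicRanges::start(sites),
               end = GenomicRanges::end(sites),
               motif = as.character(mc[[motif_col]]),
               posterior = as.numeric(mc$score),
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("chrom", "start", "end", "motif", "posterior")
                  %in% names(sites)))
    sites
  }
}

#' Per-bin unspliced expression matrix for the activity model
#'
#' Unspliced reads track nascent transcription with mRNA stability removed,
#' which is what a transcription-factor activity model should explain. For
#' each gene, the per-bin mean of log1p smoothed unspliced counts is
#' computed and centered across bins; empty bins become NA and are excluded
#' from the ridge solve.
#'
#' @param ds an \code{ExpressionDataset} with smoothed layers.
#' @param assignment a normalized \code{PhaseAssignment}.
#' @return genes x bins matrix, per-gene centered across non-NA bins.
#' @export
binned_unspliced_expression <- function(ds, assignment) {
  stopifnot(is(ds, "ExpressionDataset"), is(assignment, "PhaseAssignment"))
  if (is.null(ds$U_smooth)) stop("run knn_smooth() first")
  n_bins <- assignment$n_bins
  L <- log1p(ds$U_smooth)
  E <- matrix(NA_real_, length(ds$gene_ids), n_bins,
              dimnames = list(ds$gene_ids, NULL))
  for (b in sort(unique(assignment$bin))) {
    E[, b + 1L] <- colMeans(L[assignment$bin == b, , drop = FALSE])
  }
  sweep(E, 1L, rowMeans(E, na.rm = TRUE))
}

#' Infer motif activities across phase bins by ridge regression
#'
#' Fits the linear model \eqn{E \approx N A} per phase bin: expression of
#' promoter \eqn{p} in bin \eqn{c} is explained by the site counts
#' \eqn{N_{pm}} weighted by the (latent) motif activities \eqn{A_{mc}},
#' with an L2 penalty on \eqn{A}. The ridge strength is chosen by repeated
#' (default 10x) random 80/20 cross-validation over promoters, and the
#' per-repeat optima are combined by geometric mean. Expression rows and
#' site-count columns are centered before solving, so activities come out
#' centered across bins.
#'
#' @param E genes x bins expression matrix
#'   (\code{\link{binned_unspliced_expression}}); row names must match the
#'   site-count promoters when both are named.
#' @param N a \code{SiteCountMatrix} or plain promoters x motifs matrix.
#' @param lambda_grid candidate ridge strengths (log-spaced).
#' @param cv_repeats number of cross-validation repeats.
#' @param seed RNG seed for the CV splits.
#' @param center center E rows (across bins) and N columns (across
#'   promoters) before solving (default TRUE). Pass FALSE when the inputs
#'   are already centered or when the raw linear system is wanted.
#' @return a \code{MotifActivities}: \code{A} (motifs x bins), chosen
#'   \code{lambda}, per-motif-and-bin \code{z} scores, per-motif combined
#'   \code{z_motif}, the CV error curve, and flags for all-zero motifs.
#' @export
infer_activities <- function(E, N,
                             lambda_grid = 10^seq(-4, 2, length.out = 25),
                             cv_repeats = 10L, seed = 0L, center = TRUE) {
  if (length(lambda_grid) == 0L) stop("lambda grid is empty")
  if (is(N, "SiteCountMatrix")) N <- N$N
  N <- as.matrix(N)
  E <- as.matrix(E)
  if (!is.null(rownames(E)) && !is.null(rownames(N))) {
    shared <- intersect(rownames(E), rownames(N))
    if (length(shared) == 0L) stop("no shared promoters between E and N")
    E <- E[shared, , drop = FALSE]
    N <- N[shared, , drop = FALSE]
  }
  if (nrow(E) != nrow(N)) {
    stop(sprintf("E has %d rows but N has %d promoters", nrow(E), nrow(N)))
  }

  zero_motif <- colSums(N != 0) == 0L
  Nc <- N[, !zero_motif, drop = FALSE]
  if (center) {
    Nc <- scale(Nc, center = TRUE, scale = FALSE)
    E <- sweep(E, 1L, rowMeans(E, na.rm = TRUE))
  }
  good_bins <- colSums(is.na(E)) == 0L
  if (!any(good_bins)) stop("no bins with complete expression values")
  Eg <- E[, good_bins, drop = FALSE]
  n_p <- nrow(Nc)

  ridge_solve <- function(Ntr, Etr, lambda) {
    sv <- svd(Ntr)
    keep <- sv$d > max(sv$d) * 1e-12
    d <- sv$d[keep]
    shrink <- d / (d^2 + lambda)
    sv$v[, keep, drop = FALSE] %*%
      (shrink * crossprod(sv$u[, keep, drop = FALSE], Etr))
  }

  set.seed(seed)
  cv_err <- matrix(NA_real_, cv_repeats, length(lambda_grid))
  lam_best <- numeric(cv_repeats)
  for (r in seq_len(cv_repeats)) {
    test <- sample.int(n_p, max(1L, round(0.2 * n_p)))
    train <- setdiff(seq_len(n_p), test)
    sv <- svd(Nc[train, , drop = FALSE])
    keep <- sv$d > max(sv$d) * 1e-12
    d <- sv$d[keep]
    UtE <- crossprod(sv$u[, keep, drop = FALSE], Eg[train, , drop = FALSE])
    Vk <- sv$v[, keep, drop = FALSE]
    for (li in seq_along(lambda_grid)) {
      A <- Vk %*% ((d / (d^2 + lambda_grid[li])) * UtE)
      pred <- Nc[test, , drop = FALSE] %*% A
      cv_err[r, li] <- mean((Eg[test, , drop = FALSE] - pred)^2)
    }
    lam_best[r] <- lambda_grid[which.min(cv_err[r, ])]
  }
  lambda <- exp(mean(log(lam_best)))

  sv <- svd(Nc)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  Uk <- sv$u[, keep, drop = FALSE]
  Vk <- sv$v[, keep, drop = FALSE]
  shrink <- d / (d^2 + lambda)
  A_good <- Vk %*% (shrink * crossprod(Uk, Eg))

  # ridge-based standard errors: Cov(A[,c]) = sigma_c^2 V D^2/(D^2+lam)^2 V'
  fitted <- Nc %*% A_good
  df_eff <- sum(d^2 / (d^2 + lambda))
  sigma2 <- colSums((Eg - fitted)^2) / max(n_p - df_eff, 1)
  var_scale <- rowSums(sweep(Vk^2, 2L, (d * shrink)^2, "*"))
  se <- sqrt(outer(var_scale, sigma2))
  z_good <- A_good / pmax(se, .Machine$double.eps)

  n_motifs <- ncol(N)
  A <- matrix(0, n_motifs, ncol(E),
              dimnames = list(colnames(N), NULL))
  z <- matrix(0, n_motifs, ncol(E), dimnames = dimnames(A))
  A[, ] <- NA_real_; z[, ] <- NA_real_
  A[!zero_motif, good_bins] <- A_good
  z[!zero_motif, good_bins] <- z_good
  A[zero_motif, ] <- 0
  z[zero_motif, ] <- 0
  if (any(zero_motif)) {
    warning(sprintf("%d motif(s) with all-zero site counts set to activity 0",
                    sum(zero_motif)))
  }
  structure(list(A = A, lambda = lambda, z = z,
                 z_motif = sqrt(rowMeans(z^2, na.rm = TRUE)),
                 cv_error = colMeans(cv_err),
                 lambda_grid = lambda_grid,
                 lambda_per_repeat = lam_best,
                 zero_motifs = colnames(N)[zero_motif]),
            class = "MotifActivities")
}

#' @export
print.MotifActivities <- function(x, ...) {
  cat(sprintf("MotifActivities: %d motifs x %d bins, lambda = %.4g\n",
              nrow(x$A), ncol(x$A), x$lambda))
  invisible(x)
}
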