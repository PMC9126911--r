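write_sites_gff <- function(path) {
  writeLines(c(
    "chr1\tmotevo\tTFBS\t1200\t1210\t0.7\t+\t.\tMotif=E2F1",
    "chr1\tmotevo\tTFBS\t1500\t1512\t0.3\t-\t.\tMotif=E2F1",
    "chr1\tmotevo\tTFBS\t3500\t3510\t0.9\t+\t.\tMotif=MYB",
    "chr2\tmotevo\tTFBS\t800\t815\t0.5\t+\t.\tMotif=MYB"),
    path)
  path
}

test_that("site counts sum posteriors inside the promoter window", {
  gff <- write_sites_gff(withr::local_tempfile(fileext = ".gff"))
  tss <- data.frame(gene = c("G1", "G2"), chrom = c("chr1", "chr2"),
                    pos = c(2000L, 1000L), strand = c("+", "-"))
  sc <- build_site_counts(gff, tss, window_bp = 1000L)
  # two E2F1 sites (0.7 + 0.3) inside G1's window; the MYB site at 3500 is
  # 1.5 kb downstream and excluded
  expect_equal(sc$N["G1", "E2F1"], 1.0)
  expect_equal(sc$N["G1", "MYB"], 0)
  expect_equal(sc$N["G2", "MYB"], 0.5)
  # chromosome naming mismatches are fatal with examples
  tss_bad <- transform(tss, chrom = c("1", "2"))
  expect_error(build_site_counts(gff, tss_bad, 1000L), "chromosome")
})

test_that("the ridge solution matches the normal-equations oracle", {
  set.seed(5)
  N <- matrix(rexp(80 * 12), 80, 12)
  E <- matrix(rnorm(80 * 6), 80, 6)
  lam <- 0.73
  A <- infer_activities(E, N, lambda_grid = lam, cv_repeats = 2,
                        center = FALSE)$A
  oracle <- solve(crossprod(N) + lam * diag(12), crossprod(N, E))
  expect_lt(max(abs(A - oracle)), 1e-8)
})

test_that("ridge limits behave: OLS as lambda -> 0, shrinkage as
           lambda -> Inf", {
  set.seed(6)
  N <- matrix(rnorm(144), 12, 12)
  E <- matrix(rnorm(12 * 5), 12, 5)
  A0 <- infer_activities(E, N, lambda_grid = 1e-12, cv_repeats = 2,
                         center = FALSE)$A
  expect_lt(max(abs(A0 - solve(N, E))), 1e-8)
  Ainf <- infer_activities(E, N, lambda_grid = 1e8, cv_repeats = 2,
                           center = FALSE)$A
  expect_lt(sqrt(sum(Ainf^2)), 1e-3)
  expect_error(infer_activities(E, N, lambda_grid = numeric(0)), "empty")
})

test_that("planted activities are recovered through cross-validated ridge", {
  set.seed(42)
  N <- matrix(rpois(200 * 20, 1.5) * runif(200 * 20), 200, 20)
  A_true <- matrix(rnorm(20 * 50), 20, 50)
  A_true <- sweep(A_true, 1, rowMeans(A_true))
  E <- N %*% A_true + matrix(rnorm(200 * 50, 0, 0.5), 200, 50)
  act <- infer_activities(E, N, seed = 7)
  cors <- vapply(1:20, function(m) cor(act$A[m, ], A_true[m, ]), 0)
  expect_gte(min(cors), 0.95)
  # centering convention: each activity series has mean (close to) zero
  expect_lt(max(abs(rowMeans(act$A))), 1e-8)
  # activities are invariant to adding a constant to a gene's expression
  E2 <- E; E2[3, ] <- E2[3, ] + 100
  act2 <- infer_activities(E2, N, lambda_grid = act$lambda, cv_repeats = 2,
                           seed = 7)
  expect_equal(act2$A, act$A, tolerance = 1e-6)
})

test_that("all-zero motifs are flagged and empty bins excluded", {
  set.seed(8)
  N <- cbind(matrix(rexp(60 * 4), 60, 4), 0)
  colnames(N) <- paste0("m", 1:5)
  E <- matrix(rnorm(60 * 6), 60, 6)
  E[, 4] <- NA   # an empty phase bin
  expect_warning(act <- infer_activities(E, N, lambda_grid = 1,
                                         cv_repeats = 2), "all-zero")
  expect_equal(act$zero_motifs, "m5")
  expect_true(all(act$A["m5", ] == 0))
  expect_true(all(is.na(act$A[1:4, 4])))
  expect_true(all(is.finite(act$A[1:4, -4])))
})

test_that("binned unspliced expression averages, centers and handles
           single-cell bins", {
  ds <- small_sim()
  # constant gene: all-zero centered row
  ds$U_smooth[, 1] <- 5
  asg <- assignment_from_phase(ds$true_phase, ds$cell_ids)
  E <- binned_unspliced_expression(ds, asg)
  expect_equal(unname(E[1, ]), rep(0, 50), tolerance = 1e-12)
  # per-bin means equal a direct tapply computation (including bins that
  # hold a single cell, which reproduce that cell's value pre-centering)
  g2 <- ds$gene_ids[2]
  m <- rep(NA_real_, 50)
  agg <- tapply(log1p(ds$U_smooth[, g2]), asg$bin, mean)
  m[as.integer(names(agg)) + 1L] <- agg
  expect_equal(unname(E[g2, ]), m - mean(m, na.rm = TRUE), tolerance = 1e-12)
  # planted peaks: binned rows of cycling genes peak near phi_s
  par <- attr(ds, "sim_params")
  cyc <- head(par$gene[par$type == "cycling"], 10)
  hits <- vapply(cyc, function(g) {
    pk <- (which.max(E[g, ]) - 0.5) / 50
    d <- abs(pk - par$phi_u[par$gene == g])
    min(d, 1 - d) <= 2.5 / 50
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
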