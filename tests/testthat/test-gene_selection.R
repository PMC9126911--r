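test_that("EM recovers two well-separated Gaussian components", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(1000), 500, 2),
               matrix(rnorm(1000, mean = 5), 500, 2))
  fit <- fit_two_gaussian_mixture(pts, seed = 1)
  expect_false(fit$degenerate)
  means <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(means[1, ] - c(0, 0))), 0.2)
  expect_lt(max(abs(means[2, ] - c(5, 5))), 0.2)
  expect_equal(sum(fit$weights), 1)
})

test_that("a single Gaussian yields close means or a degenerate flag", {
  set.seed(12)
  pts <- matrix(rnorm(2000), 1000, 2)
  fit <- fit_two_gaussian_mixture(pts, seed = 2)
  sep <- sqrt(sum((fit$means[1, ] - fit$means[2, ])^2))
  expect_true(sep < 1.0 || fit$degenerate)
})

test_that("too few points is an error", {
  expect_error(fit_two_gaussian_mixture(matrix(rnorm(10), 5, 2)),
               "at least 10")
})

test_that("Hotelling T2 matches the closed-form two-sample statistic", {
  A <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  B <- A + 10
  pts <- rbind(A, B)
  fit <- list(responsibilities = cbind(rep(c(1, 0), each = 4),
                                       rep(c(0, 1), each = 4)))
  fit <- hotelling_separation(fit, pts)

  # independent closed-form evaluation on the printed points
  n1 <- n2 <- 4
  d <- colMeans(A) - colMeans(B)
  Sp <- ((n1 - 1) * cov(A) + (n2 - 1) * cov(B)) / (n1 + n2 - 2)
  T2_oracle <- as.numeric(n1 * n2 / (n1 + n2) * t(d) %*% solve(Sp) %*% d)
  expect_equal(fit$T2, T2_oracle, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-4)

  # identical groups: zero separation
  same <- rbind(A, A)
  fit0 <- hotelling_separation(
    list(responsibilities = cbind(rep(c(1, 0), each = 4),
                                  rep(c(0, 1), each = 4))), same)
  expect_equal(fit0$T2, 0)
  expect_equal(fit0$p_value, 1)

  # affine invariance: rescaling the units leaves T2 unchanged
  fit2 <- hotelling_separation(
    list(responsibilities = fit$responsibilities), pts * 2)
  expect_equal(fit2$T2, fit$T2, tolerance = 1e-10)
})

test_that("branch counting separates loops, ridges and isolated blobs", {
  set.seed(9)
  mk_fit <- function(a, b, sd) {
    list(means = rbind(a, b),
         covariances = list(diag(sd^2, 2), diag(sd^2, 2)),
         degenerate = FALSE)
  }
  # annulus with density maxima at opposite ends: two arcs = two branches
  th <- runif(1500, 0, 2 * pi)
  r <- 1 + rnorm(1500, 0, 0.07)
  ann <- rbind(cbind(r * cos(th), r * sin(th)),
               cbind(rnorm(250, -1, 0.08), rnorm(250, 0, 0.08)),
               cbind(rnorm(250, 1, 0.08), rnorm(250, 0, 0.08)))
  expect_equal(count_branches(ann, mk_fit(c(-1, 0), c(1, 0), 0.1)), 2L)

  # a single straight ridge between the maxima
  line <- rbind(cbind(runif(800, -1, 1), rnorm(800, 0, 0.08)),
                cbind(rnorm(150, -1, 0.07), rnorm(150, 0, 0.07)),
                cbind(rnorm(150, 1, 0.07), rnorm(150, 0, 0.07)))
  expect_equal(count_branches(line, mk_fit(c(-1, 0), c(1, 0), 0.1)), 1L)

  # two isolated blobs with an empty corridor
  blobs <- rbind(cbind(rnorm(400, -2, 0.1), rnorm(400, 0, 0.1)),
                 cbind(rnorm(400, 2, 0.1), rnorm(400, 0, 0.1)))
  expect_equal(count_branches(blobs, mk_fit(c(-2, 0), c(2, 0), 0.1)), 0L)
})

test_that("selection is invariant to uniform per-gene rescaling", {
  ds <- small_sim()
  g <- attr(ds, "sim_params")$gene[1]
  pts <- cbind(ds$S_smooth[, g], ds$U_smooth[, g])
  fit <- fit_two_gaussian_mixture(pts, seed = 3)
  fit <- hotelling_separation(fit, pts)
  nb <- count_branches(pts, fit)

  scaled <- pts * 3.7
  fit_s <- fit_two_gaussian_mixture(scaled, seed = 3)
  fit_s <- hotelling_separation(fit_s, scaled)
  expect_equal(fit_s$T2, fit$T2, tolerance = 1e-8)
  expect_equal(count_branches(scaled, fit_s), nb)
})

test_that("an impossible alpha level selects nothing and failures are
           flagged, not fatal", {
  ds <- small_sim()
  genes <- attr(ds, "sim_params")$gene[c(1:6, 31:36)]
  sel <- select_cycling_genes(ds, gene_list = genes, alpha_level = 0,
                              seed = 2)
  expect_equal(sum(sel$selected), 0L)
  expect_equal(sort(sel$gene), sort(genes))
  expect_error(select_cycling_genes(
    ExpressionDataset(matrix(1L, 3, 2), matrix(1L, 3, 2),
                      letters[1:3], c("g1", "g2"))), "knn_smooth")
})
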