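test_that("periodic kinetics reproduce the constant-rate fixed point", {
  out <- periodic_kinetics(function(th) rep(10, length(th)),
                           beta = 2, gamma = 1, T_period = 20, n_grid = 64)
  expect_equal(out$u, rep(5, 64), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(out$s, rep(10, 64), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("fast splicing drains the unspliced pool", {
  out <- periodic_kinetics(function(th) rep(10, length(th)),
                           beta = 1000, gamma = 1, T_period = 20)
  expect_true(all(out$u <= 10 / 1000 + 1e-8))
  expect_equal(out$s, rep(10, 200), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("slowly varying transcription gives the quasi-static solution", {
  # with rates fast relative to the cycle, u(theta) tracks alpha(theta)/beta
  alpha <- function(th) 5 + 2 * cos(2 * pi * th)   # kappa small: broad bump
  out <- periodic_kinetics(alpha, beta = 5, gamma = 5, T_period = 100)
  qs <- alpha(out$theta) / 5
  expect_lt(max(abs(out$u - qs) / qs), 0.05)
  # periodic boundary: first and last grid values close around the wrap
  expect_lt(abs(out$u[1] - out$u[200]) / mean(out$u), 0.05)
})

test_that("identical configs and seeds give identical populations", {
  cfg <- sim_config(n_cells = 120, n_cycling_genes = 10, n_flat_genes = 10,
                    seed = 99)
  d1 <- simulate_population(cfg)
  d2 <- simulate_population(cfg)
  expect_identical(d1$S_raw, d2$S_raw)
  expect_identical(d1$U_raw, d2$U_raw)
  expect_identical(d1$true_phase, d2$true_phase)
})

test_that("planted expression peaks are recoverable from binned means", {
  ds <- default_sim()
  par <- attr(ds, "sim_params")
  bins <- pmin(floor(ds$true_phase * 50), 49L)
  cyc <- which(par$type == "cycling")
  hit <- vapply(cyc, function(g) {
    m <- tapply(ds$S_smooth[, g], bins, mean)
    peak_bin <- as.integer(names(m)[which.max(m)])
    true_bin <- min(floor(par$phi_s[g] * 50), 49L)
    d <- abs(peak_bin - true_bin)
    min(d, 50L - d) <= 1L
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("total RNA content doubles over the cycle by construction", {
  ds <- default_sim()
  late <- ds$true_phase > 0.95
  early <- ds$true_phase < 0.05
  ratio <- mean(ds$total_counts[late]) / mean(ds$total_counts[early])
  g <- attr(ds, "sim_config")$growth_factor
  expect_lt(abs(ratio - g) / g, 0.1)
})

test_that("flat genes vary only through cell volume", {
  ds <- default_sim()
  par <- attr(ds, "sim_params")
  flat <- head(par$gene[par$type == "flat"], 30)
  bins <- pmin(floor(ds$true_phase * 20), 19L)
  V <- attr(ds, "sim_config")$growth_factor^ds$true_phase
  for (g in flat[c(1, 10, 20, 30)]) {
    dev <- ds$S_raw[, g] / V
    m <- tapply(dev, bins, mean)
    n_per_bin <- tabulate(bins + 1L, 20L)
    # Poisson expectation for the CV of binned means of rate lambda
    lam <- mean(dev)
    poisson_cv <- sqrt(mean(1 / n_per_bin) / lam) / 1
    cv <- sd(m) / mean(m)
    expect_lt(cv, 3 * poisson_cv)
  }
})

test_that("cycling genes trace loops with enclosed area; flat genes do not", {
  ds <- default_sim()
  par <- attr(ds, "sim_params")
  bins <- pmin(floor(ds$true_phase * 25), 24L)
  loop_area <- function(g) {
    s <- tapply(ds$S_smooth[, g], bins, mean)
    u <- tapply(ds$U_smooth[, g], bins, mean)
    # normalize scale so areas are comparable across genes
    s <- s / max(s); u <- u / max(u)
    cyclephase:::polygon_area(cbind(s, u))
  }
  cyc_area <- vapply(head(par$gene[par$type == "cycling"], 20), loop_area, 0)
  flat_area <- vapply(head(par$gene[par$type == "flat"], 20), loop_area, 0)
  expect_gt(median(cyc_area), 5 * median(flat_area))
})
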