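test_that("seed angles follow the atan2 definition", {
  # two cells designed so the z-scores are (-1, 1) in both layers
  S <- matrix(c(0, 2, 0, 2), 2, 2)
  U <- matrix(c(2, 0, 0, 2), 2, 2)
  ds <- manual_dataset(S, U)
  a <- seed_phase_from_gene(ds, "g01")
  expect_equal(unname(a), atan2(c(1, -1), c(-1, 1)))
  a2 <- seed_phase_from_gene(ds, "g02")
  expect_equal(unname(a2), atan2(c(-1, 1), c(-1, 1)))
  # zero-variance gene is rejected with a hint
  ds$S_smooth[, "g01"] <- 1
  expect_error(seed_phase_from_gene(ds, "g01"), "another seed gene")
})

test_that("seed angles correlate with the true phase on simulated data", {
  ds <- small_sim()
  par <- attr(ds, "sim_params")
  g <- par$gene[par$type == "cycling"][3]
  a <- seed_phase_from_gene(ds, g) / (2 * pi)
  rho <- circular_correlation(a - floor(a), ds$true_phase)
  expect_gte(abs(rho), 0.5)
})

test_that("training beats the mean predictor and stops early", {
  m <- small_model()
  # inputs are z-scored, so the column-mean predictor has MSE 1
  expect_lt(tail(m$history$step2_val, 1), 1)
  expect_lt(length(m$history$step1_val), m$cfg$max_epochs)
  expect_lt(length(m$history$step2_val), m$cfg$max_epochs)
})

test_that("training is deterministic given the seed", {
  ds <- small_sim()
  genes <- head(attr(ds, "sim_params")$gene, 6)
  cfg <- model_config(input_gene = genes[1], max_epochs = 30L, seed = 8)
  m1 <- train_deepcycle(ds, genes, cfg)
  m2 <- train_deepcycle(ds, genes, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("decoded trajectories are exactly periodic with the right shape", {
  m <- small_model()
  expect_identical(decode_trajectory(m, 0.25), decode_trajectory(m, 1.25))
  out <- decode_trajectory(m, c(0.1, 0.6))
  expect_equal(dim(out), c(2L, length(m$genes), 2L))
  expect_true(all(is.finite(out)))
})

test_that("decoded loops enclose area for cycling genes but not flat ones", {
  m <- small_model()
  tr <- m$trajectory
  area <- function(g) {
    s <- tr[, g, "s"]; u <- tr[, g, "u"]
    cyclephase:::polygon_area(cbind(s / max(s), u / max(u)))
  }
  cyc_genes <- grep("^CYC", m$genes, value = TRUE)
  flat_genes <- grep("^FLAT", m$genes, value = TRUE)
  expect_gt(min(vapply(cyc_genes, area, 0)),
            max(vapply(flat_genes, area, 0)))
  # fit quality separates cycling from flat as well
  expect_gt(mean(m$r_squared[cyc_genes]), mean(m$r_squared[flat_genes]))
})

test_that("phase assignment is an exact nearest-bin rule", {
  m <- small_model()
  ds <- small_sim()
  # a synthetic cell placed exactly on bin 7's decoded vector
  N <- length(m$genes)
  z <- m$traj_z[8L, ]    # 0-based bin 7
  st <- m$stats
  S <- matrix(rep(z[seq_len(N)] * st$s_sd + st$s_mu, each = 2), 2, N)
  U <- matrix(rep(z[N + seq_len(N)] * st$u_sd + st$u_mu, each = 2), 2, N)
  colnames(S) <- colnames(U) <- m$genes
  probe <- manual_dataset(S, U)
  probe$gene_ids <- m$genes
  colnames(probe$S_smooth) <- colnames(probe$U_smooth) <- m$genes
  asg <- assign_phase(m, probe)
  expect_equal(asg$bin, c(7L, 7L))   # identical cells, identical bins
  # genes missing from the dataset are reported
  expect_error(assign_phase(m, small_sim_subset <- subset_genes(
    ds, m$genes[-1])), "missing")
})

test_that("phase recovery is invariant to the seed gene choice", {
  ds <- small_sim()
  par <- attr(ds, "sim_params")
  genes <- head(par$gene[par$type == "cycling"], 8)
  rhos <- vapply(genes[c(1, 5)], function(g) {
    m <- train_deepcycle(ds, genes,
                         model_config(input_gene = g, max_epochs = 150L,
                                      seed = 4))
    abs(circular_correlation(assign_phase(m, ds)$theta, ds$true_phase))
  }, 0)
  expect_true(all(rhos >= 0.7))
  expect_lt(abs(rhos[1] - rhos[2]), 0.15)
})
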