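test_that("a single-gene marker score equals that gene's z-score", {
  ds <- small_sim()
  asg <- assignment_from_phase(ds$true_phase, ds$cell_ids)
  g <- ds$gene_ids[1]
  sc <- marker_score(ds, asg, g)
  expect_equal(attr(sc, "per_cell"), zscore_per_gene(ds$S_smooth[, g]),
               ignore_attr = TRUE)
  expect_error(marker_score(ds, asg, c("NOPE1", "NOPE2")), "no marker genes")
})

test_that("planted S-program scores peak inside their phase window", {
  ds <- small_sim()
  asg <- assignment_from_phase(ds$true_phase, ds$cell_ids)
  mk <- sim_marker_lists(ds)
  sc <- marker_score(ds, asg, mk$s_genes)
  peak_theta <- (which.max(sc) - 0.5) / 50
  expect_gte(peak_theta, 0.45 - 2 / 50)
  expect_lte(peak_theta, 0.65 + 2 / 50)
})

test_that("transition rules return exactly the rule-defined bins", {
  tab <- synthetic_score_table(cyce_peak = 10L, sg2_cross = 30L,
                               drop_bin = 48L)
  tr <- detect_transitions(tab)
  expect_equal(tr$bin_G1S, 11L)   # bin after the cyclin-E argmax
  expect_equal(tr$bin_SG2, 30L)   # first bin with G2M above S
  expect_equal(tr$bin_MG1, 48L)   # steepest drop of the counts series
  expect_error(
    detect_transitions(transform(tab, G2M_score = S_score + 1)),
    "never cross")
})

test_that("alignment maps mitosis to theta = 1 and is idempotent", {
  set.seed(21)
  tab <- synthetic_score_table(cyce_peak = 10L, sg2_cross = 30L,
                               drop_bin = 48L)
  theta <- runif(300)
  asg <- assignment_from_phase(theta, normalized = FALSE)
  tr <- detect_transitions(tab)
  al <- normalize_and_align(asg, tr)
  expect_true(al$normalized)
  expect_equal(al$transitions$theta_MG1, 1)
  expect_lt(al$transitions$theta_G1S, al$transitions$theta_SG2)
  expect_lt(al$transitions$theta_SG2, 1)

  # pairwise circular distances between cells are preserved (isometry)
  cd <- function(a, b) pmin(abs(a - b), 1 - abs(a - b))
  i <- sample(300, 50); j <- sample(300, 50)
  expect_equal(cd(al$theta[i], al$theta[j]), cd(asg$theta[i], asg$theta[j]),
               tolerance = 1e-12)

  # idempotence: re-detecting on the aligned table changes nothing
  tr2 <- detect_transitions(al$transitions$score_table)
  al2 <- normalize_and_align(al, tr2)
  expect_false(al2$transitions$orientation_flipped)
  expect_equal(al2$transitions$rotation_applied, 0)
  expect_equal(al2$theta, al$theta)
})

test_that("a reflected assignment is flipped back to the same transitions", {
  set.seed(22)
  tab <- synthetic_score_table(cyce_peak = 10L, sg2_cross = 30L,
                               drop_bin = 48L)
  theta <- runif(400)
  asg <- assignment_from_phase(theta, normalized = FALSE)
  al <- normalize_and_align(asg, detect_transitions(tab))

  refl <- assignment_from_phase(cyclephase:::wrap_phase(-theta),
                                normalized = FALSE)
  tab_r <- cyclephase:::flip_score_table(tab)
  al_r <- normalize_and_align(refl, detect_transitions(tab_r))
  expect_true(al_r$transitions$orientation_flipped)
  expect_equal(al_r$transitions$theta_G1S, al$transitions$theta_G1S)
  expect_equal(al_r$transitions$theta_SG2, al$transitions$theta_SG2)
})

test_that("RNA fold change recovers the planted growth factor", {
  for (g in c(1, 3)) {
    ds <- simulate_population(sim_config(n_cells = 600, n_cycling_genes = 30,
                                         n_flat_genes = 40, growth_factor = g,
                                         seed = 11))
    asg <- assignment_from_phase(ds$true_phase, ds$cell_ids)
    fold <- rna_fold_change(ds, asg)
    expect_lt(abs(fold - g) / g, 0.1)
  }
  # flank estimator agrees when the assignment is noise-free
  ds <- simulate_population(sim_config(n_cells = 600, n_cycling_genes = 30,
                                       n_flat_genes = 40, seed = 11))
  asg <- assignment_from_phase(ds$true_phase, ds$cell_ids)
  expect_lt(abs(rna_fold_change(ds, asg, method = "flank") - 2) / 2, 0.15)
  expect_error(rna_fold_change(ds, assignment_from_phase(
    ds$true_phase, ds$cell_ids, normalized = FALSE)), "normalized")
})

test_that("discrete phase labels partition the cycle at the transitions", {
  tab <- synthetic_score_table()
  asg <- assignment_from_phase(seq(0, 0.99, length.out = 200),
                               normalized = FALSE)
  al <- normalize_and_align(asg, detect_transitions(tab))
  lab <- assign_cell_cycle_phase(al)
  expect_equal(levels(lab), c("G1", "S", "G2M"))
  tr <- al$transitions
  expect_true(all(al$theta[lab == "G1"] < tr$theta_G1S))
  expect_true(all(al$theta[lab == "S"] >= tr$theta_G1S &
                    al$theta[lab == "S"] < tr$theta_SG2))
  expect_true(all(al$theta[lab == "G2M"] >= tr$theta_SG2))
})
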