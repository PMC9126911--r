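# Shared fixtures, computed once per test session. The default simulation
# is the package's reference study population: 2000 cells, 80 cycling and
# 120 flat genes, Poisson capture, seed 0.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_sim <- function() {
  cached("default_sim", {
    ds <- simulate_population(sim_config(seed = 0))
    knn_smooth(ds)
  })
}

# a small, quick population for module-level checks
small_sim <- function() {
  cached("small_sim", {
    ds <- simulate_population(sim_config(n_cells = 400, n_cycling_genes = 30,
                                         n_flat_genes = 40, seed = 1))
    knn_smooth(ds, n_neighbors = 15L, n_pcs = 20L)
  })
}

small_model <- function() {
  cached("small_model", {
    ds <- small_sim()
    par <- attr(ds, "sim_params")
    genes <- c(head(par$gene[par$type == "cycling"], 8),
               head(par$gene[par$type == "flat"], 2))
    train_deepcycle(ds, genes,
                    model_config(input_gene = genes[1], max_epochs = 150L,
                                 seed = 4))
  })
}

# the full pipeline on the default study population (shared by the
# acceptance checks)
reference_run <- function() {
  cached("reference_run", run_pipeline(pipeline_config(seed = 0)))
}

# hand-built dataset with prescribed smoothed layers
manual_dataset <- function(S_smooth, U_smooth) {
  n <- nrow(S_smooth); g <- ncol(S_smooth)
  ids <- sprintf("c%02d", seq_len(n))
  genes <- sprintf("g%02d", seq_len(g))
  ds <- ExpressionDataset(matrix(1L, n, g), matrix(1L, n, g), ids, genes)
  dimnames(S_smooth) <- dimnames(U_smooth) <- list(ids, genes)
  ds$S_smooth <- S_smooth
  ds$U_smooth <- U_smooth
  ds
}

# a synthetic 50-bin score table with known rule outcomes
synthetic_score_table <- function(n = 50L, cyce_peak = 10L, sg2_cross = 30L,
                                  drop_bin = 48L) {
  bin <- seq_len(n) - 1L
  cyce <- cos(2 * pi * (bin - cyce_peak) / n)
  s_peak <- (cyce_peak + sg2_cross) %/% 2L
  s_score <- 1 + cos(2 * pi * (bin - s_peak) / n)
  g2m <- ifelse(bin >= sg2_cross & bin < drop_bin, 3, 0)
  counts <- 100 + bin * 5
  counts[bin >= drop_bin] <- c(150, 140)[seq_len(n - drop_bin)]
  data.frame(bin = bin, S_score = s_score, G2M_score = g2m,
             CyclinE_score = cyce, mean_total_counts = counts,
             n_cells = rep(10L, n))
}
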