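#' Configuration for the circular autoencoder
#'
#' Hyperparameters of the two-step training procedure. The encoder maps the
#' standardized spliced/unspliced vector of the selected genes (plus the
#' seed-gene angle as a cos/sin pair) through two leaky-ReLU hidden layers
#' of width \code{hidden_multiplier} times the number of genes to a single
#' real number; a circularize layer turns it into \eqn{(\cos\theta,
#' \sin\theta)} and the decoder reconstructs the full input vector from
#' those two coordinates. Training step 1 regresses the encoder onto the
#' atan2 seed angles; step 2 trains encoder and decoder end-to-end on
#' reconstruction mean squared error, with Gaussian noise injected into the
#' inputs. Both steps use Adam, early stopping on validation loss
#' (\code{early_stop_patience}, best weights restored) and plateau-driven
#' learning-rate decay (\code{lr_plateau_factor}/\code{lr_plateau_patience}
#' down to \code{min_lr}).
#'
#' @param input_gene gene symbol used for atan2 seeding (a robustly cycling
#'   gene; on real data typically a G2/M marker such as NUSAP1 or MELK).
#' @param hidden_multiplier hidden width as a multiple of the gene count.
#' @param noise_std standard deviation of the input Gaussian noise, in
#'   z-score units.
#' @param batch_size minibatch size (default 5 cells).
#' @param val_fraction fraction of cells held out for validation (0.17).
#' @param early_stop_patience,early_stop_min_delta early-stopping settings.
#' @param lr_init,lr_plateau_factor,lr_plateau_patience,min_lr learning-rate
#'   schedule.
#' @param max_epochs epoch cap per training step; early stopping normally
#'   halts far sooner.
#' @param n_bins number of phase bins on the circle (default 50).
#' @param seed integer seed controlling initialization, the validation
#'   split, batch order and input noise.
#' @return a \code{ModelConfig} list.
#' @export
model_config <- function(input_gene = NULL,
                         hidden_multiplier = 4L,
                         noise_std = 0.1,
                         batch_size = 5L,
                         val_fraction = 0.17,
                         early_stop_patience = 20L,
                         early_stop_min_delta = 0.0,
                         lr_init = 1e-3,
                         lr_plateau_factor = 0.8,
                         lr_plateau_patience = 5L,
                         min_lr = 1e-5,
                         max_epochs = 1000L,
                         n_bins = 50L,
                         seed = 0L) {
  cfg <- list(input_gene = input_gene,
              hidden_multiplier = as.integer(hidden_multiplier),
              noise_std = noise_std,
              batch_size = as.integer(batch_size),
              val_fraction = val_fraction,
              early_stop_patience = as.integer(early_stop_patience),
              early_stop_min_delta = early_stop_min_delta,
              lr_init = lr_init,
              lr_plateau_factor = lr_plateau_factor,
              lr_plateau_patience = as.integer(lr_plateau_patience),
              min_lr = min_lr,
              max_epochs = as.integer(max_epochs),
              n_bins = as.integer(n_bins),
              seed = as.integer(seed))
  stopifnot(cfg$hidden_multiplier >= 1L, cfg$noise_std >= 0,
            cfg$batch_size >= 1L,
            cfg$val_fraction > 0, cfg$val_fraction < 1,
            cfg$n_bins >= 8L, cfg$max_epochs >= 1L)
  class(cfg) <- "ModelConfig"
  cfg
}

#' Seed phases from a single cycling gene
#'
#' The initial per-cell angle is \code{atan2(z(u), z(s))} of the smoothed
#' unspliced and spliced values of one gene. For a gene traversing its
#' expression loop this angle already orders cells around the cycle, which
#' is what training step 1 bootstraps from.
#'
#' @param ds an \code{ExpressionDataset} with smoothed layers.
#' @param gene gene symbol with nonzero variance in both layers.
#' @return per-cell angle in radians in \code{(-pi, pi]}.
#' @export
seed_phase_from_gene <- function(ds, gene) {
  stopifnot(is(ds, "ExpressionDataset"))
  if (is.null(ds$S_smooth)) stop("run knn_smooth() first")
  if (!gene %in% ds$gene_ids) stop("gene not in dataset: ", gene)
  s <- ds$S_smooth[, gene]
  u <- ds$U_smooth[, gene]
  if (pop_sd(s) == 0 || pop_sd(u) == 0) {
    stop(sprintf(
      "gene %s has zero variance in a layer; choose another seed gene", gene))
  }
  atan2(zscore_per_gene(u), zscore_per_gene(s))
}

#' Train the circular autoencoder
#'
#' Learns a single circular latent coordinate (the transcriptional phase)
#' from the standardized spliced/unspliced values of the selected genes.
#' See \code{\link{model_config}} for the architecture and schedule. After
#' training, the decoder is evaluated at the \code{n_bins} bin-center
#' phases to produce the per-gene cycle trajectory, and a per-gene
#' \eqn{R^2} of that trajectory against the cell values is computed as a
#' fit-quality diagnostic (cycling genes should fit well; flat genes
#' should not).
#'
#' @param ds an \code{ExpressionDataset} with smoothed layers, >= 100 cells.
#' @param genes character vector of >= 2 selected (cycling) genes.
#' @param cfg a \code{\link{model_config}}; its \code{input_gene} must be
#'   one of the dataset's genes (defaults to the first of \code{genes}).
#' @param ablate "none" (default), or "unspliced"/"spliced" to zero that
#'   half of every input before training -- the self-check ablation: with
#'   only one layer the joint dynamics are lost and phase recovery should
#'   degrade markedly.
#' @return a \code{TrainedModel}: network weights, the config, training
#'   history, standardization statistics, the \code{n_bins} x n_genes x 2
#'   trajectory array (dimensions: bin, gene, (s, u)) and per-gene
#'   \code{r_squared}.
#' @export
train_deepcycle <- function(ds, genes, cfg = model_config(),
                            ablate = c("none", "unspliced", "spliced")) {
  ablate <- match.arg(ablate)
  stopifnot(is(ds, "ExpressionDataset"), is(cfg, "ModelConfig"))
  if (is.null(ds$S_smooth)) stop("run knn_smooth() first")
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("need at least 2 genes to train")
  missing <- setdiff(genes, ds$gene_ids)
  if (length(missing) > 0L) {
    stop("genes absent from dataset: ", paste(missing, collapse = ", "))
  }
  n_cells <- length(ds$cell_ids)
  if (n_cells < 100L) stop("need at least 100 cells to train")
  if (n_cells < cfg$batch_size) stop("fewer cells than the batch size")
  input_gene <- cfg$input_gene
  if (is.null(input_gene)) input_gene <- genes[1L]
  if (!input_gene %in% genes) {
    stop("input_gene must be one of the training genes: ", input_gene)
  }

  # standardized inputs: [z(s_g)] then [z(u_g)], cells x 2N
  zs <- zscore_matrix(ds$S_smooth[, genes, drop = FALSE])
  zu <- zscore_matrix(ds$U_smooth[, genes, drop = FALSE])
  X <- cbind(zs$z, zu$z)
  N_genes <- length(genes)
  if (ablate == "unspliced") X[, N_genes + seq_len(N_genes)] <- 0
  if (ablate == "spliced") X[, seq_len(N_genes)] <- 0
  gidx <- match(input_gene, genes)
  if (ablate == "none" &&
      (pop_sd(ds$S_smooth[, input_gene]) == 0 ||
       pop_sd(ds$U_smooth[, input_gene]) == 0)) {
    stop(sprintf(
      "seed gene %s has zero variance in a layer; choose another seed gene",
      input_gene))
  }

  set.seed(cfg$seed)
  n_val <- max(1L, round(cfg$val_fraction * n_cells))
  val_idx <- sort(sample.int(n_cells, n_val))
  train_idx <- setdiff(seq_len(n_cells), val_idx)

  H <- cfg$hidden_multiplier * length(genes)
  fit <- cpp_train_deepcycle(
    t(X), train_idx - 1L, val_idx - 1L,
    iu = length(genes) + gidx - 1L, is = gidx - 1L,
    hidden = H,
    noise_std = cfg$noise_std,
    batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs,
    es_patience = cfg$early_stop_patience,
    es_min_delta = cfg$early_stop_min_delta,
    lr_init = cfg$lr_init,
    lr_factor = cfg$lr_plateau_factor,
    lr_patience = cfg$lr_plateau_patience,
    min_lr = cfg$min_lr,
    seed = cfg$seed)

  model <- structure(list(
    weights = fit[c("W1", "b1", "W2", "b2", "W3", "b3",
                    "V1", "c1", "V2", "c2", "V3", "c3")],
    history = fit$history,
    cfg = cfg,
    genes = genes,
    input_gene = input_gene,
    stats = list(s_mu = zs$mu, s_sd = zs$sd, u_mu = zu$mu, u_sd = zu$sd)
  ), class = "TrainedModel")

  # the decoder traverses the expression loop at an arbitrary speed;
  # re-parameterize the latent circle at constant arc length in z-space so
  # phase differences are proportional to transcriptional change
  model$arc <- arc_length_map(model)
  centers <- (seq_len(cfg$n_bins) - 0.5) / cfg$n_bins
  model$traj_z <- decode_z(model, phi_to_decoder(model, centers))
  N <- length(genes)
  traj <- array(NA_real_, dim = c(cfg$n_bins, N, 2L),
                dimnames = list(NULL, genes, c("s", "u")))
  traj[, , "s"] <- sweep(sweep(model$traj_z[, seq_len(N), drop = FALSE],
                               2L, zs$sd, "*"), 2L, zs$mu, "+")
  traj[, , "u"] <- sweep(sweep(model$traj_z[, N + seq_len(N), drop = FALSE],
                               2L, zu$sd, "*"), 2L, zu$mu, "+")
  model$trajectory <- traj

  assign <- assign_phase(model, ds)
  pred <- model$traj_z[assign$bin + 1L, , drop = FALSE]
  resid2 <- (X - pred)^2
  tot2 <- sweep(X, 2L, colMeans(X))^2
  r2_col <- 1 - colSums(resid2) / pmax(colSums(tot2), .Machine$double.eps)
  model$r_squared <- setNames(
    (r2_col[seq_len(N)] + r2_col[N + seq_len(N)]) / 2, genes)
  model
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("TrainedModel: %d genes, %d phase bins, seed gene %s\n",
              length(x$genes), x$cfg$n_bins, x$input_gene))
  cat(sprintf("  epochs: step1 %d, step2 %d; median gene R^2 = %.2f\n",
              length(x$history$step1_val), length(x$history$step2_val),
              stats::median(x$r_squared)))
  invisible(x)
}


# cumulative arc length of the decoded loop in z-space, used to
# re-parameterize the latent circle at constant speed
arc_length_map <- function(model, n_fine = 1000L) {
  th <- seq(0, 1, length.out = n_fine + 1L)[-(n_fine + 1L)]
  Z <- decode_z(model, th)
  seg <- sqrt(rowSums((Z[c(seq(2L, n_fine), 1L), , drop = FALSE] - Z)^2))
  cum <- c(0, cumsum(pmax(seg, 1e-12)))
  list(phi = cum / cum[n_fine + 1L], theta = c(th, 1))
}

# map arc-length phase phi (cycles) to the decoder's native phase
phi_to_decoder <- function(model, phi) {
  if (is.null(model$arc)) return(phi)
  stats::approx(model$arc$phi, model$arc$theta,
                xout = wrap_phase(phi), rule = 2)$y
}

# decoder forward pass in z-score space at phases given in cycles;
# returns length(theta) x 2N
decode_z <- function(model, theta) {
  w <- model$weights
  z <- rbind(cos(2 * pi * wrap_phase(theta)),
             sin(2 * pi * wrap_phase(theta)))
  lrelu <- function(a) pmax(a, 0.1 * a)
  g1 <- lrelu(w$V1 %*% z + as.vector(w$c1))
  g2 <- lrelu(w$V2 %*% g1 + as.vector(w$c2))
  t(w$V3 %*% g2 + as.vector(w$c3))
}

#' Decode the predicted (u, s) expression at arbitrary phases
#'
#' Evaluates the trained decoder at the given phases. The output depends on
#' \eqn{\theta} only through \eqn{(\cos 2\pi\theta, \sin 2\pi\theta)}, so it
#' is exactly periodic: \code{decode_trajectory(m, 0.25)} and
#' \code{decode_trajectory(m, 1.25)} are identical.
#'
#' @param model a \code{TrainedModel}.
#' @param theta numeric vector of phases in cycles (wrapped mod 1).
#' @return array length(theta) x n_genes x 2 of predicted (s, u) on the
#'   smoothed-count scale.
#' @export
decode_trajectory <- function(model, theta) {
  stopifnot(is(model, "TrainedModel"))
  Z <- decode_z(model, phi_to_decoder(model, theta))
  N <- length(model$genes)
  st <- model$stats
  out <- array(NA_real_, dim = c(length(theta), N, 2L),
               dimnames = list(NULL, model$genes, c("s", "u")))
  out[, , "s"] <- sweep(sweep(Z[, seq_len(N), drop = FALSE],
                              2L, st$s_sd, "*"), 2L, st$s_mu, "+")
  out[, , "u"] <- sweep(sweep(Z[, N + seq_len(N), drop = FALSE],
                              2L, st$u_sd, "*"), 2L, st$u_mu, "+")
  out
}

#' Assign every cell to its nearest phase bin
#'
#' Standardizes the dataset with the training statistics and assigns each
#' cell to the phase bin whose decoded trajectory point is closest in
#' Euclidean distance in the 2N-dimensional standardized space. Works on
#' held-out cells too (e.g. an arrested subpopulation mapped with a model
#' trained on cycling cells). Distance ties go to the lower bin index.
#'
#' @param model a \code{TrainedModel}.
#' @param ds an \code{ExpressionDataset} containing all training genes.
#' @return a \code{PhaseAssignment}: \code{cell_ids}, \code{theta} (bin
#'   center, cycles), \code{bin} (0-based, in \code{[0, n_bins)}),
#'   \code{n_bins}, and the \code{normalized}/\code{oriented} flags (FALSE
#'   until \code{\link{normalize_and_align}}).
#' @export
assign_phase <- function(model, ds) {
  stopifnot(is(model, "TrainedModel"), is(ds, "ExpressionDataset"))
  if (is.null(ds$S_smooth)) stop("run knn_smooth() first")
  missing <- setdiff(model$genes, ds$gene_ids)
  if (length(missing) > 0L) {
    stop("genes missing from dataset: ", paste(missing, collapse = ", "))
  }
  st <- model$stats
  S <- ds$S_smooth[, model$genes, drop = FALSE]
  U <- ds$U_smooth[, model$genes, drop = FALSE]
  X <- cbind(sweep(sweep(S, 2L, st$s_mu), 2L, st$s_sd, "/"),
             sweep(sweep(U, 2L, st$u_mu), 2L, st$u_sd, "/"))
  Tz <- model$traj_z                      # n_bins x 2N
  # argmin_k ||x - t_k||^2 = argmin_k (||t_k||^2 - 2 x . t_k)
  d <- sweep(-2 * X %*% t(Tz), 2L, rowSums(Tz^2), "+")
  bin <- max.col(-d, ties.method = "first") - 1L
  n_bins <- model$cfg$n_bins
  structure(list(cell_ids = ds$cell_ids,
                 theta = (bin + 0.5) / n_bins,
                 bin = bin,
                 n_bins = n_bins,
                 normalized = FALSE, oriented = FALSE),
            class = "PhaseAssignment")
}

#' @export
print.PhaseAssignment <- function(x, ...) {
  cat(sprintf("PhaseAssignment: %d cells over %d bins (%s)\n",
              length(x$cell_ids), x$n_bins,
              if (x$normalized) "normalized, mitosis at theta = 1"
              else "raw orientation"))
  invisible(x)
}
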