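# internal: restrict a dataset to a cell subset (logical or index)
subset_cells <- function(ds, keep) {
  for (layer in c("S_raw", "U_raw", "S_smooth", "U_smooth")) {
    if (!is.null(ds[[layer]])) ds[[layer]] <- ds[[layer]][keep, , drop = FALSE]
  }
  ds$cell_ids <- ds$cell_ids[keep]
  ds$total_counts <- ds$total_counts[keep]
  if (!is.null(ds$true_phase)) ds$true_phase <- ds$true_phase[keep]
  if (!is.null(ds$true_labels)) ds$true_labels <- ds$true_labels[keep]
  ds$knn_graph <- NULL
  ds
}

#' Assemble a pipeline configuration
#'
#' Nested configuration for \code{\link{run_pipeline}}. Every block is
#' validated before any stage runs. The single global \code{seed} fans out
#' to per-stage seeds by fixed offsets so each stage is individually
#' reproducible.
#'
#' @param seed global integer seed.
#' @param outdir output directory for artifacts (phases.tsv,
#'   selection.tsv, summary.json); NULL writes nothing.
#' @param simulation a \code{\link{sim_config}} (its seed is overridden by
#'   the global seed), or NULL to load data via \code{input} instead.
#' @param input NULL, or a list with \code{spliced}, \code{unspliced},
#'   \code{cells}, \code{genes} paths for \code{\link{load_counts}}.
#' @param smoothing list with \code{n_neighbors}, \code{n_pcs}.
#' @param selection list with \code{alpha_level}, optional \code{gene_list}
#'   (path or character vector), \code{max_train_genes} (cap on genes
#'   passed to the autoencoder, strongest separations first).
#' @param model a \code{\link{model_config}}; \code{input_gene} NULL means
#'   the selected gene with the highest Hotelling T2.
#' @param annotation list with marker lists \code{s_genes},
#'   \code{g2m_genes}, \code{cyclin_e_genes} (character vectors or file
#'   paths; the default "planted" uses \code{\link{sim_marker_lists}} on
#'   simulated data).
#' @param verbose print stage progress.
#' @return a validated \code{PipelineConfig}.
#' @export
pipeline_config <- function(seed = 0L,
                            outdir = NULL,
                            simulation = sim_config(),
                            input = NULL,
                            smoothing = list(n_neighbors = 30L, n_pcs = 30L),
                            selection = list(alpha_level = 0.01,
                                             gene_list = NULL,
                                             max_train_genes = 40L),
                            model = model_config(),
                            annotation = list(s_genes = "planted",
                                              g2m_genes = "planted",
                                              cyclin_e_genes = "planted"),
                            verbose = FALSE) {
  blocks <- list(smoothing = smoothing, selection = selection,
                 model = model, annotation = annotation)
  for (nm in names(blocks)) {
    if (is.null(blocks[[nm]])) stop("missing configuration block: ", nm)
  }
  if (is.null(simulation) && is.null(input)) {
    stop("missing configuration block: simulation or input")
  }
  if (!is.null(simulation)) stopifnot(is(simulation, "SimulationConfig"))
  stopifnot(is(model, "ModelConfig"))
  if (!all(c("n_neighbors", "n_pcs") %in% names(smoothing))) {
    stop("smoothing block needs n_neighbors and n_pcs")
  }
  stopifnot(smoothing$n_neighbors >= 1L, smoothing$n_pcs >= 1L)
  if (is.null(selection$alpha_level) || selection$alpha_level < 0 ||
      selection$alpha_level > 1) {
    stop("selection block needs alpha_level in [0, 1]")
  }
  if (is.null(selection$max_train_genes)) selection$max_train_genes <- 40L
  for (nm in c("s_genes", "g2m_genes", "cyclin_e_genes")) {
    if (is.null(annotation[[nm]])) {
      stop("annotation block needs marker list: ", nm)
    }
  }
  structure(list(seed = as.integer(seed), outdir = outdir,
                 simulation = simulation, input = input,
                 smoothing = smoothing, selection = selection,
                 model = model, annotation = annotation,
                 verbose = isTRUE(verbose)),
            class = "PipelineConfig")
}

read_gene_list <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read.table(x, header = FALSE, stringsAsFactors = FALSE)[[1L]])
  }
  x
}

#' Run the full phase-inference pipeline
#'
#' Executes simulate/load, kNN smoothing, cycling-gene selection, circular
#' autoencoder training, phase assignment, transition annotation with
#' mitosis alignment, and the RNA-content fold change, writing a
#' machine-readable summary. When the dataset carries ground-truth phases
#' (simulations), the summary also reports the circular correlation
#' between inferred and true phase. When the dataset carries an arrested
#' subpopulation, the model is trained on cycling cells only and arrested
#' cells are mapped with the trained model.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return invisibly, a list with \code{summary} plus the intermediate
#'   objects (\code{ds}, \code{selection}, \code{model},
#'   \code{assignment}, \code{transitions}).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(is(cfg, "PipelineConfig"))
  say <- function(...) if (cfg$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("stage simulate/load")
  ds <- stage("data", {
    if (!is.null(cfg$simulation)) {
      sim <- cfg$simulation
      sim$seed <- cfg$seed
      simulate_population(sim)
    } else {
      load_counts(cfg$input$spliced, cfg$input$unspliced,
                  cfg$input$cells, cfg$input$genes)
    }
  })

  say("stage smooth (%d cells)", length(ds$cell_ids))
  ds <- stage("smooth", knn_smooth(ds, cfg$smoothing$n_neighbors,
                                   cfg$smoothing$n_pcs))

  say("stage select-genes")
  gene_list <- read_gene_list(cfg$selection$gene_list)
  selection <- stage("select", select_cycling_genes(
    ds, gene_list = gene_list,
    alpha_level = cfg$selection$alpha_level,
    seed = cfg$seed + 1L))
  sel_genes <- selection$gene[selection$selected]
  if (length(sel_genes) < 2L) {
    stop("pipeline stage 'select' failed: fewer than 2 genes selected")
  }
  train_genes <- utils::head(sel_genes, cfg$selection$max_train_genes)

  mcfg <- cfg$model
  mcfg$seed <- cfg$seed + 2L
  if (is.null(mcfg$input_gene)) mcfg$input_gene <- train_genes[1L]

  has_arrest <- !is.null(ds$true_labels) && any(ds$true_labels == "arrested")
  train_ds <- if (has_arrest) subset_cells(ds, ds$true_labels != "arrested")
              else ds

  say("stage fit (%d genes, input gene %s)", length(train_genes),
      mcfg$input_gene)
  model <- stage("fit", train_deepcycle(train_ds, train_genes, mcfg))

  say("stage assign")
  assignment <- stage("assign", assign_phase(model, ds))

  say("stage annotate")
  markers <- lapply(
    cfg$annotation[c("s_genes", "g2m_genes", "cyclin_e_genes")],
    function(x) {
      if (identical(x, "planted")) {
        if (is.null(attr(ds, "sim_params"))) {
          stop("'planted' marker lists require simulated data")
        }
        return(NULL)
      }
      read_gene_list(x)
    })
  if (is.null(markers$s_genes)) {
    planted <- sim_marker_lists(ds)
    markers <- planted[c("s_genes", "g2m_genes", "cyclin_e_genes")]
  }
  annotated <- stage("annotate", {
    tab <- build_score_table(ds, assignment, markers$s_genes,
                             markers$g2m_genes, markers$cyclin_e_genes)
    tr <- detect_transitions(tab)
    normalize_and_align(assignment, tr)
  })
  transitions <- annotated$transitions

  fold <- stage("fold-change", rna_fold_change(ds, annotated))

  phase_labels <- assign_cell_cycle_phase(annotated)
  summary <- list(
    n_cells = length(ds$cell_ids),
    n_genes = length(ds$gene_ids),
    n_selected = length(sel_genes),
    selected_genes = sel_genes,
    train_genes = train_genes,
    input_gene = mcfg$input_gene,
    transitions = list(theta_G1S = transitions$theta_G1S,
                       theta_SG2 = transitions$theta_SG2,
                       theta_MG1 = transitions$theta_MG1,
                       orientation_flipped = transitions$orientation_flipped,
                       rotation_applied = transitions$rotation_applied),
    fold_change = fold,
    phase_fractions = as.list(table(phase_labels) / length(phase_labels)),
    theta = setNames(annotated$theta, ds$cell_ids),
    seed = cfg$seed)
  if (!is.null(ds$true_phase)) {
    summary$phase_recovery <- abs(
      circular_correlation(annotated$theta, ds$true_phase))
  }

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(
      data.frame(cell_id = ds$cell_ids, theta = annotated$theta,
                 bin = annotated$bin, phase = phase_labels),
      file.path(cfg$outdir, "phases.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(selection, file.path(cfg$outdir, "selection.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }

  invisible(list(summary = summary, ds = ds, selection = selection,
                 model = model, assignment = annotated,
                 transitions = transitions))
}
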