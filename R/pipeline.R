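#' Pipeline configuration
#'
#' Collects every workflow constant in one validated object: preprocessing
#' thresholds, model settings, resampling settings and the master seed. All
#' randomness in a run derives from `seed` with fixed stage offsets
#' (simulation uses `seed`, the split plan uses `seed + 1000`), so stages
#' can be re-run in isolation.
#'
#' @param out_dir output directory for result files (NULL = no files).
#' @param seed master seed (mandatory; there is no silent nondeterminism).
#' @param input_dir optional directory holding a cohort written by
#'   [write_cohort]; when NULL a synthetic cohort is simulated.
#' @param synthetic a [synthetic_config] used when simulating.
#' @param eps M-value clipping constant.
#' @param miss_thresh,hwe_alpha genotype QC thresholds.
#' @param n_splits,train_frac,persistence_threshold resampling settings.
#' @param n_components latent components (default 2).
#' @param keepX_select per-block sparsity budgets for pre-selection.
#' @param design_inter inter-block design weight (outcome weights are 1).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1, input_dir = NULL,
                            synthetic = NULL,
                            eps = 1e-6, miss_thresh = 0.05,
                            hwe_alpha = 1e-6,
                            n_splits = 100, train_frac = 0.8,
                            persistence_threshold = 0.7, n_components = 2,
                            keepX_select = list(expression = 50,
                                                methylation = 50,
                                                genotype = 20),
                            design_inter = 1) {
  if (is.null(seed) || !is.finite(seed)) stop("a seed is mandatory")
  if (persistence_threshold <= 0 || persistence_threshold > 1)
    stop("persistence_threshold must be in (0, 1]")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 input_dir = input_dir, synthetic = synthetic,
                 eps = eps, miss_thresh = miss_thresh,
                 hwe_alpha = hwe_alpha, n_splits = n_splits,
                 train_frac = train_frac,
                 persistence_threshold = persistence_threshold,
                 n_components = n_components, keepX_select = keepX_select,
                 design_inter = design_inter),
            class = "pipeline_config")
}

#' Preprocess a cohort into analysis-ready blocks
#'
#' Expression: low-median filter, median-of-ratios size factors,
#' `log2(count / sf + 1)`. Methylation: M-value transform. Genotypes:
#' missingness / HWE / monomorphism QC with mean-dosage imputation.
#' Phenotypes: sex/age/BMI/stimulatory-index block (HbA1c dropped).
#'
#' @param cohort a [simulate_cohort] or [read_cohort] result.
#' @param eps,miss_thresh,hwe_alpha thresholds (see [pipeline_config]).
#' @return list with `blocks` (named list of [omics_block]s), `reports`
#'   (QC reports) and `size_factors`.
#' @export
preprocess_cohort <- function(cohort, eps = 1e-6, miss_thresh = 0.05,
                              hwe_alpha = 1e-6) {
  counts <- t(cohort$expression_counts$values)      # genes x samples
  fl <- filter_low_expression(counts)
  sf <- size_factors(fl$counts)
  expr <- t(normalize_and_log(fl$counts, sf))
  mval <- beta_to_m(cohort$methylation_beta$values, eps)
  qc <- qc_genotypes(t(cohort$genotype_dosage$values),
                     miss_thresh = miss_thresh, hwe_alpha = hwe_alpha)
  list(blocks = list(
         expression = omics_block(expr, "expression"),
         methylation = omics_block(mval, "methylation"),
         genotype = omics_block(t(qc$dosages), "genotype"),
         phenotype = assemble_phenotype_block(cohort$phenotypes)),
       reports = list(low_expression = fl$report, genotype = qc$report),
       size_factors = sf)
}

#' Run the full integration workflow
#'
#' simulate (or read) -> preprocess -> split plan -> persistence selection
#' over the omics blocks -> integrative evaluation on the persistent panel
#' (phenotype block exempt from selection) -> per-block comparison models ->
#' interpretation outputs. With `out_dir` set, tidy TSV/JSON result files
#' and a run manifest (config snapshot, seed, dimensions, output checksums)
#' are written; identical seeds yield byte-identical outputs.
#'
#' @param config a [pipeline_config].
#' @return invisibly, a list with the cohort, blocks, plan, panel,
#'   evaluation results (`evaluations`), interpretation objects and the
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir))
      stop("input directory not found: ", config$input_dir)
    cohort <- read_cohort(config$input_dir)
    log_stage("input", "read cohort from %s", config$input_dir)
  } else {
    cohort <- simulate_cohort(config$synthetic)
    log_stage("simulate", "n = %d, cases = %d", length(cohort$labels),
              sum(cohort$labels))
  }
  y <- factor(ifelse(cohort$labels == 1, "case", "control"),
              levels = c("control", "case"))

  prep <- preprocess_cohort(cohort, eps = config$eps,
                            miss_thresh = config$miss_thresh,
                            hwe_alpha = config$hwe_alpha)
  blocks <- prep$blocks
  log_stage("preprocess", "dims: %s",
            paste(sprintf("%s=%d", names(blocks),
                          vapply(blocks, function(b) ncol(b$values),
                                 integer(1))), collapse = ", "))

  plan <- make_splits(length(y), n_splits = config$n_splits,
                      train_frac = config$train_frac,
                      seed = config$seed + 1000)
  omic_names <- setdiff(names(blocks), "phenotype")
  panel <- run_persistence_selection(blocks[omic_names], y, plan,
                                     keepX = config$keepX_select,
                                     n_components = config$n_components,
                                     threshold = config$persistence_threshold)
  log_stage("select", "panel: %s",
            paste(sprintf("%s=%d", names(panel$panel),
                          lengths(panel$panel)), collapse = ", "))

  design <- make_design(names(blocks), inter_block = config$design_inter)
  evals <- list(
    integrative = evaluate_over_splits(
      blocks, y, plan, panel = panel$panel, model = "block",
      n_components = config$n_components, design = design))
  for (b in names(blocks)) {
    pb <- if (b %in% names(panel$panel)) panel$panel[b] else NULL
    evals[[b]] <- tryCatch(
      evaluate_over_splits(blocks, y, plan, panel = pb, model = b,
                           n_components = config$n_components),
      error = function(e) {
        warning("single-block evaluation failed for '", b, "': ",
                conditionMessage(e))
        NULL
      })
  }
  acc2 <- metric_distribution(evals$integrative, "accuracy",
                              config$n_components)
  log_stage("evaluate", "integrative accuracy (comp %d): %.1f +/- %.1f %%",
            config$n_components, 100 * acc2$mean, 100 * acc2$sd)

  ## final model on the full cohort for interpretation
  keep <- panel$panel[lengths(panel$panel) > 0]
  full <- blocks
  for (b in names(keep))
    full[[b]]$values <- full[[b]]$values[, keep[[b]], drop = FALSE]
  full <- full[c(names(keep), "phenotype")]
  scaled <- lapply(full, function(b) autoscale(b)$values)
  final <- fit_block_plsda(scaled, y, n_components = config$n_components,
                           design = make_design(names(scaled),
                                                config$design_inter))
  fc <- feature_component_correlations(final, scaled)
  assoc <- cross_omics_association(fc)
  net <- build_network(assoc, threshold = 0.7)
  heat <- cluster_heatmap_order(do.call(cbind, scaled))
  arrows <- arrow_plot_data(final)
  log_stage("interpret", "%d panel features, network avg degree %.2f",
            nrow(assoc), net$average_degree)

  manifest <- list(
    config = config[setdiff(names(config), c("synthetic"))],
    seed = config$seed,
    package_version = as.character(utils::packageVersion("blockpls")),
    dimensions = lapply(blocks, function(b) dim(b$values)),
    panel_sizes = lengths(panel$panel),
    skipped_splits = evals$integrative$skipped,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(cohort = cohort, blocks = blocks, plan = plan,
                 panel = panel, evaluations = evals, final_model = final,
                 feature_correlations = fc, association = assoc,
                 network = net, heatmap = heat, arrows = arrows,
                 manifest = manifest)
  if (!is.null(config$out_dir)) {
    result$manifest$files <- write_pipeline_outputs(result, config$out_dir)
  }
  invisible(result)
}

# Serialize the tidy result tables; returns named paths with checksums.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  panel_df <- do.call(rbind, lapply(names(result$panel$frequencies),
    function(b) {
      f <- result$panel$frequencies[[b]]
      data.frame(block = b, feature = names(f), frequency = unname(f),
                 in_panel = names(f) %in% result$panel$panel[[b]])
    }))
  paths <- c(
    panel = wt(panel_df, "panel.tsv"),
    metrics = wt(do.call(rbind, lapply(names(result$evaluations),
      function(m) {
        ev <- result$evaluations[[m]]
        if (is.null(ev)) return(NULL)
        cbind(model = m, ev$metrics)
      })), "metrics.tsv"),
    summary = wt(do.call(rbind, lapply(names(result$evaluations),
      function(m) {
        ev <- result$evaluations[[m]]
        if (is.null(ev)) return(NULL)
        cbind(model = m, ev$summary)
      })), "summary.tsv"),
    arrows = wt(result$arrows, "arrow_plot.tsv"),
    network = wt(result$network$edges, "network_edges.tsv"),
    heatmap = wt(data.frame(
      axis = c(rep("sample", length(result$heatmap$sample_order)),
               rep("feature", length(result$heatmap$feature_order))),
      position = c(seq_along(result$heatmap$sample_order),
                   seq_along(result$heatmap$feature_order)),
      id = c(result$heatmap$sample_order, result$heatmap$feature_order)),
      "heatmap_order.tsv"))
  assoc_path <- file.path(out_dir, "association.tsv")
  assoc_df <- data.frame(feature = rownames(result$association),
                         block = unname(attr(result$association, "block")),
                         as.data.frame(unclass(result$association)))
  utils::write.table(assoc_df, assoc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, association = assoc_path)
  mpath <- file.path(out_dir, "manifest.json")
  manifest <- result$manifest
  manifest$files <- NULL
  manifest$checksums <- as.list(tools::md5sum(unname(paths)))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  c(paths, manifest = mpath)
}
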