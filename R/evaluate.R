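#' Plan repeated unstratified hold-out train/test splits
#'
#' Each split draws `floor(train_frac * n)` training samples uniformly at
#' random, without regard to class labels — so the case/control ratio varies
#' between splits, mirroring deployment on an unselected population. Split
#' `i` is seeded with `seed + i`, so any split can be regenerated in
#' isolation.
#'
#' @param n number of samples.
#' @param n_splits number of repetitions (default 100).
#' @param train_frac training fraction in `(0, 1)` (default 0.8).
#' @param seed master seed.
#' @return a `split_plan`: list of `list(train, test)` index pairs plus the
#'   plan parameters.
#' @export
make_splits <- function(n, n_splits = 100, train_frac = 0.8, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  n_train <- floor(train_frac * n)
  if (n_train < 1 || n_train >= n)
    stop("train or test set would be empty at n = ", n)
  splits <- lapply(seq_len(n_splits), function(i) {
    set.seed(seed + i)
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  })
  structure(list(splits = splits, n = n, n_splits = n_splits,
                 train_frac = train_frac, seed = seed),
            class = "split_plan")
}

#' @exportS3Method base::print
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d splits of %d samples (train %d / test %d)\n",
              x$n_splits, x$n, length(x$splits[[1]]$train),
              length(x$splits[[1]]$test)))
  invisible(x)
}

#' Persistence (stability) feature selection across hold-out splits
#'
#' Per split and per omics block: autoscale the training portion, fit a
#' sparse two-component PLS-DA with that block's `keepX` budget, and mark a
#' feature "selected" if it carries a nonzero loading on any component. A
#' feature's selection frequency is its selected-split count divided by the
#' number of splits; the persistent panel keeps features whose frequency
#' reaches `threshold` ("at least" semantics: frequency == threshold is in).
#'
#' @param blocks named list of preprocessed [omics_block]s or matrices
#'   (samples x features), all sharing sample order.
#' @param y two-class labels.
#' @param plan a [make_splits] plan covering the blocks' samples.
#' @param keepX named list of per-block sparsity budgets.
#' @param n_components components per fit (default 2).
#' @param threshold persistence threshold (default 0.7).
#' @return a `feature_panel`: per-block frequency vectors, the threshold,
#'   the per-block persistent feature sets, and the skipped-split count.
#' @export
run_persistence_selection <- function(blocks, y, plan, keepX,
                                      n_components = 2, threshold = 0.7) {
  y <- as_class_factor(y)
  Xs <- lapply(blocks, as_block_matrix)
  if (any(vapply(Xs, nrow, integer(1)) != plan$n))
    stop("plan does not cover the blocks' samples")
  for (b in names(Xs)) {
    k <- if (b %in% names(keepX)) keepX[[b]] else "all"
    if (is.numeric(k) && any(k > ncol(Xs[[b]])))
      stop("keepX exceeds block size for '", b, "'")
  }
  counts <- lapply(Xs, function(x) {
    v <- numeric(ncol(x)); names(v) <- colnames(x); v
  })
  skipped <- 0L
  for (sp in plan$splits) {
    ytr <- y[sp$train]
    if (length(unique(ytr)) < 2 || any(table(ytr) < 2)) {
      skipped <- skipped + 1L
      warning("skipping a split with a degenerate training class balance")
      next
    }
    for (b in names(Xs)) {
      k <- if (b %in% names(keepX)) keepX[[b]] else "all"
      sc <- autoscale(Xs[[b]][sp$train, , drop = FALSE])
      fit <- fit_plsda(sc$values, ytr, n_components = n_components,
                       keepX = k)
      sel <- selected_features(fit)
      counts[[b]][sel] <- counts[[b]][sel] + 1
    }
  }
  freqs <- lapply(counts, function(v) v / plan$n_splits)
  structure(list(frequencies = freqs, threshold = threshold,
                 panel = lapply(freqs, function(f) names(f)[f >= threshold]),
                 n_splits = plan$n_splits, skipped = skipped),
            class = "feature_panel")
}

#' Re-threshold a feature panel
#'
#' Recomputes the persistent sets at a new threshold from the stored
#' frequencies; raising the threshold can only shrink each set.
#'
#' @param panel a [run_persistence_selection] result.
#' @param threshold new persistence threshold.
#' @return a `feature_panel` at the new threshold.
#' @export
panel_at_threshold <- function(panel, threshold) {
  panel$threshold <- threshold
  panel$panel <- lapply(panel$frequencies,
                        function(f) names(f)[f >= threshold])
  panel
}

#' @exportS3Method base::print
print.feature_panel <- function(x, ...) {
  cat(sprintf("feature_panel (threshold %.2f over %d splits):\n",
              x$threshold, x$n_splits))
  for (b in names(x$panel))
    cat(sprintf("  %s: %d persistent feature(s)\n", b, length(x$panel[[b]])))
  invisible(x)
}

#' Evaluate a model over repeated hold-out splits
#'
#' Per split: restrict each block to its panel features, autoscale the
#' training portion and apply the training statistics to the test portion,
#' fit the requested model (integrative multi-block, or a single-block
#' PLS-DA), and score the test set per cumulative component with accuracy,
#' ROC AUC and MCC, alongside the majority-class baseline learned on the
#' training labels. Splits whose training set lacks two usable classes are
#' skipped with a warning and counted.
#'
#' In `mode = "per_split"` the panel argument is ignored for selection:
#' features are re-selected within each split by a sparse PLS-DA fit with
#' `keepX_select`, reproducing the fully split-local workflow.
#'
#' @param blocks named list of preprocessed blocks (samples x features).
#' @param y two-class labels.
#' @param plan a [make_splits] plan.
#' @param panel optional named list of feature IDs per block (e.g. the
#'   `panel` element of a [run_persistence_selection] result); blocks not
#'   named keep all features. Blocks whose panel is empty are dropped.
#' @param model `"block"` for the integrative model, or the name of a single
#'   block.
#' @param n_components components to fit and evaluate cumulatively.
#' @param keepX named list of per-block budgets for the evaluated model
#'   (default all features of the restricted blocks).
#' @param design design matrix for the integrative model (default full).
#' @param mode `"fixed_panel"` (default) or `"per_split"`.
#' @param keepX_select per-block budgets for split-local selection (only in
#'   `"per_split"` mode).
#' @return list with `metrics` (long data.frame: split, component, metric,
#'   value), `summary` (mean/SD per metric and component), `skipped`, and
#'   the evaluated `model` label.
#' @export
evaluate_over_splits <- function(blocks, y, plan, panel = NULL,
                                 model = "block", n_components = 2,
                                 keepX = list(), design = NULL,
                                 mode = c("fixed_panel", "per_split"),
                                 keepX_select = list()) {
  mode <- match.arg(mode)
  y <- as_class_factor(y)
  Xs <- lapply(blocks, as_block_matrix)
  if (model != "block") {
    if (!model %in% names(Xs)) stop("unknown block '", model, "'")
    Xs <- Xs[model]
  }
  if (mode == "fixed_panel" && !is.null(panel)) {
    for (b in intersect(names(panel), names(Xs)))
      Xs[[b]] <- Xs[[b]][, intersect(colnames(Xs[[b]]), panel[[b]]),
                         drop = FALSE]
    empty <- names(Xs)[vapply(Xs, ncol, integer(1)) == 0]
    if (length(empty)) {
      warning("dropping block(s) with an empty panel: ",
              paste(empty, collapse = ", "))
      Xs <- Xs[setdiff(names(Xs), empty)]
    }
    if (!length(Xs)) stop("no block has a nonempty panel")
  }
  case <- levels(y)[2]
  rows <- list()
  skipped <- 0L
  for (si in seq_along(plan$splits)) {
    sp <- plan$splits[[si]]
    ytr <- y[sp$train]; yte <- y[sp$test]
    if (length(unique(ytr)) < 2 || any(table(ytr) < 2)) {
      skipped <- skipped + 1L
      warning("skipping split ", si, ": degenerate training class balance")
      next
    }
    Xb <- Xs
    if (mode == "per_split") {
      for (b in names(Xb)) {
        if (!b %in% names(keepX_select)) next
        sc <- autoscale(Xb[[b]][sp$train, , drop = FALSE])
        fit <- fit_plsda(sc$values, ytr, n_components = n_components,
                         keepX = keepX_select[[b]])
        Xb[[b]] <- Xb[[b]][, selected_features(fit), drop = FALSE]
      }
    }
    tr <- lapply(Xb, function(x) autoscale(x[sp$train, , drop = FALSE]))
    te <- mapply(function(x, s)
      autoscale(x[sp$test, , drop = FALSE], train_stats = s$stats)$values,
      Xb, tr, SIMPLIFY = FALSE)
    trv <- lapply(tr, `[[`, "values")

    if (model == "block") {
      fit <- fit_block_plsda(trv, ytr, n_components = n_components,
                             keepX = keepX, design = design)
      predict_k <- function(k) predict_consensus(fit, te, k)
    } else {
      kx <- if (model %in% names(keepX)) keepX[[model]] else "all"
      fit <- fit_plsda(trv[[model]], ytr, n_components = n_components,
                       keepX = kx)
      predict_k <- function(k) predict_plsda(fit, te[[model]], k)
    }
    base_pred <- rep(levels(y)[which.max(table(ytr))], length(yte))
    rows[[length(rows) + 1]] <- data.frame(
      split = si, component = NA_integer_, metric = "baseline_accuracy",
      value = accuracy(base_pred, yte))
    for (k in seq_len(n_components)) {
      pr <- predict_k(k)
      cc <- confusion_counts(pr$labels, yte, case)
      auc <- if (length(unique(yte)) == 2)
        roc_auc(pr$decision, yte, positive = case) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        split = si, component = k,
        metric = c("accuracy", "auc", "mcc"),
        value = c(accuracy(pr$labels, yte), auc,
                  mcc(cc["tp"], cc["tn"], cc["fp"], cc["fn"])))
    }
  }
  metrics <- do.call(rbind, rows)
  main <- metrics[metrics$metric != "baseline_accuracy", , drop = FALSE]
  summary <- stats::aggregate(value ~ metric + component, main,
                              function(v) c(mean = mean(v, na.rm = TRUE),
                                            sd = stats::sd(v, na.rm = TRUE)),
                              na.action = stats::na.pass)
  summary <- data.frame(metric = summary$metric,
                        component = summary$component,
                        mean = summary$value[, "mean"],
                        sd = summary$value[, "sd"])
  base <- metrics[metrics$metric == "baseline_accuracy", "value"]
  summary <- rbind(summary,
                   data.frame(metric = "baseline_accuracy",
                              component = NA_integer_,
                              mean = mean(base), sd = stats::sd(base)))
  list(metrics = metrics, summary = summary, skipped = skipped,
       model = model)
}

#' Mean/SD summary of one metric from an evaluation result
#'
#' @param eval_result an [evaluate_over_splits] result.
#' @param metric metric name.
#' @param component component index (NA for the baseline).
#' @return list with `mean`, `sd`, `values`.
#' @export
metric_distribution <- function(eval_result, metric, component = NA) {
  m <- eval_result$metrics
  sel <- m$metric == metric &
    (if (is.na(component)) is.na(m$component) else
      !is.na(m$component) & m$component == component)
  v <- m$value[sel]
  if (!length(v)) stop("no values for metric '", metric, "'")
  list(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
       values = v)
}
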