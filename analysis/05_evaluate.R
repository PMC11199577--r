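#!/usr/bin/env Rscript

# Step 5 — hold-out evaluation of the integrative and single-block models.
#
# Over the same 100 splits used for selection: restrict to the persistent
# panel, refit on each training set (integrative model and each block
# alone), and score the 22 held-out samples per cumulative component with
# accuracy, ROC AUC and MCC. The majority-class baseline is learned per
# split from the training labels. Per-split accuracies of the integrative
# model are compared with each single-omic model by Mann-Whitney U tests.

suppressPackageStartupMessages(library(blockpls))

cohort <- readRDS("scratch/01_cohort.rds")
prep <- readRDS("scratch/02_preprocessed.rds")
sel <- readRDS("scratch/03_selection.rds")
y <- cohort$labels

models <- c("block", "expression", "methylation", "genotype", "phenotype")
evals <- list()
for (m in models) {
  pb <- if (m == "block") sel$panel$panel else
    if (m %in% names(sel$panel$panel)) sel$panel$panel[m] else NULL
  evals[[m]] <- suppressWarnings(
    evaluate_over_splits(prep$blocks, y, sel$plan, panel = pb, model = m,
                         n_components = 2))
}
saveRDS(evals, "scratch/05_evaluations.rds")

summary_df <- do.call(rbind, lapply(names(evals), function(m)
  cbind(model = m, evals[[m]]$summary)))
write.table(summary_df, "results/05_metrics_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (m in models) {
  a <- metric_distribution(evals[[m]], "accuracy", 2)
  message(sprintf("%-12s accuracy (comp 2): %5.1f +/- %4.1f %%",
                  m, 100 * a$mean, 100 * a$sd))
}
base <- metric_distribution(evals$block, "baseline_accuracy")
message(sprintf("%-12s accuracy          : %5.1f +/- %4.1f %%",
                "baseline", 100 * base$mean, 100 * base$sd))

# integrative vs single-omic per-split accuracy comparisons
comp <- do.call(rbind, lapply(setdiff(models, "block"), function(m) {
  mw <- mann_whitney_u(
    metric_distribution(evals$block, "accuracy", 2)$values,
    metric_distribution(evals[[m]], "accuracy", 2)$values)
  data.frame(comparison = paste0("integrative_vs_", m),
             U = mw$U, p = mw$p)
}))
write.table(comp, "results/05_model_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/05_metrics_summary.tsv and ",
        "results/05_model_comparisons.tsv")
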