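#!/usr/bin/env Rscript

# Step 1 — simulate the synthetic multi-omics cohort.
#
# Builds a 110-donor cohort (32 cases / 78 controls) with three omics blocks
# at reduced desk-scale dimensions (2000 genes, 3000 CpGs, 1000 SNPs), 20
# planted informative features per block at standardized effect size 2, and
# phenotypes drawn from the published per-class summaries. The full cohort
# (matrices, labels, phenotypes, VCF, planted truth) is written under
# scratch/ for the later steps; a small structural summary goes to results/.

suppressPackageStartupMessages(library(blockpls))

seed <- 1
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
cohort <- simulate_cohort(cfg)
print(cohort)

write_cohort(cohort, "scratch/cohort")
saveRDS(cohort, "scratch/01_cohort.rds")

summary_df <- data.frame(
  block = c("expression", "methylation", "genotype", "phenotype"),
  features = c(ncol(cohort$expression_counts$values),
               ncol(cohort$methylation_beta$values),
               ncol(cohort$genotype_dosage$values), 4),
  planted = c(nrow(cohort$truth$expression),
              nrow(cohort$truth$methylation),
              nrow(cohort$truth$genotype), 0))
write.table(summary_df, "results/01_cohort_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("cohort: %d samples (%d cases); blocks: %s",
                length(cohort$labels), sum(cohort$labels),
                paste(summary_df$block, summary_df$features,
                      sep = "=", collapse = ", ")))
message("wrote scratch/cohort/ and results/01_cohort_summary.tsv")
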