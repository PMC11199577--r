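#!/usr/bin/env Rscript

# Step 2 — preprocess each block to its analysis scale.
#
# Expression: drop genes with median raw count < 1, median-of-ratios size
# factors, log2(count/sf + 1). Methylation: M-values (clipped logit of
# beta). Genotypes: missingness (>5%), Hardy-Weinberg (p < 1e-6) and
# monomorphism filters, then mean-dosage imputation. Phenotypes: sex, age,
# BMI, stimulatory index (HbA1c is discarded — it is quasi-definitional for
# case status). QC bookkeeping goes to results/.

suppressPackageStartupMessages(library(blockpls))

cohort <- readRDS("scratch/01_cohort.rds")
prep <- preprocess_cohort(cohort)

saveRDS(prep, "scratch/02_preprocessed.rds")

qc <- do.call(rbind, lapply(names(prep$reports), function(nm) {
  r <- prep$reports[[nm]]
  data.frame(stage = nm, filter = names(r$removed),
             removed = unname(r$removed), features_in = r$n_in,
             features_out = r$n_out)
}))
write.table(qc, "results/02_qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (b in names(prep$blocks)) print(prep$blocks[[b]])
message(sprintf("size factors span %.2f-%.2f across samples",
                min(prep$size_factors), max(prep$size_factors)))
message("wrote results/02_qc_report.tsv")
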