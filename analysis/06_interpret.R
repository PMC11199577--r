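#!/usr/bin/env Rscript

# Step 6 — interpretation layers over the fitted integrative model.
#
# Circle-plot coordinates (feature vs consensus-component correlations),
# the component-space cross-omics association matrix, correlation networks
# (overall and per block pair, with average degrees), and the
# hierarchical-clustering orders behind the panel heatmap.
#
# Link threshold: because the consensus averages four blocks, a single
# feature rarely correlates with a consensus component beyond ~0.8, which
# caps component-space associations near 0.6 on this cohort; the networks
# here therefore use |r| >= 0.5 (the package default of 0.7 suits data
# where fewer blocks dilute the consensus less).

suppressPackageStartupMessages(library(blockpls))

fit <- readRDS("scratch/04_model.rds")
cohort <- readRDS("scratch/01_cohort.rds")

fc <- feature_component_correlations(fit$model, fit$scaled)
circle <- data.frame(feature = rownames(fc),
                     block = unname(attr(fc, "block")),
                     comp1 = fc[, 1], comp2 = fc[, 2], row.names = NULL)
write.table(circle, "results/06_circle_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

assoc <- cross_omics_association(fc)
net <- build_network(assoc, threshold = 0.5)
print(net)
write.table(net$edges, "results/06_network_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

blocks <- unique(attr(assoc, "block"))
pairs <- t(combn(blocks, 2))
density <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  sub <- build_network(assoc, threshold = 0.5, block_pair = pairs[i, ])
  data.frame(block_a = pairs[i, 1], block_b = pairs[i, 2],
             edges = nrow(sub$edges), nodes = length(sub$nodes),
             average_degree = sub$average_degree)
}))
write.table(density, "results/06_network_density.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

heat <- cluster_heatmap_order(do.call(cbind, fit$scaled))
write.table(data.frame(
  axis = c(rep("sample", length(heat$sample_order)),
           rep("feature", length(heat$feature_order))),
  position = c(seq_along(heat$sample_order),
               seq_along(heat$feature_order)),
  id = c(heat$sample_order, heat$feature_order)),
  "results/06_heatmap_order.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

# do cases and controls occupy contiguous leaf ranges?
leaf_class <- cohort$labels[heat$sample_order]
boundaries <- sum(diff(leaf_class) != 0)
message(sprintf(
  "heatmap: %d class boundary(ies) along the sample dendrogram leaves",
  boundaries))
message("wrote results/06_* interpretation tables")
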