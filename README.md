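# blockpls

Supervised integration of multi-omics data for binary disease prediction:
multi-block sparse PLS-DA with persistence feature selection, built for
small-n / large-p case–control cohorts (on the order of 100 donors, with
RNA-seq counts, DNA-methylation betas, genotype dosages and clinical
phenotypes measured on the same samples).

## The method

Each omics block $X_i$ (samples × features, autoscaled) receives its own
sparse weight vector $a_i$ and latent score $t_i = X_i a_i$ per component.
The weights are estimated jointly, maximizing the design-weighted sum of
score covariances with the other blocks and with the dummy-coded outcome:

$$\max_{\{a_i\}} \sum_{i<j} c_{ij}\,\mathrm{cov}(t_i, t_j)
  + \sum_i c_{iY}\,\mathrm{cov}(t_i, t_Y),
  \qquad \lVert a_i \rVert_2 = 1,\ \lVert a_i \rVert_0 \le keepX_i,$$

solved by NIPALS-style block-coordinate ascent with hard thresholding, two
components by default. Samples are placed at their **consensus**
coordinate — the mean of their block scores — and classified by the
nearest consensus class centroid; the signed centroid-distance difference
feeds the ROC curve.

Feature selection is by **persistence**: over 100 random unstratified
80/20 train/test splits, a sparse PLS-DA is fitted per block on each
training set, and only features with a nonzero loading in at least 70% of
splits enter the final panel. Evaluation refits on each split's training
half and reports held-out accuracy, ROC AUC and Matthews correlation
(mean ± SD across splits) against the majority-class baseline; models are
compared by Mann–Whitney U tests on per-split accuracies.

Because the motivating donor data are access-restricted, the package
ships a seeded synthetic cohort generator with planted ground truth
(negative-binomial counts, Beta-distributed methylation with logit-space
effects, Hardy–Weinberg genotypes, phenotypes drawn from published
per-class summaries), so every stage is testable end to end. See
`vignettes/multiomics-integration.Rmd` for the model, assumptions, and
every numerical choice.

## Worked example

```r
library(blockpls)

co   <- simulate_cohort(synthetic_config(seed = 1))   # 110 donors, 32 cases
prep <- preprocess_cohort(co)                          # M-values, size factors, QC
plan <- make_splits(110, n_splits = 100, train_frac = 0.8, seed = 1001)

panel <- run_persistence_selection(
  prep$blocks[c("expression", "methylation", "genotype")],
  co$labels, plan,
  keepX = list(expression = 50, methylation = 50, genotype = 20))
print(panel)
#> feature_panel (threshold 0.70 over 100 splits):
#>   expression: 25 persistent feature(s)
#>   methylation: 29 persistent feature(s)
#>   genotype: 10 persistent feature(s)

ev  <- evaluate_over_splits(prep$blocks, co$labels, plan,
                            panel = panel$panel, model = "block")
acc <- metric_distribution(ev, "accuracy", 2)
base <- metric_distribution(ev, "baseline_accuracy")
sprintf("integrative accuracy %.1f +/- %.1f %% vs baseline %.1f %%",
        100 * acc$mean, 100 * acc$sd, 100 * base$mean)
#> [1] "integrative accuracy 100.0 +/- 0.0 % vs baseline 71.5 %"
```

The persistent panel recovers 82% of the planted features on this seed
(64 of the 6000 candidate features are retained, including 49 of the 60
planted), and the two-component integrative model separates the held-out
cases perfectly — about 29 accuracy points above the 71% majority
baseline, which is what a planted standardized effect of 2 should yield.
Genotype and phenotype blocks alone do far worse (93% and 59%), so the
signal genuinely lives in the joint panel.

The same steps run as a narrated workflow in `analysis/01_simulate.R`
through `analysis/06_interpret.R` (executed from the repository root, each
writing its tables under `results/` and its intermediates under
`scratch/`): cohort simulation, preprocessing/QC, persistence selection,
full-cohort integration (arrow-plot coordinates), hold-out evaluation with
model comparisons, and the interpretation layers (circle coordinates,
cross-omics association networks with per-block-pair edge densities,
heatmap clustering orders).

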