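test_that("split plans are unstratified, sized 80/20 and reproducible", {
  plan <- make_splits(110, n_splits = 100, train_frac = 0.8, seed = 7)
  expect_true(all(vapply(plan$splits, function(s) length(s$train),
                         integer(1)) == 88))
  expect_true(all(vapply(plan$splits, function(s) length(s$test),
                         integer(1)) == 22))
  for (s in plan$splits[1:5]) {
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), 1:110)
  }
  expect_identical(make_splits(110, 100, 0.8, seed = 7), plan)
  expect_false(identical(make_splits(110, 100, 0.8, seed = 8), plan))
  # unstratified: the test-set case count varies across splits
  co <- simulate_cohort(small_config(seed = 2))
  test_cases <- vapply(plan$splits,
                       function(s) sum(co$labels[s$test]), integer(1))
  expect_gt(length(unique(test_cases)), 1)
  expect_error(make_splits(3, 10, 0.01), "empty")
})

test_that("persistence panels obey the at-least-70% boundary and monotonicity", {
  fake <- structure(list(
    frequencies = list(ex = c(f1 = 0.70, f2 = 0.69, f3 = 0.95, f4 = 0.10)),
    threshold = 0.70,
    panel = list(ex = c("f1", "f3")),
    n_splits = 100, skipped = 0L), class = "feature_panel")
  at70 <- panel_at_threshold(fake, 0.70)
  expect_setequal(at70$panel$ex, c("f1", "f3"))   # 70/100 is in
  expect_false("f2" %in% at70$panel$ex)           # 69/100 is out
  at80 <- panel_at_threshold(fake, 0.80)
  expect_true(all(at80$panel$ex %in% at70$panel$ex))
  # monotone over a threshold grid
  for (thr in seq(0.1, 1, by = 0.1))
    expect_true(all(panel_at_threshold(fake, thr + 0.1)$panel$ex %in%
                      panel_at_threshold(fake, thr)$panel$ex))
})

test_that("persistence selection recovers planted features (reduced scale)", {
  co <- simulate_cohort(small_config(seed = 13))
  pr <- suppressMessages(preprocess_cohort(co))
  plan <- make_splits(110, n_splits = 30, seed = 99)
  omics <- pr$blocks[c("expression", "methylation", "genotype")]
  pan <- run_persistence_selection(
    omics, co$labels, plan,
    keepX = list(expression = 25, methylation = 25, genotype = 15))
  planted <- unlist(lapply(co$truth, function(d) d$feature))
  in_panel <- unlist(pan$panel)
  expect_gt(mean(planted %in% in_panel), 0.8)
  # frequencies live in [0, 1] and the panel respects the threshold
  for (b in names(pan$frequencies)) {
    expect_true(all(pan$frequencies[[b]] >= 0 & pan$frequencies[[b]] <= 1))
    expect_setequal(pan$panel[[b]],
                    names(which(pan$frequencies[[b]] >= 0.7)))
  }
  expect_error(
    run_persistence_selection(omics, co$labels, plan,
                              keepX = list(expression = 10000)),
    "keepX exceeds")
})

test_that("a perfectly separable signal evaluates to accuracy 1, SD 0", {
  set.seed(4)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  # every feature carries a shift far beyond the noise scale, so the classes
  # stay separated even after per-split autoscaling
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:3)))
  X[y == 1, ] <- X[y == 1, ] + 10
  plan <- make_splits(n, n_splits = 20, train_frac = 0.8, seed = 3)
  ev <- evaluate_over_splits(list(ex = X), y, plan, model = "ex",
                             n_components = 2)
  s <- ev$summary
  acc <- s[s$metric == "accuracy", ]
  expect_equal(acc$mean, c(1, 1))
  expect_equal(acc$sd, c(0, 0))
  expect_equal(s[s$metric == "mcc", "mean"], c(1, 1))
})

test_that("label permutation drives AUC to chance and accuracy to baseline", {
  co <- simulate_cohort(small_config(seed = 17))
  pr <- suppressMessages(preprocess_cohort(co))
  set.seed(555)
  y_perm <- sample(co$labels)
  names(y_perm) <- names(co$labels)
  plan <- make_splits(110, n_splits = 50, seed = 23)
  ev <- evaluate_over_splits(pr$blocks["expression"], y_perm, plan,
                             model = "expression", n_components = 2,
                             keepX = list(expression = 25))
  s <- ev$summary
  auc1 <- s[s$metric == "auc" & s$component == 1, ]
  expect_gt(auc1$mean, 0.4)
  expect_lt(auc1$mean, 0.6)
  # under the null a nearest-centroid classifier's expected accuracy lies
  # between the label-agreement rate of class-blind guessing
  # (p^2 + (1-p)^2) and the majority baseline; check the mean sits in that
  # band, widened by 3 SE of the per-split accuracies
  acc <- metric_distribution(ev, "accuracy", 1)
  base <- metric_distribution(ev, "baseline_accuracy")
  p_case <- mean(y_perm == 1)
  agree <- p_case^2 + (1 - p_case)^2
  se <- stats::sd(acc$values) / sqrt(length(acc$values))
  expect_gt(acc$mean, agree - 3 * se)
  expect_lt(acc$mean, base$mean + 3 * se)
})

test_that("single-class training splits are skipped and counted", {
  set.seed(8)
  n <- 12
  y <- c(rep(0, 9), rep(1, 3))
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:4)))
  plan <- make_splits(n, n_splits = 40, train_frac = 0.5, seed = 2)
  degenerate <- sum(vapply(plan$splits, function(s) {
    tab <- table(factor(y[s$train], levels = c(0, 1)))
    any(tab < 2)
  }, logical(1)))
  expect_gt(degenerate, 0)                   # the fixture exercises the path
  suppressWarnings(
    ev <- evaluate_over_splits(list(ex = X), y, plan, model = "ex",
                               n_components = 1))
  expect_equal(ev$skipped, degenerate)
  expect_equal(length(unique(ev$metrics$split)),
               plan$n_splits - degenerate)
})

test_that("MCC and accuracy rank model variants concordantly", {
  co <- simulate_cohort(small_config(
    seed = 19, effect_size = c(expression = 1.2, methylation = 0.8,
                               genotype = 0.5)))
  pr <- suppressMessages(preprocess_cohort(co))
  plan <- make_splits(110, n_splits = 20, seed = 31)
  pan <- run_persistence_selection(
    pr$blocks[c("expression", "methylation", "genotype")], co$labels, plan,
    keepX = list(expression = 25, methylation = 25, genotype = 15),
    threshold = 0.5)
  models <- c("block", "expression", "methylation", "genotype", "phenotype")
  acc <- mcc_v <- numeric(0)
  for (m in models) {
    pb <- if (m == "block") pan$panel else
      if (m %in% names(pan$panel)) pan$panel[m] else NULL
    ev <- suppressWarnings(
      evaluate_over_splits(pr$blocks, co$labels, plan, panel = pb,
                           model = m, n_components = 2))
    acc <- c(acc, metric_distribution(ev, "accuracy", 2)$mean)
    mcc_v <- c(mcc_v, metric_distribution(ev, "mcc", 2)$mean)
  }
  expect_gt(stats::cor(acc, mcc_v, method = "spearman"), 0.9)
})

test_that("mean and SD summaries are recomputable from per-split values", {
  sep <- separable_matrix(n = 30, p = 8, n_signal = 2, delta = 1.5, seed = 6)
  plan <- make_splits(30, n_splits = 15, seed = 4)
  ev <- evaluate_over_splits(list(ex = sep$X), sep$y, plan, model = "ex",
                             n_components = 2)
  for (k in 1:2) for (met in c("accuracy", "auc", "mcc")) {
    d <- metric_distribution(ev, met, k)
    row <- ev$summary[ev$summary$metric == met &
                        !is.na(ev$summary$component) &
                        ev$summary$component == k, ]
    expect_equal(row$mean, mean(d$values, na.rm = TRUE))
    expect_equal(row$sd, stats::sd(d$values, na.rm = TRUE))
  }
})

test_that("per-split selection mode mirrors the split-local workflow", {
  co <- simulate_cohort(small_config(seed = 23, n_genes = 150, n_cpgs = 100,
                                     n_snps = 60))
  pr <- suppressMessages(preprocess_cohort(co))
  plan <- make_splits(110, n_splits = 5, seed = 11)
  ev <- evaluate_over_splits(
    pr$blocks[c("expression", "methylation")], co$labels, plan,
    model = "block", n_components = 2, mode = "per_split",
    keepX_select = list(expression = 20, methylation = 20))
  acc <- metric_distribution(ev, "accuracy", 2)
  expect_length(acc$values, 5)
  expect_true(all(acc$values >= 0 & acc$values <= 1))
})
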