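test_that("M-value transform matches the clipped logit formula", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0, eps = 1e-6), log2(1e-6 / (1 - 1e-6)))
  expect_equal(beta_to_m(1, eps = 1e-6), -log2(1e-6 / (1 - 1e-6)))
  expect_error(beta_to_m(matrix(c(0.2, 1.3), 1)), "\\[1,2\\]")
  expect_error(beta_to_m(0.5, eps = 0.6), "eps")
  # monotonicity
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(beta_to_m(b)) > 0))
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(5, 9, 2, 5, 9, 2, 5, 9, 2), nrow = 3)
  expect_equal(unname(size_factors(m)), c(1, 1, 1))
  fx <- matrix(c(2, 2, 4, 4), nrow = 2)       # two genes x two samples
  expect_equal(unname(size_factors(fx)), c(1 / sqrt(2), sqrt(2)))
  # multiplying one sample's column by c scales its factor relative to the
  # others by c (the per-gene geometric means absorb c^(1/m))
  fx2 <- fx; fx2[, 2] <- fx2[, 2] * 3
  sf <- size_factors(fx); sf2 <- size_factors(fx2)
  expect_equal(sf2[2] / sf2[1], 3 * sf[2] / sf[1])
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  counts <- matrix(rnbinom(200 * 8, mu = 50, size = 5), 200, 8) + 1
  ours <- unname(size_factors(counts))
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(counts))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("count normalization absorbs global scaling and logs correctly", {
  expect_equal(normalize_and_log(matrix(3), 1), matrix(2))
  expect_equal(normalize_and_log(matrix(0), 2), matrix(0))
  fx <- matrix(c(2, 2, 4, 4), nrow = 2)
  norm <- normalize_and_log(fx, size_factors(fx))
  expect_equal(norm[, 1], norm[, 2])
  expect_equal(unname(2^norm[, 1] - 1), rep(2 * sqrt(2), 2))
  # the ratio estimator is scale-free: a global rescaling of all counts
  # leaves every factor unchanged (only relative depths are identified) ...
  set.seed(7)
  m <- matrix(rpois(60, 20) + 1, 10, 6)
  expect_equal(size_factors(m * 5), size_factors(m))
  # ... while per-sample depth differences are fully absorbed: columns that
  # are scalar multiples of each other normalize to identical columns
  base <- matrix(rpois(40, 30) + 1, 10, 4)
  depth <- c(0.5, 1, 2, 4)
  scaled <- sweep(base[, c(1, 1, 1, 1)], 2, depth, "*")
  nm <- normalize_and_log(scaled, size_factors(scaled))
  for (j in 2:4) expect_equal(nm[, j], nm[, 1])
  expect_error(normalize_and_log(m, rep(0, 6)), "positive")
})

test_that("low-expression filter uses the median >= 1 boundary", {
  m <- rbind(a = c(0, 0, 1), b = c(1, 1, 9), c = c(3, 5, 2))
  out <- filter_low_expression(m)
  expect_identical(rownames(out$counts), c("b", "c"))
  expect_equal(out$report$removed[["low_expression"]], 1)
  # idempotence
  again <- filter_low_expression(out$counts)
  expect_identical(again$counts, out$counts)
  # all-zero input
  z <- filter_low_expression(matrix(0, 3, 4))
  expect_equal(nrow(z$counts), 0)
  expect_equal(z$report$removed[["low_expression"]], 3)
})

test_that("HWE chi-square matches hand-computed fixtures", {
  r <- hwe_chisq(25, 50, 25)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  r2 <- hwe_chisq(30, 40, 30)
  expect_equal(r2$chi2, 4)                     # expected (25, 50, 25)
  expect_equal(r2$p, stats::pchisq(4, 1, lower.tail = FALSE))
  expect_error(hwe_chisq(100, 0, 0), "monomorphic")
  expect_error(hwe_chisq(-1, 2, 3), "non-negative")
})

test_that("genotype QC filters, imputes and keeps its books straight", {
  d <- rbind(
    v_miss = c(0, 1, NA, NA, NA, 2, 0, 1, 0, 1),  # 30% missing
    v_mono = rep(0, 10),
    v_ok   = c(0, 1, 2, 1, 0, 1, 2, 1, 0, 1),
    v_imp  = c(0, 1, NA, 1, 0, 1, 2, 1, 0, 1))    # 10% missing
  out <- qc_genotypes(d, miss_thresh = 0.15)
  expect_identical(rownames(out$dosages), c("v_ok", "v_imp"))
  expect_equal(unname(out$dosages["v_imp", 3]),
               mean(c(0, 1, 1, 0, 1, 2, 1, 0, 1)))
  rep <- out$report
  expect_equal(rep$n_in - sum(rep$removed), rep$n_out)
  # (0, 1, missing) with a permissive threshold imputes the observed mean
  tiny <- qc_genotypes(matrix(c(0, 1, NA), 1), miss_thresh = 0.5)
  expect_equal(unname(tiny$dosages[1, 3]), 0.5)
  # idempotence on the already-clean output (imputed values are no longer
  # integral dosages, so re-run on the integral rows only)
  again <- qc_genotypes(d[c("v_ok"), , drop = FALSE], miss_thresh = 0.15)
  expect_identical(again$dosages, out$dosages["v_ok", , drop = FALSE])
  expect_error(qc_genotypes(matrix(c(0, 3), 1)), "dosage")
})

test_that("HWE-violating variants are removed at the alpha threshold", {
  # 60 samples split between the two homozygotes, no heterozygotes:
  # chi2 = n = 60, p << 1e-6 (an all-het variant would instead be caught
  # by the single-observed-dosage filter)
  both <- rbind(bad = rep(c(0, 2), 30), ok = rep(c(0, 1, 2, 1), 15))
  out <- qc_genotypes(both, hwe_alpha = 1e-6)
  expect_identical(rownames(out$dosages), "ok")
  expect_equal(out$report$removed[["hwe"]], 1)
})

test_that("autoscaling standardizes, drops constants, honours train stats", {
  set.seed(1)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  sc <- autoscale(m)
  expect_lt(max(abs(colMeans(sc$values))), 1e-12)
  expect_equal(unname(apply(sc$values, 2, sd)), rep(1, 4))
  m2 <- cbind(m, konst = 5)
  sc2 <- autoscale(m2)
  expect_identical(sc2$stats$dropped, "konst")
  expect_equal(ncol(sc2$values), 4)
  # test rows scaled with train stats differ from self-scaling
  fx <- matrix(c(1, 2, 3, 10, 1, 1, 2, 8), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  tr <- autoscale(fx[1:2, , drop = FALSE])
  te_train_stats <- autoscale(fx[3:4, , drop = FALSE], tr$stats)$values
  te_own <- autoscale(fx[3:4, , drop = FALSE])$values
  expect_false(isTRUE(all.equal(te_train_stats, te_own)))
})

test_that("phenotype block keeps four coded features and drops HbA1c", {
  tab <- data.frame(sex = c("male", "female", "male"), age = c(60, 62, 70),
                    bmi = c(25, 28, 30), stimulatory_index = c(5, 7, 6),
                    hba1c = c(50, 36, 38))
  expect_message(b <- assemble_phenotype_block(tab), "HbA1c")
  expect_equal(ncol(b$values), 4)
  expect_false("hba1c" %in% colnames(b$values))
  expect_true(all(b$values[, "sex"] %in% c(0, 1)))
  expect_equal(unname(b$values[, "sex"]), c(1, 0, 1))
  expect_error(assemble_phenotype_block(tab[, c("sex", "age")]), "bmi")
})
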