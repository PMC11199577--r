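#' Convert methylation beta values to M-values
#'
#' M = log2(beta / (1 - beta)) after clipping beta into `[eps, 1 - eps]` so
#' that boundary values do not map to +/- infinity. M-values are the standard
#' analysis scale for array methylation.
#'
#' @param beta numeric matrix or vector with entries in `[0, 1]`.
#' @param eps clipping constant in `(0, 0.5)`; default `1e-6`.
#' @return object of the same shape with M-values.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 0.5)
    stop("`eps` must be a single value in (0, 0.5)")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad)) {
    coords <- if (is.matrix(beta)) {
      ij <- arrayInd(bad, dim(beta))
      paste0("[", ij[, 1], ",", ij[, 2], "]")
    } else as.character(bad)
    stop("beta values outside [0, 1] at: ",
         paste(utils::head(coords, 5), collapse = " "),
         if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Median-of-ratios size factors for count data
#'
#' The estimator divides each sample's counts by the per-gene geometric mean
#' across samples and takes the per-sample median of those ratios over genes
#' whose counts are positive in every sample (the median is taken in log
#' space, the standard convention — it differs from the arithmetic median of
#' ratios only in how an even number of genes is interpolated). This absorbs
#' relative library-size differences so that normalized counts are
#' comparable across samples; only relative depths are identified, so the
#' factors are anchored by the geometric-mean pseudo-reference, not by an
#' absolute scale.
#'
#' @param counts non-negative matrix, genes in rows, samples in columns.
#' @return positive numeric vector of per-sample size factors (named if the
#'   matrix has column names).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene has strictly positive counts in every sample; ",
         "size factors are undefined")
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  apply(counts[all_pos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_geo)))
}

#' Remove lowly expressed genes
#'
#' Keeps a gene iff its median unnormalized count across samples is at least
#' 1; genes below that are treated as non-informative noise.
#'
#' @param counts genes x samples count matrix.
#' @return list with `counts` (filtered matrix) and `report` (a [qc_report]).
#' @export
filter_low_expression <- function(counts) {
  counts <- as.matrix(counts)
  med <- apply(counts, 1, stats::median)
  keep <- med >= 1
  list(counts = counts[keep, , drop = FALSE],
       report = qc_report(
         n_in = nrow(counts), n_out = sum(keep),
         removed = c(low_expression = sum(!keep)),
         thresholds = c(median_count = 1)))
}

#' Normalize counts by size factors and log-transform
#'
#' Entry-wise `log2(count / size_factor + 1)`, a variance-stabilizing scale
#' suitable for downstream PLS.
#'
#' @param counts genes x samples matrix.
#' @param sf per-sample positive size factors (length `ncol(counts)`).
#' @return matrix of the same shape.
#' @export
normalize_and_log <- function(counts, sf) {
  counts <- as.matrix(counts)
  if (length(sf) != ncol(counts))
    stop("length(sf) != number of samples")
  if (any(sf <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the proportions expected from the estimated allele frequency.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return list with `chi2` and `p`.
#' @export
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  obs <- c(n_AA, n_Aa, n_aa)
  if (any(obs < 0)) stop("genotype counts must be non-negative")
  n <- sum(obs)
  if (n <= 0) stop("total genotype count must be positive")
  if (sum(obs > 0) < 2)
    stop("monomorphic genotype counts: HWE test undefined ",
         "(handled by the monomorphic filter)")
  p_hat <- (2 * n_AA + n_Aa) / (2 * n)
  expd <- c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2) * n
  nz <- expd > 0
  chi2 <- sum((obs[nz] - expd[nz])^2 / expd[nz])
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Genotype quality control
#'
#' Drops variants in order by (1) missingness above `miss_thresh`, (2)
#' Hardy-Weinberg equilibrium p-value below `hwe_alpha` (computed on all
#' samples), (3) monomorphism (a single observed dosage value). Remaining
#' missing entries are imputed with the variant's mean observed dosage, since
#' the downstream latent-variable models need complete data.
#'
#' @param dosages variants x samples matrix with entries in `{0, 1, 2, NA}`.
#' @param miss_thresh maximum tolerated missing fraction; default 0.05.
#' @param hwe_alpha HWE exclusion p-value; default `1e-6`.
#' @return list with `dosages` (filtered, imputed, variants x samples) and
#'   `report` (a [qc_report]).
#' @export
qc_genotypes <- function(dosages, miss_thresh = 0.05, hwe_alpha = 1e-6) {
  dosages <- as.matrix(dosages)
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1, 2 or missing")
  n_in <- nrow(dosages)

  miss_frac <- rowMeans(is.na(dosages))
  drop_miss <- miss_frac > miss_thresh
  d <- dosages[!drop_miss, , drop = FALSE]

  hwe_p <- apply(d, 1, function(v) {
    v <- v[!is.na(v)]
    counts <- c(sum(v == 0), sum(v == 1), sum(v == 2))
    if (sum(counts > 0) < 2) return(NA_real_)  # monomorphic: not testable
    hwe_chisq(counts[3], counts[2], counts[1])$p
  })
  drop_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  d <- d[!drop_hwe, , drop = FALSE]

  mono <- apply(d, 1, function(v) length(unique(v[!is.na(v)])) <= 1)
  d <- d[!mono, , drop = FALSE]

  if (anyNA(d)) {
    for (i in which(rowSums(is.na(d)) > 0)) {
      v <- d[i, ]
      d[i, is.na(v)] <- mean(v, na.rm = TRUE)
    }
  }
  list(dosages = d,
       report = qc_report(
         n_in = n_in, n_out = nrow(d),
         removed = c(missingness = sum(drop_miss),
                     hwe = sum(drop_hwe),
                     monomorphic = sum(mono)),
         thresholds = c(miss_thresh = miss_thresh, hwe_alpha = hwe_alpha)))
}

#' Autoscale a block (unit-variance standardization)
#'
#' Per feature: subtract the training mean and divide by the training SD.
#' Features with zero training SD carry no information and are dropped (and
#' recorded in the returned stats). When `train_stats` is supplied the stored
#' training statistics are applied instead — the test-set contract: test
#' samples are always scaled with the train split's parameters.
#'
#' @param x samples x features matrix or [omics_block].
#' @param train_stats optional `stats` element from a previous call.
#' @return list with `values` (scaled matrix) and `stats` (list: `center`,
#'   `scale`, `kept`, `dropped`).
#' @export
autoscale <- function(x, train_stats = NULL) {
  m <- as_block_matrix(x)
  if (is.null(train_stats)) {
    ctr <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    kept <- sdv > 0
    train_stats <- list(center = ctr[kept], scale = sdv[kept],
                        kept = colnames(m)[kept],
                        dropped = colnames(m)[!kept])
  }
  missing_feat <- setdiff(train_stats$kept, colnames(m))
  if (length(missing_feat))
    stop("features absent from input: ",
         paste(utils::head(missing_feat, 5), collapse = ", "))
  m <- m[, train_stats$kept, drop = FALSE]
  scaled <- sweep(sweep(m, 2, train_stats$center, "-"), 2,
                  train_stats$scale, "/")
  list(values = scaled, stats = train_stats)
}

#' Assemble the phenotype block
#'
#' Keeps sex, age, BMI and stimulatory index. HbA1c, if present, is discarded
#' (it is quasi-definitional for case status and would leak the label). Sex
#' is coded male = 1, female = 0.
#'
#' @param table data.frame with columns `sex`, `age`, `bmi`,
#'   `stimulatory_index` (and optionally `hba1c`, ignored). `sex` may be
#'   0/1 numeric or "male"/"female" character/factor.
#' @param sample_ids optional; defaults to `rownames(table)`.
#' @return an [omics_block] named `"phenotype"` with exactly four features.
#' @export
assemble_phenotype_block <- function(table, sample_ids = rownames(table)) {
  needed <- c("sex", "age", "bmi", "stimulatory_index")
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("missing phenotype column(s): ", paste(miss, collapse = ", "))
  if ("hba1c" %in% names(table))
    message("dropping HbA1c from the phenotype block (label-dependent)")
  sex <- table$sex
  if (is.character(sex) || is.factor(sex))
    sex <- as.integer(tolower(as.character(sex)) %in% c("male", "m", "1"))
  if (!all(sex %in% c(0, 1))) stop("sex must code to {0, 1}")
  m <- cbind(sex = as.numeric(sex), age = as.numeric(table$age),
             bmi = as.numeric(table$bmi),
             stimulatory_index = as.numeric(table$stimulatory_index))
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(m)))
  rownames(m) <- sample_ids
  omics_block(m, "phenotype")
}

#' QC report bookkeeping record
#'
#' @param n_in,n_out feature counts before/after filtering.
#' @param removed named vector of per-filter removal counts.
#' @param thresholds named vector of thresholds used.
#' @return a `qc_report` list; `n_in - sum(removed)` must equal `n_out`.
#' @export
qc_report <- function(n_in, n_out, removed, thresholds = numeric()) {
  if (n_in - sum(removed) != n_out)
    stop("inconsistent QC bookkeeping: ", n_in, " - ", sum(removed),
         " != ", n_out)
  structure(list(n_in = n_in, n_out = n_out, removed = removed,
                 thresholds = thresholds), class = "qc_report")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d features in, %d out\n", x$n_in, x$n_out))
  for (nm in names(x$removed))
    cat(sprintf("  removed by %s: %d\n", nm, x$removed[[nm]]))
  invisible(x)
}
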