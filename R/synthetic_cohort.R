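#' Configuration for the synthetic multi-omics cohort
#'
#' Defaults emulate the structure of a human islet case/control cohort:
#' 110 donors of whom 32 are cases, three omics blocks (RNA-seq counts,
#' methylation betas, genotype dosages) at reduced desk-scale dimensions,
#' a small set of planted class-discriminating features per block, and
#' phenotype distributions (age, BMI, stimulatory index, HbA1c, sex ratio)
#' matching the cohort's published per-class summaries.
#'
#' `effect_size` is a standardized mean shift: informative expression
#' features shift their log2 mean by `effect_size` times the gene's
#' approximate log-scale SD, informative CpGs shift in logit space by
#' `effect_size` times the logit-scale SD, and informative variants shift
#' the case allele frequency by `effect_size * 0.1` (capped inside (0, 1)).
#'
#' @param n_samples cohort size.
#' @param case_fraction fraction of cases in `(0, 1)`.
#' @param n_genes,n_cpgs,n_snps block dimensions.
#' @param n_informative named vector: planted informative features per block.
#' @param effect_size named vector: standardized shift per block.
#' @param library_size_range range of per-sample library-size factors
#'   (uniform draw).
#' @param nb_dispersion negative-binomial dispersion for counts.
#' @param beta_precision concentration of the Beta draw around each CpG's
#'   class mean (larger = less sample-to-sample noise).
#' @param maf_range minor-allele-frequency range, within `(0, 0.5]`.
#' @param genotype_missing_rate fraction of dosage entries set missing.
#' @param phenotype_params per-phenotype `c(mean, sd)` per class plus the
#'   per-class probability of male sex.
#' @param seed integer seed; the cohort is fully determined by it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_samples = 110,
    case_fraction = 32 / 110,
    n_genes = 2000, n_cpgs = 3000, n_snps = 1000,
    n_informative = c(expression = 20, methylation = 20, genotype = 20),
    effect_size = c(expression = 2, methylation = 2, genotype = 2),
    library_size_range = c(0.5, 2),
    nb_dispersion = 0.2,
    beta_precision = 30,
    maf_range = c(0.05, 0.5),
    genotype_missing_rate = 0.01,
    phenotype_params = list(
      age = list(case = c(62.9, 7.7), control = c(61.5, 8.0)),
      bmi = list(case = c(27.8, 3.8), control = c(26.0, 3.9)),
      stimulatory_index = list(case = c(6.3, 5.2), control = c(8.0, 7.0)),
      hba1c = list(case = c(51.5, 9.7), control = c(36.7, 3.6)),
      sex_male_prob = c(case = 20 / 32, control = 48 / 78)),
    seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              case_fraction = case_fraction,
              n_genes = as.integer(n_genes), n_cpgs = as.integer(n_cpgs),
              n_snps = as.integer(n_snps),
              n_informative = n_informative, effect_size = effect_size,
              library_size_range = library_size_range,
              nb_dispersion = nb_dispersion,
              beta_precision = beta_precision,
              maf_range = maf_range,
              genotype_missing_rate = genotype_missing_rate,
              phenotype_params = phenotype_params,
              seed = as.integer(seed))
  sizes <- c(expression = cfg$n_genes, methylation = cfg$n_cpgs,
             genotype = cfg$n_snps)
  if (any(c(cfg$n_samples, sizes) < 1)) stop("all counts must be >= 1")
  if (cfg$case_fraction <= 0 || cfg$case_fraction >= 1)
    stop("case_fraction must be in (0, 1)")
  for (b in names(sizes)) {
    if (is.na(cfg$n_informative[b]) || is.na(cfg$effect_size[b]))
      stop("n_informative and effect_size must name block '", b, "'")
    if (cfg$n_informative[b] > sizes[b])
      stop("n_informative exceeds block size for '", b, "'")
  }
  if (any(!is.finite(cfg$effect_size))) stop("effect sizes must be finite")
  if (any(cfg$library_size_range <= 0) || cfg$nb_dispersion <= 0 ||
      cfg$beta_precision <= 0)
    stop("library_size_range, nb_dispersion, beta_precision must be positive")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$genotype_missing_rate < 0 || cfg$genotype_missing_rate >= 1)
    stop("genotype_missing_rate must be in [0, 1)")
  structure(cfg, class = "synthetic_config")
}

#' Simulate a multi-omics cohort with planted ground truth
#'
#' Generates, for `n_samples` donors with `round(n * case_fraction)` cases:
#' negative-binomial RNA-seq counts with log-normal-like baseline means and
#' per-sample library factors; Beta-distributed methylation values with
#' logit-space class effects; Hardy-Weinberg genotype dosages with shifted
#' case allele frequencies for informative variants; and per-class normal
#' phenotypes. The identities and effect directions of the planted
#' informative features are returned as ground truth for recovery tests.
#'
#' @param config a [synthetic_config].
#' @return a `synthetic_cohort` list: `labels` (0/1 integer vector, 1 = case,
#'   named by sample ID), `expression_counts`, `methylation_beta`,
#'   `genotype_dosage` (each an [omics_block], samples x features),
#'   `phenotypes` (data.frame with sex, age, bmi, stimulatory_index, hba1c),
#'   `truth` (per block: data.frame of informative feature IDs and signs),
#'   and the `config`.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  n_cases <- round(n * config$case_fraction)
  if (n_cases < 1 || n_cases >= n)
    stop("case_fraction yields an empty class at n = ", n)
  labels <- integer(n)
  labels[sample.int(n, n_cases)] <- 1L
  names(labels) <- ids
  case <- labels == 1L

  ## --- expression: NB counts, planted log2-mean shifts -------------------
  g_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  inf_g <- sort(sample.int(config$n_genes, config$n_informative["expression"]))
  sign_g <- sample(c(-1, 1), length(inf_g), replace = TRUE)
  log2_mu <- stats::rnorm(config$n_genes, mean = 5, sd = 1.5)
  mu <- pmax(2^log2_mu, 0.5)
  disp <- config$nb_dispersion
  # delta-method log2-scale SD of an NB(mu, dispersion) observation
  sd_log2 <- sqrt(1 / mu + disp) / log(2)
  shift <- numeric(config$n_genes)
  shift[inf_g] <- sign_g * config$effect_size["expression"] * sd_log2[inf_g]
  lib <- stats::runif(n, config$library_size_range[1],
                      config$library_size_range[2])
  mu_mat <- outer(mu, lib)                       # genes x samples
  mu_mat[, case] <- outer(mu * 2^shift, lib[case])
  counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                  size = 1 / disp),
                   nrow = config$n_genes, dimnames = list(g_ids, ids))

  ## --- methylation: Beta draws around class means, logit effects ---------
  c_ids <- sprintf("cg%06d", seq_len(config$n_cpgs))
  inf_c <- sort(sample.int(config$n_cpgs, config$n_informative["methylation"]))
  sign_c <- sample(c(-1, 1), length(inf_c), replace = TRUE)
  base_m <- 0.05 + 0.9 * stats::rbeta(config$n_cpgs, 0.5, 0.5)
  phi <- config$beta_precision
  sd_logit <- sqrt(1 / ((phi + 1) * base_m * (1 - base_m)))
  lshift <- numeric(config$n_cpgs)
  lshift[inf_c] <- sign_c * config$effect_size["methylation"] * sd_logit[inf_c]
  mean_mat <- matrix(base_m, config$n_cpgs, n)   # cpgs x samples
  mean_mat[, case] <- stats::plogis(stats::qlogis(base_m) + lshift)
  betas <- matrix(stats::rbeta(length(mean_mat), mean_mat * phi,
                               (1 - mean_mat) * phi),
                  nrow = config$n_cpgs, dimnames = list(c_ids, ids))
  betas <- pmin(pmax(betas, 1e-4), 1 - 1e-4)    # keep strictly inside (0,1)

  ## --- genotypes: HWE dosages, shifted case allele frequency -------------
  s_ids <- sprintf("snp%04d", seq_len(config$n_snps))
  inf_s <- sort(sample.int(config$n_snps, config$n_informative["genotype"]))
  sign_s <- sample(c(-1, 1), length(inf_s), replace = TRUE)
  maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  p_case <- maf
  p_case[inf_s] <- maf[inf_s] + sign_s * config$effect_size["genotype"] * 0.1
  p_case <- pmin(pmax(p_case, 1e-3), 1 - 1e-3)
  p_mat <- matrix(maf, config$n_snps, n)
  p_mat[, case] <- p_case
  dos <- matrix(stats::rbinom(length(p_mat), size = 2, prob = p_mat),
                nrow = config$n_snps, dimnames = list(s_ids, ids))
  dos <- dos * 1.0
  if (config$genotype_missing_rate > 0) {
    miss <- stats::runif(length(dos)) < config$genotype_missing_rate
    dos[miss] <- NA_real_
  }

  ## --- phenotypes --------------------------------------------------------
  pp <- config$phenotype_params
  draw <- function(par) {
    v <- numeric(n)
    v[case] <- stats::rnorm(sum(case), par$case[1], par$case[2])
    v[!case] <- stats::rnorm(sum(!case), par$control[1], par$control[2])
    v
  }
  sexp <- ifelse(case, pp$sex_male_prob["case"], pp$sex_male_prob["control"])
  phen <- data.frame(
    sex = stats::rbinom(n, 1, sexp),
    age = draw(pp$age), bmi = draw(pp$bmi),
    stimulatory_index = draw(pp$stimulatory_index),
    hba1c = draw(pp$hba1c),
    row.names = ids)

  truth <- list(
    expression = data.frame(feature = g_ids[inf_g], sign = sign_g),
    methylation = data.frame(feature = c_ids[inf_c], sign = sign_c),
    genotype = data.frame(feature = s_ids[inf_s], sign = sign_s))

  structure(list(
    labels = labels,
    expression_counts = omics_block(t(counts), "expression"),
    methylation_beta = omics_block(t(betas), "methylation"),
    genotype_dosage = omics_block(t(dos), "genotype"),
    phenotypes = phen,
    truth = truth,
    config = config), class = "synthetic_cohort")
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples (%d cases), %d genes / %d CpGs / %d SNPs\n",
    length(x$labels), sum(x$labels), ncol(x$expression_counts$values),
    ncol(x$methylation_beta$values), ncol(x$genotype_dosage$values)))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits one features-as-rows TSV per omics block, the phenotype table, a
#' two-column label file (`sample_id`, `status` in case/control), the planted
#' truth as JSON, and the genotype block additionally as an uncompressed
#' VCFv4.2 file with GT fields.
#'
#' @param cohort a [simulate_cohort] result.
#' @param directory output directory (created if absent).
#' @return invisibly, the named vector of written file paths.
#' @export
write_cohort <- function(cohort, directory) {
  if (!is.character(directory) || length(directory) != 1 ||
      !nzchar(directory))
    stop("`directory` must be a non-empty path")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(directory, "expression_counts.tsv"),
    methylation = file.path(directory, "methylation_beta.tsv"),
    genotype = file.path(directory, "genotype_dosage.tsv"),
    phenotypes = file.path(directory, "phenotypes.tsv"),
    labels = file.path(directory, "labels.tsv"),
    truth = file.path(directory, "truth.json"),
    vcf = file.path(directory, "genotype.vcf"))
  write_omics_matrix(cohort$expression_counts, paths["expression"])
  write_omics_matrix(cohort$methylation_beta, paths["methylation"])
  write_omics_matrix(cohort$genotype_dosage, paths["genotype"])
  phen <- cbind(sample_id = rownames(cohort$phenotypes), cohort$phenotypes)
  utils::write.table(phen, paths["phenotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(sample_id = names(cohort$labels),
                    status = ifelse(cohort$labels == 1, "case", "control"))
  utils::write.table(lab, paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "columns",
                       digits = NA)
  write_dosage_vcf(cohort$genotype_dosage, paths["vcf"])
  invisible(paths)
}

#' Read a cohort previously written with [write_cohort]
#'
#' @param directory the directory passed to [write_cohort].
#' @return a list with the same block/label/phenotype/truth structure as
#'   [simulate_cohort] (without the config).
#' @export
read_cohort <- function(directory) {
  lab <- utils::read.table(file.path(directory, "labels.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  labels <- as.integer(lab$status == "case")
  names(labels) <- lab$sample_id
  phen <- utils::read.table(file.path(directory, "phenotypes.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  rownames(phen) <- phen$sample_id
  phen$sample_id <- NULL
  truth_raw <- jsonlite::read_json(file.path(directory, "truth.json"),
                                   simplifyVector = TRUE)
  truth <- lapply(truth_raw, as.data.frame)
  list(
    labels = labels,
    expression_counts = read_omics_matrix(
      file.path(directory, "expression_counts.tsv"), "expression"),
    methylation_beta = read_omics_matrix(
      file.path(directory, "methylation_beta.tsv"), "methylation"),
    genotype_dosage = read_omics_matrix(
      file.path(directory, "genotype_dosage.tsv"), "genotype"),
    phenotypes = phen,
    truth = truth)
}
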