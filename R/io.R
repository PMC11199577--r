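#' Read a delimited omics matrix
#'
#' On-disk layout is features-as-rows: first column feature IDs, header row of
#' sample IDs. The delimiter is inferred from the extension (`.csv` = comma,
#' anything else = tab). The returned block is transposed to the package's
#' in-memory samples x features orientation.
#'
#' @param path input file.
#' @param block_name label for the resulting [omics_block].
#' @return an [omics_block].
#' @export
read_omics_matrix <- function(path, block_name = "block") {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file: ", path)
  split_row <- strsplit(lines, sep, fixed = TRUE)
  header <- split_row[[1]]
  n_col <- length(header)
  body <- split_row[-1]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1] + 1L
    stop("ragged row at line ", bad, " of ", path)
  }
  feat <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(feat))
    stop("duplicate feature ID in ", path, ": ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  samples <- header[-1]
  vals <- vapply(body, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    v
  }, numeric(n_col - 1L))
  # vals is samples x features after vapply; check numeric parse
  raw <- unlist(lapply(body, `[`, -1L))
  bad_cell <- which(is.na(suppressWarnings(as.numeric(raw))) &
                      !(raw %in% c("NA", "")))
  if (length(bad_cell)) {
    line_no <- (bad_cell[1] - 1L) %/% (n_col - 1L) + 2L
    stop("non-numeric cell at line ", line_no, " of ", path)
  }
  m <- matrix(vals, nrow = length(samples), ncol = length(feat),
              dimnames = list(samples, feat))
  omics_block(m, block_name)
}

#' Write an omics block as a delimited matrix
#'
#' Features-as-rows, first column `feature_id`, header = sample IDs; full
#' precision so a read-back reproduces the block exactly. Delimiter follows
#' the extension as in [read_omics_matrix].
#'
#' @param block an [omics_block] (or samples x features matrix).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_omics_matrix <- function(block, path) {
  if (!is.character(path) || length(path) != 1 || !nzchar(path))
    stop("`path` must be a non-empty file path")
  m <- t(as_block_matrix(block))                 # features x samples on disk
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- paste(c("feature_id", colnames(m)), collapse = sep)
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i],
            format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = sep), character(1))
  ok <- tryCatch(writeLines(c(header, rows), path), error = function(e)
    stop("failed writing ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Write a genotype dosage block as a minimal VCFv4.2 file
#'
#' One biallelic record per variant (REF A, ALT G on a synthetic chromosome),
#' genotypes encoded in the GT field: dosage 0 = `0/0`, 1 = `0/1`, 2 = `1/1`,
#' missing = `./.`.
#'
#' @param block genotype [omics_block], dosages in `{0, 1, 2, NA}`.
#' @param path output `.vcf` path.
#' @return invisibly, `path`.
#' @export
write_dosage_vcf <- function(block, path) {
  m <- t(as_block_matrix(block))                 # variants x samples
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be integers 0/1/2 or missing to encode GT fields")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                     "Description=\"Genotype\">"),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(m)), collapse = "\t"))
  recs <- vapply(seq_len(nrow(m)), function(i) {
    gts <- ifelse(is.na(m[i, ]), "./.", gt_code[as.character(m[i, ])])
    paste(c("1", i * 100L, rownames(m)[i], "A", "G", ".", "PASS", ".", "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read genotype dosages from a VCF file
#'
#' Parses GT fields of biallelic records into ALT-allele counts (0/1/2);
#' `./.` becomes missing. Multiallelic records are skipped with a warning
#' giving their count. The variant ID is the VCF ID field, or
#' `CHROM:POS:REF:ALT` when the ID is `.`.
#'
#' @param path VCF file (uncompressed or bgzipped; anything `vcfR` reads).
#' @return a genotype [omics_block] (samples x variants).
#' @export
read_vcf_dosage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("GT field absent from FORMAT in ", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning("skipped ", sum(multi), " multiallelic record(s) in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (!nrow(gt)) stop("no biallelic records with GT in ", path)
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste(fix[no_id, "CHROM"], fix[no_id, "POS"],
                      fix[no_id, "REF"], fix[no_id, "ALT"], sep = ":")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  })
  rownames(dos) <- ids
  omics_block(t(dos), "genotype")
}
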