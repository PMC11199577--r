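#' Construct an omics block
#'
#' An omics block is one data layer's samples x features numeric matrix with
#' unique sample and feature identifiers and a block name. All in-memory
#' semantics in this package are samples x features; on-disk matrices are
#' stored features-as-rows (the omics convention) and transposed on read.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param block_name one of `"expression"`, `"methylation"`, `"genotype"`,
#'   `"phenotype"` or a custom label.
#' @param sample_ids,feature_ids optional identifier vectors; defaults to the
#'   matrix dimnames.
#' @return an object of class `omics_block`: a list with elements `values`
#'   (with dimnames set), and `block_name`.
#' @export
omics_block <- function(values, block_name,
                        sample_ids = rownames(values),
                        feature_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("sample and feature identifiers are required (dimnames or arguments)")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != nrow(values)")
  if (length(feature_ids) != ncol(values))
    stop("length(feature_ids) != ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, block_name = as.character(block_name)[1]),
            class = "omics_block")
}

#' @exportS3Method base::print
print.omics_block <- function(x, ...) {
  cat(sprintf("omics_block '%s': %d samples x %d features\n",
              x$block_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

sample_ids <- function(block) rownames(block$values)
feature_ids <- function(block) colnames(block$values)

# Coerce either an omics_block or a plain samples x features matrix to matrix.
as_block_matrix <- function(x) {
  if (inherits(x, "omics_block")) x$values else as.matrix(x)
}
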