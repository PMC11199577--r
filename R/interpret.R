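#' Correlate panel features with the consensus components
#'
#' Pearson correlation of each (scaled) feature vector with each consensus
#' component score. The pair (correlation with component 1, correlation with
#' component 2) gives each feature's circle-plot coordinates: predictive
#' features sit near the unit circle's poles, uninformative ones near the
#' center. Zero-variance features get correlation 0 with a warning.
#'
#' @param model a [fit_block_plsda] model.
#' @param blocks named list of the matrices the model was fitted on (scaled,
#'   samples x features).
#' @return features x components correlation matrix with a `block` attribute
#'   giving each feature's block membership.
#' @export
feature_component_correlations <- function(model, blocks) {
  cons <- model$consensus_scores
  mats <- lapply(model$block_names, function(b) {
    X <- as_block_matrix(blocks[[b]])[, model$features[[b]], drop = FALSE]
    X
  })
  X <- do.call(cbind, mats)
  membership <- rep(model$block_names, vapply(mats, ncol, integer(1)))
  sds <- apply(X, 2, stats::sd)
  out <- matrix(0, ncol(X), ncol(cons),
                dimnames = list(colnames(X),
                                paste0("comp", seq_len(ncol(cons)))))
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " zero-variance feature(s); correlation set to 0")
  out[ok, ] <- stats::cor(X[, ok, drop = FALSE], cons)
  attr(out, "block") <- stats::setNames(membership, colnames(X))
  out
}

#' Cross-omics feature association matrix
#'
#' Latent-space approximation to between-feature association: the
#' component-space inner product `sum_h cor(x_j, t_h) * cor(x_k, t_h)`,
#' clipped to `[-1, 1]` with a unit diagonal. Features from different blocks
#' are never correlated directly; their association is carried entirely by
#' the shared components, which is what circos-style cross-omics link plots
#' display.
#'
#' @param feat_cor a [feature_component_correlations] matrix.
#' @return symmetric `association_matrix` with the `block` attribute carried
#'   over.
#' @export
cross_omics_association <- function(feat_cor) {
  if (ncol(feat_cor) < 1) stop("at least one component is required")
  m <- tcrossprod(feat_cor)
  m <- pmin(pmax(m, -1), 1)
  diag(m) <- 1
  attr(m, "block") <- attr(feat_cor, "block")
  class(m) <- c("association_matrix", class(m))
  m
}

#' Threshold an association matrix into a feature network
#'
#' Keeps undirected edges with `|r| >= threshold` (no self-edges), optionally
#' restricted to pairs spanning two named blocks. The average degree is
#' `2 * |E| / |V|` over the nodes that have at least one edge.
#'
#' @param assoc an [cross_omics_association] matrix.
#' @param threshold edge threshold in `(0, 1]`.
#' @param block_pair optional `c(block_a, block_b)`: keep only edges with one
#'   endpoint in each.
#' @return a `feature_network`: `edges` (data.frame from/to/weight), `nodes`,
#'   `average_degree`, `threshold`.
#' @export
build_network <- function(assoc, threshold = 0.7, block_pair = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  membership <- attr(assoc, "block")
  m <- unclass(assoc)
  m[lower.tri(m, diag = TRUE)] <- 0
  idx <- which(abs(m) >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(m)[idx[, 1]],
                      to = colnames(m)[idx[, 2]],
                      weight = m[idx])
  if (!is.null(block_pair) && nrow(edges)) {
    if (is.null(membership)) stop("association matrix lacks block membership")
    ba <- membership[edges$from]; bb <- membership[edges$to]
    keep <- (ba == block_pair[1] & bb == block_pair[2]) |
      (ba == block_pair[2] & bb == block_pair[1])
    edges <- edges[keep, , drop = FALSE]
  }
  nodes <- unique(c(edges$from, edges$to))
  avg_deg <- if (length(nodes)) 2 * nrow(edges) / length(nodes) else 0
  structure(list(edges = edges, nodes = nodes, average_degree = avg_deg,
                 threshold = threshold),
            class = "feature_network")
}

#' @exportS3Method base::print
print.feature_network <- function(x, ...) {
  cat(sprintf(
    "feature_network: %d node(s), %d edge(s) at |r| >= %.2f (avg degree %.2f)\n",
    length(x$nodes), nrow(x$edges), x$threshold, x$average_degree))
  invisible(x)
}

#' Hierarchical-clustering orders for the panel heatmap
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) applied
#' independently to samples (rows) and features (columns) of the
#' standardized panel matrix; returns the deterministic leaf orders and the
#' linkage objects.
#'
#' @param m samples x features matrix with standardized columns.
#' @return list with `sample_order`, `feature_order`, `sample_hclust`,
#'   `feature_hclust`.
#' @export
cluster_heatmap_order <- function(m) {
  m <- as_block_matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 samples and 2 features to cluster")
  hr <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                      method = "complete")
  list(sample_order = rownames(m)[hr$order],
       feature_order = colnames(m)[hc$order],
       sample_hclust = hr, feature_hclust = hc)
}

#' Tidy arrow-plot data for a fitted multi-block model
#'
#' One row per sample and block with the block's component coordinates
#' (arrow tips) plus the consensus coordinates (arrow origins) and the class
#' label.
#'
#' @param model a [fit_block_plsda] model.
#' @return data.frame: sample, block, comp1, comp2, consensus1, consensus2,
#'   class.
#' @export
arrow_plot_data <- function(model) {
  cons <- model$consensus_scores
  ids <- rownames(cons)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(cons)))
  do.call(rbind, lapply(model$block_names, function(b) {
    s <- model$scores[[b]]
    data.frame(sample = ids, block = b,
               comp1 = s[, 1],
               comp2 = if (ncol(s) > 1) s[, 2] else NA_real_,
               consensus1 = cons[, 1],
               consensus2 = if (ncol(cons) > 1) cons[, 2] else NA_real_,
               class = as.character(model$y), row.names = NULL)
  }))
}
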