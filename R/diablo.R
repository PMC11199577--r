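## Multi-block sparse PLS-DA (DIABLO-style) solver.
##
## Each omics block gets its own sparse weight vector and latent score per
## component; the block-coordinate iteration maximizes the design-weighted
## sum of score covariances between blocks and with the dummy-coded outcome.
## Each per-block update is the exact maximizer of its subproblem (weight
## proportional to the hard-thresholded gradient, renormalized), so the
## objective is non-decreasing over iterations.

#' Build a block design matrix
#'
#' Symmetric non-negative weights over the data blocks plus the outcome,
#' zero diagonal. The default ties every pair of blocks and every block to
#' the outcome with weight 1 (a "full" design).
#'
#' @param block_names character vector of block names.
#' @param inter_block weight between data blocks (default 1).
#' @param to_outcome weight between each block and the outcome (default 1);
#'   must be positive.
#' @return square matrix with dimnames `c(block_names, "outcome")`.
#' @export
make_design <- function(block_names, inter_block = 1, to_outcome = 1) {
  if (to_outcome <= 0) stop("every block must be tied to the outcome")
  nm <- c(block_names, "outcome")
  d <- matrix(inter_block, length(nm), length(nm), dimnames = list(nm, nm))
  d[, "outcome"] <- d["outcome", ] <- to_outcome
  diag(d) <- 0
  d
}

check_design <- function(design, block_names) {
  nm <- c(block_names, "outcome")
  if (!all(nm %in% rownames(design)) || !all(nm %in% colnames(design)))
    stop("design must be named over all blocks plus 'outcome'")
  design <- design[nm, nm]
  if (any(design < 0)) stop("design weights must be non-negative")
  if (max(abs(design - t(design))) > 1e-12) stop("design must be symmetric")
  if (any(diag(design) != 0)) stop("design diagonal must be zero")
  if (any(design[block_names, "outcome"] <= 0))
    stop("every block must have a positive outcome weight")
  design
}

#' Fit a multi-block sparse PLS-DA model
#'
#' Joint latent components across omics blocks. Per component, the
#' block-coordinate update sets each block's weight proportional to
#' `t(X_i) %*% z_i` where `z_i` is the design-weighted sum of the other
#' blocks' scores and the outcome score, hard-thresholds it to that block's
#' `keepX` budget and renormalizes; the outcome score is updated against the
#' design-weighted sum of block scores. After convergence each block is
#' deflated by its own score/x-loading and the outcome by the consensus
#' (across-block mean) score. A single per-component global sign (the
#' largest-magnitude entry of the weights concatenated over alphabetically
#' sorted block names is made positive) is applied to all blocks jointly, so
#' cross-block score alignment — and hence the consensus average — is
#' preserved and the fit is invariant to block order.
#'
#' With a single block this reduces exactly to [fit_plsda] on that block.
#'
#' @param blocks named list of autoscaled samples x features matrices (or
#'   [omics_block]s) sharing sample order.
#' @param y two-class labels.
#' @param n_components number of components (default 2).
#' @param keepX named list: per block, `"all"` or a budget per component.
#'   Blocks absent from the list get `"all"`.
#' @param design design matrix from [make_design]; default full design.
#' @param tol,max_iter convergence control.
#' @return a `block_pls_model`: per-block weights/scores/x-loadings,
#'   consensus scores, objective traces, design, training labels.
#' @export
fit_block_plsda <- function(blocks, y, n_components = 2, keepX = list(),
                            design = NULL, tol = 1e-9, max_iter = 5000) {
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    stop("blocks must be a named list")
  Xs <- lapply(blocks, as_block_matrix)
  ns <- vapply(Xs, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("blocks disagree on sample count")
  rn <- lapply(Xs, rownames)
  if (!is.null(rn[[1]])) {
    for (i in seq_along(rn))
      if (!identical(rn[[i]], rn[[1]]))
        stop("blocks disagree on sample order (block '",
             names(blocks)[i], "')")
  }
  y <- as_class_factor(y)
  if (nlevels(y) != 2) stop("y must contain exactly two classes")
  if (length(y) != ns[1]) stop("length(y) != sample count")
  n_components <- as.integer(n_components)
  bn <- names(Xs)
  if (is.null(design)) design <- make_design(bn)
  design <- check_design(design, bn)

  kx <- lapply(bn, function(b) {
    k <- if (b %in% names(keepX)) keepX[[b]] else "all"
    normalize_keepx(k, n_components, ncol(Xs[[b]]))
  })
  names(kx) <- bn

  Yc <- dummy_outcome(y)
  Xd <- Xs
  W <- lapply(Xs, function(x)
    matrix(0, ncol(x), n_components, dimnames = list(colnames(x), NULL)))
  C <- W
  Tm <- lapply(Xs, function(x)
    matrix(0, nrow(x), n_components, dimnames = list(rownames(x), NULL)))
  obj_trace <- vector("list", n_components)

  for (h in seq_len(n_components)) {
    t_Y <- Yc[, 1]
    a <- lapply(bn, function(b) {
      v <- drop(crossprod(Xd[[b]], t_Y))
      v <- sparsify_weights(v, kx[[b]][[h]])
      nrm <- sqrt(sum(v^2))
      if (nrm == 0) stop("degenerate init for block '", b,
                         "' in component ", h)
      v / nrm
    })
    names(a) <- bn
    ts <- lapply(bn, function(b) drop(Xd[[b]] %*% a[[b]]))
    names(ts) <- bn

    objective <- function() {
      o <- 0
      if (length(bn) > 1)
        for (i in seq_len(length(bn) - 1))
          for (j in seq((i + 1), length(bn)))
            o <- o + design[bn[i], bn[j]] * sum(ts[[i]] * ts[[j]])
      for (b in bn) o <- o + design[b, "outcome"] * sum(ts[[b]] * t_Y)
      o
    }
    trace_h <- objective()
    iter <- 0
    repeat {
      iter <- iter + 1
      a_old <- a
      for (b in bn) {
        z <- design[b, "outcome"] * t_Y
        for (j in setdiff(bn, b))
          z <- z + design[b, j] * ts[[j]]
        v <- drop(crossprod(Xd[[b]], z))
        v <- sparsify_weights(v, kx[[b]][[h]])
        nrm <- sqrt(sum(v^2))
        if (nrm == 0) stop("degenerate weight for block '", b,
                           "' in component ", h)
        a[[b]] <- v / nrm
        ts[[b]] <- drop(Xd[[b]] %*% a[[b]])
      }
      zy <- Reduce(`+`, lapply(bn, function(b)
        design[b, "outcome"] * ts[[b]]))
      w_y <- drop(crossprod(Yc, zy))
      w_y <- w_y / sqrt(sum(w_y^2))
      t_Y <- drop(Yc %*% w_y)
      trace_h <- c(trace_h, objective())
      delta <- max(vapply(bn, function(b)
        max(abs(a[[b]] - a_old[[b]])), numeric(1)))
      if (delta < tol) break
      if (iter >= max_iter)
        stop("block solver did not converge for component ", h,
             " within ", max_iter, " iterations")
    }
    # one global sign per component keeps cross-block alignment intact;
    # the reference is the concatenated weight vector over alphabetically
    # sorted block names, so the convention is block-order invariant
    vec <- unlist(a[sort(bn)], use.names = FALSE)
    s <- sign(vec[which.max(abs(vec))])
    for (b in bn) { a[[b]] <- s * a[[b]]; ts[[b]] <- s * ts[[b]] }
    t_Y <- s * t_Y

    t_cons <- Reduce(`+`, ts) / length(ts)
    for (b in bn) {
      tt <- sum(ts[[b]]^2)
      c_b <- drop(crossprod(Xd[[b]], ts[[b]])) / tt
      Xd[[b]] <- Xd[[b]] - tcrossprod(ts[[b]], c_b)
      W[[b]][, h] <- a[[b]]; C[[b]][, h] <- c_b; Tm[[b]][, h] <- ts[[b]]
    }
    d_y <- drop(crossprod(Yc, t_cons)) / sum(t_cons^2)
    Yc <- Yc - tcrossprod(t_cons, d_y)
    obj_trace[[h]] <- trace_h
  }

  consensus <- Reduce(`+`, Tm) / length(Tm)
  structure(list(weights = W, x_loadings = C, scores = Tm,
                 consensus_scores = consensus,
                 objective_trace = obj_trace,
                 design = design, y = y, levels = levels(y),
                 block_names = bn,
                 features = lapply(Xs, colnames),
                 n_components = n_components, keepX = kx),
            class = "block_pls_model")
}

#' @exportS3Method base::print
print.block_pls_model <- function(x, ...) {
  cat(sprintf("block_pls_model: %d components, blocks %s\n",
              x$n_components,
              paste(sprintf("%s(%d)", x$block_names,
                            lengths(x$features)), collapse = ", ")))
  invisible(x)
}

#' Project new samples onto a fitted multi-block model
#'
#' Applies each block's stored weight/deflation sequence; projecting the
#' training blocks reproduces the stored scores.
#'
#' @param model a [fit_block_plsda] model.
#' @param blocks named list of matrices, scaled with the training stats.
#' @return named list of samples x components score matrices.
#' @export
project_blocks <- function(model, blocks) {
  miss <- setdiff(model$block_names, names(blocks))
  if (length(miss))
    stop("missing block(s): ", paste(miss, collapse = ", "))
  out <- lapply(model$block_names, function(b) {
    Xd <- as_block_matrix(blocks[[b]])
    mf <- setdiff(model$features[[b]], colnames(Xd))
    if (length(mf))
      stop("block '", b, "' lacks features: ",
           paste(utils::head(mf, 10), collapse = ", "))
    Xd <- Xd[, model$features[[b]], drop = FALSE]
    Tm <- matrix(0, nrow(Xd), model$n_components,
                 dimnames = list(rownames(Xd), NULL))
    for (h in seq_len(model$n_components)) {
      t_h <- drop(Xd %*% model$weights[[b]][, h])
      Xd <- Xd - tcrossprod(t_h, model$x_loadings[[b]][, h])
      Tm[, h] <- t_h
    }
    Tm
  })
  names(out) <- model$block_names
  out
}

#' Consensus (across-block average) coordinates
#'
#' Each sample's consensus coordinate is the arithmetic mean of its per-block
#' scores; the per-block scores are returned alongside as the arrow-plot
#' "tips".
#'
#' @param block_scores named list of equal-shape score matrices.
#' @return list with `consensus` (matrix) and `per_block` (the input list).
#' @export
consensus_scores <- function(block_scores) {
  dims <- lapply(block_scores, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("score matrices must share dimensions")
  list(consensus = Reduce(`+`, block_scores) / length(block_scores),
       per_block = block_scores)
}

#' Predict with the consensus-centroid rule
#'
#' New samples are projected per block, averaged into consensus coordinates,
#' and assigned to the nearest consensus class centroid in the cumulative
#' `k`-component space (centroids = class means of the training consensus
#' scores). Decision values as in [predict_plsda].
#'
#' @param model a [fit_block_plsda] model.
#' @param blocks named list of matrices scaled with the training stats.
#' @param k components used.
#' @return list with `labels`, `decision`, and `consensus` coordinates.
#' @export
predict_consensus <- function(model, blocks, k = model$n_components) {
  if (k < 1 || k > model$n_components)
    stop("k must be between 1 and ", model$n_components)
  proj <- project_blocks(model, blocks)
  cons <- consensus_scores(proj)$consensus[, seq_len(k), drop = FALSE]
  centroids <- class_centroids(model$consensus_scores, model$y, k)
  out <- nearest_centroid_predict(cons, centroids, model$y, model$levels)
  out$consensus <- cons
  out
}
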