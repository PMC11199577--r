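## Bespoke NIPALS (sparse) PLS-DA engine.
##
## The outcome is dummy-coded (one column-centered indicator column per
## class); components are extracted one at a time by the NIPALS power
## iteration with an optional per-component sparsity budget (keepX) applied
## by hard-thresholding the weight vector to its keepX largest absolute
## entries. Prediction assigns the nearest class centroid in the cumulative
## latent score space.

# Zero all but the k largest |entries|; ties broken by ascending index so the
# nonzero count is exactly k.
sparsify_weights <- function(a, k) {
  if (is.character(k) || k >= length(a)) return(a)
  if (k < 1) stop("keepX must be >= 1")
  ord <- order(-abs(a), seq_along(a))
  a[-ord[seq_len(k)]] <- 0
  a
}

# Coerce labels to a two-level factor with the control/negative class first.
# 0/1 input puts 1 (case) second by sort order; explicit case/control strings
# are reordered so that "control" is the first (negative) level.
as_class_factor <- function(y) {
  y <- droplevels(as.factor(y))
  if (setequal(levels(y), c("case", "control")))
    y <- factor(y, levels = c("control", "case"))
  y
}

# Column-centered class indicator matrix; column order = factor level order.
dummy_outcome <- function(y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("exactly two classes are required, got ",
                            nlevels(y))
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  scale(Y, center = TRUE, scale = FALSE)
}

normalize_keepx <- function(keepX, n_components, p) {
  if (length(keepX) == 1) keepX <- rep(list(keepX), n_components)
  if (length(keepX) != n_components)
    stop("keepX must have length 1 or n_components")
  keepX <- lapply(keepX, function(k) {
    if (identical(k, "all")) return("all")
    k <- as.integer(k)
    if (k < 1) stop("keepX must be >= 1 (or \"all\")")
    if (k > p) stop("keepX (", k, ") exceeds the number of features (", p, ")")
    k
  })
  keepX
}

#' Fit a (sparse) PLS-DA model
#'
#' NIPALS estimation of `n_components` latent components of an autoscaled
#' samples x features matrix against the column-centered class indicator
#' matrix. With a finite `keepX`, the weight vector of each component is
#' hard-thresholded to its `keepX` largest absolute entries before
#' renormalization, so exactly `keepX` features get a nonzero loading. After
#' each component both the data and the outcome are deflated by the
#' component's scores. The sign of each component is fixed by making its
#' largest-magnitude weight entry positive.
#'
#' With `keepX = "all"` and one component, the weight vector equals the
#' dominant left singular vector of `t(X) %*% Y` up to sign.
#'
#' @param X autoscaled samples x features matrix (see [autoscale]).
#' @param y two-class labels (factor or coercible; with 0/1 input, 1 — the
#'   case class — is the second level).
#' @param n_components number of latent components (default 2).
#' @param keepX `"all"`, a single sparsity budget, or one per component.
#' @param tol convergence tolerance on the weight update (default 1e-9).
#' @param max_iter iteration cap per component (default 500).
#' @return a `pls_model`: per-component weights, scores, x/y-loadings,
#'   training labels and feature IDs.
#' @export
fit_plsda <- function(X, y, n_components = 2, keepX = "all",
                      tol = 1e-9, max_iter = 500) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as_class_factor(y)
  if (nlevels(y) != 2) stop("y must contain exactly two classes")
  if (any(table(y) < 2)) stop("each class needs at least 2 samples")
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  n_components <- as.integer(n_components)
  p <- ncol(X)
  keepX <- normalize_keepx(keepX, n_components, p)

  Yc <- dummy_outcome(y)
  Xd <- X
  W <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  C <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  D <- matrix(0, ncol(Yc), n_components)
  Tm <- matrix(0, nrow(X), n_components, dimnames = list(rownames(X), NULL))

  for (h in seq_len(n_components)) {
    u <- Yc[, 1]
    a_old <- rep(Inf, p)
    iter <- 0
    repeat {
      iter <- iter + 1
      a <- drop(crossprod(Xd, u))
      a <- sparsify_weights(a, keepX[[h]])
      nrm <- sqrt(sum(a^2))
      if (nrm == 0) stop("degenerate weight vector in component ", h,
                         " (no class signal left)")
      a <- a / nrm
      t_h <- drop(Xd %*% a)
      b <- drop(crossprod(Yc, t_h))
      b <- b / sqrt(sum(b^2))
      u <- drop(Yc %*% b)
      if (max(abs(a - a_old)) < tol) break
      if (iter >= max_iter)
        stop("NIPALS did not converge for component ", h,
             " within ", max_iter, " iterations")
      a_old <- a
    }
    tt <- sum(t_h^2)
    c_h <- drop(crossprod(Xd, t_h)) / tt
    d_h <- drop(crossprod(Yc, t_h)) / tt
    # sign convention: largest-|weight| entry positive
    s <- sign(a[which.max(abs(a))])
    a <- s * a; t_h <- s * t_h; c_h <- s * c_h; d_h <- s * d_h
    Xd <- Xd - tcrossprod(t_h, c_h)
    Yc <- Yc - tcrossprod(t_h, d_h)
    W[, h] <- a; C[, h] <- c_h; D[, h] <- d_h; Tm[, h] <- t_h
  }

  structure(list(weights = W, x_loadings = C, y_loadings = D, scores = Tm,
                 y = y, levels = levels(y), features = colnames(X),
                 n_components = n_components, keepX = keepX),
            class = "pls_model")
}

#' @exportS3Method base::print
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d components, %d features, classes %s\n",
              x$n_components, length(x$features),
              paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Project new samples onto a fitted PLS-DA model's latent space
#'
#' Applies the stored weight/deflation sequence; the input must contain the
#' model's features and be scaled with the model's training statistics.
#'
#' @param model a [fit_plsda] model.
#' @param X_new samples x features matrix.
#' @return samples x components score matrix.
#' @export
transform_plsda <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new)) && ncol(X_new) == length(model$features))
    colnames(X_new) <- model$features
  miss <- setdiff(model$features, colnames(X_new))
  if (length(miss))
    stop("features missing from input: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10)
         else "")
  Xd <- X_new[, model$features, drop = FALSE]
  Tm <- matrix(0, nrow(Xd), model$n_components,
               dimnames = list(rownames(Xd), NULL))
  for (h in seq_len(model$n_components)) {
    t_h <- drop(Xd %*% model$weights[, h])
    Xd <- Xd - tcrossprod(t_h, model$x_loadings[, h])
    Tm[, h] <- t_h
  }
  Tm
}

#' Rank features by loading-score importance
#'
#' Importance of a feature is the maximum over components of its absolute
#' weight; features are returned in descending importance, ties broken by
#' ascending feature index.
#'
#' @param model a [fit_plsda] model.
#' @return data.frame with `feature`, `importance`, in rank order.
#' @export
loading_importance <- function(model) {
  imp <- apply(abs(model$weights), 1, max)
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = model$features[ord], importance = unname(imp[ord]),
             row.names = NULL)
}

#' Select the top-K features of a fitted model
#'
#' @param model a [fit_plsda] model.
#' @param K number of features, `1 <= K <=` number of features.
#' @return character vector of feature IDs (importance order).
#' @export
select_top_features <- function(model, K) {
  if (!is.numeric(K) || K <= 0) stop("K must be a positive count")
  if (K > length(model$features)) stop("K exceeds the number of features")
  loading_importance(model)$feature[seq_len(K)]
}

# Features with a nonzero loading on any component (the sparse-selection
# notion used by the persistence harness).
selected_features <- function(model) {
  model$features[rowSums(model$weights != 0) > 0]
}

# Class centroids of a score matrix over cumulative components 1..k.
class_centroids <- function(scores, y, k) {
  m <- vapply(levels(y), function(cl)
    colMeans(scores[y == cl, seq_len(k), drop = FALSE]), numeric(k))
  matrix(m, nrow = k, dimnames = list(NULL, levels(y)))
}

# Nearest-centroid assignment shared by single- and multi-block prediction.
# Tie (equal distance) goes to the majority training class; decision value is
# d(first level) - d(second level), so positive means "second level" (case).
nearest_centroid_predict <- function(scores_k, centroids, y_train, levels) {
  d <- vapply(seq_len(ncol(centroids)), function(j)
    sqrt(rowSums(sweep(scores_k, 2, centroids[, j], "-")^2)),
    numeric(nrow(scores_k)))
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(scores_k))
  decision <- d[, 1] - d[, 2]
  counts <- table(factor(y_train, levels = levels))
  majority <- which.max(counts)     # first max = first level on frequency tie
  idx <- max.col(-d, ties.method = "first")
  idx[abs(decision) < 1e-12] <- majority
  labels <- factor(levels[idx], levels = levels)
  list(labels = labels, decision = unname(decision))
}

#' Predict class labels with a fitted PLS-DA model
#'
#' Nearest class centroid in the cumulative `k`-component latent space;
#' centroids are the class means of the training scores. The decision value
#' is the distance to the first-level (control) centroid minus the distance
#' to the second-level (case) centroid, so larger values favour the case
#' class; equidistant samples go to the majority training class.
#'
#' @param model a [fit_plsda] model.
#' @param X_new samples x features matrix, scaled with the training stats.
#' @param k number of components used, `1 <= k <= n_components`.
#' @return list with `labels` (factor) and `decision` (numeric).
#' @export
predict_plsda <- function(model, X_new, k = model$n_components) {
  if (k < 1 || k > model$n_components)
    stop("k must be between 1 and ", model$n_components)
  scores <- transform_plsda(model, X_new)[, seq_len(k), drop = FALSE]
  centroids <- class_centroids(model$scores, model$y, k)
  nearest_centroid_predict(scores, centroids, model$y, model$levels)
}
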