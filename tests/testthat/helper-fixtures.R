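# Shared fixture builders; everything is generated in code under fixed seeds.

# Standardized random matrix with feature names.
random_scaled_matrix <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  scale(m)
}

# Balanced labels for a matrix with n rows.
balanced_labels <- function(n) rep(c(0, 1), length.out = n)

# A small, clearly separable two-class dataset: `n_signal` features shifted
# by `delta` between classes, the rest noise.
separable_matrix <- function(n = 20, p = 10, n_signal = 3, delta = 3,
                             seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  m[y == 1, seq_len(n_signal)] <- m[y == 1, seq_len(n_signal)] + delta
  list(X = scale(m), y = y)
}

# Reduced-size synthetic configuration for fast unit tests (the full-scale
# defaults are exercised by the acceptance suite).
small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 300, n_cpgs = 300, n_snps = 150,
               n_informative = c(expression = 10, methylation = 10,
                                 genotype = 10),
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# Dominant left singular vector of t(X) %*% Y_centered, sign-fixed like the
# NIPALS engine: the independent oracle for the first dense PLS weight.
svd_weight_oracle <- function(X, y) {
  Y <- stats::model.matrix(~ factor(y) - 1)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  u <- svd(crossprod(X, Yc))$u[, 1]
  u * sign(u[which.max(abs(u))])
}

# Brute-force pairwise ROC AUC (ties count 1/2): the independent oracle.
pairwise_auc_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Exhaustive-enumeration two-sided Mann-Whitney p-value for small untied
# samples: enumerate all C(n_a + n_b, n_a) assignments of the pooled values.
mw_exact_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
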