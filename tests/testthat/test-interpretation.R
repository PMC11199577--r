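# A small fitted two-block model plus its scaled inputs, reused across tests.
interp_fixture <- function(seed = 2) {
  set.seed(seed)
  n <- 30
  y <- rep(c(0, 1), length.out = n)
  mk <- function(prefix, p) {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%02d", 1:n), paste0(prefix, 1:p)))
    m[y == 1, 1:2] <- m[y == 1, 1:2] + 2.5
    scale(m)
  }
  blocks <- list(ex = mk("g", 6), me = mk("c", 5))
  model <- fit_block_plsda(blocks, y, n_components = 2)
  list(model = model, blocks = blocks, y = y)
}

test_that("feature-component correlations are plain Pearson correlations", {
  fx <- interp_fixture()
  fc <- feature_component_correlations(fx$model, fx$blocks)
  expect_equal(nrow(fc), 11)
  expect_equal(colnames(fc), c("comp1", "comp2"))
  # brute force on raw vectors
  cons <- fx$model$consensus_scores
  for (f in rownames(fc)) {
    b <- if (startsWith(f, "g")) "ex" else "me"
    expect_equal(fc[f, "comp1"], cor(fx$blocks[[b]][, f], cons[, 1]))
    expect_equal(fc[f, "comp2"], cor(fx$blocks[[b]][, f], cons[, 2]))
  }
  expect_true(all(abs(fc) <= 1 + 1e-9))
  # circle coordinates lie in the unit disk on this fixture
  expect_true(all(sqrt(rowSums(fc^2)) <= 1 + 1e-9))
  expect_identical(unname(attr(fc, "block")),
                   rep(c("ex", "me"), c(6, 5)))
})

test_that("a feature equal to a component sits at the circle pole", {
  fx <- interp_fixture()
  cons <- fx$model$consensus_scores
  fake_blocks <- fx$blocks
  fake_blocks$ex[, 1] <- cons[, 1]            # feature == comp1 scores
  fc <- feature_component_correlations(fx$model, fake_blocks)
  expect_equal(unname(fc["g1", "comp1"]), 1)
  # orthogonal noise feature lands near the origin
  set.seed(99)
  resid <- residuals(lm(rnorm(nrow(cons)) ~ cons))
  fake_blocks$ex[, 2] <- resid
  fc2 <- feature_component_correlations(fx$model, fake_blocks)
  expect_lt(max(abs(fc2["g2", ])), 1e-8)
})

test_that("zero-variance features get correlation zero with a warning", {
  fx <- interp_fixture()
  fb <- fx$blocks
  fb$me[, 3] <- 0
  expect_warning(fc <- feature_component_correlations(fx$model, fb),
                 "zero-variance")
  expect_equal(unname(fc["c3", ]), c(0, 0))
})

test_that("cross-omics association is the component-space inner product", {
  # hand-built correlation matrix for six features
  C <- matrix(c(1, 0, 0.8, 0.6, 0.5, 0.5,
                0, 1, 0.6, -0.8, 0.5, -0.5), 6, 2,
              dimnames = list(paste0("f", 1:6), c("comp1", "comp2")))
  attr(C, "block") <- setNames(rep(c("a", "b"), each = 3), paste0("f", 1:6))
  A <- cross_omics_association(C)
  # brute-force double sum
  for (i in 1:6) for (j in 1:6) {
    want <- sum(C[i, ] * C[j, ])
    if (i == j) want <- 1
    expect_equal(unname(A[i, j]), min(max(want, -1), 1))
  }
  expect_equal(unclass(A), t(unclass(A)), ignore_attr = TRUE)
  expect_true(all(abs(A) <= 1))
  expect_equal(unname(diag(A)), rep(1, 6))
  # both perfectly on comp1 -> association 1
  expect_equal(unname(A["f1", "f3"]), 0.8)
  P <- matrix(c(1, 1, 0, 0), 2, 2,
              dimnames = list(c("x", "y"), c("comp1", "comp2")))
  expect_equal(unname(cross_omics_association(P)["x", "y"]), 1)
  # comp1-only vs comp2-only -> association 0
  Q <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("x", "y"), c("comp1", "comp2")))
  expect_equal(unname(cross_omics_association(Q)["x", "y"]), 0)
})

test_that("network construction counts edges and degrees correctly", {
  # complete graph on 4 nodes
  A <- matrix(0.9, 4, 4, dimnames = list(paste0("n", 1:4), paste0("n", 1:4)))
  diag(A) <- 1
  attr(A, "block") <- setNames(rep(c("a", "b"), 2), paste0("n", 1:4))
  net <- build_network(A, threshold = 0.7)
  expect_equal(nrow(net$edges), 6)
  expect_equal(net$average_degree, 3)
  # threshold above every off-diagonal entry: empty graph
  empty <- build_network(A, threshold = 0.95)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$average_degree, 0)
  # 5 nodes, all 10 edges -> degree 4, verified by counting
  B <- matrix(0.8, 5, 5, dimnames = list(paste0("m", 1:5), paste0("m", 1:5)))
  diag(B) <- 1
  netB <- build_network(B, threshold = 0.7)
  expect_equal(nrow(netB$edges), choose(5, 2))
  expect_equal(netB$average_degree, 2 * choose(5, 2) / 5)
  # edge count is non-increasing in the threshold
  set.seed(12)
  R <- tcrossprod(matrix(runif(20, -1, 1), 10, 2)) / 2
  diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:10), paste0("v", 1:10))
  counts <- vapply(seq(0.1, 1, by = 0.1), function(thr)
    nrow(build_network(R, thr)$edges), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(build_network(A, threshold = 0), "threshold")
})

test_that("block-pair restriction keeps only spanning edges", {
  A <- matrix(0.9, 4, 4, dimnames = list(paste0("n", 1:4), paste0("n", 1:4)))
  diag(A) <- 1
  attr(A, "block") <- setNames(c("a", "a", "b", "b"), paste0("n", 1:4))
  net <- build_network(A, threshold = 0.7, block_pair = c("a", "b"))
  expect_equal(nrow(net$edges), 4)           # 2 x 2 cross-block pairs
  ba <- attr(A, "block")[net$edges$from]
  bb <- attr(A, "block")[net$edges$to]
  expect_true(all(ba != bb))
})

test_that("hierarchical clustering separates planted classes contiguously", {
  set.seed(44)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  m <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:10)))
  m[y == 1, ] <- m[y == 1, ] + 4
  ord <- cluster_heatmap_order(scale(m))
  leaf_classes <- y[match(ord$sample_order, rownames(m))]
  expect_equal(sum(diff(leaf_classes) != 0), 1)   # one class boundary
  # duplicated samples end up adjacent
  m2 <- rbind(m, dup = m[5, ])
  rownames(m2) <- c(rownames(m), "dup")
  ord2 <- cluster_heatmap_order(scale(m2))
  pos <- match(c(rownames(m)[5], "dup"), ord2$sample_order)
  expect_equal(abs(diff(pos)), 1)
  expect_error(cluster_heatmap_order(m[1, , drop = FALSE]), "at least 2")
})

test_that("arrow-plot data carries per-block tips and consensus origins", {
  fx <- interp_fixture()
  ar <- arrow_plot_data(fx$model)
  expect_equal(nrow(ar), 2 * 30)
  expect_setequal(unique(ar$block), c("ex", "me"))
  cons <- fx$model$consensus_scores
  ex_rows <- ar[ar$block == "ex", ]
  expect_equal(ex_rows$comp1, unname(fx$model$scores$ex[, 1]))
  expect_equal(ex_rows$consensus1, unname(cons[, 1]))
  # consensus is the mean of the two block tips, row by row
  me_rows <- ar[ar$block == "me", ]
  expect_equal((ex_rows$comp1 + me_rows$comp1) / 2, ex_rows$consensus1)
})
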