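test_that("first layer of an all-zero matrix is the rescaled constant column", {
  tab <- labeled_table(matrix(0, 4, 3), c(1, -1, 1, -1))
  layer <- build_first_layer(tab, nlpnn_config(seed = 1))
  expect_equal(ncol(layer$F), 1L)
  # norm sqrt(4) = 2, direction = all-ones
  expect_equal(abs(layer$F[, 1]), rep(1, 4), tolerance = 1e-12)
  expect_equal(length(unique(round(layer$F[, 1], 10))), 1L)
})

test_that("first layer spans the augmented matrix when width allows", {
  # n = 2, d = 1, X = (1, -1): [1 X] has orthogonal columns, width 2
  tab2 <- labeled_table(matrix(c(1, -1), 2, 1), c(1, -1))
  layer2 <- build_first_layer(tab2, nlpnn_config(omega = 5, seed = 1))
  expect_equal(ncol(layer2$F), 2L)
  expect_equal(qr(layer2$F)$rank, 2L)
  expect_equal(colSums(layer2$F^2), rep(2, 2), tolerance = 1e-9)

  set.seed(11)
  X <- matrix(rnorm(80), 20, 4)
  tab <- labeled_table(X, rep(c(1, -1), 10))
  layer <- build_first_layer(tab, nlpnn_config(omega = 5, seed = 1))
  A <- cbind(1, X)
  Q <- qr.Q(qr(A))  # brute-force orthonormalization oracle
  resid <- max(abs(layer$F - Q %*% crossprod(Q, layer$F)))
  expect_lt(resid, 1e-8)
  resid2 <- local({
    Qf <- qr.Q(qr(layer$F))
    max(abs(A - Qf %*% crossprod(Qf, A)))
  })
  expect_lt(resid2, 1e-8)
})

test_that("candidate products follow the i-major, j-minor Hadamard order", {
  prev <- nlpnn:::new_basis_layer(1L, F = cbind(c(1, 2)), construction = NULL)
  first <- nlpnn:::new_basis_layer(1L, F = cbind(c(3, 4), c(0, 1)),
                                   construction = NULL)
  cand <- candidate_products(prev, first)
  expect_equal(unname(cand), cbind(c(3, 8), c(0, 2)), ignore_attr = TRUE)
  expect_equal(attr(cand, "pairs")$i, c(1L, 1L))
  expect_equal(attr(cand, "pairs")$j, c(1L, 2L))

  # counting: w_prev = 3, w_1 = 4 -> 12 columns, lexicographic (i, j)
  p3 <- nlpnn:::new_basis_layer(2L, F = matrix(rnorm(12), 3, 4)[, 1:3],
                                construction = NULL)
  f4 <- nlpnn:::new_basis_layer(1L, F = matrix(rnorm(12), 3, 4),
                                construction = NULL)
  cand2 <- candidate_products(p3, f4)
  expect_equal(ncol(cand2), 12L)
  pr <- attr(cand2, "pairs")
  expect_equal(pr$i, rep(1:3, each = 4))
  expect_equal(pr$j, rep(1:4, times = 3))
})

test_that("OLS selection drops dependent candidates and prefers y-correlated ones", {
  set.seed(3)
  n <- 6
  X <- matrix(rnorm(n * 2), n, 2)
  tab <- labeled_table(X, rep(c(1, -1), 3))
  cfg <- nlpnn_config(omega = c(3, 3), seed = 3)
  first <- build_first_layer(tab, cfg)
  stack <- nlpnn:::new_feature_stack(list(first), n)

  # candidates identical to an accumulated column -> empty layer
  dup <- first$F[, c(1, 1), drop = FALSE]
  attr(dup, "pairs") <- data.frame(i = c(1L, 1L), j = c(1L, 1L))
  empty <- select_layer_columns(dup, stack, tab$y, 3, 1e-8)
  expect_equal(ncol(empty$F), 0L)

  zero <- matrix(0, n, 2)
  attr(zero, "pairs") <- data.frame(i = c(1L, 1L), j = c(1L, 2L))
  expect_equal(ncol(select_layer_columns(zero, stack, tab$y, 3, 1e-8)$F), 0L)

  # a candidate exactly equal to y (orthogonalized) must be picked first;
  # oracle = exhaustive stepwise search maximizing explained y-variance
  y <- tab$y
  Q1 <- qr.Q(qr(first$F))
  resid_y <- y - Q1 %*% crossprod(Q1, y)
  cand <- cbind(rnorm(n), resid_y, rnorm(n))
  attr(cand, "pairs") <- data.frame(i = rep(1L, 3), j = 1:3)
  sel <- select_layer_columns(cand, stack, y, 2, 1e-8)
  expect_equal(sel$construction[[1]]$j, 2L)
  oracle_first <- which.max(apply(cand, 2, function(cc) {
    r <- cc - Q1 %*% crossprod(Q1, cc)
    (crossprod(r, y))^2 / sum(r^2)
  }))
  expect_equal(sel$construction[[1]]$j, as.integer(oracle_first))
})

test_that("stack columns are normalized, independent, and capped in width", {
  set.seed(7)
  X <- matrix(rnorm(60 * 3), 60, 3)
  tab <- labeled_table(X, sample(c(-1, 1), 60, replace = TRUE))
  cfg <- nlpnn_config(omega = c(4, 4, 4), seed = 7)
  stack <- build_stack(tab, cfg)
  feats <- nlpnn:::stack_features(stack)
  expect_equal(unname(colSums(feats^2)), rep(60, ncol(feats)), tolerance = 1e-6)
  expect_equal(qr(feats)$rank, ncol(feats))
  widths <- vapply(stack$layers, function(l) ncol(l$F), integer(1))
  expect_true(all(widths <= c(4, 4, 4)[seq_along(widths)]))
})

test_that("stack with unlimited width matches the monomial design span", {
  set.seed(12)
  X <- as.matrix(expand.grid(x1 = seq(-1, 1, length.out = 5),
                             x2 = seq(-1, 1, length.out = 5)))
  dimnames(X) <- NULL
  tab <- labeled_table(X, rep(c(1, -1), length.out = 25))
  stack <- build_stack(tab, nlpnn_config(omega = c(50, 50), seed = 12))
  Fm <- nlpnn:::stack_features(stack)
  D <- monomial_design(X, monomial_exponents(2, 2))
  expect_equal(qr(Fm)$rank, qr(D)$rank)
  QF <- qr.Q(qr(Fm))
  expect_lt(max(abs(D - QF %*% crossprod(QF, D))), 1e-6)
})

test_that("M = 1 stack is exactly the first layer and build is deterministic", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  tab <- labeled_table(X, rep(c(1, -1), 10))
  cfg1 <- nlpnn_config(omega = 3, seed = 5)
  s1 <- build_stack(tab, cfg1)
  expect_length(s1$layers, 1L)
  expect_identical(s1$layers[[1]]$F, build_first_layer(tab, cfg1)$F)

  cfg2 <- nlpnn_config(omega = c(3, 3), seed = 5)
  expect_identical(build_stack(tab, cfg2), build_stack(tab, cfg2))
})

test_that("transform replays training features and hand-unrolled products", {
  set.seed(8)
  X <- matrix(rnorm(30 * 2), 30, 2)
  tab <- labeled_table(X, rep(c(1, -1), 15))
  stack <- build_stack(tab, nlpnn_config(omega = c(3, 3), seed = 8))
  replay <- transform_stack(stack, X)
  expect_equal(replay, nlpnn:::stack_features(stack), tolerance = 1e-10)

  x_new <- matrix(rnorm(2), 1, 2)
  out <- transform_stack(stack, x_new)
  first <- cbind(1, x_new) %*% stack$layers[[1]]$construction
  manual <- first
  for (r in stack$layers[[2]]$construction) {
    manual <- cbind(manual, r$scale * first[, r$i] * first[, r$j])
  }
  expect_equal(out, manual, tolerance = 1e-12)

  # all-zero row activates only the constant part of the projection
  zrow <- transform_stack(stack, matrix(0, 1, 2), m = 1)
  expect_equal(zrow, matrix(c(1, 0, 0), 1, 3) %*% stack$layers[[1]]$construction)

  expect_error(transform_stack(stack, matrix(0, 1, 3)), "columns")
})
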