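test_that("classifier_weight matches the closed form and its analytic inversions", {
  expect_equal(classifier_weight(0.5), 0)
  expect_equal(classifier_weight(0.2), 0.5 * log(4), tolerance = 1e-12)
  expect_equal(classifier_weight(1 / (1 + exp(2))), 1, tolerance = 1e-12)
  # strictly decreasing, positive iff epsilon < 0.5
  eps <- seq(0.01, 0.99, by = 0.01)
  a <- classifier_weight(eps)
  expect_true(all(diff(a) < 0))
  expect_true(all((a > 0) == (eps < 0.5)))
  expect_error(classifier_weight(0), "epsilon")
  expect_error(classifier_weight(1), "epsilon")
})

test_that("weighted_error sums the distribution mass on mistakes", {
  y <- c(1, 1, -1, -1)
  D <- rep(0.25, 4)
  expect_equal(weighted_error(D, y, y), 0)
  expect_equal(weighted_error(D, y, -y), 1)
  expect_equal(weighted_error(D, y, c(1, -1, -1, -1)), 0.25)
  expect_error(weighted_error(D, y, c(1, 1)), "length")
})

test_that("update_weights reweights mistakes and renormalizes", {
  y <- c(1, 1)
  # alpha = 0: no change
  st <- update_weights(c(0.5, 0.5), 0, y, c(1, -1))
  expect_equal(st$D, c(0.5, 0.5))
  # all correct: renormalization restores the distribution
  st2 <- update_weights(c(0.3, 0.7), 0.7, y, y)
  expect_equal(st2$D, c(0.3, 0.7))
  # hand computation: D = (1/2, 1/2), sample 2 wrong, alpha = ln 2
  st3 <- update_weights(c(0.5, 0.5), log(2), y, c(1, -1))
  expect_equal(st3$D, c(0.2, 0.8), tolerance = 1e-12)
  expect_equal(st3$Z, 1.25, tolerance = 1e-12)
})

test_that("any base learner has weighted error exactly 1/2 under the updated weights", {
  set.seed(40)
  for (rep in 1:5) {
    n <- 50
    x <- rnorm(n)
    y <- ifelse(x + 0.3 * rnorm(n) > 0, 1, -1)
    D <- runif(n)
    D <- D / sum(D)
    stump <- fit_stump(x, y, D)
    eps <- weighted_error(D, y, stump$pred)
    alpha <- classifier_weight(eps)
    D2 <- update_weights(D, alpha, y, stump$pred)$D
    expect_equal(weighted_error(D2, y, stump$pred), 0.5, tolerance = 1e-9)
    expect_equal(sum(D2), 1, tolerance = 1e-9)
    expect_true(all(D2 >= 0))
  }
})

test_that("L_max = 1 reproduces a lone NLPNN fit with uniform weights", {
  tab <- make_affine_table(n = 100, d = 2, seed = 41)
  val <- make_affine_table(n = 40, d = 2, seed = 141)
  cfg <- nlpnn_config(seed = 41)
  single <- nlpnn(tab, cfg)
  ens <- aepnn(tab, L_max = 1, config = cfg, val_table = val)
  X_test <- matrix(rnorm(60), 30, 2)
  expect_equal(predict(ens, X_test), predict(single, X_test))
  expect_equal(ens$L, 1L)
})

test_that("a separable dataset stops boosting after one perfect round", {
  tab <- make_affine_table(n = 100, d = 2, margin = 0.8, seed = 42)
  val <- make_affine_table(n = 40, d = 2, margin = 0.8, seed = 142)
  ens <- aepnn(tab, L_max = 5, config = nlpnn_config(seed = 42),
               val_table = val)
  expect_equal(ens$L, 1L)
  expect_equal(ens$epsilon, 0)
  # capped vote weight: alpha = classifier_weight(1/(2n))
  expect_equal(ens$alpha, classifier_weight(1 / (2 * nrow(tab$X))))
})

test_that("ensemble votes follow the weighted sign with ties positive", {
  tab <- make_xor_grid()
  cfg <- nlpnn_config(omega = c(3, 3), seed = 2)
  ens <- aepnn(tab, L_max = 1, config = cfg, val_table = tab)
  # single member: equals that member's predictions
  expect_equal(predict(ens, tab$X), predict(ens$members[[1]], tab$X))

  # hand-built ensembles exercise the vote arithmetic
  fake <- ens
  fake$members <- list(ens$members[[1]], ens$members[[1]])
  fake$alpha <- c(1, 1)
  fake$L <- 2L
  m1 <- predict(ens$members[[1]], tab$X)
  expect_equal(predict(fake, tab$X), m1)  # identical members agree

  # opposite equal votes -> +1 everywhere (sign(0) = +1)
  s <- 1 * m1 + 1 * (-m1)
  expect_equal(nlpnn:::sign_pos(s), rep(1, length(m1)))
  # alpha = (1.0, 0.5, 0.4), member votes (+1, -1, -1) -> sign(0.1) = +1
  expect_equal(nlpnn:::sign_pos(1.0 * 1 + 0.5 * -1 + 0.4 * -1), 1)
})

test_that("training exponential loss is non-increasing over accepted rounds", {
  set.seed(43)
  syn <- synth_generate(synth_spec(n = 300, d = 4, degree = 3,
                                   imbalance_ratio = 3, label_noise = 0.05,
                                   seed = 43))
  tab <- zero_fill(syn$table)
  val <- make_oracle_testset(syn$truth, 4, n = 100, seed = 143)
  ens <- aepnn(tab, L_max = 4, config = nlpnn_config(seed = 43),
               val_table = val)
  S <- numeric(nrow(tab$X))
  losses <- numeric(ens$L)
  for (l in seq_len(ens$L)) {
    S <- S + ens$alpha[l] * predict(ens$members[[l]], tab$X)
    losses[l] <- mean(exp(-tab$y * S))
  }
  expect_true(all(diff(losses) <= 1e-9))
})

test_that("select_iterations trades recall growth against accuracy drop", {
  h <- data.frame(accuracy = c(0.90, 0.88, 0.80),
                  recall = c(0.10, 0.20, 0.25))
  # growth differences: l=2: 1.0 - 0.0222 = 0.9778; l=3: 1.5 - 0.1111 = 1.3889
  expect_equal(select_iterations(h), 3L)

  up <- data.frame(accuracy = rep(0.9, 3), recall = c(0.1, 0.2, 0.3))
  expect_equal(select_iterations(up), 3L)

  flat <- data.frame(accuracy = rep(0.9, 4), recall = rep(0.2, 4))
  expect_equal(select_iterations(flat), 1L)

  # zero baseline recall uses the 1/(2 n_pos) floor
  z <- data.frame(accuracy = c(0.9, 0.9), recall = c(0, 0.5))
  expect_equal(select_iterations(z, n_pos = 20), 2L)
  expect_error(select_iterations(z[0, ]), "empty")
})
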