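test_that("residual vectors match ordinary least squares", {
  # orthogonal regressor leaves xi unchanged
  expect_equal(residual_vector(c(1, -1, 1, -1), c(1, 1, -1, -1)),
               c(1, -1, 1, -1))
  # perfect collinearity gives the zero vector
  xj <- c(0.3, -1.2, 0.9)
  expect_equal(residual_vector(2 * xj, xj), rep(0, 3), tolerance = 1e-12)
  # independent OLS oracle: fit the slope with lm, subtract
  xi <- c(1, 2, 3); xj2 <- c(1, 0, -1)
  b <- unname(coef(lm(xi ~ xj2))[2])
  expect_equal(residual_vector(xi, xj2), xi - b * xj2, tolerance = 1e-12)
  expect_equal(residual_vector(xi, xj2), c(2, 2, 2))
  expect_error(residual_vector(xi, c(1, 1, 1)), "degenerate")
})

test_that("residuals are orthogonal to the regressor (property)", {
  set.seed(42)
  for (i in 1:250) {
    n <- sample(10:80, 1)
    xi <- rnorm(n); xj <- runif(n, -2, 2)
    r <- residual_vector(xi, xj)
    expect_lt(abs(cov(r, xj)), 1e-10)
  }
})

test_that("independence score separates exogenous from endogenous candidates", {
  set.seed(7)
  n <- 2000
  # null band from independent pairs
  null_scores <- replicate(100, {
    independence_score(runif(n, -1, 1), matrix(runif(n, -1, 1), ncol = 1))
  })
  x <- runif(n, -1, 1)
  e <- runif(n, -1, 1)
  child <- 0.8 * x + e
  s_cause <- independence_score(x, matrix(child, ncol = 1))
  s_effect <- independence_score(child, matrix(x, ncol = 1))
  # cause scores inside the null band, effect far below it
  expect_gte(s_cause, min(null_scores) * 3)
  expect_lt(s_effect, min(null_scores) * 10)
  expect_gt(s_cause, s_effect)
  # degenerate inputs
  expect_equal(independence_score(x, NULL), 0)
  # scale invariance
  expect_equal(independence_score(3.7 * x, matrix(0.2 * child, ncol = 1)),
               s_effect0 <- independence_score(x, matrix(child, ncol = 1)),
               tolerance = 1e-10)
})

test_that("causal ordering is trivial, equivariant, and deterministic", {
  expect_equal(causal_order(matrix(rnorm(50), 50, 1)), 1L)
  ch <- preset_spec("chain5")
  X <- generate_features(ch, 3000, 13)
  ord <- causal_order(X)
  # column permutation maps the ordering by the same permutation
  perm <- c(3L, 5L, 1L, 2L, 4L)           # new position of old column i
  Xp <- X[, order(perm)]                  # column k of Xp is old column order(perm)[k]
  ordp <- causal_order(Xp)
  expect_equal(order(perm)[ordp], ord)
  expect_identical(causal_order(X), ord)
})

test_that("near-Gaussian data trigger the unidentifiability warning but still run", {
  set.seed(9)
  n <- 5000
  e <- matrix(rnorm(2 * n), n, 2)
  X <- cbind(e[, 1], 0.8 * e[, 1] + e[, 2])
  expect_warning(ord <- causal_order(X), "Gaussian")
  expect_setequal(ord, 1:2)
})

test_that("strength matrix recovers OLS coefficients via the covariance", {
  # null case: independent columns give near-zero coefficients
  set.seed(11)
  X0 <- matrix(runif(50000 * 3, -1, 1), ncol = 3)
  S0 <- strength_matrix(X0, 1:3)
  expect_lt(max(abs(S0)), 0.02)
  # chain5 with the true order: 0.8 on the chain, ~0 elsewhere
  Xc <- generate_features(preset_spec("chain5"), 50000, 17)
  S <- strength_matrix(Xc, 1:5)
  for (k in 2:5) expect_equal(S[k, k - 1], 0.8, tolerance = 0.05 / 0.8)
  off <- S; off[cbind(2:5, 1:4)] <- 0
  expect_lt(max(abs(off)), 0.05)
  # p = 1 gives the 1x1 zero matrix
  expect_equal(strength_matrix(matrix(rnorm(10), ncol = 1), 1L),
               matrix(0, 1, 1), ignore_attr = TRUE)
  # cross-check one full regression against lm
  fit <- lm(Xc[, 3] ~ Xc[, 1] + Xc[, 2])
  expect_equal(unname(S[3, 1:2]), unname(coef(fit)[2:3]), tolerance = 1e-8)
  expect_error(strength_matrix(Xc, c(1, 1, 2, 3, 4)), "permutation")
})

test_that("singular predecessor covariance falls back to ridge with a warning", {
  set.seed(2)
  x <- rnorm(100)
  X <- cbind(x, x, rnorm(100))            # duplicated predecessor
  expect_warning(S <- strength_matrix(X, 1:3), "ridge")
  expect_true(all(is.finite(S)))
})

test_that("edge thresholding applies the absolute-value rule", {
  S <- matrix(c(0, 0, 0.8, 0, 0, 0, -0.03, 0.2, 0), 3, 3, byrow = TRUE)
  expect_equal(threshold_edges(S, 0), (S != 0) * 1)
  expect_equal(sum(threshold_edges(S, 10)), 0)
  expect_equal(sum(threshold_edges(S, 0.1)), 2)   # |0.8| and |0.2| survive
  expect_error(threshold_edges(S, -1), "non-negative")
})

test_that("the fitted causal model is deterministic and structurally valid", {
  tab <- make_dataset(preset_spec("hub10"), 800, 3)
  m1 <- lingam(tab, tau = 0.05)
  m2 <- lingam(tab, tau = 0.05)
  expect_identical(m1$ordering, m2$ordering)
  expect_identical(m1$strength, m2$strength)
  # strength support respects the ordering (constructor invariant)
  pos <- order(m1$ordering)
  for (k in seq_along(pos)) for (j in seq_along(pos))
    if (pos[j] >= pos[k]) expect_identical(m1$strength[k, j], 0)
  # adjacency <-> strength threshold coupling
  expect_equal(m1$adjacency, (abs(m1$strength) > m1$threshold) * 1)
  # label anchored most downstream by default
  expect_equal(m1$ordering[length(m1$ordering)], m1$label_index)
})

test_that("hub10 parent recovery: retained nodes include the true label parents", {
  hits <- 0
  for (s in 1:10) {
    tab <- make_dataset(preset_spec("hub10"), 3000, s)
    m <- lingam(tab, tau = 0.05)
    if (all(c("f1", "f2", "f3") %in% m$graph$nodes)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
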