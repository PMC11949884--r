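test_that("squash preserves direction and bounds norms in [0,1)", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  u <- c(1, 0, 0)
  expect_equal(squash(u), 0.5 * u)
  s <- 10 * c(0, 1)
  expect_equal(sqrt(sum(squash(s)^2)), 100 / 101)
  expect_equal(squash(s) / sqrt(sum(squash(s)^2)), c(0, 1))
  # norm strictly increasing in the input norm, always < 1
  set.seed(1)
  dir <- rnorm(4); dir <- dir / sqrt(sum(dir^2))
  norms <- sapply(seq(0.1, 20, length.out = 40),
                  function(a) sqrt(sum(squash(a * dir)^2)))
  expect_true(all(diff(norms) > 0))
  expect_true(all(norms >= 0 & norms < 1))
})

test_that("dynamic routing matches a straight-line independent execution", {
  # degenerate: one capsule, one class
  v1 <- array(c(0.3, -0.2), c(1, 1, 2))
  rt <- dynamic_routing(v1, r = 2)
  expect_equal(rt$c, matrix(1, 1, 1))
  expect_equal(rt$v[1, ], squash(c(0.3, -0.2)))
  # r = 1, two classes: couplings are softmax of zero logits
  set.seed(3)
  votes <- array(rnorm(3 * 2 * 4, sd = 0.5), c(3, 2, 4))
  rt1 <- dynamic_routing(votes, r = 1)
  expect_equal(rt1$c, matrix(0.5, 3, 2))
  # fixed small vote set, r = 3: full agreement with the oracle
  votes2 <- array(c(0.2, -0.4, 0.5, 0.3, -0.1, 0.25, 0.6, -0.2), c(2, 2, 2))
  rt3 <- dynamic_routing(votes2, r = 3)
  or3 <- oracle_routing(votes2, 3)
  expect_equal(rt3$v, or3$v, tolerance = 1e-12)
  expect_equal(rt3$c, or3$c, tolerance = 1e-12)
  # coupling rows sum to one at every iteration
  for (it in 1:3)
    expect_equal(rowSums(or3$c_history[[it]]), rep(1, 2), tolerance = 1e-12)
})

test_that("routing agreement grows for a dominant vote cluster", {
  d <- 4
  base <- c(2, 0, 0, 0)
  votes <- array(0, c(5, 2, d))
  for (i in 1:4) votes[i, 1, ] <- base          # cluster agrees on class 1
  votes[5, 1, ] <- -base                        # one dissenter
  for (i in 1:5) votes[i, 2, ] <- rep(0.1, d)
  cs <- sapply(1:4, function(r) dynamic_routing(votes, r)$c[1, 1])
  expect_true(all(diff(cs) >= 0))
  expect_gt(cs[4], 0.5)
  # dissenter is routed away from the cluster class
  expect_lt(dynamic_routing(votes, 4)$c[5, 1], 0.5)
})

test_that("margin loss reproduces hand-computed values and is non-negative", {
  cfg <- caps_config(m_plus = 0.9, m_minus = 0.1, lambda_neg = 0.5)
  # both hinges inactive
  expect_equal(margin_loss(c(0.05, 0.95), 1, cfg), 0)
  # norms (0.5, 0.5), label 1: 0.4^2 + 0.5 * 0.4^2 = 0.24
  expect_equal(margin_loss(c(0.5, 0.5), 1, cfg), 0.24)
  set.seed(8)
  for (i in 1:50)
    expect_gte(margin_loss(runif(2), sample(0:1, 1), cfg), 0)
})

test_that("node attributes carry values, degrees, and label-parent flags", {
  g <- toy_graph()
  at <- node_attributes(g, c(f1 = 1.0, f2 = -0.5))
  expect_equal(at["f1", ], c(value = 1.0, in_degree = 0, out_degree = 1,
                             is_label_parent = 0))
  expect_equal(at["f2", ], c(value = -0.5, in_degree = 1, out_degree = 0,
                             is_label_parent = 1))
  expect_error(node_attributes(g, c(f1 = 1.0)), "missing retained")
  # empty edge set: degrees all zero
  g0 <- g; g0$adjacency[] <- 0; g0$edges <- g$edges[0, ]
  at0 <- node_attributes(g0, c(f1 = 1, f2 = 2))
  expect_true(all(at0[, c("in_degree", "out_degree")] == 0))
})

test_that("disentangle applies the K linear maps exactly", {
  attrs <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  id <- list(D = list(diag(2)))
  expect_equal(disentangle(attrs, id)[[1]], attrs)
  zero <- list(D = list(matrix(0, 2, 2)))
  expect_true(all(disentangle(attrs, zero)[[1]] == 0))
  Dk <- matrix(c(1, -1, 0.5, 2), 2, 2, byrow = TRUE)
  out <- disentangle(attrs, list(D = list(Dk)))[[1]]
  expect_equal(out, attrs %*% t(Dk))   # hand-checked: row1 = (-1, 4.5)
  expect_equal(out[1, ], c(-1, 4.5))
})

test_that("propagation is the normalized-adjacency convolution", {
  # single node, no edges: self-loop only, identity propagation
  p1 <- list(P = list(diag(2)))
  h <- list(matrix(c(0.3, -0.2), 1, 2))
  expect_equal(propagate(h, matrix(0, 1, 1), p1), tanh(h[[1]]))
  # two identical fully-connected nodes give identical capsules
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  h2 <- list(matrix(rep(c(0.4, 0.1), each = 2), 2, 2))
  out2 <- propagate(h2, A2, p1)
  expect_equal(out2[1, ], out2[2, ])
  # 3-node path, unit attributes, identity maps: capsules = tanh(rowsums of Ahat)
  A3 <- matrix(0, 3, 3); A3[2, 1] <- 1; A3[3, 2] <- 1
  S <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3, byrow = TRUE)
  d <- rowSums(S)
  Ahat <- S / sqrt(outer(d, d))
  h3 <- list(matrix(1, 3, 1))
  expect_equal(propagate(h3, A3, list(P = list(diag(1)))),
               tanh(matrix(rowSums(Ahat), 3, 1)))
})

test_that("batched training forward equals the composed per-sample operations", {
  g <- toy_graph()
  cfg <- caps_config(K = 2, d_node = 4, d_class = 3, r = 3, seed = 4)
  set.seed(4)
  pars <- causalcaps:::init_params(cfg)
  geom <- causalcaps:::caps_geometry(g)
  V <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("f1", "f2")))
  fw <- causalcaps:::caps_forward(pars, geom, V, cfg$r)
  for (s in 1:3) {
    sample <- c(f1 = unname(V[s, 1]), f2 = unname(V[s, 2]))
    attrs <- node_attributes(g, sample)
    U <- propagate(disentangle(attrs, pars), g$adjacency, pars)
    votes <- array(0, c(2, 2, 3))
    for (j in 1:2) votes[, j, ] <- U %*% t(pars$W[[j]])
    rt <- dynamic_routing(votes, cfg$r)
    expect_equal(fw$norms[s, ],
                 c(sqrt(sum(rt$v[1, ]^2)), sqrt(sum(rt$v[2, ]^2))),
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match numerical differentiation at r = 1", {
  g <- toy_graph()
  cfg <- caps_config(K = 2, d_node = 4, d_class = 3, r = 1, seed = 2)
  set.seed(2)
  pars <- causalcaps:::init_params(cfg)
  geom <- causalcaps:::caps_geometry(g)
  V <- matrix(rnorm(8), 4, 2)
  y <- c(1, 0, 1, 0)
  lossfun <- function(p) {
    fw <- causalcaps:::caps_forward(p, geom, V, 1L)
    Tm <- cbind(1 - y, y)
    mean(rowSums(Tm * pmax(0, cfg$m_plus - fw$norms)^2 +
                   cfg$lambda_neg * (1 - Tm) * pmax(0, fw$norms - cfg$m_minus)^2))
  }
  fw <- causalcaps:::caps_forward(pars, geom, V, 1L)
  bw <- causalcaps:::caps_backward(pars, geom, fw, y, cfg)
  eps <- 1e-6
  check <- function(getter, setter, grad) {
    p0 <- getter(pars)
    for (i in seq_along(p0)) {
      vp <- p0; vp[i] <- vp[i] + eps
      vm <- p0; vm[i] <- vm[i] - eps
      num <- (lossfun(setter(pars, vp)) - lossfun(setter(pars, vm))) / (2 * eps)
      expect_equal(grad[i], num, tolerance = 1e-5)
    }
  }
  check(function(p) p$D[[1]], function(p, v) { p$D[[1]] <- v; p }, bw$gD[[1]])
  check(function(p) p$P[[2]], function(p, v) { p$P[[2]] <- v; p }, bw$gP[[2]])
  check(function(p) p$W[[1]], function(p, v) { p$W[[1]] <- v; p }, bw$gW[[1]])
})

test_that("predicted probability is the normalized diseased-capsule norm", {
  expect_equal(0.9 / (0.9 + 0.1), 0.9)  # formula anchor
  g <- toy_graph()
  tab <- toy_separable_table(80)
  fit <- capsnet(g, tab, caps_config(epochs = 2, seed = 1))
  sample <- c(f1 = 0.5, f2 = -0.3)
  pr <- predict_proba(fit, sample = sample)
  expect_gte(pr, 0); expect_lte(pr, 1)
  # deterministic given params
  expect_identical(pr, predict_proba(fit, sample = sample))
})

test_that("prediction is equivariant to node relabeling", {
  g <- toy_graph()
  tab <- toy_separable_table(100)
  fit <- capsnet(g, tab, caps_config(epochs = 3, seed = 5))
  # reverse the node order everywhere
  g2 <- g
  g2$nodes <- rev(g$nodes)
  g2$adjacency <- g$adjacency[2:1, 2:1]
  fit2 <- fit
  fit2$graph <- g2
  fit2$geom <- causalcaps:::caps_geometry(g2)
  sample <- c(f1 = 1.2, f2 = -0.7)
  expect_equal(predict_proba(fit, sample = sample),
               predict_proba(fit2, sample = sample), tolerance = 1e-12)
})

test_that("training separates a linearly separable toy and rejects one class", {
  tab <- toy_separable_table(200, seed = 10)
  g <- toy_graph_single()
  fit <- capsnet(g, tab, caps_config(epochs = 50, seed = 10))
  acc <- mean(predict(fit, tab, type = "class") == tab$y)
  expect_gte(acc, 0.95)
  expect_true(all(is.finite(fit$loss_trace)))
  # permuted labels carry no signal: in-distribution AUC near chance
  perm <- local({ set.seed(99); sample(length(tab$y)) })
  tabp <- tab
  tabp$y <- tab$y[perm]
  sp <- train_test_split(200, 0.7, seed = 99)
  fitp <- capsnet(g, causalcaps:::subset_table(standardize(tabp), sp$train),
                  caps_config(epochs = 20, seed = 10))
  tep <- causalcaps:::subset_table(standardize(tabp), sp$test)
  auc <- roc_auc(tep$y_raw, predict(fitp, tep))$auc
  expect_gte(auc, 0.3); expect_lte(auc, 0.7)
  # single-class data refuse to train
  tab1 <- tab; tab1$y <- rep(1, length(tab$y))
  expect_error(capsnet(g, tab1, caps_config(epochs = 1)), "both classes")
})

test_that("training is reproducible for a fixed seed", {
  tab <- toy_separable_table(60, seed = 2)
  g <- toy_graph()
  f1 <- capsnet(g, tab, caps_config(epochs = 4, seed = 7))
  f2 <- capsnet(g, tab, caps_config(epochs = 4, seed = 7))
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$params, f2$params)
})

test_that("capsnet fits round-trip through JSON serialization", {
  tab <- toy_separable_table(60, seed = 3)
  g <- toy_graph()
  fit <- capsnet(g, tab, caps_config(epochs = 3, seed = 3))
  path <- tempfile(fileext = ".json")
  write_capsnet(fit, path)
  back <- read_capsnet(path)
  expect_equal(back$params, fit$params, tolerance = 1e-14)
  expect_equal(predict(back, tab), predict(fit, tab), tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(caps_config(K = 0), "positive integer")
  expect_error(caps_config(r = 0), "positive integer")
  expect_error(caps_config(d_node = 7, K = 4), "multiple of K")
  expect_error(caps_config(m_plus = 0.1, m_minus = 0.9), "m_minus < m_plus")
  expect_error(caps_config(lambda_neg = 0), "lambda_neg")
})
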