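# Independent oracles used across the suite. Each is a deliberately naive
# re-implementation, kept separate from the package code paths it checks.

# Brute-force reachability: can `from` reach `to` following adjacency
# edges j -> k (encoded adjacency[k, j] = 1)? Boolean matrix powers.
oracle_reaches <- function(adjacency, from, to) {
  p <- nrow(adjacency)
  E <- t(adjacency != 0)           # E[j, k]: edge j -> k
  R <- E
  for (i in seq_len(p)) R <- (R | (R %*% E) > 0)
  isTRUE(R[from, to])
}

# O(n^2) pair-counting AUC: concordant pairs + half credit for ties.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# Elementwise confusion tally.
oracle_confusion <- function(labels, preds) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && preds[i] == 1) tp <- tp + 1L
    if (labels[i] == 0 && preds[i] == 1) fp <- fp + 1L
    if (labels[i] == 0 && preds[i] == 0) tn <- tn + 1L
    if (labels[i] == 1 && preds[i] == 0) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Straight-line execution of dynamic routing, written independently of the
# package loop: explicit per-iteration logs of b, c, s, v for J classes.
oracle_routing <- function(votes, r) {
  m <- dim(votes)[1]; J <- dim(votes)[2]; d <- dim(votes)[3]
  sq <- function(s) {
    n2 <- sum(s * s)
    if (n2 == 0) rep(0, d) else (n2 / (1 + n2)) * s / sqrt(n2)
  }
  b <- matrix(0, m, J)
  hist_c <- vector("list", r)
  v <- matrix(0, J, d)
  for (it in 1:r) {
    cmat <- matrix(0, m, J)
    for (i in 1:m) cmat[i, ] <- exp(b[i, ]) / sum(exp(b[i, ]))
    hist_c[[it]] <- cmat
    for (j in 1:J) {
      s <- rep(0, d)
      for (i in 1:m) s <- s + cmat[i, j] * votes[i, j, ]
      v[j, ] <- sq(s)
    }
    for (i in 1:m) for (j in 1:J)
      b[i, j] <- b[i, j] + sum(votes[i, j, ] * v[j, ])
  }
  list(v = v, c = hist_c[[r]], c_history = hist_c)
}

# Random DAG causal model over p variables with the label at a random
# position; returns a `lingam` object with arbitrary-support strength.
random_dag_model <- function(p) {
  perm <- sample.int(p)                   # causal order (most exogenous first)
  S <- matrix(0, p, p)
  pos <- order(perm)
  for (k in seq_len(p)) for (j in seq_len(p)) {
    if (pos[j] < pos[k] && runif(1) < 0.4)
      S[k, j] <- runif(1, -1, 1)
  }
  tau <- 0.1
  A <- (abs(S) > tau) * 1
  causal_model(perm, S, A, tau, label_index = sample.int(p, 1),
               var_names = paste0("x", seq_len(p)))
}

# Small clinical table fixture written to a temp CSV.
write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Quick hub10-style table for classifier tests.
toy_separable_table <- function(n = 200, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * 2, -sqrt(3), sqrt(3)), n, 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- as.numeric(X[, 1] > 0)
  clinical_table(X, y)
}

# Hand-built two-node causal graph with an f1 -> f2 edge.
toy_graph <- function() {
  structure(list(
    nodes = c("f1", "f2"),
    edges = data.frame(from = "f1", to = "f2", weight = 0.8,
                       stringsAsFactors = FALSE),
    label_parents = "f2",
    class_name = "disease",
    adjacency = matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE,
                       dimnames = list(c("f1", "f2"), c("f1", "f2")))
  ), class = "causal_graph")
}

# Edgeless variant: both features are direct label parents, so each node
# keeps its own value through propagation (self-loops only).
toy_graph_free <- function() {
  g <- toy_graph()
  g$edges <- g$edges[0, ]
  g$adjacency[] <- 0
  g$label_parents <- c("f1", "f2")
  g
}

# Single-node graph: the one case where a node-symmetric architecture can
# target an individual feature, used for separability checks.
toy_graph_single <- function() {
  structure(list(
    nodes = "f1",
    edges = data.frame(from = character(0), to = character(0),
                       weight = numeric(0)),
    label_parents = "f1",
    class_name = "disease",
    adjacency = matrix(0, 1, 1, dimnames = list("f1", "f1"))
  ), class = "causal_graph")
}
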