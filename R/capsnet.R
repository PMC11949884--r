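#' Capsule-network hyperparameters
#'
#' Canonical capsule-network defaults: `K` disentangle channels feeding
#' node capsules of dimension `d_node` (so each channel carries
#' `d_node / K` units), class capsules of dimension `d_class`, `r` dynamic
#' routing iterations, and the standard margin-loss constants.
#'
#' @param K number of disentangle channels (>= 1; must divide `d_node`).
#' @param d_node node-capsule dimension.
#' @param d_class class-capsule dimension.
#' @param r routing iterations (>= 1).
#' @param m_plus,m_minus,lambda_neg margin-loss constants
#'   (`0 < m_minus < m_plus <= 1`, `lambda_neg` in (0, 1]).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed integer seed for initialization and batch shuffling.
#' @return An object of class `caps_config`.
#' @export
caps_config <- function(K = 4L, d_node = 8L, d_class = 16L, r = 3L,
                        m_plus = 0.9, m_minus = 0.1, lambda_neg = 0.5,
                        epochs = 40L, batch_size = 32L,
                        learning_rate = 0.002, seed = 1L) {
  if (!is_count(K) || K < 1) stopf("K must be a positive integer")
  if (!is_count(r) || r < 1) stopf("r must be a positive integer")
  if (!is_count(d_node) || d_node %% K != 0)
    stopf("d_node must be a positive multiple of K")
  if (!is_count(d_class) || d_class < 1) stopf("d_class must be positive")
  if (!(m_minus > 0 && m_minus < m_plus && m_plus <= 1))
    stopf("need 0 < m_minus < m_plus <= 1")
  if (!(lambda_neg > 0 && lambda_neg <= 1))
    stopf("lambda_neg must lie in (0, 1]")
  if (!is_count(epochs) || epochs < 1) stopf("epochs must be >= 1")
  if (!is_count(batch_size) || batch_size < 1) stopf("batch_size must be >= 1")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stopf("learning_rate must be positive")
  structure(list(K = as.integer(K), d_node = as.integer(d_node),
                 d_class = as.integer(d_class), r = as.integer(r),
                 m_plus = m_plus, m_minus = m_minus, lambda_neg = lambda_neg,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "caps_config")
}

#' The capsule squash nonlinearity
#'
#' `v = (|s|^2 / (1 + |s|^2)) * s / |s|`: direction preserved, norm mapped
#' into `[0, 1)`; `squash(0) = 0` by continuity.
#'
#' @param s numeric vector.
#' @return Squashed vector of the same length.
#' @export
squash <- function(s) {
  a2 <- sum(s^2)
  if (a2 == 0) return(s * 0)
  (a2 / (1 + a2)) * s / sqrt(a2)
}

# Row-wise squash for a matrix of capsule pre-activations.
squash_rows <- function(S) {
  a2 <- rowSums(S^2)
  coef <- ifelse(a2 == 0, 0, sqrt(a2) / (1 + a2))
  S * coef
}

# Row-wise backward pass of squash: given S and upstream dV, return dS.
squash_rows_backward <- function(S, dV) {
  a2 <- rowSums(S^2)
  a <- sqrt(a2)
  g <- ifelse(a2 == 0, 0, a / (1 + a2))
  gp_over_a <- ifelse(a2 == 0, 0, ((1 - a2) / (1 + a2)^2) / a)
  sdot <- rowSums(S * dV)
  dV * g + S * (gp_over_a * sdot)
}

#' Dynamic routing between capsule layers
#'
#' The agreement loop of capsule networks: routing logits start at zero;
#' each iteration computes coupling coefficients by a per-input softmax,
#' forms each class capsule as the coupling-weighted sum of votes, squashes
#' it, and reinforces the logits by the dot product between each vote and
#' the resulting class capsule.
#'
#' @param votes numeric array of dimension (n_inputs, n_classes, d): the
#'   prediction (vote) vector of every input capsule for every class.
#' @param r number of routing iterations (>= 1).
#' @return List with `v` (n_classes x d matrix of class capsules) and
#'   `c` (n_inputs x n_classes coupling coefficients, rows summing to 1).
#' @export
dynamic_routing <- function(votes, r = 3L) {
  stopifnot(is.array(votes), length(dim(votes)) == 3L)
  if (!is_count(r) || r < 1) stopf("r must be a positive integer")
  m <- dim(votes)[1L]; J <- dim(votes)[2L]; d <- dim(votes)[3L]
  if (m < 1L) stopf("need at least one input capsule")
  b <- matrix(0, m, J)
  v <- matrix(0, J, d)
  cmat <- matrix(1 / J, m, J)
  for (t in seq_len(r)) {
    e <- exp(b - apply(b, 1L, max))
    cmat <- e / rowSums(e)
    for (j in seq_len(J)) {
      s_j <- colSums(matrix(votes[, j, ], m, d) * cmat[, j])
      v[j, ] <- squash(s_j)
    }
    for (j in seq_len(J))
      b[, j] <- b[, j] + matrix(votes[, j, ], m, d) %*% v[j, ]
  }
  list(v = v, c = cmat)
}

#' Margin loss on class-capsule norms
#'
#' `L = sum_j T_j max(0, m_plus - |v_j|)^2 +
#'  lambda_neg (1 - T_j) max(0, |v_j| - m_minus)^2`
#' with `T_j = 1` for the true class. The positive hinge pushes the true
#' class capsule's norm above `m_plus`; the (down-weighted) negative hinge
#' pushes the other below `m_minus`.
#'
#' @param class_norms length-2 vector of capsule norms, ordered
#'   (healthy, diseased).
#' @param label 0 (healthy) or 1 (diseased).
#' @param config a [caps_config()].
#' @return Non-negative scalar loss.
#' @export
margin_loss <- function(class_norms, label, config = caps_config()) {
  stopifnot(length(class_norms) == 2L, label %in% c(0, 1))
  Tj <- if (label == 1) c(0, 1) else c(1, 0)
  sum(Tj * pmax(0, config$m_plus - class_norms)^2 +
      config$lambda_neg * (1 - Tj) * pmax(0, class_norms - config$m_minus)^2)
}

#' Per-patient node attributes on the causal graph
#'
#' Every retained feature node carries the patient's standardized value for
#' that feature plus structural attributes of the population-level graph:
#' in-degree, out-degree, and whether the node is a direct parent of the
#' disease label.
#'
#' @param graph a `causal_graph`.
#' @param sample named numeric vector holding (at least) the standardized
#'   values of every retained feature.
#' @return Matrix (n_nodes x 4) with columns value, in_degree, out_degree,
#'   is_label_parent.
#' @export
node_attributes <- function(graph, sample) {
  stopifnot(inherits(graph, "causal_graph"))
  miss <- setdiff(graph$nodes, names(sample))
  if (length(miss) > 0)
    stopf("data error: sample is missing retained feature(s): %s",
          paste(miss, collapse = ", "))
  cbind(value = as.numeric(sample[graph$nodes]),
        in_degree = rowSums(graph$adjacency),
        out_degree = colSums(graph$adjacency),
        is_label_parent = as.numeric(graph$nodes %in% graph$label_parents))
}

#' Disentangling representation layer
#'
#' Applies `K` parallel linear maps to every node's attribute vector,
#' extracting `K` heterogeneous-factor channels per node.
#'
#' @param attrs node attribute matrix (n_nodes x q).
#' @param params a parameter list with element `D`: list of K matrices
#'   (d_k x q), e.g. the `params` element of a fitted [capsnet()].
#' @return List of K matrices (n_nodes x d_k).
#' @export
disentangle <- function(attrs, params) {
  lapply(params$D, function(Dk) {
    if (ncol(Dk) != ncol(attrs))
      stopf("disentangle transform expects %d attribute(s), got %d",
            ncol(Dk), ncol(attrs))
    attrs %*% t(Dk)
  })
}

# Symmetric-normalized adjacency with self-loops:
# Ahat = Dtilde^(-1/2) (A + A^T + I) Dtilde^(-1/2), on the binary skeleton.
normalized_adjacency <- function(adjacency) {
  A <- (adjacency != 0) * 1
  S <- ((A + t(A)) != 0) * 1
  diag(S) <- 1
  dinv <- 1 / sqrt(rowSums(S))
  S * outer(dinv, dinv)
}

#' Graph-convolution step producing node capsules
#'
#' One symmetric-normalized neighborhood-averaging step per channel
#' (self-loops added, adjacency symmetrized), followed by the channel's
#' linear map and elementwise tanh; the channels are concatenated into a
#' `d_node`-dimensional capsule per node.
#'
#' @param channels list of K matrices (n_nodes x d_k), from [disentangle()].
#' @param adjacency binary directed adjacency over the retained nodes.
#' @param params parameter list with element `P`: list of K (d_k x d_k)
#'   propagation maps.
#' @return Matrix (n_nodes x d_node) of node capsules.
#' @export
propagate <- function(channels, adjacency, params) {
  Ahat <- normalized_adjacency(adjacency)
  out <- mapply(function(Hk, Pk) tanh((Ahat %*% Hk) %*% t(Pk)),
                channels, params$P, SIMPLIFY = FALSE)
  do.call(cbind, out)
}

# ---- internal batched forward / backward --------------------------------

# Reshape helper: multiply each sample's (m x d) block by Ahat.
block_prop <- function(M, Ahat, m, nb, d) {
  dim(M) <- c(m, nb * d)
  R <- Ahat %*% M
  dim(R) <- c(m * nb, d)
  R
}

# Forward pass for a batch. V: nb x m matrix of node values (samples in
# rows). Returns everything the backward pass needs.
caps_forward <- function(pars, geom, V, r) {
  nb <- nrow(V); m <- geom$m
  K <- length(pars$D)
  attrs_big <- cbind(as.vector(t(V)), geom$Cattr[rep(seq_len(m), nb), , drop = FALSE])
  H <- G <- Y <- Z <- vector("list", K)
  for (k in seq_len(K)) {
    H[[k]] <- attrs_big %*% t(pars$D[[k]])
    G[[k]] <- block_prop(H[[k]], geom$Ahat, m, nb, ncol(H[[k]]))
    Y[[k]] <- G[[k]] %*% t(pars$P[[k]])
    Z[[k]] <- tanh(Y[[k]])
  }
  U <- do.call(cbind, Z)                     # (nb*m) x d_node
  Uhat <- lapply(pars$W, function(Wj) U %*% t(Wj))   # per class, (nb*m) x d_class
  idx <- rep(seq_len(nb), each = m)
  b <- matrix(0, nb * m, 2L)
  v <- s <- vector("list", 2L)
  cmat <- matrix(0.5, nb * m, 2L)
  for (t in seq_len(r)) {
    e <- exp(b - pmax(b[, 1L], b[, 2L]))
    cmat <- e / (e[, 1L] + e[, 2L])
    for (j in 1:2) {
      s[[j]] <- rowsum(Uhat[[j]] * cmat[, j], idx)   # nb x d_class
      v[[j]] <- squash_rows(s[[j]])
    }
    if (t < r)
      for (j in 1:2)
        b[, j] <- b[, j] + rowSums(Uhat[[j]] * v[[j]][idx, , drop = FALSE])
  }
  norms <- cbind(sqrt(rowSums(v[[1L]]^2)), sqrt(rowSums(v[[2L]]^2)))
  list(attrs_big = attrs_big, H = H, G = G, Y = Y, Z = Z, U = U,
       Uhat = Uhat, idx = idx, cmat = cmat, s = s, v = v, norms = norms,
       nb = nb)
}

# Mean margin loss and parameter gradients for a batch; couplings are
# treated as constants in the backward pass.
caps_backward <- function(pars, geom, fw, y, cfg) {
  nb <- fw$nb; m <- geom$m
  Tmat <- cbind(1 - y, y)                       # nb x 2 one-hot
  pos <- pmax(0, cfg$m_plus - fw$norms)
  neg <- pmax(0, fw$norms - cfg$m_minus)
  loss <- mean(rowSums(Tmat * pos^2 + cfg$lambda_neg * (1 - Tmat) * neg^2))
  dnorm <- (Tmat * (-2 * pos) + cfg$lambda_neg * (1 - Tmat) * 2 * neg) / nb
  K <- length(pars$D)
  gD <- lapply(pars$D, function(x) x * 0)
  gP <- lapply(pars$P, function(x) x * 0)
  gW <- lapply(pars$W, function(x) x * 0)
  dU <- matrix(0, nrow(fw$U), ncol(fw$U))
  for (j in 1:2) {
    nj <- fw$norms[, j]
    dvj <- fw$v[[j]] * ifelse(nj == 0, 0, dnorm[, j] / nj)
    dsj <- squash_rows_backward(fw$s[[j]], dvj)
    dUhat <- fw$cmat[, j] * dsj[fw$idx, , drop = FALSE]
    gW[[j]] <- t(dUhat) %*% fw$U
    dU <- dU + dUhat %*% pars$W[[j]]
  }
  off <- 0L
  for (k in seq_len(K)) {
    dk <- ncol(fw$Z[[k]])
    dZ <- dU[, off + seq_len(dk), drop = FALSE]
    off <- off + dk
    dY <- dZ * (1 - fw$Z[[k]]^2)
    gP[[k]] <- t(dY) %*% fw$G[[k]]
    dG <- dY %*% pars$P[[k]]
    dH <- block_prop(dG, geom$Ahat, m, nb, dk)   # Ahat is symmetric
    gD[[k]] <- t(dH) %*% fw$attrs_big
  }
  strip <- function(l) lapply(l, function(M) { dimnames(M) <- NULL; M })
  list(loss = loss, gD = strip(gD), gP = strip(gP), gW = strip(gW))
}

adam_step <- function(state, par, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

init_params <- function(cfg, q = 4L) {
  dk <- cfg$d_node %/% cfg$K
  glorot <- function(nr, nc) matrix(stats::rnorm(nr * nc,
                                                 sd = sqrt(2 / (nr + nc))),
                                    nr, nc)
  list(D = replicate(cfg$K, glorot(dk, q), simplify = FALSE),
       P = replicate(cfg$K, glorot(dk, dk), simplify = FALSE),
       W = replicate(2L, glorot(cfg$d_class, cfg$d_node), simplify = FALSE))
}

caps_geometry <- function(graph) {
  list(m = length(graph$nodes),
       Ahat = normalized_adjacency(graph$adjacency),
       Cattr = cbind(in_degree = rowSums(graph$adjacency),
                     out_degree = colSums(graph$adjacency),
                     is_label_parent = as.numeric(graph$nodes %in%
                                                    graph$label_parents)))
}

# Node-value matrix (samples x retained nodes) from a standardized table.
caps_values <- function(graph, table) {
  if (!isTRUE(table$standardized)) table <- standardize(table)
  miss <- setdiff(graph$nodes, colnames(table$X))
  if (length(miss) > 0)
    stopf("data error: table is missing retained feature(s): %s",
          paste(miss, collapse = ", "))
  list(V = table$X[, graph$nodes, drop = FALSE],
       y = table$y_raw %||% table$y)
}

#' Fit the graph capsule-network classifier
#'
#' Trains the capsule network on per-patient instances of the (shared,
#' population-level) causal graph: each patient contributes the same graph
#' topology with their own standardized feature values as node attributes.
#' The forward pass runs the disentangling layer, one graph-convolution
#' step into node capsules, per-class votes, and dynamic routing into two
#' class capsules (healthy / diseased); training minimizes the mean margin
#' loss on the class-capsule norms with Adam. Gradients flow through votes
#' and the squashed class capsules; the routing couplings act as
#' (per-forward-pass) attention constants in the backward pass.
#'
#' @param graph a `causal_graph` from [lingam()] / [build_causal_graph()].
#' @param table a [clinical_table()] containing every retained feature and
#'   both label classes; standardized internally if needed.
#' @param config a [caps_config()].
#' @return An object of class `capsnet`: list with `params` (`D`, `P`, `W`
#'   tensors), `config`, `graph`, `loss_trace` (mean margin loss per
#'   epoch), and bookkeeping fields.
#' @export
capsnet <- function(graph, table, config = caps_config()) {
  stopifnot(inherits(graph, "causal_graph"), inherits(config, "caps_config"))
  dat <- caps_values(graph, table)
  y <- dat$y
  if (length(unique(y)) < 2L)
    stopf("training error: both classes must be present")
  geom <- caps_geometry(graph)
  n <- nrow(dat$V)
  with_seed(config$seed, {
    pars <- init_params(config)
    flat <- c(pars$D, pars$P, pars$W)
    states <- lapply(flat, function(x) list(m = x * 0, v = x * 0))
    trace <- numeric(config$epochs)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nbatch <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, n)]
        fw <- caps_forward(pars, geom, dat$V[bi, , drop = FALSE], config$r)
        bw <- caps_backward(pars, geom, fw, y[bi], config)
        step <- step + 1L
        grads <- c(bw$gD, bw$gP, bw$gW)
        for (i in seq_along(flat)) {
          upd <- adam_step(states[[i]], flat[[i]], grads[[i]],
                           config$learning_rate, step)
          flat[[i]] <- upd$par
          states[[i]] <- upd$state
        }
        ep_loss <- ep_loss + bw$loss
        nbatch <- nbatch + 1L
      }
      K <- config$K
      pars <- list(D = flat[seq_len(K)],
                   P = flat[K + seq_len(K)],
                   W = flat[2L * K + 1:2])
      trace[ep] <- ep_loss / nbatch
      if (!all(is.finite(trace[ep])))
        stopf("training diverged at epoch %d", ep)
    }
    cc_log("capsnet: trained %d epoch(s), final mean margin loss %.4f",
           config$epochs, trace[config$epochs])
    structure(list(params = pars, config = config, graph = graph,
                   geom = geom, loss_trace = trace,
                   label_name = table$label_name, n_train = n),
              class = "capsnet")
  })
}

#' Predicted disease probability for one patient
#'
#' Runs the trained capsule network on a single patient's standardized
#' feature values and returns
#' `|v_diseased| / (|v_diseased| + |v_healthy|)`; if both class-capsule
#' norms are zero, returns 0.5 with a warning.
#'
#' @param params a fitted [capsnet()] object (it carries its own graph),
#'   or a bare parameter list if `graph` is supplied.
#' @param graph the `causal_graph` (taken from `params` when omitted).
#' @param sample named numeric vector of standardized feature values.
#' @return Probability in (0, 1).
#' @export
predict_proba <- function(params, graph = NULL, sample) {
  if (inherits(params, "capsnet")) {
    graph <- graph %||% params$graph
    pars <- params$params
    r <- params$config$r
  } else {
    if (is.null(graph)) stopf("graph required with bare parameter lists")
    pars <- params
    r <- 3L
  }
  attrs <- node_attributes(graph, sample)
  chans <- disentangle(attrs, pars)
  U <- propagate(chans, graph$adjacency, pars)
  m <- nrow(U); d <- nrow(pars$W[[1L]])
  votes <- array(0, c(m, 2L, d))
  for (j in 1:2) votes[, j, ] <- U %*% t(pars$W[[j]])
  rt <- dynamic_routing(votes, r)
  nh <- sqrt(sum(rt$v[1L, ]^2)); nd <- sqrt(sum(rt$v[2L, ]^2))
  if (nh + nd == 0) {
    warning("both class-capsule norms are zero; returning 0.5", call. = FALSE)
    return(0.5)
  }
  nd / (nh + nd)
}

#' Predict disease probabilities or classes for a clinical table
#'
#' @param object a fitted [capsnet()].
#' @param newdata a [clinical_table()] containing the retained features;
#'   standardized internally if needed.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 calls.
#' @param threshold classification threshold on the probability.
#' @param ... unused.
#' @return Numeric vector, one entry per sample.
#' @export
predict.capsnet <- function(object, newdata, type = c("prob", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  dat <- caps_values(object$graph, newdata)
  fw <- caps_forward(object$params, object$geom, dat$V, object$config$r)
  tot <- fw$norms[, 1L] + fw$norms[, 2L]
  pr <- ifelse(tot == 0, 0.5, fw$norms[, 2L] / tot)
  if (any(tot == 0))
    warning("zero class-capsule norms for some samples; using 0.5",
            call. = FALSE)
  if (type == "class") as.numeric(pr > threshold) else pr
}

#' @export
print.capsnet <- function(x, ...) {
  cfg <- x$config
  cat("Graph capsule-network classifier\n")
  cat(sprintf("  graph: %d node(s); channels K=%d, d_node=%d, d_class=%d, r=%d\n",
              x$geom$m, cfg$K, cfg$d_node, cfg$d_class, cfg$r))
  cat(sprintf("  trained %d epoch(s) on %d sample(s); final loss %.4f\n",
              cfg$epochs, x$n_train, x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' @export
plot.capsnet <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
       xlab = "epoch", ylab = "mean margin loss",
       main = "Capsule-network training loss", ...)
  invisible(x)
}

#' @export
summary.capsnet <- function(object, ...) {
  cat("Graph capsule-network classifier\n")
  cat(sprintf("  retained nodes: %s\n", paste(object$graph$nodes, collapse = ", ")))
  cat(sprintf("  parameters: %d\n",
              sum(vapply(c(object$params$D, object$params$P, object$params$W),
                         length, integer(1)))))
  cat(sprintf("  loss: %.4f -> %.4f over %d epochs\n",
              object$loss_trace[1L],
              object$loss_trace[length(object$loss_trace)],
              length(object$loss_trace)))
  invisible(object)
}
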