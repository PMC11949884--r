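#' Least-squares residual of one feature on another
#'
#' The building block of the causal ordering: the residual of `xi`
#' regressed on `xj`,
#' `r_ij = xi - (cov(xi, xj) / var(xj)) * xj`.
#' By construction the residual has zero sample covariance with `xj`;
#' under the linear non-Gaussian model the residual is *statistically
#' independent* of `xj` exactly when `xj` is causally upstream, which is
#' what the independence score tests.
#'
#' @param xi,xj numeric vectors of equal length (>= 2), centered.
#' @return The residual vector, same length as `xi`.
#' @export
residual_vector <- function(xi, xj) {
  if (length(xi) != length(xj)) stopf("xi and xj must have equal length")
  if (length(xi) < 2L) stopf("need at least 2 observations")
  vj <- stats::var(xj)
  if (!is.finite(vj) || vj <= .Machine$double.eps)
    stopf("degenerate regressor: xj has (near-)zero variance")
  xi - (stats::cov(xi, xj) / vj) * xj
}

# Maximum-entropy approximation to the differential entropy of a
# standardized variable (Hyvarinen's negentropy expansion): the Gaussian
# entropy minus log-cosh and Gaussian-moment correction terms.
maxent_entropy <- function(u) {
  k1 <- 79.047
  k2 <- 7.4129
  gam <- 0.37457
  (1 + log(2 * pi)) / 2 -
    k1 * (mean(log(cosh(u))) - gam)^2 -
    k2 * mean(u * exp(-u^2 / 2))^2
}

#' Exogeneity (independence) score of a candidate root variable
#'
#' Scores how plausibly `x` is causally upstream of every column of
#' `others`. For each companion variable the residuals of both regression
#' directions are formed and the difference of the mutual informations
#' `MI(other, r_x_on_other) - MI(x, r_other_on_x)` is evaluated through the
#' maximum-entropy entropy approximation (the joint-entropy terms cancel
#' between the two directions because each (variable, residual) pair is a
#' unit-Jacobian linear transform of the same pair of observations). A
#' negative difference is evidence against exogeneity; the score is the
#' negated sum of squared negative parts, so it is always <= 0 and equals 0
#' for a perfectly exogenous candidate. Inputs are standardized internally,
#' making the score scale-invariant.
#'
#' @param x numeric vector, the candidate root.
#' @param others numeric matrix of the remaining variables (columns); a
#'   vector is treated as a single column. `NULL` or zero columns returns 0.
#' @return A real score; larger (closer to 0) = more plausibly exogenous.
#' @export
independence_score <- function(x, others) {
  if (is.null(others)) return(0)
  others <- as.matrix(others)
  if (ncol(others) < 1L) return(0)
  xs <- as.numeric(scale(x))
  s <- 0
  for (i in seq_len(ncol(others))) {
    oi <- as.numeric(scale(others[, i]))
    r_i_on_x <- residual_vector(oi, xs)
    r_x_on_i <- residual_vector(xs, oi)
    d <- (maxent_entropy(oi) + maxent_entropy(r_x_on_i / stats::sd(r_x_on_i))) -
         (maxent_entropy(xs) + maxent_entropy(r_i_on_x / stats::sd(r_i_on_x)))
    s <- s - min(0, d)^2
  }
  s
}

#' Estimate the causal ordering of standardized variables
#'
#' The iterative DirectLiNGAM loop: at each step every remaining variable
#' is scored as a candidate root against the other remaining variables
#' ([independence_score()]); the best-scoring variable is appended to the
#' ordering, all remaining variables are replaced by their least-squares
#' residuals on it, and the loop repeats until every variable is placed.
#' Ties break to the lowest column index, so the result is deterministic.
#'
#' @param X numeric matrix (samples x variables), ideally standardized; no
#'   zero-variance columns allowed.
#' @return Integer permutation of `1:ncol(X)`, most exogenous first.
#' @export
causal_order <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("data error: X contains non-finite values")
  p <- ncol(X)
  if (p == 0L) stopf("X has no columns")
  if (nrow(X) <= p)
    warning("fewer samples than variables: ordering will be unreliable",
            call. = FALSE)
  v <- apply(X, 2L, stats::var)
  if (any(v <= .Machine$double.eps)) stopf("zero-variance column in X")
  R <- scale(X)
  # negentropy per column; near-Gaussian data make the ordering unidentifiable
  J <- apply(R, 2L, function(u)
    79.047 * (mean(log(cosh(u))) - 0.37457)^2 +
      7.4129 * mean(u * exp(-u^2 / 2))^2)
  if (max(J) < 0.005)
    warning("columns look close to Gaussian; the causal ordering may be unidentifiable",
            call. = FALSE)
  remaining <- seq_len(p)
  ordering <- integer(0)
  while (length(remaining) > 1L) {
    scores <- vapply(seq_along(remaining), function(ii) {
      independence_score(R[, remaining[ii]],
                         R[, remaining[-ii], drop = FALSE])
    }, numeric(1))
    best <- remaining[which.max(scores)]   # which.max -> lowest index on ties
    ordering <- c(ordering, best)
    remaining <- setdiff(remaining, best)
    for (j in remaining)
      R[, j] <- residual_vector(R[, j], R[, best])
    R[, remaining] <- scale(R[, remaining, drop = FALSE])
  }
  c(ordering, remaining)
}

#' Causal-strength matrix by covariance regression
#'
#' Given an ordering, each variable is regressed by ordinary least squares
#' on all of its predecessors, solved through the covariance matrix
#' (normal equations). Row `k` holds the coefficients of variable `k` on
#' its predecessors; entries for non-predecessors are exactly zero.
#'
#' @param X numeric matrix (samples x variables), standardized.
#' @param ordering permutation of `1:ncol(X)` (most exogenous first).
#' @return p x p matrix of regression coefficients.
#' @export
strength_matrix <- function(X, ordering) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (!identical(sort(as.integer(ordering)), seq_len(p)))
    stopf("ordering must be a permutation of 1:%d", p)
  S <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  if (p < 2L) return(S)
  C <- stats::cov(X)
  for (t in 2:p) {
    k <- ordering[t]
    pred <- ordering[seq_len(t - 1L)]
    Cpp <- C[pred, pred, drop = FALSE]
    beta <- tryCatch(solve(Cpp, C[pred, k]),
      error = function(e) {
        warning("singular predecessor covariance: ridge fallback (1e-6)",
                call. = FALSE)
        solve(Cpp + diag(1e-6, length(pred)), C[pred, k])
      })
    S[k, pred] <- beta
  }
  S
}

#' Threshold a strength matrix into a directed adjacency matrix
#'
#' `adjacency[k, j] = 1` iff `|strength[k, j]| > tau`: an edge `j -> k` is
#' kept when the estimated direct effect exceeds the threshold in absolute
#' value.
#'
#' @param strength p x p coefficient matrix.
#' @param tau non-negative threshold on standardized coefficients.
#' @return Binary p x p matrix.
#' @export
threshold_edges <- function(strength, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stopf("tau must be a single non-negative number")
  adj <- (abs(strength) > tau) * 1
  dimnames(adj) <- dimnames(strength)
  adj
}

#' Fit the causal-discovery stage to a clinical table
#'
#' The full medical-causal-inference pipeline: standardize features and
#' label, estimate the causal ordering over all variables (the disease
#' label is treated as one more observed variable), estimate the
#' causal-strength matrix, threshold it into a directed graph, and prune
#' every feature without a directed causal path into the disease label.
#'
#' @param table a [clinical_table()]; standardized internally if needed.
#' @param tau edge threshold on standardized coefficients (default 0.05).
#' @param label_as_sink anchor the disease label as the most downstream
#'   variable (default). The method asks which clinical features are
#'   causally upstream of the disease, and a binary outcome violates the
#'   linear-SEM assumptions badly enough that letting it compete for
#'   upstream positions is unstable: the Bernoulli label tends to look
#'   maximally non-Gaussian and capture the root, inverting every label
#'   edge. With `FALSE` the label competes like any other variable.
#' @return An object of class `lingam`: a list with `ordering` (indices,
#'   most exogenous first), `var_names`, `strength`, `adjacency`,
#'   `threshold`, `label_index`, and `graph` (a `causal_graph`).
#' @seealso [build_causal_graph()], [capsnet()]
#' @export
lingam <- function(table, tau = 0.05, label_as_sink = TRUE) {
  stopifnot(inherits(table, "clinical_table"))
  if (!isTRUE(table$standardized)) table <- standardize(table)
  Z <- cbind(table$X, table$y)
  colnames(Z) <- c(table$feature_names, table$label_name)
  ordering <- if (label_as_sink)
    c(causal_order(Z[, -ncol(Z), drop = FALSE]), ncol(Z))
  else causal_order(Z)
  S <- strength_matrix(Z, ordering)
  A <- threshold_edges(S, tau)
  model <- causal_model(ordering, S, A, tau, label_index = ncol(Z),
                        var_names = colnames(Z))
  graph <- build_causal_graph(model, table$feature_names)
  cc_log("lingam: ordering [%s]; %d edge(s) kept at tau=%.3g; %d node(s) retained",
         paste(colnames(Z)[ordering], collapse = " "), sum(A), tau,
         length(graph$nodes))
  model$graph <- graph
  model$table_label <- table$label_name
  model
}

#' @rdname lingam
#' @export
fit_causal <- lingam

#' Construct a causal model object
#'
#' @param ordering permutation of variable indices, most exogenous first.
#' @param strength p x p coefficient matrix (supported only on predecessor
#'   pairs under `ordering`).
#' @param adjacency binary matrix from [threshold_edges()].
#' @param threshold the tau used.
#' @param label_index column index of the disease label variable.
#' @param var_names variable names (length p).
#' @return An object of class `lingam`.
#' @export
causal_model <- function(ordering, strength, adjacency, threshold,
                         label_index, var_names = NULL) {
  p <- nrow(strength)
  ordering <- as.integer(ordering)
  if (!identical(sort(ordering), seq_len(p)))
    stopf("ordering must be a permutation of 1:%d", p)
  if (!identical(dim(adjacency), dim(strength)))
    stopf("adjacency and strength dimensions differ")
  if (!is_count(label_index) || label_index < 1 || label_index > p)
    stopf("label_index out of range")
  pos <- order(ordering)  # pos[k] = position of variable k in the ordering
  bad <- which(strength != 0 & outer(pos, pos, `<=`), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("strength has nonzero entries outside predecessor pairs")
  structure(list(
    ordering = ordering, strength = strength, adjacency = adjacency,
    threshold = threshold, label_index = as.integer(label_index),
    var_names = var_names %||% paste0("v", seq_len(p))
  ), class = "lingam")
}

#' @export
print.lingam <- function(x, ...) {
  cat("Causal model (DirectLiNGAM)\n")
  cat(sprintf("  variables: %d (label: %s)\n", length(x$ordering),
              x$var_names[x$label_index]))
  cat(sprintf("  ordering:  %s\n",
              paste(x$var_names[x$ordering], collapse = " -> ")))
  cat(sprintf("  edges:     %d at threshold %.3g\n",
              sum(x$adjacency), x$threshold))
  if (!is.null(x$graph))
    cat(sprintf("  retained causal graph: %d node(s), label parents: %s\n",
                length(x$graph$nodes),
                paste(x$graph$label_parents, collapse = ", ")))
  invisible(x)
}

#' @export
coef.lingam <- function(object, ...) object$strength

#' @export
summary.lingam <- function(object, ...) {
  A <- object$adjacency
  edges <- which(A == 1, arr.ind = TRUE)
  ed <- data.frame(
    from = object$var_names[edges[, 2L]],
    to = object$var_names[edges[, 1L]],
    strength = object$strength[edges],
    stringsAsFactors = FALSE)
  ed <- ed[order(-abs(ed$strength)), , drop = FALSE]
  rownames(ed) <- NULL
  out <- list(ordering = object$var_names[object$ordering],
              edges = ed, threshold = object$threshold,
              graph = object$graph)
  class(out) <- "summary.lingam"
  out
}

#' @export
print.summary.lingam <- function(x, ...) {
  cat("Causal ordering:", paste(x$ordering, collapse = " -> "), "\n")
  cat(sprintf("Edges (|strength| > %.3g):\n", x$threshold))
  print(x$edges, digits = 3)
  invisible(x)
}

#' @export
plot.lingam <- function(x, ...) {
  if (is.null(x$graph)) stopf("model carries no causal graph")
  plot(x$graph, ...)
}
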