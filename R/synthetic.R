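#' Specify a linear non-Gaussian structural equation model
#'
#' A `sem_spec` is the ground truth behind a synthetic clinical table:
#' features follow a linear acyclic SEM `x = B x + e` with non-Gaussian
#' noise (the regime in which LiNGAM causal discovery is identifiable), and
#' a binary disease label is drawn from a logistic model on the features.
#' Variables are stored in the true causal order, so `B` must be strictly
#' lower triangular.
#'
#' @param B p x p coefficient matrix, strictly lower triangular; `B[k, j]`
#'   is the direct effect of feature j on feature k.
#' @param label_weights length-p vector of logistic coefficients of the
#'   disease label on the features; zero for causally irrelevant features.
#'   At least one entry must be nonzero.
#' @param noise_family `"uniform"` (bounded, platykurtic) or `"laplace"`
#'   (heavy-tailed); both clearly non-Gaussian as LiNGAM identifiability
#'   requires.
#' @param noise_scale per-variable noise standard deviation (recycled).
#' @param label_intercept logistic intercept; `NA` (default) means
#'   auto-calibrate so realized prevalence matches `target_prevalence`.
#' @param target_prevalence desired disease prevalence in (0, 1).
#' @param name optional preset name, for printing.
#' @return An object of class `sem_spec`.
#' @seealso [preset_spec()], [generate_features()], [make_dataset()]
#' @export
sem_spec <- function(B, label_weights,
                     noise_family = c("uniform", "laplace"),
                     noise_scale = 1, label_intercept = NA_real_,
                     target_prevalence = 0.5, name = NULL) {
  noise_family <- match.arg(noise_family)
  B <- as.matrix(B)
  p <- nrow(B)
  if (ncol(B) != p) stopf("B must be square")
  if (any(B[upper.tri(B, diag = TRUE)] != 0))
    stopf("B must be strictly lower triangular (variables in true causal order)")
  label_weights <- as.numeric(label_weights)
  if (length(label_weights) != p)
    stopf("label_weights must have length %d", p)
  if (all(label_weights == 0))
    stopf("configuration error: at least one label weight must be nonzero")
  if (!is.numeric(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1)
    stopf("target_prevalence must lie in (0, 1)")
  noise_scale <- rep_len(as.numeric(noise_scale), p)
  if (any(noise_scale <= 0)) stopf("noise scales must be positive")
  n_distractors <- sum(label_weights == 0 &
                         !reaches_label(B, label_weights))
  structure(list(
    p = p, B = B, order = seq_len(p),
    noise_family = noise_family, noise_scale = noise_scale,
    label_weights = label_weights, label_intercept = label_intercept,
    target_prevalence = target_prevalence,
    n_distractors = n_distractors, name = name
  ), class = "sem_spec")
}

# Which features have a directed path into the label (ancestors of the
# label through B edges ending at a nonzero-weight feature)?
reaches_label <- function(B, label_weights) {
  p <- length(label_weights)
  reach <- label_weights != 0
  repeat {
    # j reaches the label if some k with B[k, j] != 0 already does
    new <- reach | apply(B != 0 & matrix(reach, p, p), 2L, any)
    if (identical(new, reach)) break
    reach <- new
  }
  reach
}

#' Built-in generator presets
#'
#' Three canned ground truths used throughout the test battery:
#' \describe{
#'   \item{chain5}{5 features in a causal chain `x1 -> x2 -> ... -> x5`,
#'     every edge coefficient 0.8, uniform noise; the label depends on the
#'     chain's sink `x5`.}
#'   \item{hub10}{10 mutually independent features; 3 are parents of the
#'     label (strong weights), the other 7 are pure distractors.}
#'   \item{clinic37}{37 features emulating a blood-routine plus
#'     blood-biochemistry panel: 8 label parents, two downstream tiers of
#'     correlated markers, uniform noise, 30% prevalence.}
#' }
#'
#' @param name one of `"chain5"`, `"hub10"`, `"clinic37"`.
#' @return A [sem_spec()].
#' @export
preset_spec <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    stopf("configuration error: preset name must be a single string")
  switch(name,
    chain5 = {
      B <- matrix(0, 5, 5)
      for (k in 2:5) B[k, k - 1L] <- 0.8
      sem_spec(B, label_weights = c(0, 0, 0, 0, 1.5),
               noise_family = "uniform", target_prevalence = 0.5,
               name = "chain5")
    },
    hub10 = {
      sem_spec(matrix(0, 10, 10),
               label_weights = c(2, 2, 2, rep(0, 7)),
               noise_family = "uniform", target_prevalence = 0.5,
               name = "hub10")
    },
    clinic37 = {
      B <- matrix(0, 37, 37)
      for (k in 1:8)  B[k + 8L, k] <- 0.5   # first downstream marker tier
      for (k in 1:8)  B[k + 16L, k + 8L] <- 0.4  # second tier
      sem_spec(B, label_weights = c(rep(1.2, 8), rep(0, 29)),
               noise_family = "uniform", target_prevalence = 0.3,
               name = "clinic37")
    },
    stopf("configuration error: unknown preset %s (choose chain5, hub10, clinic37)",
          sQuote(name))
  )
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf("SEM spec%s: p = %d, %d feature edge(s), %d label parent(s), %d distractor(s)\n",
              if (is.null(x$name)) "" else sprintf(" %s", sQuote(x$name)),
              x$p, sum(x$B != 0), sum(x$label_weights != 0), x$n_distractors))
  cat(sprintf("  noise: %s (sd %s), target prevalence %.2f\n",
              x$noise_family,
              paste(unique(signif(x$noise_scale, 3)), collapse = "/"),
              x$target_prevalence))
  invisible(x)
}

# Unit-variance non-Gaussian noise draws, scaled per variable.
draw_noise <- function(n, spec) {
  p <- spec$p
  E <- switch(spec$noise_family,
    uniform = matrix(stats::runif(n * p, -sqrt(3), sqrt(3)), n, p),
    laplace = {
      u <- matrix(stats::runif(n * p) - 0.5, n, p)
      # inverse-CDF Laplace with variance 1 (b = 1/sqrt(2))
      -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
    })
  sweep(E, 2L, spec$noise_scale, `*`)
}

#' Sample features from the structural equation model
#'
#' Generates `x = B x + e` in the true causal order:
#' `x_k = sum_{j<k} B[k,j] x_j + e_k`.
#'
#' @param spec a [sem_spec()].
#' @param n number of samples (>= 1).
#' @param seed integer RNG seed; identical seed gives an identical matrix.
#' @return n x p numeric matrix with columns `f1...fp`.
#' @export
generate_features <- function(spec, n, seed) {
  stopifnot(inherits(spec, "sem_spec"))
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  with_seed(seed, {
    E <- draw_noise(n, spec)
    X <- matrix(0, n, spec$p)
    for (k in seq_len(spec$p)) {
      X[, k] <- E[, k]
      if (k > 1L) {
        bk <- spec$B[k, seq_len(k - 1L)]
        if (any(bk != 0))
          X[, k] <- X[, k] + X[, seq_len(k - 1L), drop = FALSE] %*% bk
      }
    }
    colnames(X) <- paste0("f", seq_len(spec$p))
    X
  })
}

#' Draw disease labels from the logistic mechanism
#'
#' `y_i ~ Bernoulli(sigmoid(intercept + w . x_i))`. When the spec leaves
#' the intercept unset, it is calibrated by root bisection so the expected
#' prevalence on this sample equals the target (realized prevalence then
#' lies within binomial noise of it).
#'
#' @param X feature matrix with `spec$p` columns.
#' @param spec a [sem_spec()].
#' @param seed integer RNG seed.
#' @return Binary 0/1 vector with attribute `"intercept"` (value used).
#' @export
generate_labels <- function(X, spec, seed) {
  stopifnot(inherits(spec, "sem_spec"))
  X <- as.matrix(X)
  if (ncol(X) != spec$p)
    stopf("X has %d columns but spec has p = %d", ncol(X), spec$p)
  if (all(spec$label_weights == 0))
    stopf("configuration error: all-zero label weights")
  eta <- drop(X %*% spec$label_weights)
  ic <- spec$label_intercept
  if (is.na(ic)) {
    f <- function(c0) mean(sigmoid(c0 + eta)) - spec$target_prevalence
    ic <- stats::uniroot(f, c(-60, 60), tol = 1e-10)$root
  }
  y <- with_seed(seed, as.numeric(stats::runif(nrow(X)) < sigmoid(ic + eta)))
  attr(y, "intercept") <- ic
  y
}

#' Generate a complete synthetic clinical table
#'
#' Composes [generate_features()] and [generate_labels()] and attaches the
#' ground truth (`B`, true order, label weights, realized intercept) as the
#' `"truth"` attribute for test harnesses.
#'
#' @inheritParams generate_features
#' @return A [clinical_table()] with label column `"disease"`.
#' @export
make_dataset <- function(spec, n, seed) {
  X <- generate_features(spec, n, seed)
  lseed <- (as.numeric(seed) + 1) %% (.Machine$integer.max - 1)
  y <- generate_labels(X, spec, lseed)
  tab <- clinical_table(X, as.numeric(y), label_name = "disease")
  attr(tab, "truth") <- list(
    B = spec$B, order = spec$order,
    label_weights = spec$label_weights,
    label_intercept = attr(y, "intercept"),
    spec_name = spec$name
  )
  tab
}

#' Write generator ground truth as JSON
#'
#' @param truth the `"truth"` attribute of a [make_dataset()] table.
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(B = truth$B, order = truth$order,
         label_weights = truth$label_weights,
         label_intercept = truth$label_intercept,
         spec_name = truth$spec_name %||% "custom"),
    path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}
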