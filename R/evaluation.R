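#' Confusion-matrix counts
#'
#' @param labels binary 0/1 vector of true disease status.
#' @param preds binary 0/1 vector of predicted status, same length.
#' @return Named list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, preds) {
  if (length(labels) != length(preds))
    stopf("data error: labels and preds have different lengths")
  if (length(labels) < 1L) stopf("data error: empty input")
  if (!all(labels %in% c(0, 1)) || !all(preds %in% c(0, 1)))
    stopf("data error: labels and preds must be 0/1")
  list(tp = sum(labels == 1 & preds == 1),
       fp = sum(labels == 0 & preds == 1),
       tn = sum(labels == 0 & preds == 0),
       fn = sum(labels == 1 & preds == 0))
}

#' Diagnostic metrics from confusion counts
#'
#' The standard battery: accuracy, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`, F1, and the Matthews
#' correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' A zero-denominator rate is reported as `NaN` with a warning; MCC with a
#' zero denominator is 0 (the random-prediction limit). By default F1 is
#' the harmonic mean of PPV and sensitivity; `f1_variant = "balanced"`
#' gives the harmonic mean of sensitivity and specificity instead.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (see [confusion()]).
#' @param f1_variant `"standard"` or `"balanced"`.
#' @return Named list of the seven metrics.
#' @export
diagnostic_metrics <- function(counts, f1_variant = c("standard", "balanced")) {
  f1_variant <- match.arg(f1_variant)
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  sens <- rate(tp, tp + fn, "sensitivity")
  spec <- rate(tn, tn + fp, "specificity")
  ppv <- rate(tp, tp + fp, "ppv")
  npv <- rate(tn, tn + fn, "npv")
  acc <- (tp + tn) / (tp + fp + tn + fn)
  hmean <- function(a, b) if (!is.finite(a) || !is.finite(b) || a + b == 0)
    NaN else 2 * a * b / (a + b)
  f1 <- if (f1_variant == "standard") hmean(ppv, sens) else hmean(sens, spec)
  mden <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mden == 0) 0 else (tp * tn - fp * fn) / mden
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       ppv = ppv, npv = npv, f1 = f1, mcc = mcc)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores in descending order with
#' trapezoidal integration; tied scores contribute half credit, so the AUC
#' equals the normalized Mann-Whitney U statistic exactly (the probability
#' that a random positive outscores a random negative, ties counted half).
#'
#' @param labels binary 0/1 vector with both classes present.
#' @param scores real-valued scores, higher = more diseased.
#' @return List with `roc` (data frame `fpr`, `tpr`, from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stopf("data error: labels and scores have different lengths")
  if (!all(labels %in% c(0, 1)))
    stopf("data error: labels must be 0/1")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stopf("evaluation error: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))        # tie groups of the sorted scores
  tp_g <- rowsum(as.numeric(lab == 1), grp)
  fp_g <- rowsum(as.numeric(lab == 0), grp)
  tpr <- c(0, cumsum(tp_g) / npos)
  fpr <- c(0, cumsum(fp_g) / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Assemble a full metrics report
#'
#' @param labels binary 0/1 vector.
#' @param scores real scores (higher = diseased).
#' @param threshold classification threshold on scores (default 0.5).
#' @param f1_variant passed to [diagnostic_metrics()].
#' @return Object of class `metrics_report` with confusion counts, all
#'   derived diagnostic metrics, ROC points and AUC.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5,
                           f1_variant = "standard") {
  preds <- as.numeric(scores > threshold)
  cnt <- confusion(labels, preds)
  mets <- diagnostic_metrics(cnt, f1_variant)
  ra <- roc_auc(labels, scores)
  structure(c(cnt, mets, list(roc = ra$roc, auc = ra$auc,
                              threshold = threshold)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Diagnostic metrics report\n")
  cat(sprintf("  confusion: tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  m <- c(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, ppv = x$ppv, npv = x$npv,
         f1 = x$f1, mcc = x$mcc, auc = x$auc)
  print(round(m, digits))
  invisible(x)
}

#' Deterministic train/test split
#'
#' @param n number of samples.
#' @param split fraction assigned to the training set, in (0, 1).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, split = 0.7, seed = 1L) {
  if (!is.numeric(split) || split <= 0 || split >= 1)
    stopf("split must lie in (0, 1)")
  with_seed(seed, {
    tr <- sort(sample.int(n, size = floor(split * n)))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}

# Subset a clinical table by row indices, preserving standardization state.
subset_table <- function(table, idx) {
  out <- table
  out$X <- table$X[idx, , drop = FALSE]
  out$y <- table$y[idx]
  if (!is.null(table$y_raw)) out$y_raw <- table$y_raw[idx]
  out$sample_ids <- table$sample_ids[idx]
  out
}

#' Evaluate a fitted classifier on a held-out split
#'
#' Splits the table deterministically by seed, scores the test portion
#' with the fitted model, classifies at the given threshold, and returns
#' the full metrics report (optionally written as JSON).
#'
#' @param model a fitted [capsnet()] (or any object with a `predict`
#'   method returning probabilities for a `clinical_table`).
#' @param table a [clinical_table()].
#' @param split training fraction in (0, 1); the complement is evaluated.
#' @param seed split seed.
#' @param threshold classification threshold (default 0.5).
#' @param out optional JSON path for the report.
#' @return A `metrics_report` for the test portion.
#' @export
evaluate_model <- function(model, table, split = 0.7, seed = 1L,
                           threshold = 0.5, out = NULL) {
  stopifnot(inherits(table, "clinical_table"))
  if (!isTRUE(table$standardized)) table <- standardize(table)
  sp <- train_test_split(nrow(table$X), split, seed)
  test <- subset_table(table, sp$test)
  scores <- predict(model, test)
  rep <- metrics_report(test$y_raw %||% test$y, scores, threshold)
  if (!is.null(out)) write_metrics_report(rep, out)
  rep
}
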