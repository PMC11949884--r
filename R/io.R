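#' Serialize a causal model to JSON
#'
#' Writes ordering, strength matrix, adjacency, threshold, label index and
#' variable names at full float precision; [read_causal_model()] restores
#' an identical object.
#'
#' @param model a `lingam` causal model.
#' @param path output JSON path.
#' @export
write_causal_model <- function(model, path) {
  stopifnot(inherits(model, "lingam"))
  if (!all(is.finite(model$strength)))
    stopf("model strength matrix contains non-finite values")
  jsonlite::write_json(list(
    ordering = model$ordering,
    strength = model$strength,
    adjacency = model$adjacency,
    threshold = model$threshold,
    label_index = model$label_index,
    var_names = model$var_names
  ), path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

json_field <- function(obj, field, path) {
  if (is.null(obj[[field]]))
    stopf("parse error in %s: missing field %s", path, sQuote(field))
  obj[[field]]
}

#' Read a causal model from JSON
#'
#' @param path JSON path written by [write_causal_model()].
#' @return A `lingam` causal model.
#' @export
read_causal_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopf("parse error in %s: %s",
                                            path, conditionMessage(e)))
  ordering <- as.integer(json_field(obj, "ordering", path))
  if (length(ordering) == 0L)
    stopf("parse error in %s: field %s is empty", path, sQuote("ordering"))
  S <- as.matrix(json_field(obj, "strength", path))
  A <- as.matrix(json_field(obj, "adjacency", path))
  storage.mode(S) <- "double"
  storage.mode(A) <- "double"
  vn <- as.character(json_field(obj, "var_names", path))
  if (length(ordering) != nrow(S) || !identical(dim(S), dim(A)) ||
      length(vn) != nrow(S))
    stopf("parse error in %s: field %s inconsistent with strength dimensions",
          path, sQuote("ordering/adjacency/var_names"))
  dimnames(S) <- dimnames(A) <- list(vn, vn)
  causal_model(ordering, S, A,
               threshold = as.numeric(json_field(obj, "threshold", path)),
               label_index = as.integer(json_field(obj, "label_index", path)),
               var_names = vn)
}

#' Write a diagnostic-metrics report to JSON
#'
#' @param report a `metrics_report` (see [evaluate_model()]).
#' @param path output JSON path.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(list(
    tp = report$tp, fp = report$fp, tn = report$tn, fn = report$fn,
    accuracy = report$accuracy, sensitivity = report$sensitivity,
    specificity = report$specificity, ppv = report$ppv, npv = report$npv,
    f1 = report$f1, mcc = report$mcc, auc = report$auc,
    roc = list(fpr = report$roc$fpr, tpr = report$roc$tpr)
  ), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a diagnostic-metrics report from JSON
#'
#' @param path JSON path written by [write_metrics_report()].
#' @return A `metrics_report`.
#' @export
read_metrics_report <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopf("parse error in %s: %s",
                                            path, conditionMessage(e)))
  for (f in c("tp", "fp", "tn", "fn", "accuracy", "sensitivity",
              "specificity", "ppv", "npv", "f1", "mcc", "auc"))
    json_field(obj, f, path)
  roc <- obj$roc
  structure(list(
    tp = as.integer(obj$tp), fp = as.integer(obj$fp),
    tn = as.integer(obj$tn), fn = as.integer(obj$fn),
    accuracy = as.numeric(obj$accuracy),
    sensitivity = as.numeric(obj$sensitivity),
    specificity = as.numeric(obj$specificity),
    ppv = as.numeric(obj$ppv), npv = as.numeric(obj$npv),
    f1 = as.numeric(obj$f1), mcc = as.numeric(obj$mcc),
    auc = as.numeric(obj$auc),
    roc = data.frame(fpr = as.numeric(roc$fpr), tpr = as.numeric(roc$tpr))
  ), class = "metrics_report")
}

#' Serialize a fitted capsule network to JSON
#'
#' Stores all learnable tensors, the configuration, and the causal graph
#' the model was trained on, at full float precision.
#'
#' @param fit a fitted [capsnet()].
#' @param path output JSON path.
#' @export
write_capsnet <- function(fit, path) {
  stopifnot(inherits(fit, "capsnet"))
  g <- fit$graph
  pack <- function(M) list(nrow = nrow(M), ncol = ncol(M),
                           data = as.vector(M))
  jsonlite::write_json(list(
    config = unclass(fit$config),
    params = list(D = lapply(fit$params$D, pack),
                  P = lapply(fit$params$P, pack),
                  W = lapply(fit$params$W, pack)),
    graph = list(nodes = g$nodes,
                 edges = g$edges,
                 label_parents = g$label_parents,
                 class_name = g$class_name),
    loss_trace = fit$loss_trace,
    label_name = fit$label_name,
    n_train = fit$n_train
  ), path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted capsule network from JSON
#'
#' @param path JSON path written by [write_capsnet()].
#' @return A fitted `capsnet` object.
#' @export
read_capsnet <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopf("parse error in %s: %s",
                                            path, conditionMessage(e)))
  for (f in c("config", "params", "graph")) json_field(obj, f, path)
  cfg <- do.call(caps_config, obj$config)
  gj <- obj$graph
  nodes <- as.character(gj$nodes)
  edges <- if (length(gj$edges) == 0) {
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  } else as.data.frame(gj$edges, stringsAsFactors = FALSE)
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(edges) > 0)
    adj[cbind(match(edges$to, nodes), match(edges$from, nodes))] <- 1
  graph <- structure(list(nodes = nodes, edges = edges,
                          label_parents = as.character(gj$label_parents),
                          class_name = gj$class_name,
                          adjacency = adj),
                     class = "causal_graph")
  unpack <- function(x) matrix(as.numeric(unlist(x$data)),
                               as.integer(unlist(x$nrow)),
                               as.integer(unlist(x$ncol)))
  pk <- obj$params
  n_of <- function(el) if (is.data.frame(el)) nrow(el) else length(el)
  get_el <- function(el, i) if (is.data.frame(el))
    as.list(el[i, , drop = TRUE]) else el[[i]]
  pars <- lapply(pk[c("D", "P", "W")], function(el)
    lapply(seq_len(n_of(el)), function(i) unpack(get_el(el, i))))
  names(pars) <- c("D", "P", "W")
  structure(list(params = pars, config = cfg, graph = graph,
                 geom = caps_geometry(graph),
                 loss_trace = as.numeric(obj$loss_trace),
                 label_name = obj$label_name %||% "disease",
                 n_train = obj$n_train %||% NA_integer_),
            class = "capsnet")
}
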