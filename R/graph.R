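#' Build the disease causal graph from a fitted causal model
#'
#' Keeps exactly the feature nodes that have a directed causal path into
#' the disease label (its causal ancestors under the thresholded
#' adjacency), then deletes the label node, recording its direct parents.
#' The deleted label becomes the class target of the graph; edges among
#' retained features keep their causal-strength weights.
#'
#' @param model a `lingam` causal model (see [causal_model()]).
#' @param feature_names names of the feature variables (everything but the
#'   label), in column order.
#' @return An object of class `causal_graph`: list with `nodes` (retained
#'   feature names), `edges` (data frame from/to/weight), `label_parents`,
#'   `class_name`, and `adjacency` (binary matrix over retained nodes).
#' @export
build_causal_graph <- function(model, feature_names) {
  stopifnot(inherits(model, "lingam"))
  A <- model$adjacency
  p <- nrow(A)
  li <- model$label_index
  if (li < 1 || li > p) stopf("label index out of range")
  vn <- model$var_names
  # adjacency[k, j] = 1 encodes an edge j -> k
  ig <- igraph::graph_from_adjacency_matrix(t(A != 0) * 1, mode = "directed")
  igraph::V(ig)$name <- vn
  # causal ancestors of the label: vertices with a directed path INTO it
  anc <- igraph::subcomponent(ig, li, mode = "in")
  retained <- setdiff(as.integer(anc), li)
  if (length(retained) == 0L)
    stopf("empty-graph error: no feature has a causal path to the label; lower tau")
  retained <- sort(retained)
  parents <- which(A[li, ] != 0)
  keep_names <- vn[retained]
  sub <- A[retained, retained, drop = FALSE]
  ed <- which(sub == 1, arr.ind = TRUE)
  edges <- data.frame(
    from = keep_names[ed[, 2L]],
    to = keep_names[ed[, 1L]],
    weight = model$strength[retained, retained, drop = FALSE][ed],
    stringsAsFactors = FALSE)
  structure(list(
    nodes = keep_names,
    edges = edges,
    label_parents = vn[parents],
    class_name = vn[li],
    adjacency = sub
  ), class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("Disease causal graph (class label: %s)\n", x$class_name))
  cat(sprintf("  %d node(s): %s\n", length(x$nodes),
              paste(x$nodes, collapse = ", ")))
  cat(sprintf("  %d edge(s) among features; label parents: %s\n",
              nrow(x$edges), paste(x$label_parents, collapse = ", ")))
  invisible(x)
}

#' Convert a causal graph to igraph
#'
#' @param graph a `causal_graph`.
#' @return A directed `igraph` object with `weight` edge attribute,
#'   `is_label_parent` vertex attribute, and `class_name` graph attribute.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  ig <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                      vertices = data.frame(name = graph$nodes))
  igraph::V(ig)$is_label_parent <-
    as.integer(igraph::V(ig)$name %in% graph$label_parents)
  ig <- igraph::set_graph_attr(ig, "class_name", graph$class_name)
  ig
}

#' Write a causal graph to GraphML and a CSV edge list
#'
#' @param graph a `causal_graph`.
#' @param path output GraphML path.
#' @param edge_csv optional path for a plain source,target,weight CSV.
#' @export
write_causal_graph <- function(graph, path, edge_csv = NULL) {
  ig <- as_igraph(graph)
  igraph::write_graph(ig, path, format = "graphml")
  if (!is.null(edge_csv)) {
    df <- graph$edges
    names(df) <- c("source", "target", "weight")
    utils::write.csv(df, edge_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Read a causal graph written by [write_causal_graph()]
#'
#' @param path GraphML path.
#' @return A `causal_graph`.
#' @export
read_causal_graph <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(ig)$name
  el <- igraph::as_data_frame(ig, what = "edges")
  edges <- data.frame(from = el$from %||% character(0),
                      to = el$to %||% character(0),
                      weight = el$weight %||% numeric(0),
                      stringsAsFactors = FALSE)
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(edges) > 0)
    adj[cbind(match(edges$to, nodes), match(edges$from, nodes))] <- 1
  structure(list(
    nodes = nodes, edges = edges,
    label_parents = nodes[igraph::V(ig)$is_label_parent == 1],
    class_name = igraph::graph_attr(ig, "class_name"),
    adjacency = adj
  ), class = "causal_graph")
}

#' @export
plot.causal_graph <- function(x, ...) {
  ig <- as_igraph(x)
  cols <- ifelse(igraph::V(ig)$is_label_parent == 1, "tomato", "skyblue")
  plot(ig, vertex.color = cols,
       edge.width = 1 + 2 * abs(igraph::E(ig)$weight %||% 1), ...)
  invisible(x)
}
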