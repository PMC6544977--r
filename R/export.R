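#' Export a characteristic graph
#'
#' `write_graph_dot()` and `write_graph_graphml()` serialize the graph with
#' node labels (site-state string, direction vector) and edge guards, via
#' igraph's writers. `write_graph_json()` dumps the full graph (nodes, state
#' matrix, direction vectors, edges, ordering) as JSON with metadata.
#'
#' @param graph a `characteristic_graph`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "dot")
  invisible(path)
}

#' @rdname write_graph_dot
#' @export
write_graph_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graph_dot
#' @export
write_graph_json <- function(graph, path) {
  ser <- list(
    model = graph$model$name,
    ordering = graph$ordering_id,
    seeds = graph$seeds,
    sites = colnames(graph$nodes),
    substances = colnames(graph$dirs),
    nodes = lapply(seq_len(nrow(graph$nodes)), function(i)
      list(id = i, state = as.list(unname(graph$nodes[i, ])),
           label = node_labels(graph)[i], dir = dir_labels(graph)[i])),
    edges = lapply(seq_len(nrow(graph$edges)), function(i)
      as.list(graph$edges[i, ])))
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' Behaviour signature from an exported igraph
#'
#' Recomputes the whole-graph behaviour signature from an igraph object that
#' carries the `dir` vertex attribute and `substance`/`kind` edge attributes
#' (as written by [write_graph_graphml()] and read back with
#' [igraph::read_graph()]). Round-tripping a graph through GraphML preserves
#' its signature.
#'
#' @param g an igraph object with the attributes above.
#' @return a character scalar comparable with [graph_signature()].
#' @export
signature_from_igraph <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  canonical_labelled_digraph(
    igraph::vertex_attr(g, "dir"),
    el[, 1L], el[, 2L],
    paste0(igraph::edge_attr(g, "substance"), ".", igraph::edge_attr(g, "kind")))
}

#' Write joint orderings as JSON lines and a CSV index
#'
#' One JSON object per line (rank-group lists per substance); the CSV index
#' has columns `ordering_id` and one per-substance ordering string column.
#'
#' @param orderings list of joint `threshold_ordering` objects.
#' @param jsonl_path,csv_path output file paths (`NULL` to skip one).
#' @return invisibly, the paths written.
#' @export
write_orderings <- function(orderings, jsonl_path = NULL, csv_path = NULL) {
  if (!is.null(jsonl_path)) {
    lines <- vapply(orderings, function(o)
      as.character(jsonlite::toJSON(lapply(o, function(groups)
        lapply(groups, as.list)), auto_unbox = FALSE)), "")
    writeLines(lines, jsonl_path)
  }
  if (!is.null(csv_path)) {
    subs <- names(orderings[[1]])
    tab <- data.frame(ordering_id = seq_along(orderings))
    for (p in subs) {
      if (length(orderings[[1]][[p]]) == 0L) next
      tab[[p]] <- vapply(orderings, function(o) ordering_string(o, p), "")
    }
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(c(jsonl_path, csv_path))
}

#' Write mined behaviour conditions as JSON
#'
#' @param conditions data frame from [mine_conditions()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_conditions_json <- function(conditions, path) {
  writeLines(jsonlite::toJSON(conditions, dataframe = "rows", pretty = TRUE),
             path)
  invisible(path)
}
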