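#' Build the characteristic graph of a model under a threshold ordering
#'
#' The characteristic graph is a directed graph over modes (complete
#' binding-site state assignments) whose edges are the guarded transitions
#' enabled by the threshold ordering. It safely over-approximates every
#' numeric simulation of the model whose parameters respect the ordering:
#' every run's mode sequence is a walk in the graph.
#'
#' With `seeds = "all_consistent"` the node set is every ordering-consistent
#' mode (transitions may still lead nowhere new); with an explicit list of
#' seed modes the graph is the reachable closure of the seeds.
#'
#' @param model a validated [hsm_model()].
#' @param ordering a `threshold_ordering` covering all threshold keys.
#' @param seeds `"all_consistent"` or a list of modes (named character
#'   vectors). A seed that is inconsistent under the ordering is an error
#'   naming the substance with an empty concentration interval.
#' @return An object of class `characteristic_graph` with fields `nodes`
#'   (integer mode matrix, one row per mode), `keys` (canonical mode
#'   encodings), `dirs` (direction matrix, `+1`/`-1`/`0` per substance),
#'   `edges` (data frame `from`, `to`, `substance`, `kind`, `sites`,
#'   `guard`), plus the `model` and `ordering` used.
#' @export
#' @examples
#' m <- toy_two_gene_model()
#' o <- enumerate_orderings(m, "s2")[[3]]
#' g <- characteristic_graph(m, o)
#' g
characteristic_graph <- function(model, ordering, seeds = "all_consistent") {
  ctx <- graph_ctx(model, ordering)
  nsite <- ctx$nsite

  if (nsite == 0L) {
    # no binding sites: a single mode and no transitions
    M <- matrix(integer(0), nrow = 1L, ncol = 0L)
    return(structure(list(model = model, ordering = ordering,
                          ordering_id = ordering_string(ordering),
                          nodes = M, keys = "", dirs = dir_rows(M, ctx),
                          edges = data.frame(from = integer(0), to = integer(0),
                                             substance = character(0),
                                             kind = character(0),
                                             sites = character(0),
                                             guard = character(0),
                                             stringsAsFactors = FALSE),
                          seeds = "all_consistent"),
                     class = "characteristic_graph"))
  }
  if (identical(seeds, "all_consistent")) {
    grid <- do.call(expand.grid, rev(lapply(ctx$nstates, function(k)
      seq_len(k) - 1L)))
    M <- as.matrix(grid[, rev(seq_len(nsite)), drop = FALSE])
    storage.mode(M) <- "integer"
    M <- M[consistent_rows(M, ctx), , drop = FALSE]
    keys <- apply(M, 1L, mode_key)
    lookup <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(keys)) lookup[[keys[i]]] <- i
    closed <- TRUE
  } else {
    if (!is.list(seeds)) stop("seeds must be \"all_consistent\" or a list of modes")
    states <- lapply(seeds, function(m) mode_to_int(model, m))
    for (st in states) {
      q <- inconsistent_substance(st, ctx)
      if (!is.na(q))
        stop(sprintf("seed mode is inconsistent: substance '%s' has an empty concentration interval", q))
    }
    M <- do.call(rbind, states)
    keys <- apply(M, 1L, mode_key)
    dup <- duplicated(keys)
    M <- M[!dup, , drop = FALSE]; keys <- keys[!dup]
    lookup <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(keys)) lookup[[keys[i]]] <- i
    closed <- FALSE
  }

  dimnames(M) <- list(NULL, ctx$idx$site_ids)
  acc <- vector("list", 2048L); nacc <- 0L
  i <- 1L
  Mlist <- lapply(seq_len(nrow(M)), function(r) M[r, ])
  while (i <= length(Mlist)) {
    dirs <- dir_row1(Mlist[[i]], ctx)
    evs <- events_for_state(Mlist[[i]], ctx, dirs)
    for (e in evs) {
      sites_str <- paste(e$sites, collapse = ",")
      for (tgt in e$targets) {
        k <- mode_key(tgt)
        j <- lookup[[k]]
        if (is.null(j)) {
          if (closed)
            stop("internal error: closure produced a mode outside the consistent set")
          Mlist[[length(Mlist) + 1L]] <- tgt
          j <- length(Mlist)
          lookup[[k]] <- j
        }
        nacc <- nacc + 1L
        if (nacc > length(acc)) acc <- c(acc, vector("list", length(acc)))
        acc[[nacc]] <- list(i, j, e$substance, e$kind, sites_str)
      }
    }
    i <- i + 1L
  }
  acc <- acc[seq_len(nacc)]
  from <- vapply(acc, `[[`, 0L, 1L); to <- vapply(acc, `[[`, 0L, 2L)
  esub <- vapply(acc, `[[`, "", 3L); ekind <- vapply(acc, `[[`, "", 4L)
  esites <- vapply(acc, `[[`, "", 5L)
  if (!closed) {
    M <- do.call(rbind, Mlist)
    dimnames(M) <- list(NULL, ctx$idx$site_ids)
    keys <- apply(M, 1L, mode_key)
  }
  dirs <- dir_rows(M, ctx)
  guard <- vapply(seq_along(from), function(k)
    guard_text(esub[k], ekind[k], strsplit(esites[k], ",", fixed = TRUE)[[1]]), "")
  edges <- data.frame(from = from, to = to, substance = esub, kind = ekind,
                      sites = esites, guard = guard, stringsAsFactors = FALSE)
  structure(list(model = model, ordering = ordering,
                 ordering_id = ordering_string(ordering),
                 nodes = M, keys = keys, dirs = dirs, edges = edges,
                 seeds = if (closed) "all_consistent" else "explicit"),
            class = "characteristic_graph")
}

#' @export
print.characteristic_graph <- function(x, ...) {
  cat(sprintf("Characteristic graph of '%s'\n", x$model$name))
  cat(sprintf("  ordering: %s\n", x$ordering_id))
  cat(sprintf("  %d modes, %d guarded transitions (seeds: %s)\n",
              nrow(x$nodes), nrow(x$edges), x$seeds))
  invisible(x)
}

# Human-readable node label: site states, FREE rendered "-".
node_labels <- function(graph, rows = seq_len(nrow(graph$nodes))) {
  sids <- colnames(graph$nodes)
  if (length(sids) == 0L) return(rep("", length(rows)))
  M <- graph$nodes[rows, , drop = FALSE]
  parts <- lapply(seq_along(sids), function(i) {
    lab <- sub("^BOUND:", "", sub("^FREE$", "-",
                                  site_state_labels(graph$model$sites[[i]])))
    paste0(sids[i], "=", lab[M[, i] + 1L])
  })
  do.call(paste, c(parts, sep = ","))
}

# Direction-vector label per node, e.g. "s1+,s2-"; flat rendered "0".
dir_labels <- function(graph, rows = seq_len(nrow(graph$dirs))) {
  subs <- colnames(graph$dirs)
  D <- graph$dirs[rows, , drop = FALSE]
  parts <- lapply(seq_along(subs), function(j)
    paste0(subs[j], c("-", "0", "+")[D[, j] + 2L]))
  do.call(paste, c(parts, sep = ","))
}

#' Convert a characteristic graph to an igraph object
#'
#' Nodes carry attributes `name` (canonical mode encoding), `label`
#' (site-state string) and `dir` (direction-vector string); edges carry
#' `guard`, `substance`, `kind` and `sites`.
#'
#' @param graph a `characteristic_graph`.
#' @return an [igraph::igraph] directed graph.
#' @export
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = graph$keys)
  g <- igraph::set_vertex_attr(g, "label", value = node_labels(graph))
  g <- igraph::set_vertex_attr(g, "dir", value = dir_labels(graph))
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to),
                           guard = graph$edges$guard,
                           substance = graph$edges$substance,
                           kind = graph$edges$kind,
                           sites = graph$edges$sites)
  }
  g
}
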