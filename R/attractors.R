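#' Strongly connected components of a characteristic graph
#'
#' @param graph a `characteristic_graph` (or an igraph object).
#' @return integer vector: component id per node. Components are numbered in
#'   order of their smallest member node, so the partition is deterministic.
#' @export
scc_partition <- function(graph) {
  if (inherits(graph, "characteristic_graph")) {
    g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = TRUE)
    if (nrow(graph$edges) > 0L)
      g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to))
  } else {
    g <- graph
  }
  memb <- igraph::components(g, mode = "strong")$membership
  first <- tapply(seq_along(memb), memb, min)
  order_map <- integer(length(first))
  order_map[as.integer(names(sort(first)))] <- seq_along(first)
  unname(order_map[memb])
}

#' Progress indicators of a strongly connected component
#'
#' A substance is a progress indicator of an SCC if its concentration changes
#' monotonically throughout the component and a threshold crossing ahead of
#' it is unavoidable: either it rises in every member mode while some site it
#' could bind stays free throughout (its association threshold will
#' eventually be crossed, forcing an exit event), or it falls in every member
#' mode while some site stays bound by it throughout (its dissociation
#' threshold will be crossed). A falling substance with no occupied site
#' merely decays towards zero and forces nothing. An SCC with a progress
#' indicator cannot host an infinite behaviour.
#'
#' @param graph a `characteristic_graph`.
#' @param members integer vector of node indices forming the SCC.
#' @return character vector of substance ids (possibly empty).
#' @export
progress_indicators <- function(graph, members) {
  D <- graph$dirs[members, , drop = FALSE]
  M <- graph$nodes[members, , drop = FALSE]
  idx <- hsm_index(graph$model)
  out <- character(0)
  for (p in idx$substances) {
    b <- idx$bind[[p]]
    if (length(b$sites) == 0L) next
    d <- D[, p]
    if (all(d == 1L)) {
      free_through <- vapply(seq_along(b$sites), function(k)
        all(M[, b$sites[k]] == 0L), TRUE)
      if (any(free_through)) out <- c(out, p)
    } else if (all(d == -1L)) {
      bound_through <- vapply(seq_along(b$sites), function(k)
        all(M[, b$sites[k]] == b$val[k]), TRUE)
      if (any(bound_through)) out <- c(out, p)
    }
  }
  out
}

#' Identify attractor candidates in a characteristic graph
#'
#' Decomposes the graph into strongly connected components and annotates each
#' with its progress indicators, finality and structure. An SCC is an
#' attractor candidate iff it has no progress indicator and can host an
#' infinite behaviour: it has at least one internal edge, or it is a steady
#' sink (a single mode with no outgoing edges at all). Finality (no edge
#' leaves the SCC) is reported separately: a candidate may admit exits whose
#' realization depends on growth-rate ratios.
#'
#' @param graph a `characteristic_graph`.
#' @return list of `scc_report` objects, ordered by smallest member node.
#'   Each has fields `id`, `members`, `n_modes`, `internal_edges` (row
#'   indices into `graph$edges`), `progress_indicators`, `is_final`,
#'   `is_attractor`, `structure` (`"steady_node"`, `"single_cycle"` or
#'   `"branched"`) and `guard_substances` (substances guarding internal
#'   edges).
#' @export
#' @examples
#' m <- toy_two_gene_model()
#' o <- enumerate_orderings(m, "s2")[[3]]
#' reports <- find_attractors(characteristic_graph(m, o))
#' sum(vapply(reports, `[[`, TRUE, "is_attractor"))  # 2
find_attractors <- function(graph) {
  part <- scc_partition(graph)
  edges <- graph$edges
  ncomp <- max(part)
  nnode <- nrow(graph$nodes)
  members_by <- split(seq_along(part), part)
  size <- lengths(members_by)
  efrom_c <- part[edges$from]; eto_c <- part[edges$to]
  internal <- efrom_c == eto_c
  internal_by <- split(which(internal), factor(efrom_c[internal], levels = seq_len(ncomp)))
  outgoing_cnt <- tabulate(efrom_c[!internal], nbins = ncomp)
  node_int_out <- tabulate(edges$from[internal], nbins = nnode)
  one_succ <- as.vector(rowsum((node_int_out == 1L) + 0L, part)) == size

  # progress indicators, aggregated per component in one pass per substance
  all_by <- function(v) as.vector(rowsum(v + 0L, part)) == size
  idx <- hsm_index(graph$model)
  pis_by <- vector("list", ncomp)
  for (i in seq_len(ncomp)) pis_by[[i]] <- character(0)
  for (p in idx$substances) {
    b <- idx$bind[[p]]
    if (length(b$sites) == 0L) next
    d <- graph$dirs[, p]
    up_all <- all_by(d == 1L)
    down_all <- all_by(d == -1L)
    free_any <- rep(FALSE, ncomp); bound_any <- rep(FALSE, ncomp)
    for (k in seq_along(b$sites)) {
      col <- graph$nodes[, b$sites[k]]
      free_any <- free_any | all_by(col == 0L)
      bound_any <- bound_any | all_by(col == b$val[k])
    }
    hit <- (up_all & free_any) | (down_all & bound_any)
    for (i in which(hit)) pis_by[[i]] <- c(pis_by[[i]], p)
  }

  out <- vector("list", ncomp)
  for (cid in seq_len(ncomp)) {
    members <- members_by[[cid]]
    inside <- internal_by[[cid]]
    outgoing <- outgoing_cnt[cid] > 0L
    pis <- pis_by[[cid]]
    steady <- size[cid] == 1L && length(inside) == 0L && !outgoing
    has_cycle <- length(inside) > 0L
    is_attr <- length(pis) == 0L && (has_cycle || steady)
    structure_ <- if (steady) "steady_node"
    else if (has_cycle && one_succ[cid]) "single_cycle"
    else "branched"
    out[[cid]] <- structure(
      list(id = cid, members = members, n_modes = size[[cid]],
           internal_edges = inside,
           progress_indicators = pis,
           is_final = !outgoing,
           is_attractor = is_attr,
           structure = structure_,
           guard_substances = sort(unique(edges$substance[inside]))),
      class = "scc_report")
  }
  out
}

#' @export
print.scc_report <- function(x, ...) {
  cat(sprintf("SCC %d: %d mode(s), %s%s%s\n", x$id, x$n_modes, x$structure,
              if (x$is_attractor) ", attractor" else "",
              if (x$is_final) ", final" else ""))
  if (length(x$progress_indicators) > 0L)
    cat(sprintf("  progress indicators: %s\n",
                paste(x$progress_indicators, collapse = ", ")))
  if (length(x$guard_substances) > 0L)
    cat(sprintf("  internal guards by: %s\n",
                paste(x$guard_substances, collapse = ", ")))
  invisible(x)
}

#' Full-identity fingerprint of an SCC
#'
#' Serializes the subgraph with complete binding-site state labels and full
#' guard texts, sorted canonically. Two SCCs (possibly from graphs of
#' different orderings) get equal fingerprints iff they consist of the same
#' modes connected by the same guarded transitions.
#'
#' @param graph a `characteristic_graph`.
#' @param scc an `scc_report` from [find_attractors()] on `graph`.
#' @return a character scalar.
#' @export
attractor_fingerprint <- function(graph, scc) {
  labs <- node_labels(graph, scc$members)
  e <- graph$edges[scc$internal_edges, , drop = FALSE]
  l_of <- stats::setNames(labs, scc$members)
  etxt <- sort(paste0(l_of[as.character(e$from)], " -> ",
                      l_of[as.character(e$to)], " [", e$guard, "]"))
  paste(c(sort(labs), etxt), collapse = "\n")
}

# Canonical form of a labelled digraph: vertices coloured by label id, each
# edge replaced by a two-node chain coloured by (edge label, end) so that
# direction and edge labels survive undirected canonical labelling (BLISS).
canonical_labelled_digraph <- function(node_labels, from, to, edge_labels) {
  n <- length(node_labels)
  m <- length(from)
  nl <- sort(unique(node_labels))
  el <- sort(unique(edge_labels))
  ncol_ <- match(node_labels, nl)
  ecol <- match(edge_labels, el)
  cols <- c(ncol_, length(nl) + 2L * ecol - 1L, length(nl) + 2L * ecol)
  g <- igraph::make_empty_graph(n + 2L * m, directed = FALSE)
  if (m > 0L) {
    el_mat <- rbind(cbind(from, n + seq_len(m)),
                    cbind(n + seq_len(m), n + m + seq_len(m)),
                    cbind(n + m + seq_len(m), to))
    g <- igraph::add_edges(g, t(el_mat))
  }
  perm <- igraph::canonical_permutation(g, colors = cols)$labeling
  h <- igraph::permute(g, perm)
  colh <- integer(length(cols)); colh[perm] <- cols
  # re-express colours by their labels so the form is comparable across graphs
  lab_of_col <- c(nl, as.vector(rbind(paste0(el, "/s"), paste0(el, "/t"))))
  eh <- igraph::as_edgelist(h, names = FALSE)
  if (nrow(eh) > 0L) {
    eh <- t(apply(eh, 1L, sort))
    eh <- eh[order(eh[, 1L], eh[, 2L]), , drop = FALSE]
  }
  paste(paste(lab_of_col[colh], collapse = ";"),
        paste(t(eh), collapse = ","), sep = "|")
}

#' Behaviour signature of an SCC
#'
#' The qualitative behaviour of an attractor abstracts away binding-site
#' identities: modes are relabelled by their direction vectors only and
#' guards by the triggering substance and threshold kind. The signature is a
#' canonical form of this relabelled subgraph, so it is invariant under node
#' reordering and under graph isomorphisms that respect the labels. Attractor
#' variants that differ in which sites are occupied but not in the behaviour
#' collapse to one signature.
#'
#' @inheritParams attractor_fingerprint
#' @return a character scalar; equal signatures mean the same qualitative
#'   behaviour.
#' @export
attractor_signature <- function(graph, scc) {
  dl <- dir_labels(graph, scc$members)
  e <- graph$edges[scc$internal_edges, , drop = FALSE]
  pos <- match(e$from, scc$members)
  pos2 <- match(e$to, scc$members)
  elab <- paste0(e$substance, ".", e$kind)
  canonical_labelled_digraph(dl, pos, pos2, elab)
}

#' Whole-graph behaviour signature
#'
#' [attractor_signature()] applied to the entire characteristic graph:
#' canonical form with direction-vector node labels and substance/kind edge
#' labels. Two orderings whose graphs have identical structure (guards
#' matching up to threshold renaming) get equal signatures.
#'
#' @param graph a `characteristic_graph`.
#' @return a character scalar.
#' @export
graph_signature <- function(graph) {
  canonical_labelled_digraph(dir_labels(graph), graph$edges$from,
                             graph$edges$to,
                             paste0(graph$edges$substance, ".", graph$edges$kind))
}
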