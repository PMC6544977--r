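# Independent oracles used by the property tests. These deliberately avoid
# the package's internal code paths: permutations are enumerated by brute
# force, consistency is decided by assigning concrete rational values to
# ranks, and SCCs come from a transitive-closure reachability matrix.

# all permutations of a small vector (n <= 8)
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# does a linear order of keys satisfy the constraints? (positions-based check,
# independent of the package's backtracking engine)
oracle_satisfies <- function(ord, keys, chains, adjacency, site_pairs) {
  pos <- match(keys, ord)
  for (sp in site_pairs) if (pos[match(sp[1], keys)] >= pos[match(sp[2], keys)])
    return(FALSE)
  for (ch in chains) {
    p <- pos[match(ch, keys)]
    if (any(diff(p) <= 0)) return(FALSE)
  }
  for (ab in adjacency) {
    pa <- pos[match(ab[1], keys)]; pb <- pos[match(ab[2], keys)]
    if (pb != pa + 1L) return(FALSE)
  }
  TRUE
}

# brute-force enumeration: filter all permutations, then add the permitted
# interleavings that satisfy the chains
oracle_orderings <- function(keys, chains = list(), adjacency = list(),
                             interleavings = list()) {
  site_pairs <- lapply(seq_len(length(keys) / 2L), function(i)
    keys[c(2L * i - 1L, 2L * i)])
  hits <- Filter(function(o) oracle_satisfies(o, keys, chains, adjacency, site_pairs),
                 all_perms(keys))
  for (il in interleavings) {
    if (oracle_satisfies(il, keys, chains, list(), site_pairs))
      hits[[length(hits) + 1L]] <- il
  }
  sort(unique(vapply(hits, paste, "", collapse = " < ")))
}

# consistency oracle: assign the rational value r to rank group r and check
# interval emptiness with concrete numbers
oracle_consistent <- function(model, ordering, mode_labels) {
  sids <- vapply(model$sites, `[[`, "", "id")
  for (p in model$substances$id) {
    groups <- ordering[[p]]
    if (length(groups) == 0L) next
    val <- list()
    for (r in seq_along(groups)) for (k in groups[[r]]) val[[k]] <- r * 1.0
    lo <- -Inf; hi <- Inf
    for (i in seq_along(model$sites)) {
      s <- model$sites[[i]]
      if (!p %in% s$ligands) next
      st <- mode_labels[[sids[i]]]
      if (identical(st, paste0("BOUND:", p))) {
        lo <- max(lo, val[[paste0(s$id, ".dis")]])
      } else if (identical(st, "FREE")) {
        hi <- min(hi, val[[paste0(s$id, ".as")]])
      }
    }
    if (!(lo < hi)) return(FALSE)
  }
  TRUE
}

# SCC oracle: u,v share a component iff u reaches v and v reaches u in the
# transitive closure (Floyd-Warshall on a boolean matrix)
oracle_scc <- function(n, from, to) {
  reach <- diag(TRUE, n)
  for (i in seq_along(from)) reach[from[i], to[i]] <- TRUE
  for (k in seq_len(n)) for (i in seq_len(n)) if (reach[i, k])
    reach[i, ] <- reach[i, ] | reach[k, ]
  same <- reach & t(reach)
  comp <- integer(n); cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { cid <- cid + 1L; comp[same[i, ]] <- cid }
  }
  comp
}

# canonical representation of a partition for comparison
partition_sets <- function(comp) {
  unname(lapply(split(seq_along(comp), comp), sort))
}

random_mode_labels <- function(model) {
  labs <- lapply(model$sites, function(s) c("FREE", paste0("BOUND:", s$ligands)))
  stats::setNames(vapply(labs, function(l) sample(l, 1L), ""),
                  vapply(model$sites, `[[`, "", "id"))
}

# hysteresis along a random walk: bind and release events of the same
# (substance, site) pair must alternate
walk_hysteresis_ok <- function(graph, start, steps = 200L) {
  last <- new.env(parent = emptyenv())
  node <- start
  for (k in seq_len(steps)) {
    out <- which(graph$edges$from == node)
    if (length(out) == 0L) return(TRUE)
    e <- out[sample.int(length(out), 1L)]
    sites <- strsplit(graph$edges$sites[e], ",", fixed = TRUE)[[1]]
    for (s in sites) {
      key <- paste(graph$edges$substance[e], s)
      prev <- last[[key]]
      if (!is.null(prev) && prev == graph$edges$kind[e]) return(FALSE)
      last[[key]] <- graph$edges$kind[e]
    }
    node <- graph$edges$to[e]
  }
  TRUE
}

# SCC-level hysteresis: an SCC with internal edges crossing the same
# (substance, site) atom in both directions cannot have that substance
# uniformly rising (or falling)
scc_hysteresis_ok <- function(graph) {
  for (r in find_attractors(graph)) {
    e <- graph$edges[r$internal_edges, , drop = FALSE]
    if (nrow(e) == 0L) next
    both <- intersect(paste(e$substance, e$sites)[e$kind == "assoc"],
                      paste(e$substance, e$sites)[e$kind == "dissoc"])
    for (key in unique(sub(" .*$", "", both))) {
      d <- graph$dirs[r$members, key]
      if (all(d == 1L) || all(d == -1L)) return(FALSE)
    }
  }
  TRUE
}

toy_joint_orderings <- function(model = toy_two_gene_model()) {
  joint_orderings(list(s1 = enumerate_orderings(model, "s1"),
                       s2 = enumerate_orderings(model, "s2")))
}

# the full phage sweep is expensive; build it once per test session
.phage_cache <- new.env(parent = emptyenv())
phage_sweep_cached <- function() {
  if (is.null(.phage_cache$sweep)) {
    m <- phage_lambda_model()
    .phage_cache$model <- m
    .phage_cache$orderings <- phage_orderings(m)
    .phage_cache$sweep <- sweep_orderings(m, .phage_cache$orderings)
  }
  .phage_cache$sweep
}
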