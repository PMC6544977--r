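#' Declare constraints on a substance's threshold ordering
#'
#' A threshold ordering is a total preorder (ties allowed) of one substance's
#' association/dissociation threshold keys. Orderings of different substances
#' are never compared: concentrations live on separate scales. Constraints
#' restrict which orderings are admissible:
#'
#' * `chains`: lists of keys that must appear in the given (strictly
#'   ascending) order;
#' * `adjacency_blocks`: pairs `c(a, b)` such that `b` must come immediately
#'   after `a` -- used to state that a site's dissociation and association
#'   thresholds are so close that no other threshold of the same substance
#'   falls between them;
#' * `permitted_interleavings`: explicit complete orderings that are admitted
#'   even though they violate an adjacency block (they must still satisfy all
#'   chains);
#' * `equalities`: sets of keys forced to share a rank (tied thresholds).
#'
#' The constraint that a site's dissociation threshold precedes its
#' association threshold is implicit and always enforced.
#'
#' @param chains list of character vectors.
#' @param adjacency_blocks list of length-2 character vectors.
#' @param permitted_interleavings list of orderings; each ordering is either a
#'   character vector of keys or a list of rank groups.
#' @param equalities list of character vectors.
#' @return An object of class `ordering_constraints`.
#' @export
ordering_constraints <- function(chains = list(), adjacency_blocks = list(),
                                 permitted_interleavings = list(),
                                 equalities = list()) {
  structure(list(chains = lapply(chains, as.character),
                 adjacency_blocks = lapply(adjacency_blocks, as.character),
                 permitted_interleavings = lapply(permitted_interleavings,
                                                  function(o) {
                                                    if (is.character(o)) as.list(o) else o
                                                  }),
                 equalities = lapply(equalities, as.character)),
            class = "ordering_constraints")
}

new_threshold_ordering <- function(groups_by_substance) {
  structure(groups_by_substance, class = "threshold_ordering")
}

#' Render a threshold ordering as text
#'
#' @param ordering a `threshold_ordering`.
#' @param substance optional substance id; default renders all substances.
#' @return a character string such as `"b2.dis < b3.dis < b3.as < b2.as"`;
#'   tied keys are joined with `"="`.
#' @export
ordering_string <- function(ordering, substance = NULL) {
  fmt1 <- function(groups) {
    paste(vapply(groups, function(g) paste(sort(g), collapse = "="), ""),
          collapse = " < ")
  }
  if (!is.null(substance)) return(fmt1(ordering[[substance]]))
  paste(vapply(names(ordering), function(p) {
    if (length(ordering[[p]]) == 0L) return(sprintf("%s: -", p))
    sprintf("%s: %s", p, fmt1(ordering[[p]]))
  }, ""), collapse = "; ")
}

#' @export
print.threshold_ordering <- function(x, ...) {
  cat("Threshold ordering\n")
  for (p in names(x)) {
    if (length(x[[p]]) == 0L) next
    cat(sprintf("  %s: %s\n", p, ordering_string(x, p)))
  }
  invisible(x)
}

#' Rank of each threshold key under an ordering
#'
#' @param ordering a `threshold_ordering`.
#' @param substance substance id.
#' @return named integer vector: the 1-based rank group of every key; tied
#'   keys share a rank.
#' @export
ordering_ranks <- function(ordering, substance) {
  groups <- ordering[[substance]]
  if (is.null(groups)) stop(sprintf("ordering has no substance '%s'", substance))
  if (length(groups) == 0L) return(integer(0))
  ranks <- rep(seq_along(groups), lengths(groups))
  names(ranks) <- unlist(groups)
  ranks
}

# Backtracking enumeration of linear orders of merged items under precedence
# and adjacency constraints, emitting sequences in lexicographic item order.
enumerate_item_orders <- function(items, pred, adj_next, adj_prev) {
  n <- length(items)
  res <- list()
  placed <- logical(n)
  seqv <- integer(n)
  free_pool <- order(items, method = "radix")
  recurse <- function(depth, last) {
    if (depth > n) {
      res[[length(res) + 1L]] <<- seqv
      return(invisible(NULL))
    }
    if (last > 0L && adj_next[last] > 0L) {
      cand <- adj_next[last]
      if (placed[cand] || !all(placed[pred[[cand]]])) return(invisible(NULL))
      cands <- cand
    } else {
      cands <- free_pool[!placed[free_pool] & adj_prev[free_pool] == 0L]
      cands <- cands[vapply(cands, function(i) all(placed[pred[[i]]]), TRUE)]
    }
    for (i in cands) {
      placed[i] <<- TRUE; seqv[depth] <<- i
      recurse(depth + 1L, i)
      placed[i] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L, 0L)
  res
}

#' Enumerate admissible threshold orderings of one substance
#'
#' Produces every total preorder of the substance's threshold keys that
#' satisfies the implicit per-site dissociation-before-association constraint
#' and all declared [ordering_constraints()]. Ties arise only from declared
#' equalities. The result is exhaustive, duplicate-free and returned in
#' lexicographic order of the rendered key sequence, so ordering indices are
#' reproducible.
#'
#' @param model an [hsm_model()].
#' @param substance substance id.
#' @param constraints an [ordering_constraints()] or `NULL` (implicit
#'   constraints only).
#' @return A list of `threshold_ordering` objects, each covering only
#'   `substance`. If the constraints are unsatisfiable the list is empty and
#'   carries a `diagnostic` attribute.
#' @export
#' @examples
#' m <- toy_two_gene_model()
#' length(enumerate_orderings(m, "s2"))  # 6
enumerate_orderings <- function(model, substance, constraints = NULL) {
  keys <- threshold_keys(model, substance)
  if (length(keys) == 0L)
    return(list(new_threshold_ordering(stats::setNames(list(list()), substance))))
  if (is.null(constraints)) constraints <- ordering_constraints()

  ck <- unique(unlist(c(constraints$chains, constraints$adjacency_blocks,
                        constraints$equalities,
                        lapply(constraints$permitted_interleavings, unlist))))
  unknown <- setdiff(ck, keys)
  if (length(unknown) > 0L)
    stop(sprintf("constraint refers to unknown threshold key(s) for '%s': %s",
                 substance, paste(unknown, collapse = ", ")))

  # union-find over equalities -> merged items
  parent <- stats::setNames(seq_along(keys), keys)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (eq in constraints$equalities) {
    idx <- match(eq, keys)
    for (j in idx[-1]) parent[findr(j)] <- findr(idx[1])
  }
  root <- vapply(seq_along(keys), findr, 0L)
  groups <- split(keys, root)
  item_names <- vapply(groups, function(g) paste(sort(g), collapse = "="), "")
  ord <- order(item_names, method = "radix")
  groups <- groups[ord]; item_names <- item_names[ord]
  item_of <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                             unlist(groups))
  n <- length(groups)

  unsat <- function(msg) {
    out <- list(); attr(out, "diagnostic") <- msg; out
  }

  # strict precedence edges: implicit dis < as per site, plus chains
  edges <- list()
  sitekeys <- matrix(keys, ncol = 2L, byrow = TRUE)  # [dis, as] per site
  for (i in seq_len(nrow(sitekeys)))
    edges[[length(edges) + 1L]] <- c(sitekeys[i, 1L], sitekeys[i, 2L])
  for (ch in constraints$chains)
    for (i in seq_len(length(ch) - 1L))
      edges[[length(edges) + 1L]] <- c(ch[i], ch[i + 1L])
  pred <- vector("list", n)
  for (i in seq_len(n)) pred[[i]] <- integer(0)
  for (e in edges) {
    a <- item_of[[e[1]]]; b <- item_of[[e[2]]]
    if (a == b)
      return(unsat(sprintf("keys '%s' and '%s' are required both strictly ordered and equal",
                           e[1], e[2])))
    pred[[b]] <- union(pred[[b]], a)
  }

  adj_next <- integer(n); adj_prev <- integer(n)
  for (ab in constraints$adjacency_blocks) {
    a <- item_of[[ab[1]]]; b <- item_of[[ab[2]]]
    if (a == b) next
    if ((adj_next[a] != 0L && adj_next[a] != b) ||
        (adj_prev[b] != 0L && adj_prev[b] != a))
      return(unsat("conflicting adjacency blocks"))
    adj_next[a] <- b; adj_prev[b] <- a
    pred[[b]] <- union(pred[[b]], a)
  }

  seqs <- enumerate_item_orders(item_names, pred, adj_next, adj_prev)

  # permitted interleavings: explicit complete orderings exempt from adjacency
  precedes_ok <- function(pos) {
    for (b in seq_len(n)) for (a in pred[[b]]) if (pos[a] >= pos[b]) return(FALSE)
    TRUE
  }
  extra <- list()
  for (o in constraints$permitted_interleavings) {
    inames <- vapply(o, function(g) paste(sort(as.character(g)), collapse = "="), "")
    idx <- match(inames, item_names)
    if (anyNA(idx) || length(idx) != n || anyDuplicated(idx))
      stop("permitted interleaving must list every threshold key exactly once, with the declared equalities")
    pos <- integer(n); pos[idx] <- seq_len(n)
    if (!precedes_ok(pos))
      stop("permitted interleaving violates a chain or the implicit dis < as order")
    extra[[length(extra) + 1L]] <- idx
  }
  seqs <- c(seqs, extra)
  strs <- vapply(seqs, function(s) paste(item_names[s], collapse = " < "), "")
  keep <- !duplicated(strs)
  seqs <- seqs[keep]; strs <- strs[keep]
  seqs <- seqs[order(strs, method = "radix")]
  if (length(seqs) == 0L) return(unsat("no ordering satisfies the constraints"))
  lapply(seqs, function(s) {
    new_threshold_ordering(stats::setNames(list(unname(groups[s])), substance))
  })
}

#' Combine per-substance orderings into joint orderings
#'
#' Takes one list of admissible orderings per substance and forms their
#' Cartesian product. The first substance varies slowest, so joint ordering
#' indices are reproducible given the deterministic per-substance enumeration.
#'
#' @param per_substance named list: substance id -> list of
#'   `threshold_ordering` objects for that substance.
#' @return A list of joint `threshold_ordering` objects of length equal to the
#'   product of the input lengths. If any input list is empty the result is
#'   empty and carries a `diagnostic` attribute.
#' @export
joint_orderings <- function(per_substance) {
  if (length(per_substance) == 0L) return(list(new_threshold_ordering(list())))
  sizes <- lengths(per_substance)
  if (any(sizes == 0L)) {
    out <- list()
    attr(out, "diagnostic") <- sprintf(
      "no admissible ordering for substance(s): %s",
      paste(names(per_substance)[sizes == 0L], collapse = ", "))
    return(out)
  }
  subs <- names(per_substance)
  total <- prod(sizes)
  out <- vector("list", total)
  idx <- rep(1L, length(sizes))
  for (k in seq_len(total)) {
    parts <- lapply(seq_along(subs), function(j)
      per_substance[[j]][[idx[j]]][[subs[j]]])
    names(parts) <- subs
    out[[k]] <- new_threshold_ordering(parts)
    # odometer: last substance fastest
    for (j in rev(seq_along(idx))) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L
    }
  }
  out
}

#' Enumerate joint orderings for a whole model
#'
#' Convenience wrapper: enumerates the admissible orderings of every substance
#' that owns at least one threshold key (substances without binding sites
#' contribute an empty ordering) and combines them with [joint_orderings()].
#'
#' @param model an [hsm_model()].
#' @param constraints named list of [ordering_constraints()] keyed by
#'   substance id; substances without an entry get implicit constraints only.
#' @return list of joint `threshold_ordering` objects.
#' @export
enumerate_joint_orderings <- function(model, constraints = list()) {
  subs <- model$substances$id
  per <- list()
  for (p in subs) {
    if (length(threshold_keys(model, p)) == 0L) next
    per[[p]] <- enumerate_orderings(model, p, constraints[[p]])
  }
  out <- joint_orderings(per)
  lapply(out, function(o) {
    full <- stats::setNames(vector("list", length(subs)), subs)
    for (p in subs) full[[p]] <- if (is.null(o[[p]])) list() else o[[p]]
    new_threshold_ordering(full)
  })
}
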