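#' Sweep attractor analysis across threshold orderings
#'
#' Builds the characteristic graph for every joint threshold ordering,
#' identifies attractors, and aggregates them across orderings: attractors
#' are classified both by full-identity fingerprint (binding-site states
#' included) and by behaviour signature (direction vectors and guard
#' substances only). Fingerprint and signature ids are assigned in order of
#' first appearance, so the sweep is reproducible given the deterministic
#' ordering enumeration.
#'
#' @param model a validated [hsm_model()].
#' @param orderings list of joint `threshold_ordering` objects, e.g. from
#'   [enumerate_joint_orderings()] or [phage_orderings()].
#' @param progress print a dot every 50 orderings.
#' @return An object of class `hsm_sweep`: `table` (one row per ordering:
#'   `ordering_id`, `ordering`, `n_attractors`, `attractor_sizes`,
#'   `fingerprints`, `signatures`, `graph_nodes`), `fingerprints` and
#'   `signatures` (the distinct strings, position = id),
#'   `signature_orderings` (list: signature id -> ordering ids), `attractors`
#'   (per ordering, the attractor `scc_report`s with `fingerprint_id` /
#'   `signature_id` attached) and the `orderings` themselves.
#' @export
sweep_orderings <- function(model, orderings, progress = FALSE) {
  fps <- character(0); sigs <- character(0)
  rows <- vector("list", length(orderings))
  atts <- vector("list", length(orderings))
  sig_ords <- list()
  for (k in seq_along(orderings)) {
    o <- orderings[[k]]
    g <- characteristic_graph(model, o)
    reports <- find_attractors(g)
    a <- Filter(function(r) r$is_attractor, reports)
    fid <- sid <- integer(length(a))
    for (j in seq_along(a)) {
      fp <- attractor_fingerprint(g, a[[j]])
      sg <- attractor_signature(g, a[[j]])
      if (!fp %in% fps) fps <- c(fps, fp)
      if (!sg %in% sigs) sigs <- c(sigs, sg)
      fid[j] <- match(fp, fps)
      sid[j] <- match(sg, sigs)
      a[[j]]$fingerprint_id <- fid[j]
      a[[j]]$signature_id <- sid[j]
      key <- as.character(sid[j])
      sig_ords[[key]] <- union(sig_ords[[key]], k)
    }
    rows[[k]] <- data.frame(
      ordering_id = k, ordering = ordering_string(o),
      n_attractors = length(a),
      attractor_sizes = paste(vapply(a, `[[`, 0L, "n_modes"), collapse = ","),
      fingerprints = paste(fid, collapse = ","),
      signatures = paste(sid, collapse = ","),
      graph_nodes = nrow(g$nodes), stringsAsFactors = FALSE)
    atts[[k]] <- a
    if (progress && k %% 50L == 0L) { cat("."); utils::flush.console() }
  }
  if (progress) cat("\n")
  sig_orderings <- lapply(seq_along(sigs), function(s)
    sort(sig_ords[[as.character(s)]]))
  structure(list(model_name = model$name,
                 table = do.call(rbind, rows),
                 fingerprints = fps, signatures = sigs,
                 signature_orderings = sig_orderings,
                 attractors = atts, orderings = orderings),
            class = "hsm_sweep")
}

#' @export
print.hsm_sweep <- function(x, ...) {
  cat(sprintf("Attractor sweep of '%s' over %d threshold ordering(s)\n",
              x$model_name, nrow(x$table)))
  cat(sprintf("  attractors per ordering: %s\n",
              paste(sort(unique(x$table$n_attractors)), collapse = ", ")))
  cat(sprintf("  %d distinct attractor fingerprint(s), %d distinct behaviour signature(s)\n",
              length(x$fingerprints), length(x$signatures)))
  for (s in seq_along(x$signatures)) {
    ords <- x$signature_orderings[[s]]
    cat(sprintf("  signature %d: seen in %d ordering(s)\n", s, length(ords)))
  }
  invisible(x)
}

#' Mine threshold-order conditions behind each behaviour
#'
#' For every behaviour signature observed in a sweep, intersects the pairwise
#' threshold rank relations over all orderings that produced it. A relation
#' `key_a < key_b` with scope `"all"` holds in every such ordering (it is
#' necessary within the examined sample); scope `"none"` means it holds in no
#' such ordering. Sufficiency of a relation set for a behaviour can then be
#' checked by testing whether every ordering satisfying it produced the
#' signature.
#'
#' @param sweep an `hsm_sweep`.
#' @return data frame with columns `signature_id`, `substance`, `key_a`,
#'   `key_b`, `scope` (`"all"` or `"none"`), sorted deterministically.
#'   Signatures produced by no ordering are omitted.
#' @export
mine_conditions <- function(sweep) {
  out <- list()
  for (s in seq_along(sweep$signatures)) {
    ords <- sweep$signature_orderings[[s]]
    if (length(ords) == 0L) next
    first <- sweep$orderings[[ords[1]]]
    for (p in names(first)) {
      if (length(first[[p]]) == 0L) next
      ranks <- lapply(ords, function(k) ordering_ranks(sweep$orderings[[k]], p))
      keys <- sort(names(ranks[[1]]))
      for (a in keys) for (b in keys) {
        if (a >= b) next
        lt_ab <- vapply(ranks, function(r) r[[a]] < r[[b]], TRUE)
        lt_ba <- !lt_ab & vapply(ranks, function(r) r[[b]] < r[[a]], TRUE)
        emit <- function(ka, kb, scope)
          out[[length(out) + 1L]] <<- data.frame(
            signature_id = s, substance = p, key_a = ka, key_b = kb,
            scope = scope, stringsAsFactors = FALSE)
        if (all(lt_ab)) emit(a, b, "all")
        if (!any(lt_ab)) emit(a, b, "none")
        if (all(lt_ba)) emit(b, a, "all")
        if (!any(lt_ba)) emit(b, a, "none")
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$signature_id, res$substance, res$key_a, res$key_b, res$scope,
            method = "radix"), , drop = FALSE]
}

#' Export a sweep as a CSV table
#'
#' One data row per ordering with columns `ordering_id`, `ordering`,
#' `n_attractors`, `attractor_sizes`, `fingerprints`, `signatures`,
#' `graph_nodes`.
#'
#' @param sweep an `hsm_sweep`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep$table, path, row.names = FALSE)
  invisible(path)
}
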