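# Analysis context: model index + ordering ranks resolved per substance.
# Site states use the internal integer encoding (0 = FREE, k = k-th ligand).
graph_ctx <- function(model, ordering) {
  idx <- hsm_index(model)
  bind <- list()
  for (p in idx$substances) {
    b <- idx$bind[[p]]
    if (length(b$sites) == 0L) next
    keys <- threshold_keys(model, p)
    ranks <- ordering_ranks(ordering, p)
    if (!setequal(names(ranks), keys))
      stop(sprintf("ordering does not cover the threshold keys of '%s'", p))
    sid <- idx$site_ids[b$sites]
    bind[[p]] <- list(sites = b$sites, val = b$val,
                      asr = unname(ranks[paste0(sid, ".as")]),
                      disr = unname(ranks[paste0(sid, ".dis")]))
  }
  gens <- list()
  for (p in idx$substances) {
    g <- idx$gen_of[[p]]
    if (!is.null(g)) gens[[p]] <- idx$cf[[g$control]]
  }
  list(model = model, idx = idx, bind = bind, gens = gens,
       subs = idx$substances, nsite = length(idx$site_ids),
       nstates = idx$nstates)
}

# Vectorized consistency over a matrix of modes (rows). A mode is consistent
# iff for every substance the implied concentration interval is non-empty:
# the largest dissociation rank among sites it occupies lies strictly below
# the smallest association rank among free sites it could bind.
consistent_rows <- function(M, ctx) {
  n <- nrow(M)
  ok <- rep(TRUE, n)
  for (p in names(ctx$bind)) {
    b <- ctx$bind[[p]]
    lo <- rep(-Inf, n); hi <- rep(Inf, n)
    for (k in seq_along(b$sites)) {
      col <- M[, b$sites[k]]
      lo <- pmax(lo, ifelse(col == b$val[k], b$disr[k], -Inf))
      hi <- pmin(hi, ifelse(col == 0L, b$asr[k], Inf))
    }
    ok <- ok & (lo < hi)
  }
  ok
}

# First substance with an empty concentration interval, or NA if consistent.
inconsistent_substance <- function(state, ctx) {
  for (p in names(ctx$bind)) {
    b <- ctx$bind[[p]]
    col <- state[b$sites]
    lo <- suppressWarnings(max(b$disr[col == b$val], -Inf))
    hi <- suppressWarnings(min(b$asr[col == 0L], Inf))
    if (lo >= hi) return(p)
  }
  NA_character_
}

# Direction of every substance in every mode: +1 expressed, -1 silent,
# 0 for substances lacking a generator (constant inputs).
dir_rows <- function(M, ctx) {
  n <- nrow(M)
  D <- matrix(0L, n, length(ctx$subs), dimnames = list(NULL, ctx$subs))
  for (p in names(ctx$gens)) {
    cf <- ctx$gens[[p]]
    code <- rep(0L, n)
    for (j in seq_along(cf$inputs))
      code <- code + M[, cf$inputs[j]] * cf$radix[j]
    D[, p] <- ifelse(cf$levels[code + 1L] > 0L, 1L, -1L)
  }
  D
}

dir_row1 <- function(state, ctx) dir_rows(matrix(state, nrow = 1L), ctx)[1L, ]

# Cascade closure: complete an (possibly inconsistent) mode into the set of
# consistent modes reachable by immediately binding free sites whose
# association threshold has already been passed by the implied concentration.
# Branching covers release-then-rebind ambiguity when a site freed by one
# ligand may already be claimable by another.
closure_complete <- function(state, ctx) {
  out <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  recurse <- function(st) {
    key <- mode_key(st)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    q <- inconsistent_substance(st, ctx)
    if (is.na(q)) {
      out[[length(out) + 1L]] <<- st
      return(invisible(NULL))
    }
    b <- ctx$bind[[q]]
    col <- st[b$sites]
    lo <- suppressWarnings(max(b$disr[col == b$val], -Inf))
    prob <- which(col == 0L & b$asr <= lo)
    if (length(prob) == 0L) return(invisible(NULL))  # unrepairable: drop branch
    for (mask in seq_len(2L^length(prob) - 1L)) {
      pick <- prob[bitwAnd(mask, 2L^(seq_along(prob) - 1L)) > 0L]
      st2 <- st
      st2[b$sites[pick]] <- b$val[pick]
      recurse(st2)
    }
    invisible(NULL)
  }
  recurse(state)
  if (length(out) > 1L) {
    keys <- vapply(out, mode_key, "")
    out <- out[order(keys, method = "radix")]
  }
  out
}

# Enabled events of a consistent mode, internal form. A rising substance can
# only cross the smallest uncrossed association rank among its free sites
# (a monotone concentration meets lower thresholds first); a falling one only
# the largest dissociation rank among the sites it occupies. Thresholds tied
# at that rank fire together as one compound event. Events of different
# substances are asynchronous: each yields its own edges.
events_for_state <- function(state, ctx, dirs = NULL) {
  if (is.null(dirs)) dirs <- dir_row1(state, ctx)
  events <- list()
  for (p in names(ctx$bind)) {
    d <- dirs[[p]]
    if (d == 0L) next
    b <- ctx$bind[[p]]
    col <- state[b$sites]
    if (d > 0L) {
      free <- which(col == 0L)
      if (length(free) == 0L) next
      r <- min(b$asr[free])
      sel <- free[b$asr[free] == r]
      tgt <- state
      tgt[b$sites[sel]] <- b$val[sel]
      kind <- "assoc"
    } else {
      bound <- which(col == b$val)
      if (length(bound) == 0L) next
      r <- max(b$disr[bound])
      sel <- bound[b$disr[bound] == r]
      tgt <- state
      tgt[b$sites[sel]] <- 0L
      kind <- "dissoc"
    }
    events[[length(events) + 1L]] <- list(
      substance = p, kind = kind, sites = ctx$idx$site_ids[b$sites[sel]],
      targets = closure_complete(tgt, ctx))
  }
  events
}

guard_text <- function(substance, kind, sites) {
  op <- if (kind == "assoc") " >= " else " <= "
  suffix <- if (kind == "assoc") ".as" else ".dis"
  paste(paste0(substance, op, sites, suffix), collapse = " & ")
}

#' Is a mode consistent with a threshold ordering?
#'
#' A mode (an assignment of a state to every binding site) is consistent iff
#' every substance's implied concentration interval is non-empty: the largest
#' dissociation rank among the sites it occupies must lie strictly below the
#' smallest association rank among the free sites it could bind. Sites bound
#' by another ligand impose no constraint.
#'
#' @param model an [hsm_model()].
#' @param ordering a `threshold_ordering` covering the model's keys.
#' @param mode named character vector, one entry per site, each `"FREE"` or
#'   `"BOUND:<substance>"`.
#' @return `TRUE` or `FALSE`; if `FALSE`, the attribute `"substance"` names a
#'   substance whose interval is empty.
#' @export
is_consistent_mode <- function(model, ordering, mode) {
  ctx <- graph_ctx(model, ordering)
  state <- mode_to_int(model, mode)
  q <- inconsistent_substance(state, ctx)
  out <- is.na(q)
  if (!out) attr(out, "substance") <- q
  out
}

#' Direction of concentration change in a mode
#'
#' Each mode uniquely determines the direction of change of every substance:
#' `"up"` if its gene's control function evaluates to a positive expression
#' level, `"down"` if the gene is off (the concentration decays, approaching
#' but never reaching zero in the qualitative abstraction), and `"flat"` only
#' for substances without a generator (constant inputs).
#'
#' @inheritParams is_consistent_mode
#' @return named character vector over substances.
#' @export
direction_vector <- function(model, mode) {
  idx <- hsm_index(model)
  ctx <- list(model = model, idx = idx, gens = NULL, subs = idx$substances)
  gens <- list()
  for (p in idx$substances) {
    g <- idx$gen_of[[p]]
    if (!is.null(g)) gens[[p]] <- idx$cf[[g$control]]
  }
  ctx$gens <- gens
  d <- dir_row1(mode_to_int(model, mode), ctx)
  stats::setNames(c("down", "flat", "up")[d + 2L], names(d))
}

#' Enabled events of a mode
#'
#' Lists the guarded transitions that can fire in a consistent mode: each
#' rising substance may bind the free site(s) carrying its minimal uncrossed
#' association rank, each falling substance may release the occupied site(s)
#' carrying its maximal dissociation rank. Thresholds tied at that rank fire
#' together as one compound event. If a target mode is inconsistent, cascade
#' closure branches into every consistent completion, each a separate edge
#' with the same guard.
#'
#' @inheritParams is_consistent_mode
#' @return list of events, each a `list(substance, kind, sites, guard,
#'   targets)` where `targets` is a list of completed target modes (named
#'   character vectors).
#' @export
enabled_events <- function(model, ordering, mode) {
  ctx <- graph_ctx(model, ordering)
  state <- mode_to_int(model, mode)
  q <- inconsistent_substance(state, ctx)
  if (!is.na(q))
    stop(sprintf("mode is inconsistent: substance '%s' has an empty concentration interval", q))
  evs <- events_for_state(state, ctx)
  lapply(evs, function(e) {
    list(substance = e$substance, kind = e$kind, sites = e$sites,
         guard = guard_text(e$substance, e$kind, e$sites),
         targets = lapply(e$targets, function(t)
           stats::setNames(mode_to_labels(model, t), ctx$idx$site_ids)))
  })
}
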