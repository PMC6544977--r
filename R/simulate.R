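#' Numeric parameters for simulation
#'
#' Bundles concrete threshold values and kinetic rates for the event-driven
#' simulator. Threshold values must respect hysteresis (dissociation strictly
#' below association for every ligand-site pair); tied thresholds get equal
#' values.
#'
#' @param model an [hsm_model()].
#' @param thresholds named list: substance id -> named numeric vector of
#'   positive threshold values keyed by threshold key (`"<site>.as"` /
#'   `"<site>.dis"`).
#' @param rates named list: generator id -> `c(growth =, degradation =)`,
#'   both positive (concentration per unit time). Defaults to the rates
#'   declared in the model, or 1/1 where absent.
#' @return an object of class `hsm_params`.
#' @export
hsm_params <- function(model, thresholds, rates = NULL) {
  subs <- model$substances$id
  for (p in subs) {
    keys <- threshold_keys(model, p)
    if (length(keys) == 0L) next
    v <- thresholds[[p]]
    if (is.null(v) || !setequal(names(v), keys))
      stop(sprintf("thresholds for '%s' must cover exactly: %s", p,
                   paste(keys, collapse = ", ")))
    if (any(v <= 0)) stop("threshold values must be positive")
    sitemat <- matrix(keys, ncol = 2L, byrow = TRUE)
    for (i in seq_len(nrow(sitemat)))
      if (v[[sitemat[i, 1L]]] >= v[[sitemat[i, 2L]]])
        stop(sprintf("'%s': dissociation value must lie strictly below association for %s",
                     p, sub("\\.dis$", "", sitemat[i, 1L])))
  }
  if (is.null(rates)) rates <- list()
  full_rates <- list()
  for (g in model$generators) {
    r <- rates[[g$id]]
    if (is.null(r)) r <- g$rates
    if (is.null(r)) r <- c(growth = 1, degradation = 1)
    if (any(r <= 0)) stop(sprintf("rates for generator '%s' must be positive", g$id))
    full_rates[[g$id]] <- c(growth = unname(r[["growth"]]),
                            degradation = unname(r[["degradation"]]))
  }
  structure(list(thresholds = thresholds, rates = full_rates),
            class = "hsm_params")
}

#' Numeric parameters realizing a threshold ordering
#'
#' Assigns concrete values to every threshold so that their order matches the
#' given ordering's ranks (tied ranks get equal values). With
#' `random = FALSE`, rank r takes value r and all rates are 1; with
#' `random = TRUE`, rank gaps and rates are drawn from the current random
#' number generator state (uniform gaps in `[0.5, 1.5]`, rates in
#' `[0.5, 2]`), producing generic parameters with no accidental cross-rank
#' ties.
#'
#' @param model an [hsm_model()].
#' @param ordering a `threshold_ordering`.
#' @param random draw random gaps and rates instead of unit values.
#' @return an [hsm_params()].
#' @export
params_for_ordering <- function(model, ordering, random = FALSE) {
  thresholds <- list()
  for (p in model$substances$id) {
    keys <- threshold_keys(model, p)
    if (length(keys) == 0L) next
    ranks <- ordering_ranks(ordering, p)
    nr <- max(ranks)
    vals <- if (random) cumsum(stats::runif(nr, 0.5, 1.5)) else seq_len(nr)
    thresholds[[p]] <- stats::setNames(vals[ranks[keys]], keys)
  }
  rates <- NULL
  if (random) {
    rates <- lapply(model$generators, function(g)
      c(growth = stats::runif(1, 0.5, 2), degradation = stats::runif(1, 0.5, 2)))
    names(rates) <- gen_ids(model)
  }
  hsm_params(model, thresholds, rates)
}

# association / dissociation value of (substance p, site index s)
thr_val <- function(params, p, site_id, kind)
  params$thresholds[[p]][[paste0(site_id, ".", kind)]]

#' Settle binding-site states against initial concentrations
#'
#' At the start of a run the binding sites switch to states compatible with
#' the initial concentrations: a site is free iff every ligand's
#' concentration lies strictly below its association value; otherwise it is
#' bound by the first declared ligand whose concentration reaches its
#' association value (crossing is inclusive: a concentration exactly at the
#' threshold binds).
#'
#' @param model an [hsm_model()].
#' @param params an [hsm_params()].
#' @param concentrations named non-negative numeric vector over substances.
#' @return a mode: named character vector over sites.
#' @export
settle_initial_mode <- function(model, params, concentrations) {
  stopifnot(all(concentrations >= 0))
  st <- settle_state(model, params, concentrations)
  stats::setNames(mode_to_labels(model, st), site_ids(model))
}

settle_state <- function(model, params, conc) {
  st <- integer(length(model$sites))
  for (i in seq_along(model$sites)) {
    s <- model$sites[[i]]
    for (k in seq_along(s$ligands)) {
      lig <- s$ligands[k]
      if (conc[[lig]] >= thr_val(params, lig, s$id, "as")) { st[i] <- k; break }
    }
  }
  st
}

#' Simulate a hybrid system model
#'
#' Exact event-driven simulation with piecewise-linear kinetics: while a gene
#' is on its product grows linearly at the growth rate, while off it decays
#' linearly at the degradation rate, floored at zero. Binding is hysteretic:
#' a free site is bound when its ligand's rising concentration reaches the
#' association value, a bound site is released when the falling concentration
#' reaches the dissociation value (both crossings inclusive). Event times are
#' computed in closed form; crossings at equal times fire as one compound
#' event, and zero-duration cascade re-binds (a freed site immediately
#' claimed by a ligand already above its association value) are merged into
#' the triggering event.
#'
#' @param model a validated [hsm_model()].
#' @param params an [hsm_params()].
#' @param init named non-negative numeric vector of initial concentrations.
#' @param horizon stop after this much simulated time (default `Inf`).
#' @param max_events stop after this many mode changes.
#' @return An object of class `hsm_run`: `times` (interval start times),
#'   `modes` (integer matrix, one row per mode), `conc` (concentrations at
#'   interval starts), `rates` (signed rates per interval), `events` (one
#'   record per transition: `time`, `substances`, `kinds`, `sites`,
#'   `cascade`), and `steady` (`TRUE` if the run ended in a mode with no
#'   pending crossing).
#' @export
simulate_hsm <- function(model, params, init, horizon = Inf, max_events = 100L) {
  stopifnot(horizon > 0, all(init >= 0))
  idx <- hsm_index(model)
  subs <- idx$substances
  conc <- stats::setNames(as.numeric(init[subs]), subs)
  st <- settle_state(model, params, conc)

  rate_of <- function(state) {
    r <- stats::setNames(numeric(length(subs)), subs)
    for (p in subs) {
      g <- idx$gen_of[[p]]
      if (is.null(g)) next
      cf <- idx$cf[[g$control]]
      code <- if (length(cf$inputs) == 0L) 0L
              else sum(state[cf$inputs] * cf$radix)
      on <- cf$levels[code + 1L] > 0L
      gr <- params$rates[[g$id]]
      r[p] <- if (on) gr[["growth"]] else -gr[["degradation"]]
    }
    r
  }

  times <- 0; modes <- list(st); concs <- list(conc)
  rates <- list(); events <- list()
  t_now <- 0; steady <- FALSE
  tol <- 1e-9
  repeat {
    rate <- rate_of(st)
    rates[[length(rates) + 1L]] <- rate
    # pending threshold crossings, one candidate per substance
    cand <- list()
    for (p in names(idx$bind)) {
      b <- idx$bind[[p]]
      if (length(b$sites) == 0L) next
      sid <- idx$site_ids[b$sites]
      col <- st[b$sites]
      if (rate[p] > 0) {
        free <- which(col == 0L)
        if (length(free) == 0L) next
        av <- vapply(sid[free], function(s) thr_val(params, p, s, "as"), 0)
        a <- min(av)
        dt <- (a - conc[[p]]) / rate[p]
        cand[[p]] <- list(dt = dt, kind = "assoc",
                          sites = b$sites[free[abs(av - a) <= tol * max(1, a)]])
      } else if (rate[p] < 0 && conc[[p]] > 0) {
        bound <- which(col == b$val)
        if (length(bound) == 0L) next
        dv <- vapply(sid[bound], function(s) thr_val(params, p, s, "dis"), 0)
        d <- max(dv)
        dt <- (conc[[p]] - d) / (-rate[p])
        cand[[p]] <- list(dt = dt, kind = "dissoc",
                          sites = b$sites[bound[abs(dv - d) <= tol * max(1, d)]])
      }
    }
    if (length(cand) == 0L) { steady <- TRUE; break }
    dts <- vapply(cand, `[[`, 0, "dt")
    dt <- min(dts)
    if (t_now + dt > horizon) break
    if (length(times) > max_events) break
    # advance concentrations (decay floored at zero)
    conc <- pmax(conc + rate * dt, 0)
    t_now <- t_now + dt
    firing <- names(cand)[dts - dt <= tol * max(1, dt)]
    at_subs <- character(0); at_kinds <- character(0); at_sites <- character(0)
    for (p in firing) {
      e <- cand[[p]]
      b <- idx$bind[[p]]
      if (e$kind == "assoc") {
        st[e$sites] <- b$val[match(e$sites, b$sites)]
      } else {
        st[e$sites] <- 0L
      }
      at_subs <- c(at_subs, p); at_kinds <- c(at_kinds, e$kind)
      at_sites <- c(at_sites, paste(idx$site_ids[e$sites], collapse = ","))
    }
    # cascade: a freed site whose other ligand already sits at/above its
    # association value is claimed instantly (first declared ligand wins)
    cascade <- character(0)
    repeat {
      st2 <- settle_state_partial(model, params, conc, st)
      changed <- which(st2 != st)
      if (length(changed) == 0L) break
      cascade <- c(cascade, idx$site_ids[changed])
      st <- st2
    }
    events[[length(events) + 1L]] <- list(time = t_now, substances = at_subs,
                                          kinds = at_kinds, sites = at_sites,
                                          cascade = cascade)
    times <- c(times, t_now)
    modes[[length(modes) + 1L]] <- st
    concs[[length(concs) + 1L]] <- conc
    if (length(times) > max_events) break
  }
  if (length(rates) < length(times)) rates[[length(rates) + 1L]] <- rate_of(st)
  structure(list(times = times,
                 modes = do.call(rbind, modes),
                 conc = do.call(rbind, concs),
                 rates = do.call(rbind, rates),
                 events = events, steady = steady,
                 model_name = model$name, params = params,
                 site_ids = idx$site_ids, substances = subs),
            class = "hsm_run")
}

# re-settle only free sites (binding cascade); bound sites keep hysteresis
settle_state_partial <- function(model, params, conc, st) {
  for (i in seq_along(model$sites)) {
    if (st[i] != 0L) next
    s <- model$sites[[i]]
    for (k in seq_along(s$ligands)) {
      lig <- s$ligands[k]
      if (conc[[lig]] >= thr_val(params, lig, s$id, "as")) { st[i] <- k; break }
    }
  }
  st
}

#' @export
print.hsm_run <- function(x, ...) {
  cat(sprintf("Simulation run of '%s': %d mode(s), %d event(s)%s\n",
              x$model_name, nrow(x$modes), length(x$events),
              if (x$steady) ", ended steady" else ""))
  invisible(x)
}

#' Qualitative observational sequence of a run
#'
#' One direction symbol per substance and mode: `"up"` while the gene is on,
#' `"down"` while it is off with positive concentration, and `"flat"` when
#' the concentration sits at zero with the gene off (nothing changes).
#'
#' @param run an `hsm_run`.
#' @return character matrix, one row per mode, one column per substance.
#' @export
observational_sequence <- function(run) {
  out <- matrix("flat", nrow(run$modes), length(run$substances),
                dimnames = list(NULL, run$substances))
  for (i in seq_len(nrow(out))) {
    r <- run$rates[i, ]
    c0 <- run$conc[i, ]
    out[i, ] <- ifelse(r > 0, "up", ifelse(c0 > 0, "down", "flat"))
  }
  out
}

#' Piecewise-linear trajectories of a run
#'
#' @param run an `hsm_run`.
#' @return data frame `time`, `substance`, `conc` with one row per breakpoint
#'   and substance.
#' @export
run_trajectories <- function(run) {
  n <- length(run$times)
  do.call(rbind, lapply(run$substances, function(p)
    data.frame(time = run$times, substance = p, conc = run$conc[, p],
               stringsAsFactors = FALSE)))
}

#' Does a run conform to a characteristic graph?
#'
#' The characteristic graph over-approximates all runs whose parameters
#' respect its threshold ordering: the run's mode sequence must be a walk in
#' the graph, each step using an edge whose guard names the crossing that
#' actually occurred. Parameters inducing a different threshold ordering than
#' the graph's are an error.
#'
#' @param run an `hsm_run`.
#' @param graph a `characteristic_graph` of the same model.
#' @return `TRUE` or `FALSE` (with attribute `"step"` locating the first
#'   failing transition).
#' @export
conforms <- function(run, graph) {
  # the ordering induced by the numeric thresholds must match the graph's
  for (p in names(run$params$thresholds)) {
    v <- run$params$thresholds[[p]]
    induced <- match(v, sort(unique(v)))
    names(induced) <- names(v)
    ranks <- ordering_ranks(graph$ordering, p)
    if (!identical(unname(induced[names(ranks)]), unname(ranks)))
      stop(sprintf("run parameters induce a different threshold ordering than the graph for '%s'", p))
  }
  keys <- apply(run$modes, 1L, mode_key)
  node <- match(keys, graph$keys)
  fail <- function(i) { out <- FALSE; attr(out, "step") <- i; out }
  if (anyNA(node)) return(fail(which(is.na(node))[1]))
  if (nrow(run$modes) == 1L) return(TRUE)
  for (i in seq_len(nrow(run$modes) - 1L)) {
    ev <- run$events[[i]]
    if (length(ev$substances) != 1L) return(fail(i))  # cross-substance tie
    cand <- which(graph$edges$from == node[i] & graph$edges$to == node[i + 1L] &
                    graph$edges$substance == ev$substances &
                    graph$edges$kind == ev$kinds &
                    graph$edges$sites == ev$sites)
    if (length(cand) == 0L) return(fail(i))
  }
  TRUE
}
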