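#' Construct a hybrid system model of a gene regulatory network
#'
#' A hybrid system model (HSM) couples continuous protein concentrations to
#' discrete binding-site states. It is assembled from four kinds of building
#' blocks:
#'
#' * **substances** -- molecules whose concentrations are continuous variables;
#' * **binding sites** -- discrete variables; a site is `FREE` or bound by one
#'   of its declared ligands. Each (ligand, site) pair owns an association
#'   threshold (`<site>.as`, concentration at which the free site is bound on
#'   the way up) and a dissociation threshold (`<site>.dis`, concentration at
#'   which the bound site is released on the way down), with
#'   dissociation < association giving hysteresis;
#' * **control functions** -- total discrete maps from tuples of binding-site
#'   states to a gene expression level (`0` = off, positive = on);
#' * **substance generators** -- genes: each produces one substance, its
#'   expression level given by one control function, with monotone growth
#'   while on and monotone degradation while off.
#'
#' @param name model name (metadata).
#' @param substances character vector of substance ids, or a data frame with
#'   columns `id` and `role`.
#' @param sites list of sites, each a `list(id =, ligands =)` where `ligands`
#'   is a character vector of substance ids (the order is used as a
#'   tie-breaking rule when several ligands could bind simultaneously).
#' @param control_functions list of control functions, each a
#'   `list(id =, inputs =, table =)`; `inputs` is a character vector of site
#'   ids and `table` a data frame with one column per input site holding state
#'   labels (`"FREE"` or `"BOUND:<substance>"`) plus an integer column `level`.
#'   The table must be total over the cross product of input site states.
#' @param generators list of generators, each a
#'   `list(id =, product =, control =, rates = c(growth =, degradation =))`;
#'   `rates` is optional and only used by the numeric simulator.
#' @param version model version string (metadata).
#'
#' @return An object of class `hsm_model`.
#' @seealso [validate_hsm()], [read_hsm()], [toy_two_gene_model()],
#'   [phage_lambda_model()]
#' @export
#' @examples
#' m <- toy_two_gene_model()
#' m
#' threshold_keys(m, "s2")
hsm_model <- function(name, substances, sites, control_functions, generators,
                      version = "1") {
  if (is.character(substances)) {
    substances <- data.frame(id = substances, role = "protein",
                             stringsAsFactors = FALSE)
  }
  substances <- as.data.frame(substances, stringsAsFactors = FALSE)
  if (is.null(substances$role)) substances$role <- "protein"
  m <- structure(
    list(name = as.character(name), version = as.character(version),
         substances = substances[, c("id", "role")],
         sites = lapply(sites, function(s) list(id = s$id,
                                                ligands = as.character(s$ligands))),
         control_functions = lapply(control_functions, function(f) {
           tab <- as.data.frame(f$table, stringsAsFactors = FALSE)
           tab$level <- as.integer(tab$level)
           list(id = f$id, inputs = as.character(f$inputs), table = tab)
         }),
         generators = lapply(generators, function(g) {
           r <- g$rates
           if (!is.null(r)) r <- c(growth = unname(r[["growth"]]),
                                   degradation = unname(r[["degradation"]]))
           list(id = g$id, product = g$product, control = g$control, rates = r)
         })),
    class = "hsm_model")
  m
}

#' @export
print.hsm_model <- function(x, ...) {
  cat(sprintf("Hybrid system model '%s' (version %s)\n", x$name, x$version))
  cat(sprintf("  %d substances: %s\n", nrow(x$substances),
              paste(x$substances$id, collapse = ", ")))
  cat(sprintf("  %d binding sites, %d control functions, %d generators\n",
              length(x$sites), length(x$control_functions),
              length(x$generators)))
  invisible(x)
}

site_ids <- function(model) vapply(model$sites, `[[`, "", "id")
cf_ids <- function(model) vapply(model$control_functions, `[[`, "", "id")
gen_ids <- function(model) vapply(model$generators, `[[`, "", "id")

#' State labels of a binding site
#'
#' A site with k ligands has k + 1 states: `"FREE"` plus `"BOUND:<ligand>"`
#' for each declared ligand, encoded internally as the integers `0, 1, ..., k`
#' in ligand declaration order.
#' @param site a site element of an `hsm_model`.
#' @return character vector of state labels.
#' @keywords internal
site_state_labels <- function(site) c("FREE", paste0("BOUND:", site$ligands))

#' Threshold keys of a substance
#'
#' Every (substance, site) ligand pair owns one dissociation and one
#' association threshold, rendered `"<site>.dis"` and `"<site>.as"`. Keys are
#' returned in site declaration order, dissociation first.
#'
#' @param model an [hsm_model()].
#' @param substance substance id.
#' @return character vector of threshold keys (possibly empty).
#' @export
threshold_keys <- function(model, substance) {
  keys <- character(0)
  for (s in model$sites) {
    if (substance %in% s$ligands) {
      keys <- c(keys, paste0(s$id, ".dis"), paste0(s$id, ".as"))
    }
  }
  keys
}

#' Validate a hybrid system model
#'
#' Checks the structural invariants of a model: unique ids, resolvable
#' cross-references, total and deterministic control tables, one generator per
#' substance, and supported expression levels. Problems are reported as
#' diagnostics, not errors, so that all violations can be listed at once.
#'
#' @param model an [hsm_model()].
#' @return A data frame with columns `code`, `where`, `message`; zero rows iff
#'   the model is well-formed.
#' @export
#' @examples
#' nrow(validate_hsm(phage_lambda_model()))  # 0: fixture is well-formed
validate_hsm <- function(model) {
  out <- list()
  bad <- function(code, where, message) {
    out[[length(out) + 1L]] <<- data.frame(code = code, where = where,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  subs <- model$substances$id
  sids <- site_ids(model)
  fids <- cf_ids(model)
  gids <- gen_ids(model)
  for (d in subs[duplicated(subs)]) bad("DUP_SUBSTANCE", d, "duplicated substance id")
  for (d in sids[duplicated(sids)]) bad("DUP_SITE", d, "duplicated site id")
  for (d in fids[duplicated(fids)]) bad("DUP_CONTROL", d, "duplicated control function id")
  for (d in gids[duplicated(gids)]) bad("DUP_GENERATOR", d, "duplicated generator id")

  for (s in model$sites) {
    if (length(s$ligands) < 1L || length(s$ligands) > 2L)
      bad("SITE_ARITY", s$id, "a site must declare one or two ligands")
    for (l in setdiff(s$ligands, subs))
      bad("UNKNOWN_SUBSTANCE", s$id, sprintf("ligand '%s' is not a declared substance", l))
  }

  for (f in model$control_functions) {
    unknown <- setdiff(f$inputs, sids)
    for (u in unknown)
      bad("UNKNOWN_SITE", f$id, sprintf("input site '%s' is not declared", u))
    if (length(unknown) > 0L) next
    ins <- lapply(f$inputs, function(i) {
      site_state_labels(model$sites[[match(i, sids)]])
    })
    want <- prod(vapply(ins, length, 0L))
    tab <- f$table
    if (!identical(sort(c(f$inputs, "level")), sort(names(tab)))) {
      bad("TABLE_COLUMNS", f$id, "table columns must be the input sites plus 'level'")
      next
    }
    keys <- if (length(f$inputs) == 0L) rep("", nrow(tab))
            else do.call(paste, c(tab[f$inputs], sep = "\r"))
    okstate <- rep(TRUE, nrow(tab))
    for (j in seq_along(f$inputs))
      okstate <- okstate & tab[[f$inputs[j]]] %in% ins[[j]]
    if (!all(okstate))
      bad("TABLE_BAD_STATE", f$id, "table refers to a state a site cannot take")
    if (anyDuplicated(keys))
      bad("TABLE_NOT_DETERMINISTIC", f$id, "duplicated input tuple")
    if (length(unique(keys[okstate])) < want)
      bad("TABLE_NOT_TOTAL", f$id,
          sprintf("table covers %d of %d input tuples", length(unique(keys[okstate])), want))
    if (any(tab$level < 0L) || anyNA(tab$level))
      bad("NEGATIVE_LEVEL", f$id, "expression levels must be non-negative integers")
    if (any(tab$level > 1L))
      bad("NOT_SUPPORTED", f$id,
          "expression levels above 1 are not supported by the analysis modules")
  }

  for (g in model$generators) {
    if (!g$product %in% subs)
      bad("UNKNOWN_PRODUCT", g$id, sprintf("product '%s' is not a declared substance", g$product))
    if (!g$control %in% fids)
      bad("UNKNOWN_CONTROL", g$id, sprintf("control function '%s' is not declared", g$control))
    if (!is.null(g$rates) && (length(g$rates) != 2L || any(g$rates <= 0)))
      bad("BAD_RATES", g$id, "growth and degradation rates must be positive")
  }
  prod_by <- vapply(model$generators, `[[`, "", "product")
  for (p in subs) {
    n <- sum(prod_by == p)
    if (n == 0L) bad("NO_GENERATOR", p, "substance is produced by no generator")
    if (n > 1L) bad("MULTIPLE_GENERATORS", p, "substance is produced by more than one generator")
  }
  if (length(out) == 0L) {
    data.frame(code = character(0), where = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

# Precomputed lookup structure used by the analysis modules. Site states are
# encoded as integers: 0 = FREE, k = bound by the k-th declared ligand.
hsm_index <- function(model) {
  sids <- site_ids(model)
  nstates <- vapply(model$sites, function(s) length(s$ligands) + 1L, 0L)
  subs <- model$substances$id
  bind <- lapply(subs, function(p) {
    w <- which(vapply(model$sites, function(s) p %in% s$ligands, TRUE))
    list(sites = w,
         val = vapply(w, function(i) match(p, model$sites[[i]]$ligands), 0L))
  })
  names(bind) <- subs
  gen_of <- lapply(subs, function(p) {
    hit <- which(vapply(model$generators, function(g) g$product == p, TRUE))
    if (length(hit) == 1L) model$generators[[hit]] else NULL
  })
  names(gen_of) <- subs
  cf <- lapply(model$control_functions, function(f) {
    ins <- match(f$inputs, sids)
    ns <- nstates[ins]
    radix <- c(1L, cumprod(ns))[seq_along(ns)]
    # level vector indexed by the mixed-radix code of input states
    code <- integer(nrow(f$table))
    for (j in seq_along(ins)) {
      st <- match(f$table[[f$inputs[j]]],
                  site_state_labels(model$sites[[ins[j]]])) - 1L
      code <- code + st * radix[j]
    }
    lev <- integer(prod(ns))
    lev[code + 1L] <- f$table$level
    list(id = f$id, inputs = ins, radix = radix, levels = lev)
  })
  names(cf) <- cf_ids(model)
  list(site_ids = sids, nstates = nstates, substances = subs,
       bind = bind, gen_of = gen_of, cf = cf)
}

# Convert a user-facing mode (named character vector of "FREE"/"BOUND:x") to
# the internal integer encoding, validating states.
mode_to_int <- function(model, mode) {
  sids <- site_ids(model)
  if (is.numeric(mode)) {
    stopifnot(length(mode) == length(sids))
    return(as.integer(mode))
  }
  if (is.null(names(mode)) || !setequal(names(mode), sids))
    stop("mode must be a named vector covering every site of the model")
  out <- integer(length(sids))
  for (i in seq_along(sids)) {
    lab <- site_state_labels(model$sites[[i]])
    v <- match(mode[[sids[i]]], lab)
    if (is.na(v))
      stop(sprintf("site '%s' cannot take state '%s'", sids[i], mode[[sids[i]]]))
    out[i] <- v - 1L
  }
  out
}

mode_to_labels <- function(model, state) {
  sids <- site_ids(model)
  vapply(seq_along(sids), function(i) {
    site_state_labels(model$sites[[i]])[state[i] + 1L]
  }, "")
}

mode_key <- function(state) paste(state, collapse = ".")
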