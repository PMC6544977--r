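#' Read and write hybrid system models as JSON
#'
#' The on-disk format is a documented JSON schema with top-level keys `name`,
#' `version`, `substances`, `sites`, `control_functions` and `generators`.
#' Control tables are serialized as arrays of `{state_tuple, level}` records,
#' with site states encoded `"FREE"` or `"BOUND:<substance>"`. Writing is
#' canonical (fixed key order, fixed record order), so
#' `write_hsm(read_hsm(path), path2)` produces a byte-identical file.
#'
#' @param path file path.
#' @return `read_hsm()` returns an [hsm_model()]; `write_hsm()` returns `path`
#'   invisibly.
#' @export
read_hsm <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- function(obj, field, where) {
    if (is.null(obj[[field]]))
      stop(sprintf("model schema violation at %s: required field '%s' is missing",
                   where, field), call. = FALSE)
    obj[[field]]
  }
  for (f in c("substances", "sites", "control_functions", "generators", "name"))
    need(x, f, "$")
  subs <- do.call(rbind, lapply(seq_along(x$substances), function(i) {
    s <- x$substances[[i]]
    where <- sprintf("$.substances[%d]", i)
    data.frame(id = need(s, "id", where),
               role = if (is.null(s$role)) "protein" else s$role,
               stringsAsFactors = FALSE)
  }))
  sites <- lapply(seq_along(x$sites), function(i) {
    s <- x$sites[[i]]
    where <- sprintf("$.sites[%d]", i)
    list(id = need(s, "id", where),
         ligands = unlist(need(s, "ligands", where)))
  })
  cfs <- lapply(seq_along(x$control_functions), function(i) {
    f <- x$control_functions[[i]]
    where <- sprintf("$.control_functions[%d]", i)
    inputs <- unlist(need(f, "inputs", where))
    rows <- need(f, "table", where)
    tab <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
      tup <- unlist(need(r, "state_tuple", paste0(where, ".table")))
      if (length(tup) != length(inputs))
        stop(sprintf("model schema violation at %s.table: state_tuple length %d, expected %d",
                     where, length(tup), length(inputs)), call. = FALSE)
      tup
    })), stringsAsFactors = FALSE)
    names(tab) <- inputs
    tab$level <- vapply(rows, function(r)
      as.integer(need(r, "level", paste0(where, ".table"))), 0L)
    list(id = need(f, "id", where), inputs = inputs, table = tab)
  })
  gens <- lapply(seq_along(x$generators), function(i) {
    g <- x$generators[[i]]
    where <- sprintf("$.generators[%d]", i)
    rates <- NULL
    if (!is.null(g$rates))
      rates <- c(growth = as.numeric(g$rates$growth),
                 degradation = as.numeric(g$rates$degradation))
    list(id = need(g, "id", where), product = need(g, "product", where),
         control = need(g, "control", where), rates = rates)
  })
  hsm_model(name = x$name, substances = subs, sites = sites,
            control_functions = cfs, generators = gens,
            version = if (is.null(x$version)) "1" else x$version)
}

#' @rdname read_hsm
#' @param model an [hsm_model()].
#' @export
write_hsm <- function(model, path) {
  ser <- list(
    name = model$name,
    version = model$version,
    substances = lapply(seq_len(nrow(model$substances)), function(i)
      list(id = model$substances$id[i], role = model$substances$role[i])),
    sites = lapply(model$sites, function(s)
      list(id = s$id, ligands = as.list(s$ligands))),
    control_functions = lapply(model$control_functions, function(f) {
      tab <- f$table
      ord <- do.call(order, unname(tab[f$inputs]))
      tab <- tab[ord, , drop = FALSE]
      list(id = f$id, inputs = as.list(f$inputs),
           table = lapply(seq_len(nrow(tab)), function(i)
             list(state_tuple = as.list(unname(unlist(tab[i, f$inputs]))),
                  level = tab$level[i])))
    }),
    generators = lapply(model$generators, function(g) {
      out <- list(id = g$id, product = g$product, control = g$control)
      if (!is.null(g$rates))
        out$rates <- list(growth = unname(g$rates[["growth"]]),
                          degradation = unname(g$rates[["degradation"]]))
      out
    }))
  json <- jsonlite::toJSON(ser, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read and write threshold-ordering constraint files
#'
#' Constraint files are JSON objects keyed by substance id; each entry may
#' have `chains`, `adjacency_blocks`, `permitted_interleavings` and
#' `equalities` (see [ordering_constraints()]).
#'
#' @param path file path.
#' @return `read_constraints()` returns a named list of
#'   [ordering_constraints()]; `write_constraints()` returns `path` invisibly.
#' @export
read_constraints <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(x, function(cs) {
    ordering_constraints(
      chains = lapply(cs$chains, unlist),
      adjacency_blocks = lapply(cs$adjacency_blocks, unlist),
      permitted_interleavings = lapply(cs$permitted_interleavings,
                                       function(o) lapply(o, unlist)),
      equalities = lapply(cs$equalities, unlist))
  })
}

#' @rdname read_constraints
#' @param constraints named list of [ordering_constraints()] keyed by substance.
#' @export
write_constraints <- function(constraints, path) {
  ser <- lapply(constraints, function(cs) {
    list(chains = lapply(cs$chains, as.list),
         adjacency_blocks = lapply(cs$adjacency_blocks, as.list),
         permitted_interleavings = lapply(cs$permitted_interleavings,
                                          function(o) lapply(o, as.list)),
         equalities = lapply(cs$equalities, as.list))
  })
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
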