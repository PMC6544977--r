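# Build a total control table over the cross product of input site states,
# with the level given by a predicate on the named state tuple.
control_table <- function(sites, inputs, fun) {
  sids <- vapply(sites, `[[`, "", "id")
  labs <- lapply(inputs, function(i) site_state_labels(sites[[match(i, sids)]]))
  names(labs) <- inputs
  tab <- expand.grid(labs, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tab$level <- vapply(seq_len(nrow(tab)), function(r)
    as.integer(fun(as.list(tab[r, inputs, drop = FALSE]))), 0L)
  tab
}

#' The two-gene toy network
#'
#' A minimal hybrid system model: gene `s1` carries a negative feedback loop
#' on itself (via site `b1`), gene `s2` a negative feedback loop on itself
#' (via `b3`) and a positive feedback on `s1` (via `b2`). Substance `s2` binds
#' two sites, so its four thresholds `b2.dis, b2.as, b3.dis, b3.as` admit six
#' orderings, each yielding its own characteristic graph.
#'
#' Control logic: `s1` is expressed iff `b1` is free and `b2` is bound by
#' `s2`; `s2` is expressed iff `b3` is free.
#'
#' @return an [hsm_model()].
#' @export
#' @examples
#' toy_two_gene_model()
toy_two_gene_model <- function() {
  sites <- list(list(id = "b1", ligands = "s1"),
                list(id = "b2", ligands = "s2"),
                list(id = "b3", ligands = "s2"))
  hsm_model(
    name = "toy_two_gene",
    substances = c("s1", "s2"),
    sites = sites,
    control_functions = list(
      list(id = "f1", inputs = c("b1", "b2"),
           table = control_table(sites, c("b1", "b2"), function(s)
             s$b1 == "FREE" && s$b2 == "BOUND:s2")),
      list(id = "f2", inputs = "b3",
           table = control_table(sites, "b3", function(s) s$b3 == "FREE"))),
    generators = list(
      list(id = "s1", product = "s1", control = "f1",
           rates = c(growth = 1, degradation = 1)),
      list(id = "s2", product = "s2", control = "f2",
           rates = c(growth = 1, degradation = 1))))
}

#' The phage lambda lysis-lysogeny switch model
#'
#' A hybrid system model of the phage lambda genetic switch with ten binding
#' sites, six control functions (`P_Q`, `P_ME`, `P_R`, `P_RN`, `P_int`,
#' `P_L`) and eleven substance generators (`cI`, `cro`, `cII`, `O`, `P`, `Q`,
#' `int`, `N`, `cIII`, `xis`, `struc`). The operator sites `bOR1..bOR3` and
#' `bOL1..bOL3` can each be free, bound by Cro, or bound by repressor;
#' repressor affinity descends along `bOR1, bOR2, bOR3` (association
#' thresholds ascend) and along `bOL1, bOL2, bOL3`, while Cro's affinity
#' order is reversed. `bQ`, `bN`, `bCII-1` and `bCII-2` bind one protein
#' each.
#'
#' Control logic (truth tables reconstructed from the switch's regulatory
#' roles; operons are modelled as several generators sharing one control
#' function):
#' * `P_R` on iff `bOR1` and `bOR2` are free (drives `cro`, `cII`, `O`, `P`);
#' * `P_RN` on iff `bN` is bound by N and `bOR1`, `bOR2` are free (drives
#'   `Q`; this realizes anti-terminated read-through past `t_R2`);
#' * `P_ME` on iff `bCII-1` is bound by CII, or `bOR3` is free and `bOR2` is
#'   not bound by repressor (drives `cI`: CII-triggered establishment, Cro on
#'   `bOR3` silencing, and repressor's own negative loop at `bOR2`);
#' * `P_L` on iff `bOL1` and `bOL2` are free (drives `N`, `cIII`, `xis`);
#' * `P_int` on iff `bCII-2` is bound by CII (drives `int`);
#' * `P_Q` on iff `bQ` is bound by Q (drives the structural genes `struc`).
#'
#' @return an [hsm_model()].
#' @seealso [phage_constraint_set()] for the admissible threshold orderings.
#' @export
phage_lambda_model <- function() {
  op <- function(id) list(id = id, ligands = c("Cro", "repressor"))
  sites <- list(op("bOR1"), op("bOR2"), op("bOR3"),
                op("bOL1"), op("bOL2"), op("bOL3"),
                list(id = "bQ", ligands = "Q"),
                list(id = "bN", ligands = "N"),
                list(id = "bCII-1", ligands = "CII"),
                list(id = "bCII-2", ligands = "CII"))
  hsm_model(
    name = "phage_lambda",
    substances = c("Cro", "repressor", "CII", "N", "Q",
                   "O", "P", "CIII", "Xis", "Int", "Struc"),
    sites = sites,
    control_functions = list(
      list(id = "P_R", inputs = c("bOR1", "bOR2"),
           table = control_table(sites, c("bOR1", "bOR2"), function(s)
             s$bOR1 == "FREE" && s$bOR2 == "FREE")),
      list(id = "P_RN", inputs = c("bN", "bOR1", "bOR2"),
           table = control_table(sites, c("bN", "bOR1", "bOR2"), function(s)
             s$bN == "BOUND:N" && s$bOR1 == "FREE" && s$bOR2 == "FREE")),
      list(id = "P_ME", inputs = c("bCII-1", "bOR2", "bOR3"),
           table = control_table(sites, c("bCII-1", "bOR2", "bOR3"), function(s)
             s$bOR3 == "FREE" &&
               (s$bOR2 != "BOUND:repressor" || s[["bCII-1"]] == "BOUND:CII"))),
      list(id = "P_L", inputs = c("bOL1", "bOL2"),
           table = control_table(sites, c("bOL1", "bOL2"), function(s)
             s$bOL1 == "FREE" && s$bOL2 == "FREE")),
      list(id = "P_int", inputs = "bCII-2",
           table = control_table(sites, "bCII-2", function(s)
             s[["bCII-2"]] == "BOUND:CII")),
      list(id = "P_Q", inputs = "bQ",
           table = control_table(sites, "bQ", function(s) s$bQ == "BOUND:Q"))),
    generators = list(
      list(id = "cI",    product = "repressor", control = "P_ME"),
      list(id = "cro",   product = "Cro",       control = "P_R"),
      list(id = "cII",   product = "CII",       control = "P_R"),
      list(id = "O",     product = "O",         control = "P_R"),
      list(id = "P",     product = "P",         control = "P_R"),
      list(id = "Q",     product = "Q",         control = "P_RN"),
      list(id = "N",     product = "N",         control = "P_L"),
      list(id = "cIII",  product = "CIII",      control = "P_L"),
      list(id = "xis",   product = "Xis",       control = "P_L"),
      list(id = "int",   product = "Int",       control = "P_int"),
      list(id = "struc", product = "Struc",     control = "P_Q")))
}

# Level-aligned cascades with the two level-2 blocks interleaved: the only
# complete orderings admitted as exceptions to per-site adjacency.
aligned_interleavings <- function(first, second, lv) {
  blk <- function(casc, i) c(paste0(casc, lv[i], ".dis"), paste0(casc, lv[i], ".as"))
  mix <- function(a, b) c(paste0(a, lv[2], ".dis"), paste0(b, lv[2], ".dis"),
                          paste0(a, lv[2], ".as"), paste0(b, lv[2], ".as"))
  list(c(blk(first, 1), blk(second, 1), mix(first, second),
         blk(first, 3), blk(second, 3)),
       c(blk(second, 1), blk(first, 1), mix(second, first),
         blk(second, 3), blk(first, 3)))
}

#' Threshold-ordering constraints for the phage lambda model
#'
#' Returns the constraint sets under which the lysis-lysogeny switch is
#' analysed. Both Cro and repressor bind the six operator sites, so each has
#' twelve thresholds; the constraints encode
#'
#' * the known affinity precedence within each operator cascade: for
#'   repressor, association thresholds ascend along `bOR1, bOR2, bOR3` and
#'   along `bOL1, bOL2, bOL3`; for Cro the order is reversed;
#' * per-site adjacency: a site's dissociation and association thresholds are
#'   so close that no other threshold of the same protein falls between them;
#' * for the `"free_interleave"` variant, two permitted interleavings of the
#'   `bOR2`/`bOL2` threshold blocks (22 orderings per protein, 484 joint);
#' * for the `"or2_ol2_equal"` variant, `bOR2` and `bOL2` thresholds tied for
#'   both proteins (4 orderings per protein, 16 joint).
#'
#' CII's two thresholds for `bCII-2` lie below those for `bCII-1` (its binding
#' concentration for `bCII-1` is the higher one), making CII's ordering
#' unique; Q and N bind a single site each.
#'
#' @param variant `"free_interleave"` or `"or2_ol2_equal"`.
#' @return named list of [ordering_constraints()] keyed by substance id,
#'   suitable for [enumerate_joint_orderings()].
#' @export
#' @examples
#' cs <- phage_constraint_set("free_interleave")
#' m <- phage_lambda_model()
#' length(enumerate_orderings(m, "Cro", cs$Cro))  # 22
phage_constraint_set <- function(variant = c("free_interleave", "or2_ol2_equal")) {
  variant <- match.arg(variant)
  casc_keys <- function(casc, lv)
    as.vector(rbind(paste0(casc, lv, ".dis"), paste0(casc, lv, ".as")))
  adj_all <- lapply(c(paste0("bOR", 1:3), paste0("bOL", 1:3)), function(s)
    c(paste0(s, ".dis"), paste0(s, ".as")))
  cro_lv <- 3:1; rep_lv <- 1:3
  base <- function(lv, inter) {
    ordering_constraints(
      chains = list(casc_keys("bOR", lv), casc_keys("bOL", lv)),
      adjacency_blocks = adj_all,
      permitted_interleavings = inter,
      equalities = if (variant == "or2_ol2_equal")
        list(c("bOR2.dis", "bOL2.dis"), c("bOR2.as", "bOL2.as")) else list())
  }
  inter_cro <- inter_rep <- list()
  if (variant == "free_interleave") {
    inter_cro <- aligned_interleavings("bOR", "bOL", cro_lv)
    inter_rep <- aligned_interleavings("bOR", "bOL", rep_lv)
  }
  list(
    Cro = base(cro_lv, inter_cro),
    repressor = base(rep_lv, inter_rep),
    CII = ordering_constraints(
      chains = list(c("bCII-2.dis", "bCII-2.as", "bCII-1.dis", "bCII-1.as")),
      adjacency_blocks = list(c("bCII-2.dis", "bCII-2.as"),
                              c("bCII-1.dis", "bCII-1.as"))))
}

#' All joint threshold orderings examined for the phage lambda model
#'
#' Concatenates the joint orderings of the `"free_interleave"` (484) and
#' `"or2_ol2_equal"` (16) constraint variants: 500 in total, duplicate-free.
#'
#' @param model the phage lambda model; defaults to [phage_lambda_model()].
#' @return list of 500 joint `threshold_ordering` objects.
#' @export
phage_orderings <- function(model = phage_lambda_model()) {
  out <- c(enumerate_joint_orderings(model, phage_constraint_set("free_interleave")),
           enumerate_joint_orderings(model, phage_constraint_set("or2_ol2_equal")))
  stopifnot(!anyDuplicated(vapply(out, ordering_string, "")))
  out
}

#' Generate a random hybrid system model
#'
#' Draws a structurally valid model with random ligand assignments and random
#' binary control tables, for property testing. The generator is pure per
#' seed: the same seed always yields the same model, and the caller's random
#' number generator state is left untouched.
#'
#' @param seed integer seed.
#' @param n_genes number of genes (and substances), at least 1.
#' @param n_sites number of binding sites, at least 0.
#' @param max_ligands maximal ligands per site (1 or 2).
#' @return an [hsm_model()].
#' @export
random_hsm <- function(seed, n_genes = 2, n_sites = 3, max_ligands = 2) {
  stopifnot(n_genes >= 1, n_sites >= 0, max_ligands %in% 1:2)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  subs <- paste0("g", seq_len(n_genes))
  sites <- lapply(seq_len(n_sites), function(i) {
    k <- sample(seq_len(min(max_ligands, n_genes)), 1L)
    list(id = paste0("r", i), ligands = sample(subs, k))
  })
  cfs <- lapply(seq_len(n_genes), function(i) {
    n_in <- if (n_sites == 0L) 0L else sample(0:min(3L, n_sites), 1L)
    inputs <- if (n_in > 0L) sort(sample(vapply(sites, `[[`, "", "id"), n_in))
              else character(0)
    if (n_in == 0L) {
      tab <- data.frame(level = sample(0:1, 1L))
    } else {
      tab <- control_table(sites, inputs, function(s) sample(0:1, 1L))
    }
    list(id = paste0("f", i), inputs = inputs, table = tab)
  })
  gens <- lapply(seq_len(n_genes), function(i)
    list(id = paste0("gene", i), product = subs[i], control = paste0("f", i),
         rates = c(growth = round(stats::runif(1, 0.5, 2), 3),
                   degradation = round(stats::runif(1, 0.5, 2), 3))))
  hsm_model(name = sprintf("random_%d", seed), substances = subs,
            sites = sites, control_functions = cfs, generators = gens)
}
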