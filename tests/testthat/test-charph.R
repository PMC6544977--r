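free_mode <- function(model) {
  stats::setNames(rep("FREE", length(model$sites)),
                  vapply(model$sites, `[[`, "", "id"))
}

test_that("mode consistency matches the rational-assignment oracle", {
  m <- toy_two_gene_model()
  jo <- toy_joint_orderings(m)
  # an all-free mode imposes no lower bounds, hence is always consistent
  for (o in jo) expect_true(is_consistent_mode(m, o, free_mode(m)))
  # ordering 3: b2.dis < b3.dis < b3.as < b2.as with both s2 sites occupied
  mode <- c(b1 = "FREE", b2 = "BOUND:s2", b3 = "BOUND:s2")
  expect_true(is_consistent_mode(m, jo[[3]], mode))
  # occupying only the weaker site contradicts hysteresis under ordering 1
  bad <- c(b1 = "FREE", b2 = "FREE", b3 = "BOUND:s2")
  expect_false(is_consistent_mode(m, jo[[1]], bad))
  expect_identical(attr(is_consistent_mode(m, jo[[1]], bad), "substance"), "s2")

  set.seed(7)
  for (rep_ in 1:60) {
    o <- jo[[sample(6L, 1L)]]
    md <- random_mode_labels(m)
    expect_identical(unclass(is_consistent_mode(m, o, md))[1],
                     oracle_consistent(m, o, md))
  }
})

test_that("repressor cannot occupy bOR2 while bOR1 stays free", {
  pm <- phage_lambda_model()
  # pick an ordering whose repressor O_L cascade sits entirely above O_R,
  # so only the O_R sites constrain the occupancy pattern under test
  o <- Filter(function(o) {
    r <- ordering_ranks(o, "repressor")
    r[["bOR3.as"]] < r[["bOL1.dis"]]
  }, phage_orderings(pm))[[1]]
  mode <- free_mode(pm)
  mode["bOR2"] <- "BOUND:repressor"
  got <- is_consistent_mode(pm, o, mode)
  expect_false(got)
  expect_identical(attr(got, "substance"), "repressor")
  mode["bOR1"] <- "BOUND:repressor"
  expect_true(is_consistent_mode(pm, o, mode))
})

test_that("direction vectors are pure functions of the control tables", {
  m <- toy_two_gene_model()
  d <- direction_vector(m, c(b1 = "FREE", b2 = "BOUND:s2", b3 = "FREE"))
  expect_identical(d, c(s1 = "up", s2 = "up"))
  d2 <- direction_vector(m, c(b1 = "BOUND:s1", b2 = "FREE", b3 = "BOUND:s2"))
  expect_identical(d2, c(s1 = "down", s2 = "down"))
  # a model whose tables are constant zero points every substance down
  sites <- list(list(id = "r1", ligands = "g1"))
  m0 <- hsm_model("allz", "g1", sites,
                  list(list(id = "f1", inputs = "r1",
                            table = data.frame(r1 = c("FREE", "BOUND:g1"),
                                               level = c(0L, 0L)))),
                  list(list(id = "gene1", product = "g1", control = "f1")))
  expect_identical(direction_vector(m0, c(r1 = "FREE")), c(g1 = "down"))
})

test_that("a rising substance can only cross its minimal free association rank", {
  m <- toy_two_gene_model()
  o <- toy_joint_orderings(m)[[3]]  # b2.dis < b3.dis < b3.as < b2.as
  evs <- enabled_events(m, o, free_mode(m))
  expect_length(evs, 1L)
  expect_identical(evs[[1]]$substance, "s2")
  expect_identical(evs[[1]]$guard, "s2 >= b3.as")
  expect_identical(evs[[1]]$targets[[1]][["b3"]], "BOUND:s2")
  # a silent gene with nothing bound has no events at all
  sites <- list(list(id = "r1", ligands = "g1"))
  m0 <- hsm_model("allz", "g1", sites,
                  list(list(id = "f1", inputs = "r1",
                            table = data.frame(r1 = c("FREE", "BOUND:g1"),
                                               level = c(0L, 0L)))),
                  list(list(id = "gene1", product = "g1", control = "f1")))
  o0 <- enumerate_orderings(m0, "g1")[[1]]
  expect_length(enabled_events(m0, o0, c(r1 = "FREE")), 0L)
  # under ordering 1 (b2 block below b3 block) the lone-b3 mode is impossible
  expect_error(enabled_events(m, toy_joint_orderings(m)[[1]],
                              c(b1 = "FREE", b2 = "FREE", b3 = "BOUND:s2")),
               "inconsistent")
})

test_that("thresholds tied by the equality variant fire as one compound event", {
  pm <- phage_lambda_model()
  o <- enumerate_joint_orderings(pm, phage_constraint_set("or2_ol2_equal"))[[1]]
  mode <- free_mode(pm)
  mode["bOR3"] <- "BOUND:Cro"; mode["bOL3"] <- "BOUND:Cro"
  evs <- enabled_events(pm, o, mode)
  cro <- Filter(function(e) e$substance == "Cro", evs)
  expect_length(cro, 1L)
  expect_setequal(cro[[1]]$sites, c("bOR2", "bOL2"))
  expect_identical(cro[[1]]$guard, "Cro >= bOR2.as & Cro >= bOL2.as")
  tgt <- cro[[1]]$targets[[1]]
  expect_identical(unname(tgt[c("bOR2", "bOL2")]),
                   c("BOUND:Cro", "BOUND:Cro"))
})

test_that("a model without binding sites has a one-node, edgeless graph", {
  m <- hsm_model("constant", "g1", sites = list(),
                 list(list(id = "f1", inputs = character(0),
                           table = data.frame(level = 1L))),
                 list(list(id = "gene1", product = "g1", control = "f1")))
  o <- enumerate_orderings(m, "g1")[[1]]
  g <- characteristic_graph(m, o)
  expect_identical(nrow(g$nodes), 1L)
  expect_identical(nrow(g$edges), 0L)
})

test_that("every toy graph stays below ten modes and rebuilds identically", {
  m <- toy_two_gene_model()
  for (o in toy_joint_orderings(m)) {
    g <- characteristic_graph(m, o)
    expect_lt(nrow(g$nodes), 10L)
    g2 <- characteristic_graph(m, o)
    expect_identical(g$nodes, g2$nodes)
    expect_identical(g$edges, g2$edges)
    # every node passes the consistency predicate
    for (i in seq_len(nrow(g$nodes))) {
      lab <- stats::setNames(hsmattract:::mode_to_labels(m, g$nodes[i, ]),
                             colnames(g$nodes))
      expect_true(is_consistent_mode(m, o, lab))
    }
  }
})

test_that("reachable graphs of Table-2 orderings 1/2 and 5/6 are isomorphic", {
  m <- toy_two_gene_model()
  jo <- toy_joint_orderings(m)
  gs <- lapply(jo, function(o)
    characteristic_graph(m, o, seeds = list(free_mode(m))))
  sig <- vapply(gs, graph_signature, "")
  expect_identical(sig[1], sig[2])
  expect_identical(sig[5], sig[6])
  expect_false(sig[1] == sig[3])
})

test_that("explicit seeds close under events and reject inconsistent modes", {
  m <- toy_two_gene_model()
  o <- toy_joint_orderings(m)[[3]]
  g_all <- characteristic_graph(m, o)
  g_reach <- characteristic_graph(m, o, seeds = list(free_mode(m)))
  expect_lte(nrow(g_reach$nodes), nrow(g_all$nodes))
  expect_true(all(g_reach$keys %in% g_all$keys))
  expect_error(
    characteristic_graph(m, toy_joint_orderings(m)[[1]],
                         seeds = list(c(b1 = "FREE", b2 = "FREE", b3 = "BOUND:s2"))),
    "s2")
})

test_that("the consistent-mode set is strictly pruned for phage lambda", {
  pm <- phage_lambda_model()
  o <- phage_orderings(pm)[[1]]
  g <- characteristic_graph(pm, o)
  bound <- prod(vapply(pm$sites, function(s) length(s$ligands) + 1L, 0L))
  expect_identical(bound, 3L^6L * 2L^4L)
  expect_lt(nrow(g$nodes), bound)
})

test_that("hysteresis holds along random walks of built graphs", {
  set.seed(11)
  m <- toy_two_gene_model()
  for (o in toy_joint_orderings(m)) {
    g <- characteristic_graph(m, o)
    for (s in sample(nrow(g$nodes), 3L))
      expect_true(walk_hysteresis_ok(g, s, steps = 150L))
  }
  for (seed in c(3, 14)) {
    rm_ <- random_hsm(seed, n_genes = 2, n_sites = 3)
    jo <- enumerate_joint_orderings(rm_)
    g <- characteristic_graph(rm_, jo[[1]])
    if (nrow(g$edges) > 0L)
      expect_true(walk_hysteresis_ok(g, sample(nrow(g$nodes), 1L)))
  }
})
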