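igraph_from_edges <- function(n, from, to) {
  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (length(from) > 0L) g <- igraph::add_edges(g, rbind(from, to))
  g
}

test_that("SCC partition matches the transitive-closure oracle", {
  g1 <- igraph_from_edges(1L, integer(0), integer(0))
  expect_identical(scc_partition(g1), 1L)
  g3 <- igraph_from_edges(3L, c(1L, 2L, 3L), c(2L, 3L, 1L))
  expect_identical(scc_partition(g3), c(1L, 1L, 1L))
  set.seed(5)
  for (rep_ in 1:30) {
    n <- sample(2:8, 1L)
    m <- sample(0:(2L * n), 1L)
    from <- sample(n, m, replace = TRUE)
    to <- sample(n, m, replace = TRUE)
    got <- scc_partition(igraph_from_edges(n, from, to))
    want <- oracle_scc(n, from, to)
    expect_identical(partition_sets(got), partition_sets(want))
  }
})

test_that("progress indicators follow the monotone-escape definition", {
  m <- toy_two_gene_model()
  jo <- toy_joint_orderings(m)
  g <- characteristic_graph(m, jo[[1]])
  # all-free mode: s2 rises with free bindable sites -> progress indicator;
  # s1 falls with nothing bound -> mere decay, no indicator
  i <- match(hsmattract:::mode_key(c(0L, 0L, 0L)), g$keys)
  expect_identical(progress_indicators(g, i), "s2")
  # attractors never retain a progress indicator (re-checked independently)
  for (o in jo) {
    gg <- characteristic_graph(m, o)
    for (r in find_attractors(gg)) {
      if (r$is_attractor) {
        expect_length(progress_indicators(gg, r$members), 0L)
      }
    }
  }
})

test_that("a falling substance with no occupied site does not force an exit", {
  pm <- phage_lambda_model()
  sw <- NULL
  o <- phage_orderings(pm)[[1]]
  g <- characteristic_graph(pm, o)
  att <- Filter(function(r) r$is_attractor, find_attractors(g))
  lys <- att[[which(vapply(att, function(a) "repressor" %in% a$guard_substances, TRUE))]]
  # in lysogeny Q decays towards zero with bQ free throughout: not an indicator
  expect_false("Q" %in% progress_indicators(g, lys$members))
  expect_true(all(g$dirs[lys$members, "Q"] == -1L))
  expect_true(all(g$nodes[lys$members, "bQ"] == 0L))
})

test_that("attractor structure classification distinguishes cycles from branches", {
  m <- toy_two_gene_model()
  jo <- toy_joint_orderings(m)
  att6 <- Filter(function(r) r$is_attractor,
                 find_attractors(characteristic_graph(m, jo[[6]])))
  expect_length(att6, 1L)
  expect_identical(att6[[1]]$structure, "single_cycle")
  expect_identical(att6[[1]]$n_modes, 2L)
  att4 <- Filter(function(r) r$is_attractor,
                 find_attractors(characteristic_graph(m, jo[[4]])))
  expect_identical(att4[[1]]$structure, "branched")
})

test_that("signatures are invariant under node insertion order, fingerprints too", {
  m <- toy_two_gene_model()
  o <- toy_joint_orderings(m)[[3]]
  g <- characteristic_graph(m, o)
  modes <- lapply(seq_len(nrow(g$nodes)), function(i)
    stats::setNames(hsmattract:::mode_to_labels(m, g$nodes[i, ]),
                    colnames(g$nodes)))
  set.seed(3)
  ref <- NULL
  for (rep_ in 1:4) {
    gp <- characteristic_graph(m, o, seeds = sample(modes))
    att <- Filter(function(r) r$is_attractor, find_attractors(gp))
    sigs <- sort(vapply(att, function(a) attractor_signature(gp, a), ""))
    fps <- sort(vapply(att, function(a) attractor_fingerprint(gp, a), ""))
    if (is.null(ref)) ref <- list(sigs, fps)
    expect_identical(list(sigs, fps), ref)
  }
})

test_that("signatures drop site identities but keep the behaviour", {
  # the same negative auto-regulatory loop wired through differently named
  # sites must give byte-identical signatures
  build <- function(site) {
    sites <- list(list(id = site, ligands = "g1"))
    hsm_model("loop", "g1", sites,
              list(list(id = "f1", inputs = site,
                        table = data.frame(stats::setNames(list(
                          c("FREE", "BOUND:g1")), site), level = c(1L, 0L)))),
              list(list(id = "gene1", product = "g1", control = "f1")))
  }
  sig_of <- function(model) {
    o <- enumerate_orderings(model, "g1")[[1]]
    g <- characteristic_graph(model, o)
    att <- Filter(function(r) r$is_attractor, find_attractors(g))
    expect_length(att, 1L)
    attractor_signature(g, att[[1]])
  }
  expect_identical(sig_of(build("siteA")), sig_of(build("siteB")))
  # fingerprints do see the site identity
  fp_of <- function(model) {
    o <- enumerate_orderings(model, "g1")[[1]]
    g <- characteristic_graph(model, o)
    att <- Filter(function(r) r$is_attractor, find_attractors(g))
    attractor_fingerprint(g, att[[1]])
  }
  expect_false(fp_of(build("siteA")) == fp_of(build("siteB")))
})

test_that("SCC-level hysteresis rules out uniform direction across opposite guards", {
  m <- toy_two_gene_model()
  for (o in toy_joint_orderings(m))
    expect_true(scc_hysteresis_ok(characteristic_graph(m, o)))
  pm <- phage_lambda_model()
  expect_true(scc_hysteresis_ok(characteristic_graph(pm, phage_orderings(pm)[[1]])))
})

test_that("condition mining on a single ordering returns that ordering's relations", {
  m <- toy_two_gene_model()
  jo <- toy_joint_orderings(m)
  sw <- sweep_orderings(m, jo[3])
  cond <- mine_conditions(sw)
  cond1 <- cond[cond$signature_id == 1L, ]
  allrel <- cond1[cond1$scope == "all" & cond1$substance == "s2", ]
  # ordering 3: b2.dis < b3.dis < b3.as < b2.as -> 6 pairwise relations
  expect_identical(nrow(allrel), 6L)
  expect_true(any(allrel$key_a == "b3.as" & allrel$key_b == "b2.as"))
  # with one ordering, "none" relations are exactly the reversed "all" ones
  nonerel <- cond1[cond1$scope == "none" & cond1$substance == "s2", ]
  expect_identical(nrow(nonerel), 6L)
})

test_that("toy sweep aggregates fingerprints and signatures reproducibly", {
  m <- toy_two_gene_model()
  jo <- toy_joint_orderings(m)
  sw <- sweep_orderings(m, jo)
  expect_identical(nrow(sw$table), 6L)
  expect_identical(sw$table$n_attractors, c(1L, 1L, 2L, 1L, 1L, 1L))
  sw2 <- sweep_orderings(m, jo)
  expect_identical(sw$table, sw2$table)
  expect_identical(sw$signatures, sw2$signatures)
  # aggregates are recomputable from the per-ordering rows
  from_rows <- sort(unique(unlist(lapply(strsplit(sw$table$signatures, ","),
                                         as.integer))))
  expect_identical(from_rows, seq_along(sw$signatures))
})
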