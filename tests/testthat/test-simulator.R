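toy_params <- function() {
  hsm_params(toy_two_gene_model(), thresholds = list(
    s1 = c(b1.dis = 1, b1.as = 3),
    s2 = c(b2.dis = 1, b2.as = 3, b3.dis = 2, b3.as = 4)))
}

test_that("parameter validation enforces hysteresis and positive rates", {
  m <- toy_two_gene_model()
  expect_error(hsm_params(m, thresholds = list(
    s1 = c(b1.dis = 3, b1.as = 1),
    s2 = c(b2.dis = 1, b2.as = 3, b3.dis = 2, b3.as = 4))), "strictly below")
  expect_error(hsm_params(m, thresholds = list(
    s1 = c(b1.dis = 1, b1.as = 3),
    s2 = c(b2.dis = 1, b2.as = 3, b3.dis = 2, b3.as = 4)),
    rates = list(s1 = c(growth = 0, degradation = 1))), "positive")
  expect_error(hsm_params(m, thresholds = list(
    s1 = c(b1.dis = 1, b1.as = 3), s2 = c(b2.dis = 1, b2.as = 3))), "cover")
})

test_that("settling binds exactly the sites whose association value is reached", {
  m <- toy_two_gene_model()
  p <- toy_params()
  expect_identical(settle_initial_mode(m, p, c(s1 = 0, s2 = 0)),
                   c(b1 = "FREE", b2 = "FREE", b3 = "FREE"))
  # s2 above b2.as and b3.as binds both of its sites
  expect_identical(settle_initial_mode(m, p, c(s1 = 0, s2 = 5))[c("b2", "b3")],
                   c(b2 = "BOUND:s2", b3 = "BOUND:s2"))
  # a concentration exactly at the association value is treated as crossed
  expect_identical(settle_initial_mode(m, p, c(s1 = 3, s2 = 3))[c("b1", "b2")],
                   c(b1 = "BOUND:s1", b2 = "BOUND:s2"))
  pm <- phage_lambda_model()
  pp <- params_for_ordering(pm, phage_orderings(pm)[[1]])
  conc <- stats::setNames(rep(0, 11), pm$substances$id)
  conc["repressor"] <- pp$thresholds$repressor[["bOR2.as"]]
  mode <- settle_initial_mode(pm, pp, conc)
  expect_identical(unname(mode[c("bOR1", "bOR2", "bOR3")]),
                   c("BOUND:repressor", "BOUND:repressor", "FREE"))
})

test_that("first crossing of an always-on gene happens at t = a / g", {
  sites <- list(list(id = "r1", ligands = "g1"))
  m <- hsm_model("ramp", "g1", sites,
                 list(list(id = "f1", inputs = character(0),
                           table = data.frame(level = 1L))),
                 list(list(id = "gene1", product = "g1", control = "f1")))
  p <- hsm_params(m, thresholds = list(g1 = c(r1.dis = 1, r1.as = 3)),
                  rates = list(gene1 = c(growth = 2, degradation = 1)))
  run <- simulate_hsm(m, p, init = c(g1 = 0), max_events = 3)
  expect_equal(run$times[2], 3 / 2)
  expect_identical(run$modes[2, 1], 1L)
  expect_true(run$steady)  # bound and still growing: no further crossing
})

test_that("a silent network is a single steady mode", {
  sites <- list(list(id = "r1", ligands = "g1"))
  m <- hsm_model("allz", "g1", sites,
                 list(list(id = "f1", inputs = "r1",
                           table = data.frame(r1 = c("FREE", "BOUND:g1"),
                                              level = c(0L, 0L)))),
                 list(list(id = "gene1", product = "g1", control = "f1")))
  p <- hsm_params(m, thresholds = list(g1 = c(r1.dis = 1, r1.as = 3)))
  run <- simulate_hsm(m, p, init = c(g1 = 0))
  expect_identical(nrow(run$modes), 1L)
  expect_true(run$steady)
  expect_identical(observational_sequence(run)[1, ], c(g1 = "flat"))
})

test_that("the toy network settles into the published two-mode alternation", {
  m <- toy_two_gene_model()
  run <- simulate_hsm(m, toy_params(), init = c(s1 = 0, s2 = 0),
                      max_events = 30)
  obs <- observational_sequence(run)
  n <- nrow(obs)
  late <- obs[(n - 5L):n, ]
  for (i in seq_len(nrow(late) - 1L)) {
    expect_true(all(late[i, ] %in% c("up", "down")))
    expect_false(late[i, "s1"] == late[i + 1L, "s1"])
    expect_false(late[i, "s2"] == late[i + 1L, "s2"])
    expect_false(late[i, "s1"] == late[i, "s2"])
  }
})

test_that("runs are continuous, piecewise monotone and hysteretic", {
  m <- toy_two_gene_model()
  set.seed(21)
  jo <- toy_joint_orderings(m)
  for (rep_ in 1:20) {
    o <- jo[[sample(6L, 1L)]]
    p <- params_for_ordering(m, o, random = TRUE)
    run <- simulate_hsm(m, p, c(s1 = runif(1, 0, 4), s2 = runif(1, 0, 4)),
                        max_events = 30)
    expect_true(all(diff(run$times) > 0))
    # continuity: each interval's endpoint matches linear propagation
    for (i in seq_len(nrow(run$conc) - 1L)) {
      dt <- run$times[i + 1L] - run$times[i]
      expect_equal(unname(run$conc[i + 1L, ]),
                   unname(pmax(run$conc[i, ] + run$rates[i, ] * dt, 0)),
                   tolerance = 1e-8)
    }
    # hysteresis: per (substance, site), bind and release alternate in time
    seen <- new.env(parent = emptyenv())
    for (ev in run$events) {
      for (j in seq_along(ev$substances)) {
        for (s in strsplit(ev$sites[j], ",", fixed = TRUE)[[1]]) {
          key <- paste(ev$substances[j], s)
          prev <- seen[[key]]
          expect_false(identical(prev, ev$kinds[j]))
          seen[[key]] <- ev$kinds[j]
        }
      }
    }
  }
})

test_that("runs walk inside their ordering's characteristic graph", {
  m <- toy_two_gene_model()
  jo <- toy_joint_orderings(m)
  graphs <- lapply(jo, function(o) characteristic_graph(m, o))
  set.seed(31)
  for (rep_ in 1:25) {
    k <- sample(6L, 1L)
    p <- params_for_ordering(m, jo[[k]], random = TRUE)
    run <- simulate_hsm(m, p, c(s1 = runif(1, 0, 5), s2 = runif(1, 0, 5)),
                        max_events = 40)
    expect_true(isTRUE(conforms(run, graphs[[k]])))
  }
  # a doctored run with a deleted intermediate mode breaks the walk
  p <- params_for_ordering(m, jo[[2]], random = TRUE)
  run <- simulate_hsm(m, p, c(s1 = 0, s2 = 0), max_events = 10)
  expect_true(isTRUE(conforms(run, graphs[[2]])))
  expect_gt(nrow(run$modes), 3L)
  run2 <- run
  keep <- setdiff(seq_len(nrow(run2$modes)), 2L)
  run2$modes <- run2$modes[keep, , drop = FALSE]
  run2$conc <- run2$conc[keep, , drop = FALSE]
  run2$rates <- run2$rates[keep, , drop = FALSE]
  run2$times <- run2$times[keep]
  run2$events <- run2$events[-1]
  expect_false(isTRUE(conforms(run2, graphs[[2]])))
  # parameters inducing a different ordering are rejected outright
  expect_error(conforms(run, graphs[[6]]), "different threshold ordering")
})
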