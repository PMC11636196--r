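test_that("compartment_graph enforces structural invariants", {
  expect_error(compartment_graph(
    data.frame(name = c("a", "s"), kind = c("technical", "sink")),
    data.frame(from = "s", to = "a")), "must not have outgoing")
  expect_error(compartment_graph(
    data.frame(name = c("a", "b"), kind = c("technical", "technical")),
    data.frame(from = "a", to = "b")), "without outgoing")
  # cycle among non-sink compartments is rejected at sort time
  expect_error(compartment_graph(
    data.frame(name = c("a", "b", "s"),
               kind = c("technical", "technical", "sink")),
    data.frame(from = c("a", "b", "b"), to = c("b", "a", "s"))),
    "cycle")
})

test_that("sample_transfer_coefficients draws, renormalises, passes points", {
  g <- branch_scenario()$graph
  # point priors already summing to 1 pass unchanged
  tc <- sample_transfer_coefficients(g, branch_scenario(0.3)$priors, 5)
  expect_true(all(tc[, "src->left"] == 0.3))
  # uniform draws renormalise to exactly 1
  pri <- list(tc_prior("src", "left", "uniform", c(0.4, 0.6)),
              tc_prior("src", "right", "uniform", c(0.4, 0.6)))
  tc2 <- sample_transfer_coefficients(g, pri, 100, seed = 1)
  expect_equal(unname(rowSums(tc2)), rep(1, 100), tolerance = 1e-12)
  # single outgoing edge gets coefficient 1 regardless of prior
  ch <- chain_scenario()
  tc3 <- sample_transfer_coefficients(ch$graph,
    list(tc_prior("A", "B", "uniform", c(0.1, 0.9)),
         tc_prior("B", "final", "point", 0.2)), 10, seed = 2)
  expect_true(all(tc3 == 1))
  # missing prior is named
  expect_error(sample_transfer_coefficients(g, pri[1], 1), "src->right")
})

test_that("chain propagation accumulates the full inflow in the sink", {
  sc <- chain_scenario(inflow_t = 10, n_years = 4)
  ens <- run_simulation(sc, n_runs = 1)
  expect_equal(unname(ens$sinks[1, "final"]), 40)
  expect_true(all(ens$stocks == 0))
})

test_that("two-branch split matches hand propagation", {
  sc <- branch_scenario(p_left = 0.7, inflow_t = 10)
  ens <- run_simulation(sc, n_runs = 1)
  expect_equal(unname(ens$sinks[1, c("left", "right")]), c(7, 3))
})

test_that("point-TC flows match an independent brute-force propagation", {
  # 4 compartments: src -> {mid, sinkA}; mid -> sinkA. Hand-roll the
  # arithmetic year by year, independently of the engine.
  graph <- compartment_graph(
    data.frame(name = c("src", "mid", "sinkA", "sinkB"),
               kind = c("technical", "technical", "sink", "sink")),
    data.frame(from = c("src", "src", "mid", "mid"),
               to = c("mid", "sinkB", "sinkA", "sinkB")))
  priors <- list(tc_prior("src", "mid", "point", 0.6),
                 tc_prior("src", "sinkB", "point", 0.4),
                 tc_prior("mid", "sinkA", "point", 0.25),
                 tc_prior("mid", "sinkB", "point", 0.75))
  inflows <- c(5, 10, 0)
  inflow <- matrix(inflows, 3, 1, dimnames = list(as.character(2021:2023), NULL))
  ens <- run_simulation(list(graph = graph, priors = priors,
                             inflow = list(src = inflow), schedules = list()),
                        n_runs = 1)
  # brute force
  sinkA <- 0; sinkB <- 0
  for (i in seq_along(inflows)) {
    mid <- inflows[i] * 0.6
    sinkB <- sinkB + inflows[i] * 0.4 + mid * 0.75
    sinkA <- sinkA + mid * 0.25
  }
  expect_identical(unname(ens$sinks[1, "sinkA"]), sinkA)
  expect_identical(unname(ens$sinks[1, "sinkB"]), sinkB)
  expect_identical(unname(ens$flows[1, "2022", "src->mid"]), 10 * 0.6)
})

test_that("release schedules hold stock and release by lag", {
  sc <- chain_scenario(inflow_t = 100, n_years = 2)
  sc$schedules <- list(A = c(0, 0.1))   # nothing at lag 0, 10% at lag 1
  ens <- run_simulation(sc, n_runs = 1)
  expect_equal(unname(ens$stocks[1, "2021", "A"]), 100)
  # year 2: cohort 1 releases 10, cohort 2 enters and holds
  expect_equal(unname(ens$flows[1, "2022", "A->B"]), 10)
  expect_equal(unname(ens$stocks[1, "2022", "A"]), 90 + 100)
})

test_that("geometric release schedule matches the closed form", {
  r <- 0.3; Y <- 6; I <- 50
  sched <- r * (1 - r)^(0:(Y - 1))     # fraction released at lag 0,1,...
  sc <- chain_scenario(inflow_t = I, n_years = Y)
  sc$schedules <- list(A = sched)
  ens <- run_simulation(sc, n_runs = 1)
  # cohort entering year t retains (1-r)^(Y-t+1) of I at end of year Y
  expect_equal(unname(ens$stocks[1, Y, "A"]),
               I * sum((1 - r)^(1:Y)), tolerance = 1e-12)
})

test_that("mass balance holds and the detector flags corruption", {
  sc <- make_scenario(n_runs = 200, seed = 3)
  ens <- run_simulation(sc, n_runs = 200)
  mb <- mass_balance_report(ens)
  expect_lt(mb$max_abs, 1e-9)
  # corrupt one sink intake
  ens$received[1, 2, "landfill"] <- ens$received[1, 2, "landfill"] * 2
  expect_gt(mass_balance_report(ens)$max_abs, 1e-9)
  # zero inflow => residual exactly zero
  sc0 <- chain_scenario(inflow_t = 0, n_years = 3)
  expect_identical(mass_balance_report(run_simulation(sc0, 1))$max_abs, 0)
})

test_that("transfer compartments end every year with zero stock", {
  sc <- make_scenario(n_runs = 100, seed = 5)
  ens <- run_simulation(sc, n_runs = 100)
  expect_true(all(ens$stocks[, , "air"] == 0))
  # and the mass routed through air lands in natural soil the same year
  expect_equal(ens$received[, , "natural_soil"], ens$received[, , "air"])
})

test_that("propagation is linear in production and seed-deterministic", {
  sc <- make_scenario(n_runs = 50, production_cv = 0, seed = 9)
  e1 <- run_simulation(sc, n_runs = 50, seed = 123)
  sc2 <- sc
  sc2$inflow <- lapply(sc$inflow, function(m) 3 * m)
  e2 <- run_simulation(sc2, n_runs = 50, seed = 123)
  expect_equal(e2$flows, 3 * e1$flows, tolerance = 1e-12)
  expect_equal(e2$sinks, 3 * e1$sinks, tolerance = 1e-12)
  # same seed, same scenario: bit-identical
  e3 <- run_simulation(sc, n_runs = 50, seed = 123)
  expect_identical(e3$flows, e1$flows)
  # all-point priors: every run identical
  scp <- make_scenario(n_runs = 20, tc_family = "point",
                       production_cv = 0, seed = 2)
  ep <- run_simulation(scp, n_runs = 20, seed = 1)
  expect_equal(apply(ep$sinks, 2, function(x) diff(range(x))),
               setNames(rep(0, ncol(ep$sinks)), colnames(ep$sinks)))
})

test_that("sink_distribution_by_form normalises mean accumulated masses", {
  scA <- branch_scenario(p_left = 0.5, inflow_t = 10)
  scB <- branch_scenario(p_left = 0.25, inflow_t = 10)
  eA <- run_simulation(scA, 1); eB <- run_simulation(scB, 1)
  sh <- sink_distribution_by_form(list(f1 = eA, f2 = eB), "left")
  expect_equal(unname(sh), c(2, 1) / 3)   # 5 t vs 2.5 t
  expect_equal(sum(sh), 1)
  # symmetric ensembles give equal shares; zero mass errors
  expect_equal(unname(sink_distribution_by_form(list(a = eA, b = eA), "left")),
               c(0.5, 0.5))
  sc0 <- branch_scenario(p_left = 0.5, inflow_t = 0)
  e0 <- run_simulation(sc0, 1)
  expect_error(sink_distribution_by_form(list(a = e0, b = e0), "left"),
               "no mass")
})

test_that("scenario graph and priors round-trip through YAML", {
  sc <- make_scenario(seed = 4)
  sc$schedules <- list(use_1 = c(0.5, 0.5))
  path <- withr::local_tempfile(fileext = ".yml")
  scenario_to_yaml(sc, path)
  back <- scenario_from_yaml(path)
  expect_equal(back$graph$compartments, sc$graph$compartments)
  expect_equal(back$graph$edges, sc$graph$edges)
  expect_equal(length(back$priors), length(sc$priors))
  expect_equal(back$priors[[1]]$params, sc$priors[[1]]$params)
  expect_equal(back$schedules$use_1, c(0.5, 0.5))
})
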