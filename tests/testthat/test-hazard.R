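test_that("toxicity record validation enforces the closed vocabularies", {
  expect_s3_class(records_of(c(1, 2)), "toxicity_records")
  expect_error(records_of(1, descriptor = "TLm"), "TLm")
  expect_error(records_of(1, regime = "subchronic"), "regime")
  expect_error(records_of(-1), "> 0")
  expect_error(toxicity_records(data.frame(species = "x")), "lacks column")
})

test_that("chronic NOEC conversion divides by both uncertainty factors", {
  uf <- default_uf_table()
  expect_equal(to_chronic_noec(5, "NOEC", "chronic", uf), 5)      # UFs 1
  expect_equal(to_chronic_noec(100, "LCx", "acute", uf), 1)       # /(10*10)
  expect_equal(to_chronic_noec(10, "LOEC", "chronic", uf), 4)     # /2.5
  expect_equal(unname(to_chronic_noec(c(5, 100), c("NOEC", "LCx"),
                                      c("chronic", "acute"), uf)), c(5, 1))
  expect_error(to_chronic_noec(1, "NOEC", "subacute", uf), "cover")
  bad <- uf; bad$uf_t["acute"] <- 0.5
  expect_error(to_chronic_noec(1, "NOEC", "acute", bad), ">= 1")
})

test_that("build_species_sets groups converted endpoints by species", {
  recs <- records_of(c(1, 2, 3), species = rep("daphnia", 3))
  sets <- build_species_sets(recs)
  expect_length(sets, 1)
  expect_equal(sets[[1]]$values, c(1, 2, 3))
  expect_identical(attr(sets, "n_records"), 3L)

  # shape of the emulated inventory: 113 records over 26 species
  hz <- make_hazard_dataset(seed = 11)
  sets26 <- build_species_sets(hz$records)
  expect_identical(attr(sets26, "n_species"), 26L)
  expect_identical(attr(sets26, "n_records"), 113L)

  expect_error(build_species_sets(recs, form = "rGO"), "GBM")
})

test_that("estimate_hc5 degenerate, monotone, scale-equivariant, seeded", {
  # single species, single value: every iteration returns that value
  one <- build_species_sets(records_of(5))
  r <- estimate_hc5(one, n_iterations = 50, seed = 1)
  expect_true(all(r$hc5_samples == 5))
  expect_equal(r$pnec_mean, 5)

  set.seed(99)
  recs <- records_of(rlnorm(20, 0, 1), species = paste0("sp", 1:20))
  sets <- build_species_sets(recs)
  a <- estimate_hc5(sets, n_iterations = 200, seed = 42)
  b <- estimate_hc5(sets, n_iterations = 200, seed = 42)
  expect_identical(a$hc5_samples, b$hc5_samples)   # seed determinism

  # scaling equivariance with the same seed
  recs10 <- recs; recs10$value <- recs10$value * 10
  c10 <- estimate_hc5(build_species_sets(recs10), n_iterations = 200, seed = 42)
  expect_equal(c10$hc5_samples, 10 * a$hc5_samples, tolerance = 1e-12)

  # lowering the most sensitive species never raises the HC5
  low <- recs; low$value[which.min(low$value)] <- min(low$value) / 10
  d <- estimate_hc5(build_species_sets(low), n_iterations = 200, seed = 42)
  expect_true(all(d$hc5_samples <= a$hc5_samples + 1e-12))

  # bracketing: HC5 lies within [min, max] of the species values
  expect_true(all(a$hc5_samples >= min(recs$value) - 1e-12))
  expect_true(all(a$hc5_samples <= max(recs$value) + 1e-12))

  expect_error(estimate_hc5(sets, n_iterations = 0), ">= 1")
})

test_that("most-sensitive-endpoint mode collapses species to their minimum", {
  recs <- records_of(c(1, 9, 2, 8), species = c("a", "a", "b", "b"))
  sets <- build_species_sets(recs)
  r <- estimate_hc5(sets, n_iterations = 20, seed = 1, mode = "most_sensitive")
  # both species degenerate at their minimum: every iteration identical
  expect_equal(unique(r$hc5_samples),
               unname(quantile(c(1, 2), 0.05, type = 7)))
})

test_that("pnec_af divides the lowest endpoint and reports it", {
  recs <- records_of(c(100, 34, 60), species = c("d", "C. pyrenoidosa", "f"))
  p <- pnec_af(recs, 1000)
  expect_equal(p$pnec, 0.034)
  expect_identical(p$min_species, "C. pyrenoidosa")
  expect_equal(pnec_af(recs, 1)$pnec, 34)
  expect_equal(pnec_af(records_of(10), 1000)$pnec, 0.01)
  # brute-force property over random tables
  set.seed(3)
  for (i in 1:5) {
    v <- rlnorm(7, 1, 2)
    expect_equal(pnec_af(records_of(v), 50)$pnec, min(v) / 50)
  }
  expect_error(pnec_af(records_of(1), 0.5), ">= 1")
})

test_that("PNEC strategy choice follows species counts and trophic cover", {
  hz <- make_hazard_dataset(seed = 2)
  sets <- build_species_sets(hz$records)
  expect_identical(choose_pnec_strategy(sets)$strategy, "pssd")

  # 5 species, no fish, no daphnids -> assessment factor
  sparse <- records_of(rlnorm(5), species = paste0("sp", 1:5),
                       group = c("algae", "plant", "other", "algae", "plant"))
  ch <- choose_pnec_strategy(build_species_sets(sparse))
  expect_identical(ch$strategy, "assessment_factor")
  expect_match(ch$rationale, "fish")
})

test_that("toxicity records round-trip through CSV and the curve is ranked", {
  hz <- make_hazard_dataset(n_species = 6, n_endpoints = 12, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_toxicity_records(hz$records, path)
  back <- read_toxicity_records(path)
  expect_equal(as.data.frame(back), as.data.frame(hz$records),
               tolerance = 1e-12)
  curve <- ssd_curve(build_species_sets(back))
  expect_true(!is.unsorted(curve$median_noec))
  expect_equal(curve$fraction_affected, ((1:6) - 0.5) / 6)
})
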