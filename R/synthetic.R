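# Dirichlet(1,...,1) rows: uninformative but valid share-matrix rows.
rdirichlet_rows <- function(n, k) {
  g <- matrix(stats::rgamma(n * k, shape = 1), n, k)
  g / rowSums(g)
}

#' Generate a complete synthetic material-flow scenario
#'
#' Builds a fully specified, statistically faithful scenario bundle for the
#' simulation engine: Dirichlet-distributed row-stochastic share matrices
#' `E` (years x categories) and `F` (categories x forms), lognormal yearly
#' production samples, a fixed toy compartment graph (per-category in-use
#' compartments feeding waste treatment, air as a transfer compartment,
#' and landfill / surface water / soils / elimination as final
#' compartments), transfer-coefficient priors around realistic central
#' values, and optional release schedules.  All randomness is governed by
#' `seed`; with `tc_family = "point"` and `production_cv = 0` the bundle
#' simulates deterministically, so expected sink masses follow in closed
#' form from the central transfer coefficients.
#'
#' @param n_categories product categories (>= 1).
#' @param n_forms material forms (>= 1); form labels come from
#'   [gbm_forms()] when `n_forms` is 3.
#' @param horizon_years years simulated (>= 1), starting at `start_year`.
#' @param start_year first calendar year label.
#' @param production_median median total production (tonnes/year).
#' @param production_cv coefficient of variation of the lognormal yearly
#'   production (>= 0).
#' @param n_runs Monte-Carlo samples generated for the production series.
#' @param tc_family `"triangular"`, `"uniform"` or `"point"` priors around
#'   the central transfer coefficients.
#' @param tc_spread half-width of the prior around each central value.
#' @param schedules optional named list of release schedules for the
#'   in-use compartments (`use_1`, `use_2`, ...); default immediate release.
#' @param seed integer seed.
#' @return scenario list with `E`, `F`, `production` (years x runs),
#'   `graph`, `priors`, `inflow`, `schedules`, `tc_central`, `years`.
#' @export
make_scenario <- function(n_categories = 3L, n_forms = 3L,
                          horizon_years = 10L, start_year = 2021L,
                          production_median = 100, production_cv = 0.5,
                          n_runs = 100L,
                          tc_family = c("triangular", "uniform", "point"),
                          tc_spread = 0.1, schedules = NULL, seed = 1L) {
  tc_family <- match.arg(tc_family)
  stopifnot(n_categories >= 1L, n_forms >= 1L, horizon_years >= 1L,
            production_cv >= 0, production_median > 0, n_runs >= 1L)
  set.seed(seed)
  years <- as.character(seq(start_year, length.out = horizon_years))
  cats <- paste0("cat_", seq_len(n_categories))
  forms <- if (n_forms == 3L) gbm_forms() else paste0("form_", seq_len(n_forms))

  E <- share_matrix(rdirichlet_rows(horizon_years, n_categories),
                    row_labels = years, col_labels = cats)
  F <- share_matrix(rdirichlet_rows(n_categories, n_forms),
                    row_labels = cats, col_labels = forms)

  sdlog <- sqrt(log(1 + production_cv^2))
  production <- matrix(
    stats::rlnorm(horizon_years * n_runs, log(production_median), sdlog),
    nrow = horizon_years, dimnames = list(years, NULL))

  use <- paste0("use_", seq_len(n_categories))
  compartments <- data.frame(
    name = c(use, "waste", "wwtp", "air", "surface_water", "landfill",
             "sludge_soil", "natural_soil", "elimination"),
    kind = c(rep("technical", n_categories), "technical", "technical",
             "transfer", "sink", "sink", "sink", "sink", "elimination"))
  tc_central <- rbind(
    do.call(rbind, lapply(use, function(u) data.frame(
      from = u, to = c("waste", "air", "surface_water"),
      tc = c(0.8, 0.1, 0.1)))),
    data.frame(from = "waste", to = c("landfill", "elimination", "wwtp"),
               tc = c(0.45, 0.45, 0.10)),
    data.frame(from = "wwtp", to = c("surface_water", "sludge_soil"),
               tc = c(0.5, 0.5)),
    data.frame(from = "air", to = "natural_soil", tc = 1))
  graph <- compartment_graph(compartments, tc_central[c("from", "to")])
  priors <- lapply(seq_len(nrow(tc_central)), function(i) {
    v <- tc_central$tc[i]
    lo <- max(0, v - tc_spread); hi <- min(1, v + tc_spread)
    switch(tc_family,
           point = tc_prior(tc_central$from[i], tc_central$to[i], "point", v),
           uniform = tc_prior(tc_central$from[i], tc_central$to[i],
                              "uniform", c(lo, hi)),
           triangular = tc_prior(tc_central$from[i], tc_central$to[i],
                                 "triangular", c(lo, v, hi)))
  })
  inflow <- stats::setNames(lapply(seq_len(n_categories), function(i) {
    production * unclass(E)[, i]
  }), use)
  if (!is.null(schedules)) {
    unknown <- setdiff(names(schedules), use)
    if (length(unknown) > 0L) {
      stop(sprintf("schedules for unknown compartment(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  list(E = E, F = F, production = production, graph = graph, priors = priors,
       inflow = inflow, schedules = schedules %||% list(),
       tc_central = tc_central, years = years, forms = forms,
       categories = cats, seed = seed)
}

#' Generate a synthetic ecotoxicity dataset with analytic ground truth
#'
#' Emulates the shape of a curated aquatic hazard inventory (by default 26
#' species carrying 113 endpoints between them): each species receives a
#' true sensitivity drawn from a lognormal species-sensitivity law, its
#' endpoints scatter lognormally around that truth, and every endpoint is
#' disguised with a dose descriptor and exposure regime drawn from the mix
#' — with its recorded value multiplied by the corresponding uncertainty
#' factors, so that standard chronic-NOEC conversion recovers the intended
#' values exactly.  The analytic 5% quantile of the species-sensitivity
#' law, `exp(meanlog + qnorm(0.05) * sdlog)`, is returned as ground truth;
#' it is a property of the law, not of the seed.
#'
#' @param n_species number of species (>= 1).
#' @param n_endpoints total endpoints, distributed as evenly as possible.
#' @param meanlog,sdlog parameters of the lognormal species-sensitivity
#'   law (natural log of mg/L); `sdlog >= 0`.
#' @param endpoint_sdlog within-species lognormal endpoint scatter.
#' @param descriptor_mix named fractions over dose descriptors, summing
#'   to 1.
#' @param acute_fraction fraction of endpoints reported from acute tests.
#' @param form material form label stamped on every record.
#' @param uf_table uncertainty-factor table used to disguise endpoints.
#' @param seed integer seed.
#' @return list with `records` (a [toxicity_records()] table) and `truth`
#'   (`hc5` in mg/L, `meanlog`, `sdlog`, `n_species`, `n_records`).
#' @export
make_hazard_dataset <- function(n_species = 26L, n_endpoints = 113L,
                                meanlog = 0, sdlog = 0.5,
                                endpoint_sdlog = 0.2,
                                descriptor_mix = c(NOEC = 0.35, ECx = 0.3,
                                                   LCx = 0.2, LOEC = 0.1,
                                                   HONEC = 0.05),
                                acute_fraction = 0.5, form = "GBM",
                                uf_table = default_uf_table(), seed = 1L) {
  stopifnot(n_species >= 1L, n_endpoints >= n_species, sdlog >= 0,
            endpoint_sdlog >= 0)
  if (abs(sum(descriptor_mix) - 1) > 1e-9) {
    stop("descriptor mix fractions must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  per <- rep(n_endpoints %/% n_species, n_species)
  extra <- n_endpoints %% n_species
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  groups <- rep(c("fish", "daphnid", "algae", "plant", "other", "amphibian"),
                length.out = n_species)
  species <- sprintf("species_%02d", seq_len(n_species))

  truth_log <- meanlog + sdlog * stats::rnorm(n_species)
  rows <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    k <- per[i]
    chronic <- exp(truth_log[i] + endpoint_sdlog * stats::rnorm(k))
    descriptor <- sample(names(descriptor_mix), k, replace = TRUE,
                         prob = descriptor_mix)
    regime <- ifelse(stats::runif(k) < acute_fraction, "acute", "chronic")
    raw <- chronic * uf_table$uf_t[regime] * uf_table$uf_dd[descriptor]
    rows[[i]] <- data.frame(species = species[i], group = groups[i],
                            form = form, descriptor = descriptor,
                            regime = regime, value = as.numeric(raw),
                            source = sprintf("synthetic:%s", species[i]))
  }
  records <- toxicity_records(do.call(rbind, rows))
  list(records = records,
       truth = list(hc5 = exp(meanlog + stats::qnorm(0.05) * sdlog),
                    meanlog = meanlog, sdlog = sdlog,
                    n_species = n_species, n_records = nrow(records)))
}
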