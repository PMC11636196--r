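#' Disaggregate a total production series into material forms
#'
#' Convenience wrapper around the share-matrix operations: composes
#' `G = E F`, splits the total production series into one series per form,
#' and derives each form's year-by-category allocation.
#'
#' @param production years x runs matrix of total production (tonnes/year),
#'   year labels as rownames.
#' @param E `share_matrix` years x categories.
#' @param F `share_matrix` categories x forms (default the shipped
#'   graphene split table [gbm_form_splits()]).
#' @return list with `G`, `production_by_form` (named list of matrices)
#'   and `allocation_by_form` (named list of `share_matrix`).
#' @export
disaggregate_production <- function(production, E, F = gbm_form_splits()) {
  G <- compose_form_shares(E, F)
  forms <- colnames(G)
  prod_by_form <- stats::setNames(
    lapply(forms, function(z) allocate_form_production(production, G, z)),
    forms)
  alloc_by_form <- stats::setNames(
    lapply(forms, function(z) reallocate_categories(E, F, z, G = G)), forms)
  list(G = G, production_by_form = prod_by_form,
       allocation_by_form = alloc_by_form)
}

#' Configuration for an end-to-end risk assessment run
#'
#' Collects every input and tunable of [run_era()] with validated
#' defaults.
#'
#' @param scenario a scenario bundle as produced by [make_scenario()]
#'   (fields `E`, `F`, `production`, `graph`, `priors`, `schedules`).
#' @param hazard_records a [toxicity_records()] table.
#' @param compartments a [compartment_spec()].
#' @param n_runs Monte-Carlo runs for the flow simulation.
#' @param n_iterations Monte-Carlo iterations for the SSD.
#' @param seed single root seed; per-stage substreams are derived from it
#'   so stages can be re-run independently with stable randomness.
#' @param pec_mode freshwater PEC convention, see [pec_freshwater()].
#' @param soil_basis `"annual"` (inflow of the final year) or
#'   `"accumulated"` (sink inventory over the horizon) for soil PECs.
#' @param min_species,required_groups PSSD sufficiency thresholds, see
#'   [choose_pnec_strategy()].
#' @param assessment_factor fallback assessment factor.
#' @param uf_table uncertainty-factor table.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return list of class `era_config`.
#' @export
era_config <- function(scenario, hazard_records, compartments,
                       n_runs = 1000L, n_iterations = 10000L, seed = 1L,
                       pec_mode = c("annual_dilution", "residence_scaled"),
                       soil_basis = c("annual", "accumulated"),
                       min_species = 8L,
                       required_groups = c("fish", "daphnid", "algae"),
                       assessment_factor = 1000,
                       uf_table = default_uf_table(),
                       output_dir = NULL) {
  stopifnot(n_runs >= 1L, n_iterations >= 1L, length(seed) == 1L)
  structure(list(scenario = scenario,
                 hazard_records = toxicity_records(as.data.frame(hazard_records)),
                 compartments = compartments,
                 n_runs = as.integer(n_runs),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 pec_mode = match.arg(pec_mode),
                 soil_basis = match.arg(soil_basis),
                 min_species = min_species,
                 required_groups = required_groups,
                 assessment_factor = assessment_factor,
                 uf_table = uf_table,
                 output_dir = output_dir),
            class = "era_config")
}

#' Run the form-specific environmental risk assessment end to end
#'
#' One seeded pass over the whole chain: form disaggregation, per-form
#' dynamic probabilistic material-flow simulation (transfer-coefficient
#' realisations are shared across forms so that form flows sum exactly to
#' the total), freshwater and soil PEC distributions, per-form PNEC by
#' probabilistic SSD or assessment factor (chosen by the data-sufficiency
#' rule, with the decision logged), and RCR distributions.  Identical
#' configuration and seed give identical results.
#'
#' @param config an [era_config()].
#' @return list of class `era_result` with `forms`, per-form entries
#'   (`production`, `ensemble`, `pec_freshwater`, `pnec`, `strategy`,
#'   `rcr`, `summary`), `total` (same fields for all forms combined),
#'   `soil_pec` (when soil masses are configured), `mass_balance`,
#'   `decisions` (logged defaults actually used) and `summary_table`.
#'   When `config$output_dir` is set, CSV samples and a JSON summary are
#'   written there as a side effect.
#' @export
run_era <- function(config) {
  stopifnot(inherits(config, "era_config"))
  sc <- config$scenario
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max, 4L)

  decisions <- c(
    sprintf("pec_mode=%s", config$pec_mode),
    sprintf("soil_basis=%s", config$soil_basis),
    sprintf("uf_t[acute]=%g; uf_dd[ECx]=%g (editable defaults)",
            config$uf_table$uf_t[["acute"]], config$uf_table$uf_dd[["ECx"]]),
    "tc_resampling=per_run (held fixed across years within a run)")

  # -- disaggregation ----------------------------------------------------
  dis <- disaggregate_production(sc$production, sc$E, sc$F)
  forms <- colnames(dis$G)

  # -- flow simulation: shared TC realisations across forms --------------
  tc <- sample_transfer_coefficients(sc$graph, sc$priors, config$n_runs,
                                     seed = stage_seed[1L])
  simulate_form <- function(P_z, E_z) {
    inflow <- stats::setNames(lapply(seq_along(sc$categories), function(i) {
      P_z * unclass(E_z)[, i]
    }), names(sc$inflow))
    run_simulation(list(graph = sc$graph, priors = sc$priors,
                        inflow = inflow, schedules = sc$schedules),
                   n_runs = config$n_runs, tc = tc)
  }
  ensembles <- stats::setNames(lapply(forms, function(z) {
    simulate_form(dis$production_by_form[[z]], dis$allocation_by_form[[z]])
  }), forms)
  total_ensemble <- simulate_form(sc$production, sc$E)
  mb <- mass_balance_report(total_ensemble)

  # -- exposure ----------------------------------------------------------
  final <- length(sc$years)
  fw_release <- function(e) as.numeric(e$received[, final, "surface_water"])
  pecs <- lapply(ensembles, function(e) {
    pec_freshwater(fw_release(e), config$compartments, mode = config$pec_mode)
  })
  pec_total <- pec_freshwater(fw_release(total_ensemble),
                              config$compartments, mode = config$pec_mode)
  soil_pec <- NULL
  if (!is.null(config$compartments$soil_mass_natural_urban_kg)) {
    soil_mass_of <- function(e, comp) {
      if (config$soil_basis == "annual") as.numeric(e$received[, final, comp])
      else as.numeric(e$sinks[, comp])
    }
    soil_pec <- lapply(ensembles, function(e) list(
      natural_urban = pec_soil(soil_mass_of(e, "natural_soil"),
                               config$compartments$soil_mass_natural_urban_kg,
                               unit = "ng/kg"),
      sludge_treated = pec_soil(soil_mass_of(e, "sludge_soil"),
                                config$compartments$soil_mass_sludge_kg,
                                unit = "ug/kg")))
  }

  # -- hazard ------------------------------------------------------------
  record_forms <- unique(config$hazard_records$form)
  pnec_for <- function(form_label, seed) {
    filt <- if (form_label %in% record_forms) form_label else NULL
    sets <- build_species_sets(config$hazard_records, form = filt,
                               uf_table = config$uf_table)
    choice <- choose_pnec_strategy(sets, min_species = config$min_species,
                                   required_groups = config$required_groups)
    pnec <- if (choice$strategy == "pssd") {
      estimate_hc5(sets, n_iterations = config$n_iterations, seed = seed)
    } else {
      recs <- config$hazard_records
      if (!is.null(filt)) recs <- recs[recs$form == filt, , drop = FALSE]
      pnec_af(recs, assessment_factor = config$assessment_factor)
    }
    list(pnec = pnec, strategy = choice$strategy, rationale = choice$rationale,
         pooled = is.null(filt) && length(record_forms) > 1L)
  }
  hazards <- stats::setNames(lapply(seq_along(forms), function(i) {
    pnec_for(forms[i], seed = stage_seed[2L] %% 100000L + i)
  }), forms)
  hazard_total <- pnec_for("__all__", seed = stage_seed[2L] %% 100000L)
  for (z in forms) {
    decisions <- c(decisions, sprintf(
      "pnec[%s]=%s (%s)%s", z, hazards[[z]]$strategy, hazards[[z]]$rationale,
      if (hazards[[z]]$pooled) " [no form-specific records; pooled dataset used]" else ""))
  }

  # -- risk --------------------------------------------------------------
  rcrs <- stats::setNames(lapply(seq_along(forms), function(i) {
    rcr_distribution(pecs[[forms[i]]], hazards[[forms[i]]]$pnec,
                     seed = stage_seed[3L] %% 100000L + i)
  }), forms)
  rcr_total <- rcr_distribution(pec_total, hazard_total$pnec,
                                seed = stage_seed[3L] %% 100000L)

  summary_table <- do.call(rbind, c(
    lapply(forms, function(z) {
      s <- summarize_rcr(rcrs[[z]])
      cbind(data.frame(form = z,
                       pec_mean_ngL = mean(pecs[[z]]$samples),
                       pnec_strategy = hazards[[z]]$strategy,
                       pnec_mgL = pnec_point_value(hazards[[z]]$pnec)), s)
    }),
    list({
      s <- summarize_rcr(rcr_total)
      cbind(data.frame(form = "total",
                       pec_mean_ngL = mean(pec_total$samples),
                       pnec_strategy = hazard_total$strategy,
                       pnec_mgL = pnec_point_value(hazard_total$pnec)), s)
    })))

  result <- structure(list(
    forms = forms, G = dis$G,
    production_by_form = dis$production_by_form,
    ensembles = ensembles, total_ensemble = total_ensemble,
    pec_freshwater = pecs, pec_total = pec_total, soil_pec = soil_pec,
    hazards = hazards, hazard_total = hazard_total,
    rcr = rcrs, rcr_total = rcr_total,
    mass_balance = list(max_abs = mb$max_abs),
    decisions = decisions, summary_table = summary_table,
    seed = config$seed), class = "era_result")

  if (!is.null(config$output_dir)) write_era_outputs(result, config)
  result
}

pnec_point_value <- function(pnec) {
  if (inherits(pnec, "ssd_result")) pnec$pnec_mean else pnec$pnec
}

#' @export
print.era_result <- function(x, ...) {
  cat("form-specific environmental risk assessment\n")
  print(x$summary_table, digits = 3)
  invisible(x)
}

write_era_outputs <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sprintf("# seed=%d n_runs=%d n_iterations=%d units: pec ng/L, pnec mg/L",
                  config$seed, config$n_runs, config$n_iterations)
  sum_path <- file.path(config$output_dir, "summary.csv")
  writeLines(meta, sum_path)
  suppressWarnings(utils::write.table(result$summary_table, sum_path,
                                      sep = ",", row.names = FALSE,
                                      append = TRUE, quote = FALSE))
  for (z in result$forms) {
    utils::write.csv(
      data.frame(run = seq_along(result$pec_freshwater[[z]]$samples),
                 pec_ngL = result$pec_freshwater[[z]]$samples,
                 rcr = result$rcr[[z]]$samples[
                   seq_along(result$pec_freshwater[[z]]$samples)]),
      file.path(config$output_dir, sprintf("samples_%s.csv", z)),
      row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = config$seed, n_runs = config$n_runs,
         n_iterations = config$n_iterations,
         pec_mode = config$pec_mode, soil_basis = config$soil_basis,
         decisions = result$decisions,
         mass_balance_max_abs = result$mass_balance$max_abs,
         summary = result$summary_table),
    file.path(config$output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$output_dir)
}

#' Write / read a compartment scenario as YAML
#'
#' Serialises the graph, transfer-coefficient priors and release schedules
#' of a scenario into a single YAML document (share matrices and
#' production series travel as CSV, see [write_share_matrix()]).
#'
#' @param scenario scenario list with `graph`, `priors`, `schedules`.
#' @param path file path.
#' @return [scenario_to_yaml()] returns `path` invisibly;
#'   [scenario_from_yaml()] returns a list with validated `graph`,
#'   `priors` and `schedules`.
#' @export
scenario_to_yaml <- function(scenario, path) {
  doc <- list(
    compartments = Map(function(n, k) list(name = n, kind = k),
                       scenario$graph$compartments$name,
                       scenario$graph$compartments$kind),
    priors = lapply(scenario$priors, function(p) {
      list(from = p$from, to = p$to, dist = p$dist,
           params = as.numeric(p$params))
    }),
    schedules = scenario$schedules %||% list())
  names(doc$compartments) <- NULL
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname scenario_to_yaml
#' @export
scenario_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  comps <- do.call(rbind, lapply(doc$compartments, function(x) {
    data.frame(name = x$name, kind = x$kind)
  }))
  priors <- lapply(doc$priors, function(p) {
    tc_prior(p$from, p$to, p$dist, as.numeric(p$params))
  })
  edges <- do.call(rbind, lapply(priors, function(p) {
    data.frame(from = p$from, to = p$to)
  }))
  schedules <- doc$schedules %||% list()
  schedules <- lapply(schedules, as.numeric)
  list(graph = compartment_graph(comps, edges), priors = priors,
       schedules = schedules)
}
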