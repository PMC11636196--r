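.descriptors <- c("NOEC", "LOEC", "HONEC", "ECx", "LCx")
.regimes <- c("acute", "chronic")
.taxon_groups <- c("fish", "algae", "daphnid", "amphibian", "plant", "other")

#' Validate a table of ecotoxicity records
#'
#' A toxicity record is one endpoint from an aquatic ecotoxicity study:
#' species, taxonomic group, material form, dose descriptor (NOEC, LOEC,
#' HONEC, ECx or LCx), exposure regime (acute or chronic), the endpoint
#' concentration in mg/L and its source.
#'
#' @param records data.frame with columns `species`, `group`, `form`,
#'   `descriptor`, `regime`, `value`, `source`.
#' @return the validated data.frame, invisibly classed `toxicity_records`.
#' @export
toxicity_records <- function(records) {
  need <- c("species", "group", "form", "descriptor", "regime", "value", "source")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop(sprintf("toxicity table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad_d <- setdiff(unique(records$descriptor), .descriptors)
  if (length(bad_d) > 0L) {
    stop(sprintf("unknown dose descriptor(s): %s (allowed: %s)",
                 paste(bad_d, collapse = ", "),
                 paste(.descriptors, collapse = ", ")), call. = FALSE)
  }
  bad_r <- setdiff(unique(records$regime), .regimes)
  if (length(bad_r) > 0L) {
    stop(sprintf("unknown exposure regime(s): %s", paste(bad_r, collapse = ", ")),
         call. = FALSE)
  }
  bad_g <- setdiff(unique(records$group), .taxon_groups)
  if (length(bad_g) > 0L) {
    stop(sprintf("unknown taxon group(s): %s (allowed: %s)",
                 paste(bad_g, collapse = ", "),
                 paste(.taxon_groups, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(records$value)) || any(records$value <= 0)) {
    stop("endpoint concentrations must be finite and > 0 (mg/L)", call. = FALSE)
  }
  class(records) <- unique(c("toxicity_records", class(records)))
  invisible(records)
}

#' Read / write toxicity records as CSV
#'
#' @param path file path; the CSV uses exactly the column vocabulary of
#'   [toxicity_records()].
#' @return validated `toxicity_records` data.frame.
#' @export
read_toxicity_records <- function(path) {
  toxicity_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_toxicity_records
#' @param records a toxicity table.
#' @export
write_toxicity_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Default uncertainty-factor table
#'
#' Factors used to extrapolate endpoints to chronic NOECs: `uf_t` converts
#' across exposure duration (acute to chronic), `uf_dd` across dose
#' descriptors.  A chronic NOEC maps to factors of one.  The shipped values
#' (acute 10; EC50/LC50-type 10, LOEC 2.5, HONEC 1) follow common practice
#' in probabilistic species-sensitivity work and are deliberately exposed
#' as an editable configuration rather than hard-coded truth.
#'
#' @return list with named vectors `uf_t` (per regime) and `uf_dd` (per
#'   descriptor), all factors >= 1.
#' @export
default_uf_table <- function() {
  list(uf_t = c(acute = 10, chronic = 1),
       uf_dd = c(NOEC = 1, HONEC = 1, LOEC = 2.5, ECx = 10, LCx = 10))
}

#' Convert an endpoint to a chronic NOEC
#'
#' Divides the endpoint concentration by the duration and descriptor
#' uncertainty factors: `value / (uf_t[regime] * uf_dd[descriptor])`.
#' Vectorised over records.
#'
#' @param value endpoint concentration(s), mg/L.
#' @param descriptor,regime vocabulary values, recycled against `value`.
#' @param uf_table an uncertainty-factor table, see [default_uf_table()].
#' @return chronic NOEC concentration(s), mg/L.
#' @export
to_chronic_noec <- function(value, descriptor, regime,
                            uf_table = default_uf_table()) {
  bad_d <- setdiff(unique(descriptor), names(uf_table$uf_dd))
  bad_r <- setdiff(unique(regime), names(uf_table$uf_t))
  if (length(bad_d) || length(bad_r)) {
    stop(sprintf("uncertainty-factor table does not cover: %s",
                 paste(c(bad_d, bad_r), collapse = ", ")), call. = FALSE)
  }
  if (any(c(uf_table$uf_t, uf_table$uf_dd) < 1)) {
    stop("uncertainty factors must be >= 1", call. = FALSE)
  }
  out <- value / (uf_table$uf_t[regime] * uf_table$uf_dd[descriptor])
  names(out) <- names(value)
  out
}

#' Group converted endpoints into per-species sensitivity sets
#'
#' Optionally filters the record table to one material form, converts every
#' endpoint to a chronic NOEC and collects the values per species.
#'
#' @param records a [toxicity_records()] table.
#' @param form material form label to keep, or `NULL` for all records.
#' @param uf_table uncertainty factors for the conversion.
#' @return list of class `species_sets`: per species a list with `species`,
#'   `group` and `values` (chronic NOECs, mg/L).  Attributes `n_records`
#'   and `n_species` carry the inventory counts.
#' @export
build_species_sets <- function(records, form = NULL,
                               uf_table = default_uf_table()) {
  records <- toxicity_records(as.data.frame(records))
  if (!is.null(form)) {
    keep <- records$form == form
    if (!any(keep)) {
      stop(sprintf("no records for form '%s'; available forms: %s", form,
                   paste(sort(unique(records$form)), collapse = ", ")),
           call. = FALSE)
    }
    records <- records[keep, , drop = FALSE]
  }
  records$chronic_noec <- to_chronic_noec(records$value, records$descriptor,
                                          records$regime, uf_table)
  sets <- lapply(split(records, records$species), function(d) {
    list(species = d$species[1L],
         group = d$group[1L],
         values = as.numeric(d$chronic_noec))
  })
  structure(sets[order(names(sets))], class = "species_sets",
            n_records = nrow(records), n_species = length(sets))
}

#' @export
print.species_sets <- function(x, ...) {
  cat(sprintf("species sensitivity sets: %d species, %d records\n",
              attr(x, "n_species"), attr(x, "n_records")))
  invisible(x)
}

#' Probabilistic species sensitivity distribution and HC5
#'
#' Monte-Carlo construction of the hazardous concentration for 5% of
#' species: each iteration draws one chronic NOEC per species (uniformly
#' from that species' endpoint set, embracing within-species endpoint
#' variability) and takes the 5th percentile of the drawn community
#' (linear interpolation between order statistics).  The mean of the HC5
#' samples is reported as the PNEC point value, with the median alongside.
#'
#' @param species_sets a [build_species_sets()] result.
#' @param n_iterations Monte-Carlo iterations (default 10000).
#' @param seed optional integer seed; results are deterministic given it.
#' @param mode `"resample"` draws among all endpoints of each species
#'   (default); `"most_sensitive"` uses only each species' lowest chronic
#'   NOEC, collapsing the per-species distribution to its minimum.
#' @return list of class `ssd_result`: `hc5_samples`, `pnec_mean`,
#'   `pnec_median`, `n_iterations`, `n_species`, `seed`, `mode`, all
#'   concentrations in mg/L.
#' @export
estimate_hc5 <- function(species_sets, n_iterations = 10000L, seed = NULL,
                         mode = c("resample", "most_sensitive")) {
  mode <- match.arg(mode)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  if (length(species_sets) < 1L) stop("need at least one species", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vals <- lapply(species_sets, function(s) {
    if (mode == "most_sensitive") min(s$values) else s$values
  })
  n_sp <- length(vals)
  draws <- matrix(0, n_iterations, n_sp)
  for (j in seq_len(n_sp)) {
    v <- vals[[j]]
    draws[, j] <- if (length(v) == 1L) v else
      v[sample.int(length(v), n_iterations, replace = TRUE)]
  }
  hc5 <- apply(draws, 1L, stats::quantile, probs = 0.05, names = FALSE, type = 7)
  structure(list(hc5_samples = hc5, pnec_mean = mean(hc5),
                 pnec_median = stats::median(hc5),
                 n_iterations = n_iterations, n_species = n_sp,
                 seed = seed, mode = mode, unit = "mg/L"),
            class = "ssd_result")
}

#' @export
print.ssd_result <- function(x, ...) {
  cat(sprintf(
    "probabilistic SSD: %d species, %d iterations\n  HC5/PNEC mean %.4g mg/L (median %.4g mg/L)\n",
    x$n_species, x$n_iterations, x$pnec_mean, x$pnec_median))
  invisible(x)
}

#' Assessment-factor PNEC
#'
#' Deterministic fallback when data are too sparse for a species
#' sensitivity distribution: the lowest endpoint concentration divided by
#' an assessment factor (up to 1000 under standard regulatory guidance).
#'
#' @param records a [toxicity_records()] table (raw endpoint values are
#'   used, as in regulatory practice).
#' @param assessment_factor divisor, >= 1 (default 1000).
#' @return list of class `pnec_af`: `pnec` (mg/L), `assessment_factor`,
#'   `min_value`, `min_species`, `min_source`.
#' @export
pnec_af <- function(records, assessment_factor = 1000) {
  records <- toxicity_records(as.data.frame(records))
  if (nrow(records) < 1L) stop("no toxicity records", call. = FALSE)
  if (assessment_factor < 1) stop("assessment factor must be >= 1", call. = FALSE)
  i <- which.min(records$value)
  structure(list(pnec = records$value[i] / assessment_factor,
                 assessment_factor = assessment_factor,
                 min_value = records$value[i],
                 min_species = records$species[i],
                 min_source = records$source[i],
                 unit = "mg/L"),
            class = "pnec_af")
}

#' @export
print.pnec_af <- function(x, ...) {
  cat(sprintf(
    "assessment-factor PNEC: %.4g mg/L (lowest endpoint %.4g mg/L, %s, AF %g)\n",
    x$pnec, x$min_value, x$min_species, x$assessment_factor))
  invisible(x)
}

#' Choose between probabilistic SSD and assessment-factor PNEC
#'
#' The probabilistic route requires enough species and representation of
#' the key trophic groups; otherwise the conservative assessment-factor
#' route is selected.  The decision and its reason are returned for the
#' audit trail.
#'
#' @param species_sets a [build_species_sets()] result.
#' @param min_species minimum species count for an SSD (default 8).
#' @param required_groups taxon groups that must be present (default fish,
#'   daphnid and algae, the standard three trophic levels).
#' @return list with `strategy` (`"pssd"` or `"assessment_factor"`) and
#'   `rationale`.
#' @export
choose_pnec_strategy <- function(species_sets, min_species = 8,
                                 required_groups = c("fish", "daphnid", "algae")) {
  n_sp <- length(species_sets)
  groups <- unique(vapply(species_sets, function(s) s$group, ""))
  missing <- setdiff(required_groups, groups)
  if (n_sp >= min_species && length(missing) == 0L) {
    list(strategy = "pssd",
         rationale = sprintf("%d species covering %s: sufficient for a probabilistic SSD",
                             n_sp, paste(required_groups, collapse = ", ")))
  } else {
    why <- character(0)
    if (n_sp < min_species) {
      why <- c(why, sprintf("only %d species (< %d)", n_sp, min_species))
    }
    if (length(missing) > 0L) {
      why <- c(why, sprintf("missing trophic group(s): %s",
                            paste(missing, collapse = ", ")))
    }
    list(strategy = "assessment_factor",
         rationale = paste(why, collapse = "; "))
  }
}

#' Export the empirical SSD curve
#'
#' Species ranked by their median chronic NOEC with the empirical
#' cumulative fraction affected, for plotting species-sensitivity curves.
#'
#' @param species_sets a [build_species_sets()] result.
#' @return data.frame with `species`, `group`, `median_noec` (mg/L),
#'   `rank`, `fraction_affected`.
#' @export
ssd_curve <- function(species_sets) {
  med <- vapply(species_sets, function(s) stats::median(s$values), 1.0)
  ord <- order(med)
  n <- length(med)
  data.frame(species = vapply(species_sets, `[[`, "", "species")[ord],
             group = vapply(species_sets, `[[`, "", "group")[ord],
             median_noec = med[ord],
             rank = seq_len(n),
             fraction_affected = (seq_len(n) - 0.5) / n,
             row.names = NULL)
}
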