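# Concentration units: power-of-ten exponent relative to g/L or g/kg.
.conc_units <- list(
  "ng/L"  = list(basis = "L",  exp = -9L),
  "ug/L"  = list(basis = "L",  exp = -6L),
  "mg/L"  = list(basis = "L",  exp = -3L),
  "ng/kg" = list(basis = "kg", exp = -9L),
  "ug/kg" = list(basis = "kg", exp = -6L),
  "mg/kg" = list(basis = "kg", exp = -3L)
)

#' Environmental compartment specification
#'
#' Receiving-compartment geometry used to convert annual release masses to
#' concentrations.  The freshwater volume is typically derived from surface
#' area times mean depth; the hydraulic residence time defaults to the
#' 40 days recommended for regional-scale freshwater assessment.
#'
#' @param freshwater_volume_L total freshwater volume (litres).
#' @param residence_time_days hydraulic residence time (days, at most 365).
#' @param soil_mass_natural_urban_kg,soil_mass_sludge_kg receiving soil
#'   masses (kilograms); optional when only freshwater is assessed.
#' @return list of class `compartment_spec`.
#' @export
compartment_spec <- function(freshwater_volume_L,
                             residence_time_days = 40,
                             soil_mass_natural_urban_kg = NULL,
                             soil_mass_sludge_kg = NULL) {
  if (freshwater_volume_L <= 0) stop("freshwater volume must be positive", call. = FALSE)
  if (residence_time_days <= 0 || residence_time_days > 365) {
    stop("residence time must lie in (0, 365] days", call. = FALSE)
  }
  for (m in c(soil_mass_natural_urban_kg, soil_mass_sludge_kg)) {
    if (!is.null(m) && m <= 0) stop("soil masses must be positive", call. = FALSE)
  }
  structure(list(freshwater_volume_L = freshwater_volume_L,
                 residence_time_days = residence_time_days,
                 soil_mass_natural_urban_kg = soil_mass_natural_urban_kg,
                 soil_mass_sludge_kg = soil_mass_sludge_kg),
            class = "compartment_spec")
}

#' Concentration distribution
#'
#' Monte-Carlo samples of an environmental concentration together with an
#' explicit unit.
#'
#' @param samples non-negative numeric vector.
#' @param unit one of `"ng/L"`, `"ug/L"`, `"mg/L"`, `"ng/kg"`, `"ug/kg"`,
#'   `"mg/kg"`.
#' @return object of class `conc_dist`.
#' @export
conc_dist <- function(samples, unit) {
  unit <- check_conc_unit(unit)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)) || any(samples < 0)) {
    stop("concentration samples must be finite and non-negative", call. = FALSE)
  }
  structure(list(samples = samples, unit = unit), class = "conc_dist")
}

check_conc_unit <- function(unit) {
  # accept the micro sign as an alias for 'u'
  unit <- gsub("µ|μ", "u", unit)
  if (!unit %in% names(.conc_units)) {
    stop(sprintf("unknown concentration unit '%s'; use one of %s", unit,
                 paste(names(.conc_units), collapse = ", ")), call. = FALSE)
  }
  unit
}

#' Convert concentration values between units
#'
#' Conversions are exact powers of ten within a basis (per litre or per
#' kilogram); converting across bases is an error.
#'
#' @param x numeric vector or a [conc_dist()].
#' @param from,to unit names; `from` is ignored (taken from the object) when
#'   `x` is a `conc_dist`.
#' @return same type as `x`, in unit `to`.
#' @export
convert_conc <- function(x, to, from = NULL) {
  to <- check_conc_unit(to)
  if (inherits(x, "conc_dist")) {
    return(conc_dist(convert_conc(x$samples, to, from = x$unit), to))
  }
  from <- check_conc_unit(from)
  uf <- .conc_units[[from]]; ut <- .conc_units[[to]]
  if (uf$basis != ut$basis) {
    stop(sprintf("cannot convert %s to %s (different bases)", from, to),
         call. = FALSE)
  }
  # exponent arithmetic keeps the factor an exact power of ten
  x * 10^(uf$exp - ut$exp)
}

#' @export
print.conc_dist <- function(x, ...) {
  cat(sprintf("concentration distribution: %d samples, mean %.4g %s\n",
              length(x$samples), mean(x$samples), x$unit))
  invisible(x)
}

# 1 metric tonne in nanograms
.T_TO_NG <- 1e15

#' Predicted environmental concentration in freshwater
#'
#' Divides the annual mass released to surface waters by the freshwater
#' compartment volume, sample-wise over the Monte-Carlo ensemble.  Two
#' conventions are exposed:
#' \describe{
#'   \item{`annual_dilution`}{`C = mass / volume` — the annual release
#'     diluted into the standing water volume (default).}
#'   \item{`residence_scaled`}{`C = (mass / volume) * residence_days / 365`
#'     — the steady-state concentration given the hydraulic residence time
#'     of the compartment.}
#' }
#'
#' @param release_t numeric vector of released masses (tonnes/year), one
#'   per Monte-Carlo run.
#' @param spec a [compartment_spec()].
#' @param mode `"annual_dilution"` or `"residence_scaled"`.
#' @return [conc_dist()] in ng/L.
#' @export
pec_freshwater <- function(release_t, spec,
                           mode = c("annual_dilution", "residence_scaled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "compartment_spec"))
  if (any(release_t < 0)) stop("release masses must be non-negative", call. = FALSE)
  conc <- release_t * .T_TO_NG / spec$freshwater_volume_L
  if (mode == "residence_scaled") {
    conc <- conc * spec$residence_time_days / 365
  }
  conc_dist(conc, "ng/L")
}

#' Predicted environmental concentration in soil
#'
#' Divides a mass (annual inflow or accumulated sink inventory, at the
#' caller's choice) by the receiving soil mass.
#'
#' @param mass_t numeric vector of masses (tonnes), one per run.
#' @param soil_mass_kg receiving soil mass (kg), positive.
#' @param unit output unit, `"ng/kg"` (natural/urban soils) or `"ug/kg"`
#'   (sludge-treated soils).
#' @return [conc_dist()] in `unit`.
#' @export
pec_soil <- function(mass_t, soil_mass_kg, unit = c("ng/kg", "ug/kg")) {
  unit <- match.arg(unit)
  if (soil_mass_kg <= 0) stop("soil mass must be positive", call. = FALSE)
  if (any(mass_t < 0)) stop("masses must be non-negative", call. = FALSE)
  ng_per_kg <- mass_t * .T_TO_NG / soil_mass_kg
  conc_dist(convert_conc(ng_per_kg, unit, from = "ng/kg"), unit)
}

#' Summarise a concentration (or any sample) distribution
#'
#' Empirical mean, standard deviation and the 5/25/75/95 percent quantiles
#' under linear interpolation between order statistics (quantile type 7).
#'
#' @param x a [conc_dist()] or numeric vector with at least two samples.
#' @return named list `mean`, `sd`, `q05`, `q25`, `q75`, `q95` (and `unit`
#'   when `x` carries one).
#' @export
summarize_distribution <- function(x) {
  unit <- NULL
  if (inherits(x, "conc_dist")) { unit <- x$unit; x <- x$samples }
  if (length(x) < 2L) stop("need at least two samples to summarise", call. = FALSE)
  q <- stats::quantile(x, c(0.05, 0.25, 0.75, 0.95), names = FALSE, type = 7)
  out <- list(mean = mean(x), sd = stats::sd(x),
              q05 = q[1L], q25 = q[2L], q75 = q[3L], q95 = q[4L])
  if (!is.null(unit)) out$unit <- unit
  out
}

#' Report-layer significant-figure rounding
#'
#' Rounds summary statistics the way flow-diagram and concentration tables
#' are printed: values with magnitude below 100 to two significant figures,
#' values of 100 and above to three significant figures.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @examples
#' round_report(c(46.23, 1040.4, 0.713, 68.7))  # 46, 1040, 0.71, 69
#' @export
round_report <- function(x) {
  ifelse(abs(x) < 100, signif(x, 2), signif(x, 3))
}

#' @rdname round_report
#' @return `format_report()` returns the rounded values as strings without
#'   trailing zeros.
#' @export
format_report <- function(x) {
  vapply(round_report(x), function(v) format(v, scientific = FALSE), "")
}
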