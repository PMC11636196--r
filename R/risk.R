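#' Risk characterisation ratio distribution
#'
#' Divides a predicted environmental concentration (PEC) distribution by a
#' predicted no-effect concentration (PNEC) after reconciling units.  With
#' a probabilistic PNEC (an [estimate_hc5()] result) the two Monte-Carlo
#' chains share no randomness, so PEC and PNEC samples are independently
#' resampled with replacement to a common sample count before division;
#' with a point PNEC the PEC samples are divided elementwise.
#'
#' @param pec a [conc_dist()] (per-litre unit).
#' @param pnec an `ssd_result`, a `pnec_af`, or a single number with its
#'   unit given in `pnec_unit`.
#' @param pnec_unit unit of a bare numeric `pnec` (e.g. `"ug/L"`).
#' @param n sample count of the result; defaults to the larger of the two
#'   inputs (point PNEC: the PEC sample count).
#' @param seed optional integer seed for the resampling.
#' @return list of class `rcr_dist`: dimensionless `samples` plus
#'   `pec_unit` and `pnec_unit` for the audit trail.
#' @export
rcr_distribution <- function(pec, pnec, pnec_unit = NULL, n = NULL,
                             seed = NULL) {
  stopifnot(inherits(pec, "conc_dist"))
  if (inherits(pnec, "ssd_result")) {
    pnec_samples <- pnec$hc5_samples
    pnec_u <- pnec$unit
  } else if (inherits(pnec, "pnec_af")) {
    pnec_samples <- pnec$pnec
    pnec_u <- pnec$unit
  } else {
    if (is.null(pnec_unit)) stop("a bare numeric PNEC needs pnec_unit", call. = FALSE)
    pnec_samples <- as.numeric(pnec)
    pnec_u <- pnec_unit
  }
  if (any(pnec_samples <= 0)) {
    stop("PNEC samples must be strictly positive", call. = FALSE)
  }
  # common unit: convert PNEC onto the PEC scale (errors across bases)
  pnec_conv <- convert_conc(pnec_samples, to = pec$unit, from = pnec_u)
  if (!is.null(seed)) set.seed(seed)
  if (length(pnec_conv) == 1L) {
    pec_s <- pec$samples
    if (!is.null(n) && n != length(pec_s)) {
      pec_s <- pec_s[sample.int(length(pec_s), n, replace = TRUE)]
    }
    samples <- pec_s / pnec_conv
  } else {
    if (is.null(n)) n <- max(length(pec$samples), length(pnec_conv))
    pec_s <- pec$samples[sample.int(length(pec$samples), n, replace = TRUE)]
    pnec_s <- pnec_conv[sample.int(length(pnec_conv), n, replace = TRUE)]
    samples <- pec_s / pnec_s
  }
  structure(list(samples = samples, pec_unit = pec$unit,
                 pnec_unit = check_conc_unit(pnec_u)),
            class = "rcr_dist")
}

#' @export
print.rcr_dist <- function(x, ...) {
  cat(sprintf(
    "RCR distribution: %d samples, mean %.3g, P(RCR > 1) = %.3g\n",
    length(x$samples), mean(x$samples), exceedance_probability(x)))
  invisible(x)
}

#' Orders of magnitude below the risk threshold of one
#'
#' `floor(-log10(mean_rcr))`: how many full powers of ten the mean risk
#' characterisation ratio lies below 1.
#'
#' @param mean_rcr positive mean RCR.
#' @return non-negative integer; a mean above 1 returns 0 with a warning.
#' @examples
#' orders_below_one(1e-5)   # 5
#' orders_below_one(3.2e-4) # 3
#' @export
orders_below_one <- function(mean_rcr) {
  if (!is.finite(mean_rcr) || mean_rcr <= 0) {
    stop("mean RCR must be positive", call. = FALSE)
  }
  if (mean_rcr > 1) {
    warning("mean RCR exceeds 1; reporting 0 orders below one")
    return(0L)
  }
  # guard against log10 of exact powers of ten landing below the integer
  as.integer(floor(-log10(mean_rcr) + 1e-12))
}

#' Probability that the RCR exceeds a threshold
#'
#' Empirical fraction of RCR samples above the threshold (default 1, the
#' regulatory trigger).
#'
#' @param rcr an `rcr_dist` or numeric vector of ratios.
#' @param threshold exceedance threshold.
#' @return fraction in `[0, 1]`.
#' @export
exceedance_probability <- function(rcr, threshold = 1) {
  samples <- if (inherits(rcr, "rcr_dist")) rcr$samples else as.numeric(rcr)
  if (length(samples) < 1L) stop("need at least one sample", call. = FALSE)
  mean(samples > threshold)
}

#' One-row risk summary
#'
#' @param rcr an `rcr_dist`.
#' @return data.frame with mean, interquartile range, exceedance
#'   probability at 1 and orders of magnitude below one.
#' @export
summarize_rcr <- function(rcr) {
  stopifnot(inherits(rcr, "rcr_dist"))
  s <- rcr$samples
  q <- stats::quantile(s, c(0.25, 0.75), names = FALSE, type = 7)
  data.frame(mean = mean(s), q25 = q[1L], q75 = q[2L],
             p_exceed_1 = exceedance_probability(rcr),
             orders_below_one = orders_below_one(mean(s)))
}
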