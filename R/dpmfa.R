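#' Compartment graph for material-flow simulation
#'
#' Defines the system of technical and environmental compartments and the
#' directed mass-flow edges between them.  Compartment kinds:
#' \describe{
#'   \item{`technical`/`environmental`}{ordinary flow-through compartments;
#'     a release schedule may turn them into in-use stocks.}
#'   \item{`transfer`}{compartments (e.g. air) through which mass flows in
#'     and out within a year without accumulating stock.}
#'   \item{`sink`}{final compartments (landfill, subsurface, soils) with no
#'     outgoing edges; they accumulate mass over the horizon.}
#'   \item{`elimination`}{mass destroyed (e.g. by incineration) and leaving
#'     the system; accumulates like a sink.}
#' }
#'
#' @param compartments data.frame with columns `name` and `kind`.
#' @param edges data.frame with columns `from` and `to`.
#' @return object of class `compartment_graph` with a precomputed
#'   topological order of the non-sink compartments.
#' @export
compartment_graph <- function(compartments, edges) {
  kinds <- c("technical", "environmental", "transfer", "sink", "elimination")
  stopifnot(is.data.frame(compartments), is.data.frame(edges))
  if (!all(c("name", "kind") %in% names(compartments)) ||
      !all(c("from", "to") %in% names(edges))) {
    stop("compartments need columns name/kind; edges need from/to", call. = FALSE)
  }
  compartments$name <- as.character(compartments$name)
  compartments$kind <- as.character(compartments$kind)
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (anyDuplicated(compartments$name)) {
    stop("duplicate compartment names", call. = FALSE)
  }
  bad_kind <- setdiff(compartments$kind, kinds)
  if (length(bad_kind) > 0L) {
    stop(sprintf("unknown compartment kind(s): %s",
                 paste(bad_kind, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(c(edges$from, edges$to), compartments$name)
  if (length(unknown) > 0L) {
    stop(sprintf("edges reference unknown compartment(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  kind_of <- stats::setNames(compartments$kind, compartments$name)
  terminal <- kind_of[edges$from] %in% c("sink", "elimination")
  if (any(terminal)) {
    stop(sprintf("sink/elimination compartment(s) %s must not have outgoing edges",
                 paste(unique(edges$from[terminal]), collapse = ", ")),
         call. = FALSE)
  }
  nonterminal <- compartments$name[!kind_of %in% c("sink", "elimination")]
  no_out <- setdiff(nonterminal, edges$from)
  if (length(no_out) > 0L) {
    stop(sprintf("non-sink compartment(s) without outgoing edges: %s",
                 paste(no_out, collapse = ", ")), call. = FALSE)
  }
  g <- structure(list(compartments = compartments, edges = edges,
                      kind = kind_of),
                 class = "compartment_graph")
  g$topo <- topological_order(g)     # errors on within-year cycles
  g
}

# Kahn topological sort of the non-sink compartments; sinks/elimination are
# appended last.  A cycle among non-sink compartments is an error because a
# single within-year pass could not propagate it.
topological_order <- function(graph) {
  kind <- graph$kind
  nodes <- names(kind)[!kind %in% c("sink", "elimination")]
  e <- graph$edges[graph$edges$to %in% nodes, , drop = FALSE]
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(e$to, levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  queue <- nodes[indeg == 0L]
  while (length(queue) > 0L) {
    n <- queue[1L]; queue <- queue[-1L]
    order <- c(order, n)
    outs <- e$to[e$from == n]
    for (m in outs) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) queue <- c(queue, m)
    }
  }
  if (length(order) < length(nodes)) {
    stop(sprintf("cycle among non-sink compartments: %s",
                 paste(setdiff(nodes, order), collapse = ", ")), call. = FALSE)
  }
  c(order, names(kind)[kind %in% c("sink", "elimination")])
}

#' Transfer-coefficient prior on one edge
#'
#' @param from,to compartment names of the edge.
#' @param dist one of `"point"`, `"uniform"`, `"triangular"`.
#' @param params numeric parameters: `v` for point, `(lo, hi)` for uniform,
#'   `(lo, mode, hi)` for triangular; all in `[0, 1]` and ordered.
#' @return a `tc_prior` list.
#' @export
tc_prior <- function(from, to, dist = c("point", "uniform", "triangular"),
                     params) {
  dist <- match.arg(dist)
  params <- as.numeric(params)
  n_need <- c(point = 1L, uniform = 2L, triangular = 3L)[[dist]]
  if (length(params) != n_need) {
    stop(sprintf("%s prior needs %d parameter(s)", dist, n_need), call. = FALSE)
  }
  if (any(params < 0 | params > 1)) {
    stop("transfer-coefficient parameters must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(params)) {
    stop("transfer-coefficient parameters must be ordered (lo <= mode <= hi)",
         call. = FALSE)
  }
  structure(list(from = from, to = to, dist = dist, params = params),
            class = "tc_prior")
}

rtriangular <- function(n, lo, mode, hi) {
  if (hi == lo) return(rep(lo, n))
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

draw_prior <- function(prior, n) {
  switch(prior$dist,
         point = rep(prior$params[1L], n),
         uniform = stats::runif(n, prior$params[1L], prior$params[2L]),
         triangular = rtriangular(n, prior$params[1L], prior$params[2L],
                                  prior$params[3L]))
}

#' Sample realised transfer coefficients
#'
#' Draws every outgoing coefficient of every non-sink compartment from its
#' prior and renormalises each compartment's outgoing vector to sum to
#' exactly one (the standard draw-then-renormalise construction of
#' probabilistic material-flow analysis).  Point priors that already sum to
#' one pass through unchanged.
#'
#' @param graph a [compartment_graph()].
#' @param priors list of [tc_prior()] objects covering every edge.
#' @param n_runs number of Monte-Carlo realisations.
#' @param seed optional integer seed.
#' @return numeric matrix `n_runs` x edges (columns named `"from->to"`),
#'   normalised per source compartment.
#' @export
sample_transfer_coefficients <- function(graph, priors, n_runs = 1L,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  edges <- graph$edges
  key <- paste0(edges$from, "->", edges$to)
  pkey <- vapply(priors, function(p) paste0(p$from, "->", p$to), "")
  missing <- setdiff(key, pkey)
  if (length(missing) > 0L) {
    stop(sprintf("no transfer-coefficient prior for edge(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  draws <- matrix(0, nrow = n_runs, ncol = nrow(edges),
                  dimnames = list(NULL, key))
  for (j in seq_along(key)) {
    draws[, j] <- draw_prior(priors[[match(key[j], pkey)]], n_runs)
  }
  for (src in unique(edges$from)) {
    cols <- which(edges$from == src)
    tot <- rowSums(draws[, cols, drop = FALSE])
    if (any(tot <= 0)) {
      stop(sprintf("all outgoing transfer coefficients of '%s' drawn zero", src),
           call. = FALSE)
    }
    draws[, cols] <- draws[, cols, drop = FALSE] / tot
  }
  draws
}

#' Propagate one year of mass through the compartment graph
#'
#' Each compartment distributes its annual throughput (external inflow +
#' same-year upstream inflow + scheduled releases from its stock cohorts)
#' over its outgoing edges according to the realised transfer coefficients.
#' Multi-hop transport (e.g. production -> air -> soil) completes within the
#' year; transfer compartments therefore end every year with zero stock,
#' while scheduled in-use compartments retain unreleased cohort mass.
#'
#' @param graph a [compartment_graph()].
#' @param tc coefficient matrix from [sample_transfer_coefficients()]
#'   (rows = runs).
#' @param inflow named list mapping compartment -> numeric vector (one
#'   external inflow per run, tonnes).
#' @param cohorts internal cohort state (list per scheduled compartment of
#'   run x entry-year matrices); use `NULL` for the first year.
#' @param schedules named list mapping compartment -> numeric vector of
#'   release fractions by lag (index 1 = same year).  Compartments without
#'   an entry release everything immediately.
#' @param year_index 1-based index of the simulated year (for cohort ages).
#' @return list with `flows` (run x edge matrix), `received` (run x
#'   compartment matrix of total inflows), `stocks` (run x compartment
#'   end-of-year stock) and the updated `cohorts`.
#' @export
propagate_year <- function(graph, tc, inflow, cohorts = NULL,
                           schedules = list(), year_index = 1L) {
  edges <- graph$edges
  comps <- graph$compartments$name
  n_runs <- nrow(tc)
  for (sched in schedules) {
    if (any(sched < 0) || sum(sched) > 1 + 1e-12) {
      stop("release schedule fractions must be non-negative and sum to <= 1",
           call. = FALSE)
    }
  }
  if (is.null(cohorts)) cohorts <- list()
  zero <- numeric(n_runs)
  received <- matrix(0, n_runs, length(comps), dimnames = list(NULL, comps))
  flows <- matrix(0, n_runs, nrow(edges),
                  dimnames = list(NULL, paste0(edges$from, "->", edges$to)))
  stocks <- matrix(0, n_runs, length(comps), dimnames = list(NULL, comps))

  for (node in graph$topo) {
    ext <- inflow[[node]] %||% zero
    upstream <- if (any(edges$to == node)) {
      rowSums(flows[, edges$to == node, drop = FALSE])
    } else zero
    received[, node] <- ext + upstream
    if (graph$kind[[node]] %in% c("sink", "elimination")) next

    sched <- schedules[[node]]
    if (is.null(sched)) {
      out_mass <- received[, node]
    } else {
      # append this year's intake as a new cohort; release fractions are of
      # the cohort's original mass, so track original and remaining
      st <- cohorts[[node]]
      if (is.null(st)) {
        st <- list(orig = matrix(numeric(0), n_runs, 0L),
                   rem = matrix(numeric(0), n_runs, 0L))
      }
      st$orig <- cbind(st$orig, received[, node])
      st$rem <- cbind(st$rem, received[, node])
      ages <- year_index - seq_len(ncol(st$orig)) + 1L  # lag 1 = this year
      frac <- ifelse(ages <= length(sched), sched[pmin(ages, length(sched))], 0)
      release <- st$orig * rep(frac, each = n_runs)
      out_mass <- rowSums(release)
      st$rem <- st$rem - release
      cohorts[[node]] <- st
      stocks[, node] <- rowSums(st$rem)
    }
    cols <- which(edges$from == node)
    flows[, cols] <- tc[, cols, drop = FALSE] * out_mass
  }
  transfer <- comps[graph$kind == "transfer"]
  if (length(transfer) > 0L && any(stocks[, transfer] != 0)) {
    stop("transfer compartments must not accumulate stock", call. = FALSE)
  }
  list(flows = flows, received = received, stocks = stocks, cohorts = cohorts)
}

#' Run a dynamic probabilistic material-flow simulation
#'
#' Monte-Carlo loop over runs and years: transfer coefficients are sampled
#' once per run (parameter uncertainty) and held fixed across years; yearly
#' external inflows are propagated through the compartment graph; sinks and
#' elimination accumulate; scheduled in-use compartments build up stock.
#'
#' @param scenario list with elements `graph` ([compartment_graph()]),
#'   `priors` (list of [tc_prior()]), `inflow` (named list mapping
#'   compartment -> years x runs matrix of external inflows, tonnes/year;
#'   year labels in rownames) and optionally `schedules` (see
#'   [propagate_year()]).
#' @param n_runs Monte-Carlo runs; inflow matrices with one column are
#'   recycled across runs.
#' @param seed integer seed; the simulation is fully deterministic given
#'   `seed` and the scenario.
#' @param tc optional precomputed coefficient matrix (e.g. to share
#'   transfer-coefficient randomness across material forms); overrides
#'   sampling.
#' @return a `flow_ensemble`: list with `flows` (run x year x edge array),
#'   `received` (run x year x compartment), `stocks` (run x year x
#'   compartment), `sinks` (run x compartment accumulated inflow over the
#'   horizon), `inflow_cum` (run x year cumulative external inflow), plus
#'   `graph`, `years`, `n_runs`.
#' @export
run_simulation <- function(scenario, n_runs = 10000L, seed = NULL, tc = NULL) {
  graph <- scenario$graph
  stopifnot(inherits(graph, "compartment_graph"), n_runs >= 1L)
  years <- rownames(scenario$inflow[[1L]])
  if (is.null(years)) stop("inflow matrices need year rownames", call. = FALSE)
  n_years <- length(years)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tc)) {
    tc <- sample_transfer_coefficients(graph, scenario$priors, n_runs)
  }
  if (nrow(tc) != n_runs) stop("tc rows must equal n_runs", call. = FALSE)

  comps <- graph$compartments$name
  edge_key <- paste0(graph$edges$from, "->", graph$edges$to)
  terminal <- comps[graph$kind %in% c("sink", "elimination")]
  flows <- array(0, c(n_runs, n_years, length(edge_key)),
                 dimnames = list(NULL, years, edge_key))
  received <- array(0, c(n_runs, n_years, length(comps)),
                    dimnames = list(NULL, years, comps))
  stocks <- array(0, c(n_runs, n_years, length(comps)),
                  dimnames = list(NULL, years, comps))
  sinks <- matrix(0, n_runs, length(terminal),
                  dimnames = list(NULL, terminal))
  inflow_cum <- matrix(0, n_runs, n_years, dimnames = list(NULL, years))

  cohorts <- NULL
  cum <- numeric(n_runs)
  for (y in seq_len(n_years)) {
    inflow_y <- lapply(scenario$inflow, function(m) {
      v <- m[years[y], ]
      if (length(v) == 1L) return(rep(as.numeric(v), n_runs))
      if (length(v) != n_runs) {
        stop("inflow sample count must be 1 or n_runs", call. = FALSE)
      }
      as.numeric(v)
    })
    step <- propagate_year(graph, tc, inflow_y, cohorts,
                           scenario$schedules %||% list(), year_index = y)
    cohorts <- step$cohorts
    flows[, y, ] <- step$flows
    received[, y, ] <- step$received
    stocks[, y, ] <- step$stocks
    sinks <- sinks + step$received[, terminal, drop = FALSE]
    cum <- cum + Reduce(`+`, inflow_y, accumulate = FALSE)
    inflow_cum[, y] <- cum
  }
  structure(list(flows = flows, received = received, stocks = stocks,
                 sinks = sinks, inflow_cum = inflow_cum, graph = graph,
                 years = years, n_runs = n_runs, tc = tc),
            class = "flow_ensemble")
}

#' @export
print.flow_ensemble <- function(x, ...) {
  cat(sprintf("flow ensemble: %d runs x %d years, %d compartments, %d edges\n",
              x$n_runs, length(x$years), nrow(x$graph$compartments),
              nrow(x$graph$edges)))
  cat("mean accumulated sink masses (t):\n")
  print(round(colMeans(x$sinks), 3))
  invisible(x)
}

#' Mass-balance residuals of a flow ensemble
#'
#' For every run and year, compares cumulative external inflow with the sum
#' of accumulated sink/elimination inventories and end-of-year stocks.  The
#' residual is reported relative to cumulative inflow (zero inflow gives a
#' zero relative residual only when the absolute residual is also zero).
#'
#' @param ensemble a `flow_ensemble` from [run_simulation()].
#' @return list with `residual` (run x year relative residuals) and
#'   `max_abs` (largest absolute relative residual).
#' @export
mass_balance_report <- function(ensemble) {
  terminal <- colnames(ensemble$sinks)
  n_years <- length(ensemble$years)
  n_runs <- ensemble$n_runs
  res <- matrix(0, n_runs, n_years, dimnames = list(NULL, ensemble$years))
  sink_cum <- numeric(n_runs)
  for (y in seq_len(n_years)) {
    rec_y <- ensemble$received[, y, terminal, drop = FALSE]
    sink_cum <- sink_cum + rowSums(matrix(rec_y, nrow = n_runs))
    held <- rowSums(matrix(ensemble$stocks[, y, , drop = FALSE], nrow = n_runs))
    bal <- ensemble$inflow_cum[, y] - sink_cum - held
    denom <- ifelse(ensemble$inflow_cum[, y] > 0, ensemble$inflow_cum[, y], 1)
    res[, y] <- bal / denom
  }
  list(residual = res, max_abs = max(abs(res)))
}

#' Share of each material form in an accumulated sink
#'
#' Normalises the mean accumulated mass of each form in one sink
#' compartment into shares summing to one.
#'
#' @param ensembles named list of `flow_ensemble`s, one per form, simulated
#'   on the same graph and horizon.
#' @param compartment sink compartment name.
#' @return named numeric vector of shares over the forms.
#' @export
sink_distribution_by_form <- function(ensembles, compartment) {
  masses <- vapply(ensembles, function(e) {
    if (!compartment %in% colnames(e$sinks)) {
      stop(sprintf("'%s' is not a sink/elimination compartment", compartment),
           call. = FALSE)
    }
    mean(e$sinks[, compartment])
  }, 1.0)
  tot <- sum(masses)
  if (tot <= 0) {
    stop(sprintf("no mass accumulated in '%s' for any form", compartment),
         call. = FALSE)
  }
  masses / tot
}
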