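# Shared fixture builders; everything is generated in code.

# chain A -> B -> sink with point transfer coefficients
chain_scenario <- function(inflow_t = 10, n_years = 3, n_runs = 1) {
  graph <- compartment_graph(
    data.frame(name = c("A", "B", "final"),
               kind = c("technical", "technical", "sink")),
    data.frame(from = c("A", "B"), to = c("B", "final")))
  priors <- list(tc_prior("A", "B", "point", 1),
                 tc_prior("B", "final", "point", 1))
  years <- as.character(seq_len(n_years) + 2020)
  inflow <- matrix(inflow_t, n_years, n_runs, dimnames = list(years, NULL))
  list(graph = graph, priors = priors, inflow = list(A = inflow),
       schedules = list())
}

# two-branch split: source -> {left, right} sinks with point TCs
branch_scenario <- function(p_left = 0.7, inflow_t = 10, n_years = 1,
                            n_runs = 1) {
  graph <- compartment_graph(
    data.frame(name = c("src", "left", "right"),
               kind = c("technical", "sink", "sink")),
    data.frame(from = c("src", "src"), to = c("left", "right")))
  priors <- list(tc_prior("src", "left", "point", p_left),
                 tc_prior("src", "right", "point", 1 - p_left))
  years <- as.character(seq_len(n_years) + 2020)
  inflow <- matrix(inflow_t, n_years, n_runs, dimnames = list(years, NULL))
  list(graph = graph, priors = priors, inflow = list(src = inflow),
       schedules = list())
}

# minimal record table builder
records_of <- function(values, species = paste0("sp", seq_along(values)),
                       group = "algae", form = "GBM",
                       descriptor = "NOEC", regime = "chronic") {
  toxicity_records(data.frame(
    species = species, group = group, form = form,
    descriptor = descriptor, regime = regime,
    value = values, source = "fixture"))
}

random_share_matrix <- function(n, k, row_labels = as.character(seq_len(n)),
                                col_labels = paste0("c", seq_len(k))) {
  g <- matrix(stats::rgamma(n * k, 1), n, k)
  share_matrix(g / rowSums(g), row_labels = row_labels,
               col_labels = col_labels)
}
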