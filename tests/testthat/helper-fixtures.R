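# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

# quick ts_matrix from a numeric matrix; proteins default to one per row
make_ts <- function(values, proteins = NULL, grid = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  proteins <- proteins %||% sprintf("PR%02d", seq_len(n))
  grid <- grid %||%
    (if (ncol(values) == 13L) default_time_grid() else seq_len(ncol(values)))
  ts_matrix(sprintf("pep%02d", seq_len(n)), proteins, values, grid)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# the printed worked-example rows: two class representatives on the
# standard 13-point grid
table2_class_one <- c(-0.11, -0.21, -0.33, -0.05, -0.01, -0.27, 0.06,
                      0.54, 0.07, -0.05, -0.21, -0.37, -1.05)
table2_class_two <- c(-0.15, -0.11, -0.08, -0.12, -0.24, -0.25, -0.18,
                      -0.21, -0.32, -0.54, -0.68, -0.28, -0.19)

# hand-computed period differences of the two rows above
table2_periods_one <- c(-0.10, -0.12, 0.28, 0.04, -0.26, 0.33, 0.48,
                        -0.47, -0.12, -0.16, -0.16, -0.68)
table2_periods_two <- c(0.04, 0.03, -0.04, -0.12, -0.01, 0.07, -0.03,
                        -0.11, -0.22, -0.14, 0.40, 0.09)

# basket dataset straight from a list of integer item vectors (first item
# doubles as the anchor)
make_baskets <- function(itemsets) {
  records <- lapply(itemsets, function(it) {
    it <- as.integer(it)
    list(anchor = it[1L], items = sort(unique(it)))
  })
  structure(list(records = records, n_records = length(records),
                 class_ids = sort(unique(unlist(itemsets)))),
            class = "dcaa_baskets")
}

# independent oracle: exhaustive enumeration of every nonempty itemset over
# the item universe, with supports counted directly
oracle_frequent_itemsets <- function(itemsets, min_support) {
  trans <- lapply(itemsets, function(x) sort(unique(as.integer(x))))
  universe <- sort(unique(unlist(trans)))
  n <- length(trans)
  out <- list()
  for (size in seq_along(universe)) {
    sets <- utils::combn(universe, size, simplify = FALSE)
    for (s in sets) {
      cnt <- sum(vapply(trans, function(tr) all(s %in% tr), logical(1)))
      if (cnt / n >= min_support) {
        out[[length(out) + 1L]] <- list(items = s, count = cnt,
                                        support = cnt / n)
      }
    }
  }
  out
}

# independent two-pass (centered) Pearson implementation
pearson_two_pass <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# canonical unordered pair labels for comparing prediction sets
pkey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# the benchmark scenario used by the end-to-end tests: 60 proteins, 40
# planted influences with lags 1-3, 3 peptides per protein, low noise
benchmark_scenario <- function(seed, n_edges = 40L) {
  truth <- plant_network(60L, n_edges, c(1L, 3L), seed = seed)
  sim <- simulate_timeseries(truth, peptides_per_protein = 3L,
                             noise_sd = 0.02, seed = seed)
  config <- dcaa_config(method = "full_trend", zero_eps = 0.12,
                        replicates = 100L, seed = seed)
  list(truth = sim$truth, matrix = sim$matrix, config = config)
}
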