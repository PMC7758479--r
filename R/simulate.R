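# Seeded synthetic-data generator: co-trending peptide groups with planted
# lagged upstream -> downstream influences, plus the matching ground truth.
# All outputs are bit-reproducible from (parameters, seed).

#' Plant a synthetic influence network
#'
#' Samples `n_edges` distinct directed edges without self-loops, with lags
#' drawn uniformly from `lag_range`. Edges are drawn uniformly subject to
#' structural constraints that follow from the profile model of
#' [simulate_timeseries()]: each target has exactly one upstream driver
#' (two parents would define its profile twice) and drivers are not
#' themselves targets, so influences form a two-level forest of stars.
#' Chained cascades are deliberately not planted: every hop shifts the
#' profile by its lag and pads the start, so cumulative shifts progressively
#' replace a deep descendant's profile with a constant stretch, making
#' planted-edge recovery ill-defined. The number of edges is capped at
#' `n_proteins - 1`.
#'
#' @param n_proteins Number of proteins.
#' @param n_edges Number of planted influences (0..`n_proteins - 1`).
#' @param lag_range Length-2 integer range of lags in period units;
#'   default `c(1, 3)`.
#' @param seed Integer RNG seed.
#' @return Object of class `dcaa_ground_truth`: list with `proteins`,
#'   `edges` (data frame `source`, `target`, `lag`), `lag_range`, `seed`,
#'   `params`.
#' @export
plant_network <- function(n_proteins, n_edges, lag_range = c(1L, 3L), seed) {
  if (n_proteins < 2L && n_edges > 0L) stop("need at least two proteins")
  if (n_edges > n_proteins - 1L) {
    stop("n_edges must not exceed n_proteins - 1 (each target has one driver)")
  }
  if (lag_range[1L] < 1L || lag_range[2L] < lag_range[1L]) {
    stop("lag_range must be an increasing positive integer interval")
  }
  proteins <- sprintf("SYNP%04d", seq_len(n_proteins))
  edges <- with_seed(seed, {
    if (n_edges == 0L) {
      data.frame(source = character(0), target = character(0),
                 lag = integer(0), stringsAsFactors = FALSE)
    } else {
      tgt <- sort(sample.int(n_proteins, n_edges))
      pool <- setdiff(seq_len(n_proteins), tgt)
      src <- pool[sample.int(length(pool), n_edges, replace = TRUE)]
      lags <- seq(lag_range[1L], lag_range[2L])
      lag <- lags[sample.int(length(lags), n_edges, replace = TRUE)]
      data.frame(source = proteins[src], target = proteins[tgt], lag = lag,
                 stringsAsFactors = FALSE)
    }
  })
  structure(
    list(proteins = proteins, edges = edges,
         lag_range = as.integer(lag_range), seed = seed,
         params = list(n_proteins = n_proteins, n_edges = n_edges)),
    class = "dcaa_ground_truth"
  )
}

#' @export
print.dcaa_ground_truth <- function(x, ...) {
  cat(sprintf("dcaa_ground_truth: %d proteins, %d planted edges (lags %d..%d)\n",
              length(x$proteins), nrow(x$edges),
              x$lag_range[1L], x$lag_range[2L]))
  invisible(x)
}

# Random piecewise-linear base profile expressed as period changes: most
# periods move by a step well above the noise floor, a minority are flat so
# that all three trend symbols occur.
base_periods <- function(n_periods, step_range, zero_prob) {
  flat <- stats::runif(n_periods) < zero_prob
  sign <- ifelse(stats::runif(n_periods) < 0.5, -1, 1)
  mag <- stats::runif(n_periods, step_range[1L], step_range[2L])
  ifelse(flat, 0, sign * mag)
}

shift_profile <- function(values, lag) {
  n <- length(values)
  c(rep(values[1L], lag), values)[seq_len(n)]
}

#' Simulate peptide time series with planted lagged influences
#'
#' Source proteins receive random piecewise-linear profiles whose period
#' changes have magnitude at least `5 * noise_sd` (flat periods occur with
#' probability `zero_prob`). A target's profile is its source's realized
#' profile shifted forward by the edge's lag in period index (early values
#' padded with the source's first value) plus independent Gaussian noise of
#' sd `noise_sd` per point; influence chains accumulate shifts. Unconnected
#' proteins get independent profiles. Every protein then emits
#' `peptides_per_protein` peptide rows, each the protein profile plus
#' independent Gaussian noise.
#'
#' @param truth A [plant_network()] result.
#' @param peptides_per_protein Peptide rows per protein; default 3.
#' @param n_timepoints Number of time points; default 13 (the standard
#'   grid). Other lengths use a unit-spaced grid.
#' @param noise_sd Gaussian noise sd per point; default 0.02.
#' @param seed Integer RNG seed; defaults to the truth's seed.
#' @param step_range Magnitude range of non-flat period changes; default
#'   `c(0.3, 0.8)`.
#' @param zero_prob Probability of a flat period; default 0.2.
#' @return List with `matrix` (a [ts_matrix()]) and `truth` (the input
#'   ground truth extended with `profiles` and the generator `params`).
#' @export
simulate_timeseries <- function(truth, peptides_per_protein = 3L,
                                n_timepoints = 13L, noise_sd = 0.02,
                                seed = truth$seed,
                                step_range = c(0.3, 0.8), zero_prob = 0.2) {
  stopifnot(inherits(truth, "dcaa_ground_truth"))
  if (peptides_per_protein < 1L) stop("peptides_per_protein must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  grid <- if (n_timepoints == 13L) default_time_grid() else seq_len(n_timepoints)
  n_prot <- length(truth$proteins)
  prot_index <- stats::setNames(seq_len(n_prot), truth$proteins)

  sim <- with_seed(seed, {
    profiles <- matrix(NA_real_, n_prot, n_timepoints,
                       dimnames = list(truth$proteins, NULL))
    parent <- rep(NA_integer_, n_prot)
    lag_of <- rep(NA_integer_, n_prot)
    if (nrow(truth$edges)) {
      parent[prot_index[truth$edges$target]] <- prot_index[truth$edges$source]
      lag_of[prot_index[truth$edges$target]] <- truth$edges$lag
    }
    # roots first, then children whose parents are already realized; the
    # planted forest is acyclic, so repeated passes terminate. Profiles are
    # drawn in protein order per pass, keeping the draw sequence (and hence
    # the output) a pure function of the seed.
    pending <- seq_len(n_prot)
    while (length(pending)) {
      progressed <- FALSE
      for (v in pending) {
        p <- parent[v]
        if (is.na(p)) {
          periods <- base_periods(n_timepoints - 1L, step_range, zero_prob)
          profiles[v, ] <- cumsum(c(0, periods)) +
            stats::rnorm(n_timepoints, 0, noise_sd)
          progressed <- TRUE
        } else if (!anyNA(profiles[p, ])) {
          profiles[v, ] <- shift_profile(profiles[p, ], lag_of[v]) +
            stats::rnorm(n_timepoints, 0, noise_sd)
          progressed <- TRUE
        }
      }
      pending <- which(rowSums(is.na(profiles)) > 0)
      if (!progressed && length(pending)) {
        stop("internal error: cyclic ground truth")  # nocov
      }
    }
    peptide_id <- character(0); protein_id <- character(0)
    vals <- matrix(NA_real_, n_prot * peptides_per_protein, n_timepoints)
    r <- 0L
    for (v in seq_len(n_prot)) {
      for (k in seq_len(peptides_per_protein)) {
        r <- r + 1L
        vals[r, ] <- profiles[v, ] + stats::rnorm(n_timepoints, 0, noise_sd)
        peptide_id[r] <- sprintf("%s_pep%d", truth$proteins[v], k)
        protein_id[r] <- truth$proteins[v]
      }
    }
    list(profiles = profiles,
         matrix = ts_matrix(peptide_id, protein_id, vals, grid))
  })

  truth$profiles <- sim$profiles
  truth$params <- utils::modifyList(truth$params, list(
    peptides_per_protein = as.integer(peptides_per_protein),
    n_timepoints = as.integer(n_timepoints), noise_sd = noise_sd,
    step_range = step_range, zero_prob = zero_prob, sim_seed = seed))
  list(matrix = sim$matrix, truth = truth)
}

#' Ground truth as a reference pair set
#'
#' The planted edges as an unordered [ppi_set()], usable as the reference of
#' [hit_rate()] / [evaluate_hit_rate()].
#'
#' @param truth A `dcaa_ground_truth`.
#' @return A [ppi_set()].
#' @export
truth_reference <- function(truth) {
  stopifnot(inherits(truth, "dcaa_ground_truth"))
  if (nrow(truth$edges) == 0L) stop("ground truth has no planted edges")
  ppi_set(truth$edges$source, truth$edges$target)
}

#' Precision and recall of predictions against the planted network
#'
#' Unordered matching of predicted protein pairs against planted edges:
#' precision is the planted fraction among predictions, recall the predicted
#' fraction of planted pairs. With no predictions, recall is 0 and precision
#' is reported as `NA` (undefined).
#'
#' @param predicted Prediction data frame from [classes_to_proteins()] (or
#'   any input accepted by [hit_rate()]); a `depth` column, when present,
#'   fuels the per-depth table.
#' @param truth A `dcaa_ground_truth` with at least one planted edge.
#' @return List with `precision`, `recall`, `n_predicted`, `n_planted`, and
#'   `per_depth` (data frame `depth`, `n_predicted`, `n_hit`, `precision`,
#'   `recall_contribution`).
#' @export
evaluate_recovery <- function(predicted, truth) {
  stopifnot(inherits(truth, "dcaa_ground_truth"))
  if (nrow(truth$edges) == 0L) stop("ground truth has no planted edges")
  planted <- unique(pair_key(truth$edges$source, truth$edges$target))
  if (is.data.frame(predicted) && nrow(predicted) == 0L) {
    return(list(precision = NA_real_, recall = 0, n_predicted = 0L,
                n_planted = length(planted),
                per_depth = data.frame(depth = integer(0),
                                       n_predicted = integer(0),
                                       n_hit = integer(0),
                                       precision = numeric(0),
                                       recall_contribution = numeric(0))))
  }
  keys <- canonical_pair_keys(predicted)
  hits <- keys %in% planted
  per_depth <- if (is.data.frame(predicted) && "depth" %in% names(predicted)) {
    pk <- pair_key(predicted$protein_a, predicted$protein_b)
    do.call(rbind, lapply(sort(unique(predicted$depth)), function(d) {
      kd <- unique(pk[predicted$depth == d])
      data.frame(depth = d, n_predicted = length(kd),
                 n_hit = sum(kd %in% planted),
                 precision = sum(kd %in% planted) / length(kd),
                 recall_contribution = sum(kd %in% planted) / length(planted))
    }))
  } else {
    data.frame(depth = NA_integer_, n_predicted = length(keys),
               n_hit = sum(hits), precision = mean(hits),
               recall_contribution = sum(planted %in% keys) / length(planted))
  }
  list(precision = mean(hits),
       recall = sum(planted %in% keys) / length(planted),
       n_predicted = length(keys), n_planted = length(planted),
       per_depth = per_depth)
}
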