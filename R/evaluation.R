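# Hit-rate evaluation of predicted protein pairs against a reference
# interaction set, with a seeded random-matching baseline and an empirical
# significance test.

canonical_pair_keys <- function(predicted) {
  if (is.character(predicted) && is.null(dim(predicted))) {
    return(unique(predicted))
  }
  if (is.data.frame(predicted)) {
    cols <- intersect(c("protein_a", "protein_b"), names(predicted))
    if (length(cols) == 2L) {
      return(unique(pair_key(predicted$protein_a, predicted$protein_b)))
    }
    predicted <- as.matrix(predicted[, 1:2])
  }
  m <- as.matrix(predicted)
  if (ncol(m) < 2L) stop("predicted pairs need two columns")
  unique(pair_key(m[, 1L], m[, 2L]))
}

#' Hit rate of predicted pairs
#'
#' `R = m / M`, where `M` is the number of distinct predicted unordered
#' pairs and `m` the number of them present in the reference set. Matching
#' ignores pair orientation and duplicate predictions.
#'
#' @param predicted Predicted pairs: a data frame with `protein_a` /
#'   `protein_b`, a two-column matrix, or canonical pair keys. Must be
#'   non-empty.
#' @param reference A [ppi_set()].
#' @return List with `m`, `M`, `R`.
#' @export
hit_rate <- function(predicted, reference) {
  stopifnot(inherits(reference, "ppi_set"))
  keys <- canonical_pair_keys(predicted)
  if (length(keys) == 0L) stop("empty prediction set: hit rate undefined")
  m <- sum(keys %in% reference$keys)
  list(m = m, M = length(keys), R = m / length(keys))
}

# Unrank 1-based indices of the unordered pair space of 1..n (pairs ordered
# (1,2), (1,3), ..., (1,n), (2,3), ...) into (i, j) index pairs.
unrank_pairs <- function(idx, n) {
  sizes <- (n - 1L):1L
  ends <- cumsum(sizes)
  i <- findInterval(idx, ends, left.open = TRUE) + 1L
  j <- i + (idx - c(0L, ends)[i])
  cbind(i = i, j = j)
}

#' Random-matching baseline
#'
#' Each replicate draws `M_prime` distinct unordered protein pairs uniformly
#' from the pair space of `universe` and computes its hit rate
#' `R' = n / M'` against the reference. Reproducible: the RNG is seeded with
#' `seed` and the caller's RNG state is restored afterwards.
#'
#' @param universe Character vector of candidate accessions (>= 2 after
#'   deduplication); typically all proteins of the input matrix.
#' @param M_prime Number of pairs per replicate (must not exceed
#'   `choose(length(universe), 2)`).
#' @param reference A [ppi_set()].
#' @param replicates Number of replicates; default 100.
#' @param seed Integer RNG seed.
#' @return Numeric vector of `R'` values with attribute `seed`.
#' @export
random_baseline <- function(universe, M_prime, reference, replicates = 100L,
                            seed) {
  stopifnot(inherits(reference, "ppi_set"))
  universe <- sort(unique(as.character(universe)))
  n <- length(universe)
  if (n < 2L) stop("universe must contain at least two accessions")
  total <- choose(n, 2)
  if (M_prime < 1L || M_prime > total) {
    stop("M_prime must lie in 1..", total, " for this universe")
  }
  if (replicates < 1L) stop("replicates must be positive")
  rs <- with_seed(seed, {
    vapply(seq_len(replicates), function(rep) {
      idx <- sample.int(total, M_prime)
      ij <- unrank_pairs(sort(idx), n)
      keys <- pair_key(universe[ij[, "i"]], universe[ij[, "j"]])
      sum(keys %in% reference$keys) / M_prime
    }, numeric(1))
  })
  attr(rs, "seed") <- seed
  rs
}

#' Empirical significance of an observed hit rate
#'
#' One-sided add-one empirical p-value,
#' `p = (1 + #\{R' >= R_observed\}) / (1 + replicates)`, plus a secondary
#' normal-approximation z-score `(R_observed - mean(R')) / sd(R')`. With 100
#' replicates the smallest attainable p is 1/101, matching the granularity
#' at which baseline comparisons are usually reported. A zero-variance
#' baseline leaves the z-score undefined (`NA`) while p is still computed.
#'
#' @param R_observed Observed hit rate.
#' @param baseline Numeric vector of baseline `R'` values (non-empty).
#' @return List with `p_empirical` and `z_score`.
#' @export
significance <- function(R_observed, baseline) {
  if (length(baseline) == 0L) stop("empty baseline")
  p <- (1 + sum(baseline >= R_observed)) / (1 + length(baseline))
  z <- if (length(baseline) >= 2L && stats::sd(baseline) > 0) {
    (R_observed - mean(baseline)) / stats::sd(baseline)
  } else NA_real_
  list(p_empirical = p, z_score = z)
}

#' Full hit-rate report
#'
#' Convenience wrapper running [hit_rate()], [random_baseline()] (with
#' `M_prime = M`) and [significance()] in one call.
#'
#' @inheritParams hit_rate
#' @inheritParams random_baseline
#' @return Object of class `dcaa_hit_report`: list with `m`, `M`, `R`,
#'   `baseline_mean`, `baseline_sd`, `replicates`, `p_empirical`, `z_score`,
#'   `seed` and the full `baseline` vector.
#' @export
evaluate_hit_rate <- function(predicted, reference, universe,
                              replicates = 100L, seed) {
  hr <- hit_rate(predicted, reference)
  baseline <- random_baseline(universe, hr$M, reference, replicates, seed)
  sig <- significance(hr$R, baseline)
  structure(
    list(m = hr$m, M = hr$M, R = hr$R,
         baseline_mean = mean(baseline), baseline_sd = stats::sd(baseline),
         replicates = as.integer(replicates),
         p_empirical = sig$p_empirical, z_score = sig$z_score,
         seed = seed, baseline = baseline),
    class = "dcaa_hit_report"
  )
}

#' @export
print.dcaa_hit_report <- function(x, ...) {
  cat(sprintf(
    "dcaa_hit_report: R = %d/%d = %.4f | baseline %.4f +/- %.4f (%d reps) | p = %.4g\n",
    x$m, x$M, x$R, x$baseline_mean, x$baseline_sd, x$replicates,
    x$p_empirical))
  invisible(x)
}
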