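# Delayed sliding-window comparison of class representatives and
# construction of the shopping-basket dataset mined by Apriori.

#' Convert a series to period differences
#'
#' `T_k = t_{k+1} - t_k`: the change over each interval between adjacent time
#' points of a class representative.
#'
#' @param representative Numeric vector of finite values (length >= 2).
#' @return Numeric vector of length `length(representative) - 1`.
#' @export
to_periods <- function(representative) {
  if (length(representative) < 2L) stop("need at least two values")
  if (any(!is.finite(representative))) stop("values must be finite")
  diff(representative)
}

#' Period matrix of a representative matrix
#'
#' Row-wise [to_periods()] for a class-representative matrix.
#'
#' @param representatives Numeric matrix (classes x time points).
#' @return Numeric matrix (classes x periods) with the same row names.
#' @export
period_matrix <- function(representatives) {
  out <- t(apply(representatives, 1L, to_periods))
  rownames(out) <- rownames(representatives)
  out
}

#' Enumerate delayed sliding windows
#'
#' A window spec `w.s.d` compares `w` consecutive periods of a leading class
#' starting at period `s` against a lagging class offset by `d` periods.
#' All feasible `(s, d)` with `s >= 1`, `1 <= d <= max_delay` and
#' `s + d + w - 1 <= n_periods` are returned. For the default 12-period grid
#' with `window_len = 9` and `max_delay = 3` these are the six specs
#' 9.1.1, 9.1.2, 9.1.3, 9.2.1, 9.2.2 and 9.3.1, covering every delay
#' scenario of one to three periods.
#'
#' @param n_periods Total number of periods available (12 on the default
#'   grid).
#' @param window_len Number of periods compared (default 9).
#' @param max_delay Largest delay considered (default 3).
#' @return Data frame with columns `window_len`, `start`, `delay`, `label`;
#'   zero rows when no spec is feasible.
#' @export
enumerate_windows <- function(n_periods, window_len = 9L, max_delay = 3L) {
  if (window_len < 1L || max_delay < 1L || n_periods < 1L) {
    stop("n_periods, window_len and max_delay must be positive")
  }
  grid <- expand.grid(delay = seq_len(max_delay),
                      start = seq_len(max(n_periods, 1L)))
  ok <- grid$start + grid$delay + window_len - 1L <= n_periods
  grid <- grid[ok, , drop = FALSE]
  grid <- grid[order(grid$start, grid$delay), , drop = FALSE]
  out <- data.frame(window_len = rep(as.integer(window_len), nrow(grid)),
                    start = as.integer(grid$start),
                    delay = as.integer(grid$delay))
  out$label <- sprintf("%d.%d.%d", out$window_len, out$start, out$delay)
  rownames(out) <- NULL
  out
}

#' Single window spec
#'
#' Convenience constructor for one `w.s.d` window, validated against the
#' spec invariants.
#'
#' @param window_len,start,delay Positive integers.
#' @return One-row data frame as produced by [enumerate_windows()].
#' @export
window_spec <- function(window_len, start, delay) {
  if (window_len < 1L || start < 1L || delay < 1L) {
    stop("window_len, start and delay must all be >= 1")
  }
  data.frame(window_len = as.integer(window_len), start = as.integer(start),
             delay = as.integer(delay),
             label = sprintf("%d.%d.%d", window_len, start, delay))
}

#' Per-position delayed comparison
#'
#' For each compared position `k = s, ..., s + w - 1`, whether the leading
#' class's period `k` co-moves with the lagging class's period `k + d`:
#' either both move in the same direction (strictly positive product, with
#' both periods clear of the `zero_eps` dead zone), or both are unchanging
#' (within `zero_eps` of zero). At `zero_eps = 0` this is exactly the
#' product test `T_k(lead) * T_{k+d}(lag) > 0` or both periods equal to
#' zero; a positive `zero_eps` generalizes it to noisy data, where a flat
#' period's noise would otherwise give the product a random sign.
#'
#' @param lead,lag Period vectors (lengths at least `s + d + w - 1`).
#' @param spec One-row window spec ([window_spec()] or a row of
#'   [enumerate_windows()]).
#' @param zero_eps Tolerance of the both-unchanged branch; default 0.
#' @return Logical vector of length `w`, named by `k`.
#' @export
pair_match_profile <- function(lead, lag, spec, zero_eps = 0) {
  w <- spec$window_len[1L]; s <- spec$start[1L]; d <- spec$delay[1L]
  need <- s + d + w - 1L
  if (length(lead) < need || length(lag) < need) {
    stop("period vectors too short for window spec ", spec$label[1L])
  }
  k <- s + seq_len(w) - 1L
  lv <- lead[k]
  gv <- lag[k + d]
  both_zero <- abs(lv) <= zero_eps & abs(gv) <= zero_eps
  same_sign <- lv * gv > 0 & abs(lv) > zero_eps & abs(gv) > zero_eps
  stats::setNames(same_sign | both_zero, k)
}

#' Delayed co-movement test
#'
#' `TRUE` iff every compared position of [pair_match_profile()] holds, i.e.
#' the lagging class repeats the leading class's changes `d` periods later
#' throughout the window.
#'
#' @inheritParams pair_match_profile
#' @return Logical scalar.
#' @export
pair_matches <- function(lead, lag, spec, zero_eps = 0) {
  all(pair_match_profile(lead, lag, spec, zero_eps))
}

#' Build the shopping-basket dataset
#'
#' For every anchor class `i`, one record is formed containing `i` plus every
#' class `j` that lags behind `i` under at least one window spec
#' ([pair_matches()] with `i` leading). Records that remain singletons
#' (anchors with no partner) are discarded, so the number of records never
#' exceeds the number of classes. Matching is directional: the reverse
#' direction is covered when the partner acts as anchor.
#'
#' @param period_vectors Numeric matrix of period vectors (classes x
#'   periods, row names are class ids), e.g. from [period_matrix()].
#' @param specs Window specs ([enumerate_windows()] output); must be
#'   non-empty.
#' @param zero_eps Tolerance of the both-unchanged branch.
#' @return Object of class `dcaa_baskets`: list with `records` (each a list
#'   with integer `anchor` and sorted integer `items`), `n_records`,
#'   `class_ids`.
#' @export
build_baskets <- function(period_vectors, specs, zero_eps = 0) {
  if (is.null(dim(period_vectors))) stop("period_vectors must be a matrix")
  if (nrow(period_vectors) < 2L) stop("need at least two classes")
  if (!is.data.frame(specs) || nrow(specs) == 0L) {
    stop("specs must contain at least one window spec")
  }
  ids <- as.integer(rownames(period_vectors) %||%
                      as.character(seq_len(nrow(period_vectors))))
  n <- nrow(period_vectors)
  match_any <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(specs))) {
    w <- specs$window_len[r]; s <- specs$start[r]; d <- specs$delay[r]
    if (s + d + w - 1L > ncol(period_vectors)) {
      stop("period vectors too short for window spec ", specs$label[r])
    }
    ok <- matrix(TRUE, n, n)
    for (p in seq_len(w)) {
      lv <- period_vectors[, s + p - 1L]
      gv <- period_vectors[, s + p - 1L + d]
      lz <- abs(lv) <= zero_eps
      gz <- abs(gv) <= zero_eps
      ok <- ok & ((outer(lv, gv) > 0 & outer(!lz, !gz, "&")) |
                    outer(lz, gz, "&"))
    }
    match_any <- match_any | ok
  }
  diag(match_any) <- FALSE
  records <- list()
  for (i in seq_len(n)) {
    partners <- ids[match_any[i, ]]
    if (length(partners) >= 1L) {
      records[[length(records) + 1L]] <-
        list(anchor = ids[i], items = sort(c(ids[i], partners)))
    }
  }
  structure(
    list(records = records, n_records = length(records),
         class_ids = ids),
    class = "dcaa_baskets"
  )
}

#' @export
print.dcaa_baskets <- function(x, ...) {
  cat(sprintf("dcaa_baskets: %d records over %d classes\n",
              x$n_records, length(x$class_ids)))
  invisible(x)
}
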