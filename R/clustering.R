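# Shape-similarity clustering of peptide time courses. Three criteria are
# supported: identical change trends, bounded segment angles, and Pearson
# correlation of the whole profile.

#' Trend signature of a time course
#'
#' The sign (+1 increasing, -1 decreasing, 0 unchanging within `zero_eps`) of
#' each of the 12 line segments joining adjacent time points.
#'
#' @param values Numeric vector of finite values (length >= 2).
#' @param zero_eps Non-negative tolerance: a step with absolute difference
#'   `<= zero_eps` counts as unchanging. Default 0 (strict sign).
#' @return Integer vector in `{-1, 0, 1}` of length `length(values) - 1`.
#' @export
trend_signature <- function(values, zero_eps = 0) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (zero_eps < 0) stop("zero_eps must be non-negative")
  d <- diff(values)
  ifelse(d > zero_eps, 1L, ifelse(d < -zero_eps, -1L, 0L))
}

new_clustering <- function(method, params, peptide_id, class_id) {
  class_id <- as.integer(class_id)
  assignment <- stats::setNames(class_id, peptide_id)
  members <- split(peptide_id, class_id)
  names(members) <- as.character(sort(unique(class_id)))
  structure(
    list(method = method, params = params,
         assignment = assignment, members = members),
    class = "dcaa_clustering"
  )
}

#' @export
print.dcaa_clustering <- function(x, ...) {
  sizes <- lengths(x$members)
  cat(sprintf("dcaa_clustering (%s): %d peptides in %d classes (largest %d)\n",
              x$method, length(x$assignment), length(x$members),
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Number of classes in a clustering
#' @param clustering A `dcaa_clustering`.
#' @return Integer.
#' @export
n_classes <- function(clustering) length(clustering$members)

#' Full-trend clustering
#'
#' Peptides share a class exactly when their trend signatures are identical,
#' i.e. every one of the 12 segments changes in the same direction. The
#' partition (and its class numbering, assigned by sorted signature) is
#' independent of row order.
#'
#' @param matrix A [ts_matrix()].
#' @param zero_eps Tolerance passed to [trend_signature()].
#' @return A `dcaa_clustering`.
#' @export
cluster_full_trend <- function(matrix, zero_eps = 0) {
  stopifnot(inherits(matrix, "ts_matrix"))
  sig <- apply(matrix$values, 1L, function(v)
    paste(trend_signature(v, zero_eps), collapse = " "))
  levels <- sort(unique(sig))
  new_clustering("full_trend", list(zero_eps = zero_eps),
                 matrix$peptide_id, match(sig, levels))
}

#' Angle between two line segments
#'
#' The absolute difference of the segments' inclination angles,
#' `|atan(slope_a) - atan(slope_b)|`, in degrees (range `[0, 180)`).
#'
#' @param slope_a,slope_b Finite slopes (change per time unit).
#' @return Angle in degrees.
#' @export
segment_angle <- function(slope_a, slope_b) {
  abs(atan(slope_a) - atan(slope_b)) * 180 / pi
}

segment_slopes <- function(values, time_grid, time_scale) {
  if (time_scale == "hours") diff(values) / diff(time_grid) else diff(values)
}

#' Angle clustering
#'
#' Leader clustering scanned in input row order: a peptide joins the first
#' existing class whose leader (the class's first member) differs by at most
#' `threshold_deg` on all 12 segment angles; otherwise it founds a new class.
#' The result is deterministic for a fixed row order.
#'
#' Slopes are computed per segment index by default (`time_scale = "index"`),
#' treating each of the 12 intervals as one time unit so late, widely spaced
#' intervals are not flattened; `"hours"` divides by the actual interval
#' lengths instead.
#'
#' @param matrix A [ts_matrix()].
#' @param threshold_deg Positive angle threshold in degrees.
#' @param time_scale `"index"` (default) or `"hours"`.
#' @param require_trend If `TRUE`, additionally require identical trend
#'   signatures, which guarantees that angle classes refine full-trend
#'   classes. Default `FALSE`.
#' @param zero_eps Tolerance for the trend signatures when
#'   `require_trend = TRUE`.
#' @return A `dcaa_clustering`.
#' @export
cluster_angle <- function(matrix, threshold_deg,
                          time_scale = c("index", "hours"),
                          require_trend = FALSE, zero_eps = 0) {
  stopifnot(inherits(matrix, "ts_matrix"))
  if (threshold_deg <= 0) stop("threshold_deg must be positive")
  time_scale <- match.arg(time_scale)
  n <- n_peptides(matrix)
  slopes <- t(apply(matrix$values, 1L, segment_slopes,
                    time_grid = matrix$time_grid, time_scale = time_scale))
  theta <- atan(slopes) * 180 / pi
  sig <- if (require_trend) {
    apply(matrix$values, 1L, function(v)
      paste(trend_signature(v, zero_eps), collapse = " "))
  } else rep("", n)
  class_id <- integer(n)
  leaders <- integer(0)  # row index of each class's first member
  for (i in seq_len(n)) {
    assigned <- 0L
    for (k in seq_along(leaders)) {
      ld <- leaders[k]
      if (sig[i] == sig[ld] &&
          all(abs(theta[i, ] - theta[ld, ]) <= threshold_deg)) {
        assigned <- k
        break
      }
    }
    if (assigned == 0L) {
      leaders <- c(leaders, i)
      assigned <- length(leaders)
    }
    class_id[i] <- assigned
  }
  new_clustering("angle",
                 list(threshold_deg = threshold_deg, time_scale = time_scale,
                      require_trend = require_trend, zero_eps = zero_eps),
                 matrix$peptide_id, class_id)
}

#' Pearson correlation, moment form
#'
#' Computed as
#' `(sum(xy) - sum(x) sum(y) / N) / sqrt((sum(x^2) - sum(x)^2 / N) (sum(y^2) - sum(y)^2 / N))`
#' with `N` the vector dimension. `pearson_moment(x, x)` is exactly 1 and
#' `pearson_moment(x, -x)` exactly -1.
#'
#' @param x,y Numeric vectors of equal length `>= 2`, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_moment <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("x and y must share length >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  if (sxx <= 0 || syy <= 0) {
    stop("undefined correlation: constant vector")
  }
  r <- (sum(x * y) - sum(x) * sum(y) / n) / sqrt(sxx * syy)
  max(-1, min(1, r))
}

#' Pearson clustering
#'
#' Leader clustering as in [cluster_angle()], joining the first class whose
#' leader correlates with the candidate at `|r| > r_threshold` (absolute
#' value, so perfectly anticorrelated profiles share a class). Constant rows,
#' for which the correlation is undefined, become singleton classes.
#'
#' @param matrix A [ts_matrix()].
#' @param r_threshold Correlation threshold in (0, 1); default 0.97.
#' @return A `dcaa_clustering`.
#' @export
cluster_pearson <- function(matrix, r_threshold = 0.97) {
  stopifnot(inherits(matrix, "ts_matrix"))
  if (r_threshold <= 0 || r_threshold >= 1) {
    stop("r_threshold must lie strictly between 0 and 1")
  }
  vals <- matrix$values
  n <- n_peptides(matrix)
  constant <- apply(vals, 1L, function(v) max(v) == min(v))
  class_id <- integer(n)
  leaders <- integer(0)
  for (i in seq_len(n)) {
    assigned <- 0L
    if (!constant[i]) {
      for (k in seq_along(leaders)) {
        ld <- leaders[k]
        if (abs(pearson_moment(vals[i, ], vals[ld, ])) > r_threshold) {
          assigned <- k
          break
        }
      }
    }
    if (assigned == 0L) {
      # constant rows never become leaders for others to join: they are
      # recorded as leaders of their own singleton class only
      leaders <- c(leaders, if (constant[i]) NA_integer_ else i)
      assigned <- length(leaders)
    }
    class_id[i] <- assigned
  }
  # NA leaders (constant rows) were never compared against, so they stay
  # singletons as required
  new_clustering("pearson", list(r_threshold = r_threshold),
                 matrix$peptide_id, class_id)
}

#' Class representatives
#'
#' The representative of a class is the per-time-point arithmetic mean of its
#' members' series; a singleton's representative is its own series.
#'
#' @param clustering A `dcaa_clustering` over the peptides of `matrix`.
#' @param matrix A [ts_matrix()].
#' @return Numeric matrix, one row per class (row names are class ids).
#' @export
class_representatives <- function(clustering, matrix) {
  stopifnot(inherits(clustering, "dcaa_clustering"),
            inherits(matrix, "ts_matrix"))
  if (!all(names(clustering$assignment) %in% matrix$peptide_id)) {
    stop("clustering refers to peptides absent from the matrix")
  }
  vals <- matrix$values[names(clustering$assignment), , drop = FALSE]
  grp <- as.integer(clustering$assignment)
  k <- max(grp)
  reps <- rowsum(vals, grp, reorder = TRUE) / tabulate(grp, nbins = k)
  rownames(reps) <- as.character(seq_len(k))
  reps
}

#' Cluster-size summary
#'
#' Distribution of class sizes: for each size, how many classes have it and
#' what percentage of all classes they represent.
#'
#' @param clustering A `dcaa_clustering`.
#' @return Data frame with columns `size`, `count`, `percentage` (summing to
#'   100).
#' @export
clustering_summary <- function(clustering) {
  sizes <- lengths(clustering$members)
  if (length(sizes) == 0L) {
    return(data.frame(size = integer(0), count = integer(0),
                      percentage = numeric(0)))
  }
  tab <- table(sizes)
  data.frame(size = as.integer(names(tab)),
             count = as.integer(tab),
             percentage = 100 * as.integer(tab) / length(sizes))
}

#' Internal clustering indices
#'
#' Unsupervised quality indices: mean Euclidean distance of members to their
#' class representative (within), mean pairwise Euclidean distance among
#' representatives (between), and their ratio (smaller is tighter).
#'
#' @param clustering A `dcaa_clustering` with at least two classes.
#' @param matrix A [ts_matrix()].
#' @return List with `within`, `between`, `ratio`.
#' @export
internal_indices <- function(clustering, matrix) {
  if (n_classes(clustering) < 2L) {
    stop("internal indices need at least two classes")
  }
  reps <- class_representatives(clustering, matrix)
  grp <- clustering$assignment
  vals <- matrix$values[names(grp), , drop = FALSE]
  dev <- vals - reps[as.character(grp), , drop = FALSE]
  within <- mean(sqrt(rowSums(dev^2)))
  between <- mean(stats::dist(reps))
  list(within = within, between = between, ratio = within / between)
}
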