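# Apriori mining of frequent class itemsets and interclass association
# rules. The level-wise algorithm with downward-closure pruning is
# implemented here directly: itemsets are sorted integer vectors of class
# ids, supports are record fractions.

itemset_key <- function(items) paste(items, collapse = ",")

transactions_of <- function(baskets) {
  lapply(baskets$records, function(r) sort(unique(as.integer(r$items))))
}

#' Mine frequent class itemsets (Apriori)
#'
#' Level-wise generation: frequent 1-itemsets seed candidate 2-itemsets, and
#' so on; a candidate is kept only if all of its (k-1)-subsets are frequent
#' (every nonempty subset of a frequent itemset must itself be frequent).
#' Support of an itemset is the fraction of basket records containing all of
#' its items.
#'
#' @param baskets A [build_baskets()] result with at least one record.
#' @param min_support Minimum support in (0, 1]; itemsets with
#'   `support >= min_support` are returned. Values above 1 yield an empty
#'   result.
#' @return Data frame with columns `items` (list of sorted integer vectors),
#'   `key`, `size`, `count`, `support`; attributes `n_records` and
#'   `min_support`.
#' @export
mine_frequent_itemsets <- function(baskets, min_support) {
  stopifnot(inherits(baskets, "dcaa_baskets"))
  if (baskets$n_records < 1L) stop("empty basket dataset")
  if (min_support <= 0) stop("min_support must be positive")
  trans <- transactions_of(baskets)
  n <- length(trans)

  empty <- data.frame(key = character(0), size = integer(0),
                      count = integer(0), support = numeric(0))
  empty$items <- list()

  # level 1
  counts <- table(unlist(lapply(trans, unique)))
  keep <- as.integer(counts) / n >= min_support
  level_items <- lapply(as.integer(names(counts))[keep], identity)
  level_counts <- as.integer(counts)[keep]

  all_items <- level_items
  all_counts <- level_counts
  all_sizes <- rep(1L, length(level_items))
  frequent_keys <- vapply(level_items, itemset_key, character(1))

  k <- 1L
  while (length(level_items) >= 2L) {
    k <- k + 1L
    # candidate join: two frequent (k-1)-itemsets sharing their first k-2
    # items, then downward-closure pruning
    ord <- order(vapply(level_items, itemset_key, character(1)))
    level_items <- level_items[ord]
    cands <- list()
    for (i in seq_along(level_items)) {
      for (j in seq_along(level_items)) {
        if (j <= i) next
        a <- level_items[[i]]; b <- level_items[[j]]
        if (k == 2L || identical(a[seq_len(k - 2L)], b[seq_len(k - 2L)])) {
          cand <- sort(unique(c(a, b)))
          if (length(cand) != k) next
          subs_ok <- all(vapply(seq_len(k), function(drop)
            itemset_key(cand[-drop]) %in% frequent_keys, logical(1)))
          if (subs_ok) cands[[itemset_key(cand)]] <- cand
        }
      }
    }
    if (length(cands) == 0L) break
    cnt <- vapply(cands, function(cand)
      sum(vapply(trans, function(tr) all(cand %in% tr), logical(1))),
      integer(1))
    keep <- cnt / n >= min_support
    level_items <- unname(cands[keep])
    level_counts <- unname(cnt[keep])
    if (length(level_items) == 0L) break
    all_items <- c(all_items, level_items)
    all_counts <- c(all_counts, level_counts)
    all_sizes <- c(all_sizes, rep(k, length(level_items)))
    frequent_keys <- c(frequent_keys,
                       vapply(level_items, itemset_key, character(1)))
  }

  if (length(all_items) == 0L) {
    out <- empty
  } else {
    out <- data.frame(
      key = vapply(all_items, itemset_key, character(1)),
      size = all_sizes, count = all_counts,
      support = all_counts / n, stringsAsFactors = FALSE)
    out$items <- all_items
    out <- out[order(out$size, out$key), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_records") <- n
  attr(out, "min_support") <- min_support
  out
}

#' Derive association rules from frequent itemsets
#'
#' Every frequent itemset of size 2..`max_rule_size` is split into all
#' ordered pairs of a non-empty antecedent `Y` and consequent `X`
#' (`X` and `Y` disjoint, jointly spanning the itemset). Rule confidence is
#' `support(X ∪ Y) / support(Y)`; rules below `min_confidence` are dropped.
#' Downstream interaction inference consumes the 1-antecedent, 1-consequent
#' rules (`rule_size == 2`); larger rules, if requested via `max_rule_size`,
#' are carried along flagged by their size.
#'
#' @param itemsets Output of [mine_frequent_itemsets()].
#' @param min_confidence Minimum confidence in (0, 1]; default 0.9.
#' @param max_rule_size Largest itemset size expanded into rules; default 2.
#' @return Data frame with columns `antecedent`, `consequent` (comma-joined
#'   class ids), `rule_size`, `support` (of the joint itemset), `confidence`.
#' @export
derive_rules <- function(itemsets, min_confidence = 0.9, max_rule_size = 2L) {
  if (min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must lie in [0, 1]")
  }
  out <- data.frame(antecedent = character(0), consequent = character(0),
                    rule_size = integer(0), support = numeric(0),
                    confidence = numeric(0), stringsAsFactors = FALSE)
  if (nrow(itemsets) == 0L) return(out)
  supp <- stats::setNames(itemsets$support, itemsets$key)
  big <- itemsets[itemsets$size >= 2L & itemsets$size <= max_rule_size, ,
                  drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(big))) {
    items <- big$items[[r]]
    s_all <- big$support[r]
    k <- length(items)
    # all non-trivial antecedent subsets
    for (mask in seq_len(2L^k - 2L)) {
      sel <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
      y <- items[sel]; x <- items[!sel]
      conf <- s_all / supp[[itemset_key(y)]]
      if (conf >= min_confidence) {
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = itemset_key(y), consequent = itemset_key(x),
          rule_size = k, support = s_all, confidence = conf,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(out)
  out <- do.call(rbind, rows)
  out <- out[order(out$rule_size, out$antecedent, out$consequent), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of pairwise (1 to 1) rules
#' @param rules A [derive_rules()] result.
#' @return Integer count of rules with one antecedent and one consequent.
#' @export
n_pair_rules <- function(rules) sum(rules$rule_size == 2L)

#' Tune the minimum support on a grid
#'
#' Mines the baskets at each support of a descending grid (confidence fixed)
#' and picks the largest support whose pairwise-rule count falls inside
#' `target_range` (by default a few hundred rules, 50..600). If no grid value
#' lands inside the range, the support whose count is closest to the range is
#' chosen, ties resolving to the larger support (fewer, stronger rules).
#'
#' @param baskets A [build_baskets()] result.
#' @param min_confidence Confidence used while scanning; default 0.9.
#' @param support_grid Numeric vector of candidate supports (any order).
#' @param target_range Length-2 integer range of acceptable rule counts.
#' @return List with `min_support` (the chosen value) and `scan`, a data
#'   frame of `min_support`, `min_confidence`, `n_rules` (pairwise) and
#'   `n_rules_all` over the full grid.
#' @export
tune_support <- function(baskets, min_confidence = 0.9, support_grid,
                         target_range = c(50L, 600L)) {
  if (length(support_grid) == 0L) stop("support_grid must be non-empty")
  grid <- sort(unique(support_grid), decreasing = TRUE)
  n_rules <- integer(length(grid))
  n_all <- integer(length(grid))
  for (i in seq_along(grid)) {
    its <- mine_frequent_itemsets(baskets, grid[i])
    rules <- derive_rules(its, min_confidence,
                          max_rule_size = max(its$size, 2L))
    n_rules[i] <- n_pair_rules(rules)
    n_all[i] <- nrow(rules)
  }
  scan <- data.frame(min_support = grid, min_confidence = min_confidence,
                     n_rules = n_rules, n_rules_all = n_all)
  inside <- which(n_rules >= target_range[1L] & n_rules <= target_range[2L])
  chosen <- if (length(inside)) {
    grid[inside[1L]]  # grid is descending: first hit is the largest support
  } else {
    dist <- pmax(target_range[1L] - n_rules, n_rules - target_range[2L], 0)
    cand <- which(dist == min(dist))
    # equally distant supports: too few rules everywhere -> take the
    # smallest support (the one closest to producing rules); otherwise the
    # larger support wins (fewer, stronger rules)
    if (all(n_rules[cand] < target_range[1L])) {
      grid[cand[length(cand)]]
    } else {
      grid[cand[1L]]
    }
  }
  list(min_support = chosen, scan = scan)
}
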