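# Expansion of class-level association rules into protein-pair predictions
# by one-, two- and three-step reasoning over the rule graph.

#' Build the rule graph
#'
#' One undirected edge per unordered class pair appearing in a pairwise
#' (1 antecedent, 1 consequent) rule; parallel rules in either direction are
#' merged into the edge's metadata. Rules of other sizes are rejected with a
#' warning. Edges are undirected because the downstream reference databases
#' record undirected physical interactions; the originating rule directions
#' are kept in the metadata for users interested in putative regulatory
#' direction.
#'
#' @param rules A [derive_rules()] data frame.
#' @return Object of class `dcaa_rule_graph`: list with `nodes` (sorted
#'   integer class ids) and `edges` (data frame `a`, `b` with `a < b`,
#'   `n_rules`, `best_confidence`, `max_support`, `directions`).
#' @export
build_rule_graph <- function(rules) {
  pairwise <- rules$rule_size == 2L
  if (any(!pairwise)) {
    warning(sum(!pairwise),
            " rule(s) with more than one antecedent or consequent ignored")
  }
  rules <- rules[pairwise, , drop = FALSE]
  if (nrow(rules) == 0L) {
    edges <- data.frame(a = integer(0), b = integer(0), n_rules = integer(0),
                        best_confidence = numeric(0), max_support = numeric(0),
                        directions = character(0), stringsAsFactors = FALSE)
    return(structure(list(nodes = integer(0), edges = edges),
                     class = "dcaa_rule_graph"))
  }
  y <- as.integer(rules$antecedent)
  x <- as.integer(rules$consequent)
  a <- pmin(y, x)
  b <- pmax(y, x)
  key <- paste(a, b)
  agg <- function(v, f) as.vector(tapply(v, key, f))
  ord <- !duplicated(key)
  dirs <- tapply(sprintf("%d->%d", y, x), key,
                 function(s) paste(sort(s), collapse = ";"))
  edges <- data.frame(
    a = as.vector(tapply(a, key, `[`, 1L)),
    b = as.vector(tapply(b, key, `[`, 1L)),
    n_rules = as.vector(tapply(key, key, length)),
    best_confidence = agg(rules$confidence, max),
    max_support = agg(rules$support, max),
    directions = as.vector(dirs),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges),
            class = "dcaa_rule_graph")
}

#' @export
print.dcaa_rule_graph <- function(x, ...) {
  cat(sprintf("dcaa_rule_graph: %d classes, %d undirected edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

adjacency_list <- function(graph) {
  adj <- lapply(stats::setNames(vector("list", length(graph$nodes)),
                                graph$nodes), function(x) integer(0))
  for (r in seq_len(nrow(graph$edges))) {
    a <- as.character(graph$edges$a[r]); b <- as.character(graph$edges$b[r])
    adj[[a]] <- c(adj[[a]], graph$edges$b[r])
    adj[[b]] <- c(adj[[b]], graph$edges$a[r])
  }
  adj
}

#' Multi-step reasoning over the rule graph
#'
#' Depth 1 (direct connection) is the edge set. Depth 2 links the endpoints
#' of simple two-edge paths (one shared intermediate class), excluding pairs
#' already at depth 1. Depth 3 links endpoints of simple three-edge paths
#' (all four classes distinct), excluding depths 1 and 2. Pairs are
#' unordered, so each unordered class pair appears at its minimum depth only.
#'
#' @param graph A [build_rule_graph()] result.
#' @param max_depth 1, 2 or 3.
#' @return Named list `depth1`..`depth<max_depth>` of two-column integer
#'   matrices (`a < b`).
#' @export
infer_class_pairs <- function(graph, max_depth = 3L) {
  stopifnot(inherits(graph, "dcaa_rule_graph"))
  if (!max_depth %in% 1:3) stop("max_depth must be 1, 2 or 3")
  as_pair_matrix <- function(keys) {
    m <- key_to_pair(keys)
    out <- matrix(as.integer(m), ncol = 2L)
    colnames(out) <- c("a", "b")
    out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  }
  e <- graph$edges
  d1_keys <- pair_key(e$a, e$b)
  out <- list(depth1 = as_pair_matrix(d1_keys))
  if (max_depth == 1L) return(out)
  adj <- adjacency_list(graph)
  d2_keys <- character(0)
  for (mid in names(adj)) {
    nb <- adj[[mid]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(sort(nb), 2L)
      d2_keys <- c(d2_keys, pair_key(cmb[1L, ], cmb[2L, ]))
    }
  }
  d2_keys <- setdiff(unique(d2_keys), d1_keys)
  out$depth2 <- as_pair_matrix(d2_keys)
  if (max_depth == 2L) return(out)
  d3_keys <- character(0)
  for (r in seq_len(nrow(e))) {
    x <- e$a[r]; y <- e$b[r]
    u <- setdiff(adj[[as.character(x)]], y)
    v <- setdiff(adj[[as.character(y)]], x)
    if (length(u) && length(v)) {
      g <- expand.grid(u = u, v = v)
      g <- g[g$u != g$v & g$u != y & g$v != x, , drop = FALSE]
      if (nrow(g)) d3_keys <- c(d3_keys, pair_key(g$u, g$v))
    }
  }
  d3_keys <- setdiff(unique(d3_keys), c(d1_keys, d2_keys))
  out$depth3 <- as_pair_matrix(d3_keys)
  out
}

class_protein_sets <- function(clustering, matrix) {
  prot <- strsplit(matrix$protein_id, ";", fixed = TRUE)
  names(prot) <- matrix$peptide_id
  lapply(clustering$members, function(peps)
    sort(unique(unlist(prot[peps]))))
}

#' Expand class pairs into protein-pair predictions
#'
#' Each class pair `(i, j)` emits the cross product of the protein sets of
#' the two classes (a class's protein set is the union of its member
#' peptides' accessions). Self-pairs are removed, and a protein pair
#' reachable at several depths is reported once at its minimum depth.
#'
#' @param class_pairs Output of [infer_class_pairs()].
#' @param clustering The `dcaa_clustering` the rules were mined from.
#' @param matrix The [ts_matrix()] underlying the clustering.
#' @param graph Optional [build_rule_graph()] result; when supplied, depth-1
#'   predictions carry the best confidence of their supporting edges.
#' @return Data frame with columns `protein_a`, `protein_b`
#'   (lexicographically ordered), `depth`, `n_supporting_class_pairs`,
#'   `best_confidence` (NA beyond depth 1 or without `graph`).
#' @export
classes_to_proteins <- function(class_pairs, clustering, matrix,
                                graph = NULL) {
  psets <- class_protein_sets(clustering, matrix)
  known <- as.integer(names(psets))
  edge_conf <- if (!is.null(graph) && nrow(graph$edges)) {
    stats::setNames(graph$edges$best_confidence,
                    pair_key(graph$edges$a, graph$edges$b))
  } else NULL
  seen <- character(0)
  rows <- list()
  for (depth in seq_along(class_pairs)) {
    pairs <- class_pairs[[depth]]
    if (is.null(pairs) || nrow(pairs) == 0L) next
    bad <- setdiff(unique(c(pairs)), known)
    if (length(bad)) stop("unknown class id(s): ", paste(bad, collapse = ", "))
    acc <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(pairs))) {
      pa <- psets[[as.character(pairs[r, 1L])]]
      pb <- psets[[as.character(pairs[r, 2L])]]
      if (!length(pa) || !length(pb)) next
      g <- expand.grid(a = pa, b = pb, stringsAsFactors = FALSE)
      g <- g[g$a != g$b, , drop = FALSE]
      if (!nrow(g)) next
      keys <- unique(pair_key(g$a, g$b))
      conf <- if (depth == 1L && !is.null(edge_conf)) {
        unname(edge_conf[pair_key(pairs[r, 1L], pairs[r, 2L])])
      } else NA_real_
      for (key in keys) {
        prev <- acc[[key]]
        if (is.null(prev)) {
          acc[[key]] <- list(n = 1L, conf = conf)
        } else {
          acc[[key]] <- list(n = prev$n + 1L,
                             conf = suppressWarnings(
                               max(prev$conf, conf, na.rm = TRUE)))
        }
      }
    }
    keys <- setdiff(ls(acc), seen)
    if (length(keys)) {
      m <- key_to_pair(sort(keys))
      info <- lapply(sort(keys), function(k) acc[[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        protein_a = m[, 1L], protein_b = m[, 2L],
        depth = depth,
        n_supporting_class_pairs = vapply(info, function(z) z$n, integer(1)),
        best_confidence = vapply(info, function(z) {
          if (is.null(z$conf) || !is.finite(z$conf)) NA_real_ else z$conf
        }, numeric(1)),
        stringsAsFactors = FALSE)
      seen <- c(seen, keys)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      depth = integer(0),
                      n_supporting_class_pairs = integer(0),
                      best_confidence = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$depth, out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
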