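# Rule graph construction, multi-step reasoning and protein expansion.

rule_df <- function(pairs) {
  n <- nrow(pairs)
  data.frame(antecedent = as.character(pairs[, 1]),
             consequent = as.character(pairs[, 2]),
             rule_size = rep(2L, n), support = rep(0.1, n),
             confidence = rep(0.95, n), stringsAsFactors = FALSE)
}

test_that("rule graphs merge parallel rules and reject wide ones", {
  g <- build_rule_graph(rule_df(rbind(c(1, 2), c(2, 1))))
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$n_rules, 2L)
  expect_identical(g$edges$directions, "1->2;2->1")

  empty <- build_rule_graph(rule_df(matrix(integer(0), ncol = 2)))
  expect_identical(length(empty$nodes), 0L)

  path <- build_rule_graph(rule_df(rbind(c(1, 2), c(2, 3))))
  expect_identical(nrow(path$edges), 2L)
  expect_identical(path$nodes, 1:3)

  wide <- rule_df(rbind(c(1, 2)))
  wide$antecedent[1] <- "1,4"
  wide$rule_size[1] <- 3L
  expect_warning(gw <- build_rule_graph(rbind(wide, rule_df(rbind(c(2, 3))))),
                 "ignored")
  expect_identical(nrow(gw$edges), 1L)
})

test_that("reasoning depths follow simple-path semantics with exclusion", {
  path <- build_rule_graph(rule_df(rbind(c(1, 2), c(2, 3), c(3, 4))))
  got <- infer_class_pairs(path, 3)
  expect_identical(pkey(got$depth1[, 1], got$depth1[, 2]),
                   c("1 2", "2 3", "3 4"))
  expect_identical(pkey(got$depth2[, 1], got$depth2[, 2]), c("1 3", "2 4"))
  expect_identical(pkey(got$depth3[, 1], got$depth3[, 2]), "1 4")

  tri <- build_rule_graph(rule_df(rbind(c(1, 2), c(2, 3), c(1, 3))))
  got_tri <- infer_class_pairs(tri, 3)
  expect_identical(nrow(got_tri$depth1), 3L)
  expect_identical(nrow(got_tri$depth2), 0L)
  expect_identical(nrow(got_tri$depth3), 0L)

  none <- infer_class_pairs(build_rule_graph(rule_df(matrix(integer(0), ncol = 2))), 3)
  expect_identical(vapply(none, nrow, integer(1)),
                   c(depth1 = 0L, depth2 = 0L, depth3 = 0L))
})

test_that("depths equal graph distances on random graphs (independent oracle)", {
  skip_if_not_installed("igraph")
  set.seed(55)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    m <- sample(5:14, 1)
    pairs <- unique(t(apply(
      matrix(sample(n, 2 * m, replace = TRUE), ncol = 2), 1, sort)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) < 2) next
    g <- build_rule_graph(rule_df(pairs))
    got <- infer_class_pairs(g, 3)
    ig <- igraph::graph_from_edgelist(
      matrix(as.character(pairs), ncol = 2), directed = FALSE)
    dm <- igraph::distances(ig)
    want_at <- function(d) {
      idx <- which(dm == d & upper.tri(dm), arr.ind = TRUE)
      sort(pkey(as.integer(rownames(dm)[idx[, 1]]),
                as.integer(colnames(dm)[idx[, 2]])))
    }
    expect_identical(sort(pkey(got$depth1[, 1], got$depth1[, 2])), want_at(1))
    expect_identical(sort(pkey(got$depth2[, 1], got$depth2[, 2])), want_at(2))
    expect_identical(sort(pkey(got$depth3[, 1], got$depth3[, 2])), want_at(3))
    # depth sets are pairwise disjoint
    keys <- lapply(got, function(m2) pkey(m2[, 1], m2[, 2]))
    expect_identical(length(unlist(keys)), length(unique(unlist(keys))))
  }
})

test_that("reasoning output is invariant to rule-list permutations", {
  set.seed(66)
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(2, 5), c(5, 6))
  r1 <- rule_df(pairs)
  r2 <- r1[sample(nrow(r1)), ]
  g1 <- infer_class_pairs(build_rule_graph(r1), 3)
  g2 <- infer_class_pairs(build_rule_graph(r2), 3)
  expect_identical(g1, g2)
})

test_that("protein expansion crosses class members, drops self-pairs, keeps min depth", {
  # class 1 = {P1}, class 2 = {P2, P3}, class 3 = {P1, P4}
  vals <- rbind(seq(0, 12), seq(0, 12) + 1,
                seq(12, 0), seq(12, 0) + 2,
                sin(seq(0, 12) / 2), sin(seq(0, 12) / 2) + 0.1)
  ts <- make_ts(vals, proteins = c("P1", "P1", "P2", "P3", "P1", "P4"))
  cl <- cluster_full_trend(ts)
  c_of <- function(pep) unname(cl$assignment[[pep]])
  c1 <- c_of("pep01"); c2 <- c_of("pep03"); c3 <- c_of("pep05")

  pairs <- list(depth1 = rbind(c(min(c1, c2), max(c1, c2))))
  pred <- classes_to_proteins(pairs, cl, ts)
  expect_setequal(pkey(pred$protein_a, pred$protein_b), c("P1 P2", "P1 P3"))
  expect_true(all(pred$depth == 1L))

  # self-pair dropped: classes 1 and 3 share P1
  pairs13 <- list(depth1 = rbind(c(min(c1, c3), max(c1, c3))))
  pred13 <- classes_to_proteins(pairs13, cl, ts)
  expect_setequal(pkey(pred13$protein_a, pred13$protein_b), "P1 P4")

  # a pair reachable at depth 1 and again at depth 3 keeps depth 1
  both <- list(depth1 = rbind(c(min(c1, c2), max(c1, c2))),
               depth2 = matrix(integer(0), ncol = 2),
               depth3 = rbind(c(min(c1, c2), max(c1, c2))))
  pboth <- classes_to_proteins(both, cl, ts)
  expect_true(all(pboth$depth == 1L))

  expect_error(classes_to_proteins(list(depth1 = rbind(c(999L, 1000L))),
                                   cl, ts), "unknown class")
})
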