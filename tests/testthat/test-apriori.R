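# Apriori mining, rule derivation and support tuning.

test_that("the worked four-record example yields the textbook supports and rule", {
  # records {A,B}, {A,B,C}, {A,C}, {B} with A=1, B=2, C=3
  bk <- make_baskets(list(c(1, 2), c(1, 2, 3), c(1, 3), c(2)))
  its <- mine_frequent_itemsets(bk, 0.5)
  got <- setNames(its$support, its$key)
  expect_identical(sort(names(got)), sort(c("1", "2", "3", "1,2", "1,3")))
  expect_equal(got[["1"]], 0.75)
  expect_equal(got[["2"]], 0.75)
  expect_equal(got[["3"]], 0.5)
  expect_equal(got[["1,2"]], 0.5)
  expect_equal(got[["1,3"]], 0.5)

  rules <- derive_rules(its, min_confidence = 0.9)
  expect_identical(nrow(rules), 1L)
  expect_identical(rules$antecedent, "3")
  expect_identical(rules$consequent, "1")
  expect_equal(rules$confidence, 1)
  expect_equal(rules$support, 0.5)

  # confidence 0 keeps every ordered split of each frequent 2-itemset
  all_rules <- derive_rules(its, min_confidence = 0, max_rule_size = 2)
  expect_identical(nrow(all_rules), 4L)
  # recompute each confidence from the raw records
  trans <- list(c(1, 2), c(1, 2, 3), c(1, 3), c(2))
  for (r in seq_len(nrow(all_rules))) {
    y <- as.integer(all_rules$antecedent[r])
    xy <- c(y, as.integer(all_rules$consequent[r]))
    conf <- sum(sapply(trans, function(t) all(xy %in% t))) /
      sum(sapply(trans, function(t) y %in% t))
    expect_equal(all_rules$confidence[r], conf, tolerance = 1e-12)
  }

  expect_identical(nrow(mine_frequent_itemsets(bk, 1.1)), 0L)
  only_a <- mine_frequent_itemsets(make_baskets(list(c(1, 2), c(1, 3))), 1)
  expect_identical(only_a$key, "1")
  singles <- mine_frequent_itemsets(bk, 0.75)
  expect_identical(nrow(derive_rules(singles)), 0L)
  expect_error(mine_frequent_itemsets(make_baskets(list()), 0.5), "empty")
})

test_that("mined itemsets equal exhaustive enumeration on random datasets", {
  set.seed(100)
  for (i in 1:12) {
    n_items <- sample(3:8, 1)
    n_rec <- sample(5:25, 1)
    recs <- lapply(seq_len(n_rec), function(j)
      sample(n_items, sample(1:min(5, n_items), 1)))
    ms <- sample(c(0.1, 0.2, 0.3, 0.5), 1)
    bk <- make_baskets(recs)
    got <- mine_frequent_itemsets(bk, ms)
    want <- oracle_frequent_itemsets(recs, ms)
    expect_identical(nrow(got), length(want))
    want_keys <- vapply(want, function(x) paste(x$items, collapse = ","),
                        character(1))
    expect_setequal(got$key, want_keys)
    expect_equal(setNames(got$support, got$key)[want_keys],
                 setNames(vapply(want, `[[`, numeric(1), "support"),
                          want_keys))
    # downward closure on every output
    supp <- setNames(got$support, got$key)
    for (r in which(got$size > 1L)) {
      items <- got$items[[r]]
      for (drop in seq_along(items)) {
        sub <- paste(items[-drop], collapse = ",")
        expect_true(sub %in% got$key)
        expect_true(supp[[sub]] >= got$support[r])
      }
    }
  }
})

test_that("rule counts shrink as support or confidence tightens", {
  set.seed(200)
  recs <- lapply(1:30, function(j) sample(6, sample(2:4, 1)))
  bk <- make_baskets(recs)
  supports <- c(0.05, 0.1, 0.2, 0.4)
  counts_s <- sapply(supports, function(ms)
    nrow(derive_rules(mine_frequent_itemsets(bk, ms), min_confidence = 0.1)))
  expect_true(all(diff(counts_s) <= 0))
  confs <- c(0.1, 0.3, 0.6, 0.9)
  its <- mine_frequent_itemsets(bk, 0.1)
  counts_c <- sapply(confs, function(mc) nrow(derive_rules(its, mc)))
  expect_true(all(diff(counts_c) <= 0))
})

test_that("support tuning picks the largest in-range support, with fallbacks", {
  set.seed(300)
  # heterogeneous co-occurrence so rule counts vary across the grid
  recs <- c(lapply(1:40, function(j) c(1, 2)),
            lapply(1:20, function(j) c(3, 4)),
            lapply(1:60, function(j) sample(20, sample(2:5, 1)) + 4))
  bk <- make_baskets(recs)
  grid <- c(0.3, 0.15, 0.05, 0.02)
  tuned <- tune_support(bk, 0.5, grid, target_range = c(1L, 10L))
  expect_identical(tuned$scan$min_support, sort(grid, decreasing = TRUE))
  expect_true(all(diff(tuned$scan$n_rules) >= 0))  # descending grid
  inside <- tuned$scan$min_support[tuned$scan$n_rules >= 1 &
                                     tuned$scan$n_rules <= 10]
  expect_identical(tuned$min_support, max(inside))

  # unattainable thresholds: every count zero, smallest support is chosen
  zero <- tune_support(bk, 1, c(0.99, 0.995), target_range = c(50L, 600L))
  expect_true(all(zero$scan$n_rules == 0L))
  expect_identical(zero$min_support, 0.99)

  one <- tune_support(bk, 0.5, 0.3, target_range = c(0L, 1e6L))
  expect_identical(one$min_support, 0.3)
  expect_error(tune_support(bk, 0.5, numeric(0)), "non-empty")
})
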