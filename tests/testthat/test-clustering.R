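# Shape-similarity clustering: trend signatures, angle and Pearson criteria,
# representatives and summaries.

test_that("trend signatures encode segment directions with a dead zone", {
  expect_identical(trend_signature(rep(0.3, 13)), rep(0L, 12))
  expect_identical(trend_signature(table2_class_one, 0),
                   c(-1L, -1L, 1L, 1L, -1L, 1L, 1L, -1L, -1L, -1L, -1L, -1L))
  expect_identical(trend_signature(seq_len(13)), rep(1L, 12))
  # dead zone swallows small steps
  expect_identical(trend_signature(c(0, 0.05, -0.05), zero_eps = 0.1),
                   c(0L, 0L))
  expect_error(trend_signature(c(1, NA, 3)), "finite")
})

test_that("full-trend clustering partitions by exact signature, order-invariantly", {
  rows <- rbind(seq(0, 1.2, 0.1), seq(0, 1.2, 0.1) * 2 + 5,
                seq(1.2, 0, -0.1))
  ts <- make_ts(rows)
  cl <- cluster_full_trend(ts)
  expect_identical(n_classes(cl), 2L)
  expect_identical(cl$assignment[["pep01"]], cl$assignment[["pep02"]])
  expect_false(cl$assignment[["pep01"]] == cl$assignment[["pep03"]])
  expect_identical(sort(unname(lengths(cl$members))), c(1L, 2L))
  expect_identical(sum(lengths(cl$members)), n_peptides(ts))

  # permuting rows permutes nothing but the labels attached to peptides
  set.seed(9)
  vals <- matrix(rnorm(20 * 13), 20)
  ts1 <- make_ts(vals)
  perm <- sample(20)
  ts2 <- ts_matrix(ts1$peptide_id[perm], ts1$protein_id[perm],
                   vals[perm, ], default_time_grid())
  cl1 <- cluster_full_trend(ts1)
  cl2 <- cluster_full_trend(ts2)
  expect_identical(cl1$assignment[ts1$peptide_id],
                   cl2$assignment[ts1$peptide_id])
})

test_that("segment angles and angle clustering follow the leader rule", {
  expect_equal(segment_angle(1, 1), 0)
  expect_equal(segment_angle(0, 1), 45)
  expect_equal(segment_angle(1, -1), 90)

  base <- seq(0, 12)
  ts <- make_ts(rbind(base, base, base * 100))
  cl <- cluster_angle(ts, threshold_deg = 5)
  expect_identical(cl$assignment[["pep01"]], cl$assignment[["pep02"]])

  # one segment pair 45 degrees apart fails an all-segments test at 40
  a <- c(0, rep(1, 12))           # first slope 1, then 0
  b <- rep(0, 13)                 # all slopes 0
  cl2 <- cluster_angle(make_ts(rbind(a, b)), threshold_deg = 40)
  expect_identical(n_classes(cl2), 2L)
  cl3 <- cluster_angle(make_ts(rbind(a, b)), threshold_deg = 50)
  expect_identical(n_classes(cl3), 1L)

  dup <- make_ts(matrix(rep(seq(0, 1.2, 0.1), each = 6), 6, byrow = FALSE))
  expect_identical(n_classes(cluster_angle(dup, 1)), 1L)

  # with trend agreement enforced, angle classes refine full-trend classes
  set.seed(2)
  vals <- matrix(rnorm(30 * 13, sd = 1), 30)
  tsr <- make_ts(vals)
  ang <- cluster_angle(tsr, threshold_deg = 30, require_trend = TRUE)
  ful <- cluster_full_trend(tsr)
  for (cls in ang$members) {
    expect_identical(length(unique(ful$assignment[cls])), 1L)
  }
})

test_that("moment-form Pearson matches the two-pass oracle and is exact at the poles", {
  expect_equal(pearson_moment(c(1, 2, 3), c(1, 2, 4)), 0.98198,
               tolerance = 1e-5)
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(13); y <- rnorm(13)
    expect_equal(pearson_moment(x, y), pearson_two_pass(x, y),
                 tolerance = 1e-12)
    expect_equal(pearson_moment(x, y), stats::cor(x, y), tolerance = 1e-12)
  }
  x <- rnorm(13)
  expect_identical(pearson_moment(x, x), 1)
  expect_identical(pearson_moment(x, -x), -1)
  expect_error(pearson_moment(x, rep(1, 13)), "constant")
})

test_that("Pearson clustering uses |r| with singleton constant rows", {
  x <- seq(0, 1.2, 0.1) + c(0.01, -0.02, 0, 0.01, 0, 0, -0.01, 0, 0, 0.02, 0, 0, 0)
  ts <- make_ts(rbind(x, 2 * x + 1, -x, rep(0.5, 13), rep(0.5, 13)))
  cl <- cluster_pearson(ts, 0.97)
  a <- cl$assignment
  expect_identical(a[["pep01"]], a[["pep02"]])  # affine invariance
  expect_identical(a[["pep01"]], a[["pep03"]])  # |-1| > threshold
  expect_false(a[["pep04"]] == a[["pep05"]])    # constants stay singletons
  expect_identical(n_classes(cl), 3L)

  shaped <- make_ts(rbind(c(1, 2, 3), c(1, 2, 4)), grid = 1:3)
  expect_identical(n_classes(cluster_pearson(shaped, 0.97)), 1L)
})

test_that("representatives, summaries and internal indices behave on hand cases", {
  vals <- rbind(seq(1, 13), seq(3, 15), seq(13, 1))
  ts <- make_ts(vals)
  cl <- cluster_full_trend(ts)
  reps <- class_representatives(cl, ts)
  up <- cl$assignment[["pep01"]]
  expect_equal(unname(reps[as.character(up), ]), seq(2, 14))
  down <- cl$assignment[["pep03"]]
  expect_equal(unname(reps[as.character(down), ]), seq(13, 1))

  smry <- clustering_summary(cl)
  expect_equal(sum(smry$percentage), 100, tolerance = 1e-9)
  expect_identical(smry$count[smry$size == 2L], 1L)

  idx <- internal_indices(cl, ts)
  expect_equal(idx$within, mean(c(sqrt(13), sqrt(13), 0)))
  expect_equal(idx$between, sqrt(sum((seq(2, 14) - seq(13, 1))^2)))
  expect_equal(idx$ratio, idx$within / idx$between)

  one <- make_ts(rbind(seq(1, 13), seq(2, 14)))
  expect_error(internal_indices(cluster_full_trend(one), one),
               "at least two classes")
})
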