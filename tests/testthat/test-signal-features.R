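# Derived channels, sliding windows, window statistics and the feature schema.

test_that("channel norms match direct arithmetic and the projection identity", {
  expect_equal(
    as.numeric(channel_norms(c(3, 4, 0))),
    c(5, 4, 3, 5)
  )
  expect_equal(as.numeric(channel_norms(c(0, 0, 0))), rep(0, 4))
  expect_equal(
    as.numeric(channel_norms(c(1, 2, 2))),
    c(3, sqrt(8), sqrt(5), sqrt(5))
  )
  # each axis occurs in exactly two plane projections:
  # hori^2 + coro^2 + sagi^2 = 2 * norm^2, and every projection <= norm
  set.seed(42)
  v <- matrix(rnorm(300), ncol = 3)
  cn <- channel_norms(v)
  expect_equal(cn$hori^2 + cn$coro^2 + cn$sagi^2, 2 * cn$norm^2)
  expect_true(all(cn$hori <= cn$norm + 1e-12))
  expect_true(all(cn$coro <= cn$norm + 1e-12))
  expect_true(all(cn$sagi <= cn$norm + 1e-12))
  expect_error(channel_norms(c(1, NA, 0)), "signal-quality")
})

test_that("window stats follow the documented estimator conventions", {
  # constant window: degenerate policy zeroes variance, kurtosis, skewness
  expect_equal(
    as.numeric(window_stats(rep(3.5, 20))),
    c(3.5, 3.5, 3.5, 0, 0, 0, 0, 0)
  )
  # hand computation for (1,2,3,4): m2 = 1.25, m3 = 0, m4 = 2.5625
  s <- window_stats(c(1, 2, 3, 4))
  expect_equal(as.numeric(s), c(2.5, 4, 1, 5 / 3, sqrt(5 / 3), 2.5625 / 1.25^2, 0, 3))
  expect_named(s, c("mean", "max", "min", "variance", "std", "kurtosis",
                    "skewness", "range"))
  # symmetric two-point window
  s2 <- window_stats(c(-5, 5))
  expect_equal(as.numeric(s2[c("mean", "range", "skewness")]), c(0, 10, 0))
  expect_error(window_stats(numeric(0)))
  # cross-check moments against e1071 on a random window
  set.seed(7)
  x <- rnorm(50)
  s3 <- window_stats(x)
  expect_equal(s3[["variance"]], var(x))
  expect_equal(s3[["skewness"]], e1071::skewness(x, type = 1))
  expect_equal(s3[["kurtosis"]], e1071::kurtosis(x, type = 1) + 3)
})

test_that("sliding windows enumerate 50%-overlapping fixed windows, no padding", {
  w <- slide_windows(60)
  expect_equal(w$start, c(0L, 10L, 20L, 30L, 40L))
  expect_equal(unique(w$length), 20L)
  expect_equal(nrow(slide_windows(19)), 0L)
  expect_equal(nrow(slide_windows(20)), 1L)
  # count formula and 10-sample sharing for a range of lengths
  for (n in c(20, 25, 37, 100, 333)) {
    w <- slide_windows(n)
    expect_equal(nrow(w), floor((n - 20) / 10) + 1)
    if (nrow(w) > 1) {
      shared <- intersect(w$start[1] + 1:20, w$start[2] + 1:20)
      expect_length(shared, 10)
    }
  }
  expect_error(slide_windows(50, size = 20, overlap = 0.33), "whole number")
})

test_that("feature schema has the printed cardinalities and stable unique names", {
  expect_equal(nrow(feature_schema("TB", FALSE)), 112L)
  expect_equal(nrow(feature_schema("TB", TRUE)), 136L)
  expect_equal(nrow(feature_schema("WR", TRUE)), 136L)
  expect_equal(nrow(feature_schema("TB_WR", FALSE)), 224L)
  expect_equal(nrow(feature_schema("TB_WR", TRUE)), 272L)
  sch <- feature_schema("TB_WR", TRUE)
  expect_false(anyDuplicated(sch$feature) > 0)
  expect_identical(sch$feature, feature_schema("TB_WR", TRUE)$feature)
  # TB block strictly precedes WR block
  expect_true(max(which(sch$placement == "TB")) < min(which(sch$placement == "WR")))
})

test_that("derived channel matrix has 14 or 17 named channels", {
  s <- generate_session(mini_script(seed = 2))
  tb <- s[s$placement == "TB", ]
  ch14 <- build_channels(tb, include_euler = FALSE)
  ch17 <- build_channels(tb, include_euler = TRUE)
  expect_equal(ncol(ch14), 14L)
  expect_equal(ncol(ch17), 17L)
  expect_identical(colnames(ch17)[15:17], c("pitch", "roll", "yaw"))
  expect_true(all(ch14[, "a_hori"] <= ch14[, "a_norm"] + 1e-12))
  expect_true(all(ch14[, "g_sagi"] <= ch14[, "g_norm"] + 1e-12))
  one <- build_channels(tb[1, ], include_euler = FALSE)
  expect_equal(dim(one), c(1L, 14L))
  expect_error(build_channels(tb[0, ]), "empty")
})

test_that("window labels take the sample majority with ties to transition", {
  w <- tibble::tibble(start = 0L, length = 20L)
  expect_equal(label_windows(rep(7L, 20), w), 7L)
  expect_equal(label_windows(c(rep(3L, 10), rep(0L, 10)), w), 0L)
  expect_equal(label_windows(c(rep(3L, 11), rep(4L, 9)), w), 3L)
  expect_equal(label_windows(c(rep(5L, 10), rep(9L, 10)), w), 0L)
})

test_that("feature extraction yields the schema widths and is deterministic", {
  s <- generate_session(mini_script(seed = 5))
  for (cfg in list(list("TB", FALSE, 112L), list("WR", TRUE, 136L),
                   list("TB_WR", FALSE, 224L), list("TB_WR", TRUE, 272L))) {
    fe <- extract_features(s, cfg[[1]], include_euler = cfg[[2]])
    expect_equal(ncol(fe) - 3L, cfg[[3]])
    expect_false(any(!is.finite(as.matrix(fe[, -(1:3)]))))
    expect_equal(nrow(fe), nrow(slide_windows(sum(s$placement == "TB"))))
  }
  fe1 <- extract_features(s, "TB_WR", include_euler = TRUE)
  fe2 <- extract_features(s, "TB_WR", include_euler = TRUE)
  expect_identical(fe1, fe2)
  # fused extraction equals per-sensor extraction concatenated
  tb <- extract_features(s, "TB", include_euler = TRUE)
  wr <- extract_features(s, "WR", include_euler = TRUE)
  expect_equal(as.matrix(fe1[, 4:139]), as.matrix(tb[, -(1:3)]), ignore_attr = TRUE)
  expect_equal(as.matrix(fe1[, 140:275]), as.matrix(wr[, -(1:3)]), ignore_attr = TRUE)
  # a missing stream is refused for the fused modality
  expect_error(extract_features(s[s$placement == "TB", ], "TB_WR"), "missing stream")
})

test_that("select_feature_block reproduces direct extraction", {
  s <- generate_session(mini_script(seed = 6))
  full <- extract_features(s, "TB_WR", include_euler = TRUE)
  sub <- select_feature_block(full, "WR", include_euler = FALSE)
  direct <- extract_features(s, "WR", include_euler = FALSE)
  expect_equal(sub, direct, ignore_attr = TRUE)
  expect_identical(attr(sub, "schema")$feature, attr(direct, "schema")$feature)
  expect_error(select_feature_block(direct, "TB_WR", TRUE), "missing")
})
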