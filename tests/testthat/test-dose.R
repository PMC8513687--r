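test_that("aggregation computes mean, sample sd and count per cell", {
  tab <- aggregate_features(tibble::tibble(
    dose_nM = 0, feature = "ct_pks_ms", value = rep(5, 19)))
  expect_equal(tab$mean, 5)
  expect_equal(tab$sd, 0)
  expect_equal(tab$n, 19L)

  tab2 <- aggregate_features(tibble::tibble(
    dose_nM = 0, feature = "x", value = c(1, 2, 3)))
  expect_equal(tab2$mean, 2)
  expect_equal(tab2$sd, 1)

  expect_error(aggregate_features(
    tibble::tibble(dose_nM = numeric(), feature = character(),
                   value = numeric())), "empty")
})

test_that("aggregation matches direct recomputation on raw records", {
  set.seed(8)
  recs <- tibble::tibble(
    dose_nM = rep(c(0, 3, 10), each = 19),
    feature = rep("fpd_ms", 57),
    value = rnorm(57, mean = rep(c(238.6, 226.2, 208.1), each = 19), sd = 5))
  tab <- aggregate_features(recs)
  for (d in c(0, 3, 10)) {
    v <- recs$value[recs$dose_nM == d]
    expect_equal(tab$mean[tab$dose_nM == d], mean(v))
    expect_equal(tab$sd[tab$dose_nM == d], sd(v))
    expect_equal(tab$n[tab$dose_nM == d], 19L)
  }
})

test_that("a seeded baseline run yields 19 beats per optical feature", {
  p <- quadcell_preset("BASELINE_0NM")
  rec <- synth_paced_recording(p$monolayer, p$protocol)
  long <- extract_features(rec)
  long$dose_nM <- p$dose_nM
  tab <- aggregate_features(long[long$modality == "optical", ])
  expect_true(all(tab$n == 19L))
})

test_that("strictly decreasing dose means give a decreasing trend", {
  set.seed(3)
  recs <- tibble::tibble(
    dose_nM = rep(c(0, 3), each = 19),
    value = rnorm(38, mean = rep(c(238.6, 226.2), each = 19), sd = 3))
  res <- trend_test(recs, n_permutations = 499, seed = 1)
  expect_equal(res$direction, "decreasing")
  expect_lt(res$p_value, 0.05)
  expect_lt(res$statistic, 0)
})

test_that("identical dose distributions give no direction", {
  set.seed(4)
  recs <- tibble::tibble(
    dose_nM = rep(c(0, 3, 10), each = 10),
    value = rnorm(30))
  res <- trend_test(recs, n_permutations = 499, seed = 2)
  expect_equal(res$direction, "none")
  expect_error(trend_test(tibble::tibble(dose_nM = 0, value = 1:3)),
               "2 doses")
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  # 2 doses x 3 beats: all choose(6, 3) = 20 label assignments
  recs <- tibble::tibble(dose_nM = rep(c(0, 3), each = 3),
                         value = c(10, 11, 9, 6, 7, 5))
  res <- trend_test(recs, method = "exhaustive")
  expect_equal(res$n_permutations, 20L)

  # independent oracle: enumerate assignments with utils::combn directly
  y <- recs$value
  slope_of <- function(x) cov(x, y) / var(x)
  obs <- slope_of(c(1, 1, 1, 2, 2, 2))
  picks <- utils::combn(6, 3)
  null_stats <- apply(picks, 2, function(ix) {
    x <- rep(2, 6)
    x[ix] <- 1
    slope_of(x)
  })
  p_oracle <- mean(abs(null_stats) >= abs(obs) - 1e-12)
  expect_equal(res$p_value, p_oracle)

  # Monte-Carlo converges to the exhaustive value
  mc <- trend_test(recs, n_permutations = 9999, seed = 7)
  expect_equal(mc$p_value, p_oracle, tolerance = 0.2)
})

test_that("type-I error stays near nominal on null data", {
  set.seed(99)
  n_rep <- 300
  rejections <- 0
  for (i in seq_len(n_rep)) {
    recs <- tibble::tibble(dose_nM = rep(c(0, 3, 10), each = 10),
                           value = rnorm(30))
    p <- trend_test(recs, n_permutations = 199, seed = i)$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_rep, 0.08)
})

test_that("glance returns a plain one-row tibble", {
  recs <- tibble::tibble(dose_nM = rep(c(0, 3), each = 3),
                         value = c(10, 11, 9, 6, 7, 5))
  g <- glance(trend_test(recs, method = "exhaustive"))
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1)
})
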