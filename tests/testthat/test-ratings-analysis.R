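make_records <- function(values_by_cell) {
  # values_by_cell: list of lists with participant, gender, scheme, value
  do.call(rbind, lapply(values_by_cell, as.data.frame))
}

test_that("per-condition averaging is a plain cell mean, order invariant", {
  rec <- data.frame(participant = 1, gender = "female", scheme = "NHQ",
                    attribute = "flow", value = rep(2.5, 8))
  cm <- average_per_condition(rec)
  expect_equal(cm$value, 2.5)
  expect_equal(cm$n, 8)

  bb <- sim_backbone()
  rt <- generate_synthetic_ratings(bb$lists, bb$meta,
                                   rating_gen_params(n_participants = 6),
                                   seed = 3)
  cm1 <- average_per_condition(rt)
  cm2 <- average_per_condition(rt[sample(nrow(rt)), ])
  expect_equal(cm1, cm2)
  expect_true(all(cm1$n == 8))

  # a missing cell warns and is marked NA
  rt_miss <- rt[!(rt$participant == 1 & rt$scheme == "HIN"), ]
  expect_warning(cm3 <- average_per_condition(rt_miss), "empty")
  expect_true(any(is.na(cm3$value)))
})

test_that("mixed model detects a planted condition deficit and reports contrasts", {
  bb <- sim_backbone()
  rp <- rating_gen_params(condition_effects = c(conLow = 0, conNHQ = 0,
                                                NHQ = 0, HIN = -1.2),
                          fto_median_slope = 0, residual_sd = 0.6)
  rt <- generate_synthetic_ratings(bb$lists, bb$meta, rp, seed = 21)
  mm <- mixed_model_ratings(average_per_condition(rt), "flow")
  an <- mm$anova
  expect_lt(an$p[an$effect == "scheme"], 1e-6)
  expect_gt(an$p[an$effect == "gender"], 0.001) # nothing planted
  expect_equal(nrow(mm$contrasts), 6) # all pairwise scheme contrasts
  hin_rows <- grepl("HIN", mm$contrasts$contrast)
  expect_true(all(mm$contrasts$p[hin_rows] < 0.01))
  expect_true(all(mm$contrasts$lower <= mm$contrasts$estimate &
                  mm$contrasts$estimate <= mm$contrasts$upper))
  expect_equal(mm$ddf_method, "Satterthwaite")
})

test_that("a gender-specific ceiling produces a detectable interaction", {
  bb <- sim_backbone()
  rp <- rating_gen_params(
    condition_effects = c(conLow = 0, conNHQ = 0, NHQ = 0, HIN = 0),
    fto_median_slope = 0, residual_sd = 0.5,
    interaction_effects = list(
      female = c(conLow = 0.6, conNHQ = 0.6, NHQ = 0.6, HIN = 0.6),
      male = c(conLow = 0.8, conNHQ = 0.4, NHQ = 0, HIN = -0.8)))
  rt <- generate_synthetic_ratings(bb$lists, bb$meta, rp, seed = 31)
  mm <- mixed_model_ratings(average_per_condition(rt), "ease_of_following")
  an <- mm$anova
  expect_lt(an$p[an$effect == "scheme:gender"], 0.01)
})

test_that("Spearman correlation equals rank-transform-then-Pearson", {
  bb <- sim_backbone()
  rt <- generate_synthetic_ratings(bb$lists, bb$meta,
                                   rating_gen_params(n_participants = 10),
                                   seed = 5)
  ct <- correlate_flow_vs_fto(rt, "median")
  d <- rt[rt$scheme %in% c("NHQ", "HIN") & rt$attribute == "flow", ]
  expect_equal(ct$rho,
               cor(rank(d$value), rank(d$realized_fto_median_ms)),
               tolerance = 1e-12)
  expect_equal(ct$n, nrow(d))
  expect_error(correlate_flow_vs_fto(rt[1:3, ], "median"), "at least 5")

  # strictly decreasing dependence gives rho exactly -1
  dec <- data.frame(participant = 1, gender = "m", scheme = "NHQ",
                    attribute = "flow", value = 10 - (1:20),
                    realized_fto_median_ms = (1:20) * 30,
                    realized_fto_iqr_ms = 100)
  expect_equal(correlate_flow_vs_fto(dec, "median")$rho, -1)
})

test_that("rank-sum: identical groups, disjoint groups, degenerate input", {
  r0 <- compare_groups_ranksum(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  r1 <- compare_groups_ranksum(1:5, 6:10)
  expect_equal(r1$p, 2 / 252) # only the two extreme assignments
  expect_equal(r1$method, "exact enumeration")

  rd <- compare_groups_ranksum(rep(3, 4), rep(3, 5))
  expect_equal(rd$p, 1)
  expect_error(compare_groups_ranksum(1:2, 1:10), "at least 3")
})

test_that("normal approximation tracks exact enumeration at small n", {
  for (seed in 1:20) {
    x <- with_seed(seed, list(a = rnorm(6), b = rnorm(6)))
    r <- compare_groups_ranksum(x$a, x$b) # exact at N = 12
    p_norm <- 2 * pnorm(-abs(r$statistic))
    expect_lt(abs(r$p - p_norm), 0.02)
  }
})

test_that("rank-sum p agrees with the standard implementation above the exact range", {
  for (seed in 1:10) {
    x <- with_seed(seed, list(a = rnorm(15), b = rnorm(18)))
    r <- compare_groups_ranksum(x$a, x$b)
    w <- wilcox.test(x$a, x$b, correct = TRUE, exact = FALSE)
    expect_equal(r$p, w$p.value, tolerance = 1e-9)
  }
})

test_that("matched-subset search equals the exhaustive window oracle", {
  rec <- median_driven_records(n = 400, seed = 2)
  for (param in c("median", "iqr")) {
    got <- find_matched_subset(rec, param)
    want <- matched_subset_oracle(rec, param)
    expect_equal(got$n_total, want$n)
    expect_equal(got$interval, want$interval)
    expect_equal(got$n_NHQ + got$n_HIN, got$n_total)
    expect_lte(abs(got$n_NHQ - got$n_HIN), 20)
    expect_gt(got$match_test$p, 0.05)
  }
})

test_that("an unbalanced inventory with a zero count allowance returns empty", {
  # 51 NHQ vs 50 HIN records on common support: every candidate window
  # holds all records, so counts always differ by one
  rec <- with_seed(6, data.frame(
    scheme = rep(c("NHQ", "HIN"), times = c(51, 50)),
    attribute = "flow", value = rnorm(101, 3),
    realized_fto_median_ms = runif(101, 380, 400),
    realized_fto_iqr_ms = runif(101, 500, 520)))
  got <- find_matched_subset(rec, "median", max_count_diff = 0)
  expect_s3_class(got, "subset_result")
  expect_equal(got$n_total, 0)
  expect_true(all(is.na(got$interval)))
})

test_that("flow deficits driven by FTO median survive IQR matching but not median matching", {
  rec <- median_driven_records(n = 400, seed = 2)
  m_med <- find_matched_subset(rec, "median")
  m_iqr <- find_matched_subset(rec, "iqr")
  expect_gt(m_med$n_total, 50)
  expect_gt(m_iqr$n_total, 50)
  # medians matched -> no flow difference; IQR matched -> medians still
  # differ -> flow difference shows
  expect_gt(m_med$contrast_test$p, 0.05)
  expect_lt(m_iqr$contrast_test$p, 0.05)
  # the unmatched parameter keeps differing in the median-matched subset
  expect_lt(m_med$unmatched_test$p, 0.05)
})
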