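test_that("correlate: perfect linear relation and degenerate input", {
  co <- correlate(c(1, 2, 3), c(10, 20, 30))
  expect_equal(co$pearson_r, 1)
  expect_equal(co$variance_explained_pct, 100)
  expect_error(correlate(c(2, 2, 2), c(1, 2, 3)), "zero variance",
               class = "hamscore_degenerate_error")
  expect_error(correlate(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("Spearman is Pearson on mid-ranks (tied case, frozen oracle)", {
  co <- correlate(c(1, 1, 2, 2), c(4, 3, 2, 1))
  # hand-ranked: x -> (1.5, 1.5, 3.5, 3.5), y -> (4, 3, 2, 1); Pearson of
  # those ranks = -0.8944272
  expect_equal(co$spearman_rho, -0.8944272, tolerance = 1e-6)
  expect_equal(co$spearman_rho, naive_spearman(c(1, 1, 2, 2), c(4, 3, 2, 1)))
})

test_that("all statistics match naive formulas on short vectors (oracle)", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:8, 1)
    x <- sample(1:12, n, replace = TRUE)   # ties likely
    y <- round(stats::runif(n, 1, 60))
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    co <- correlate(x, y)
    expect_equal(co$pearson_r, naive_pearson(x, y), tolerance = 1e-12)
    expect_equal(co$spearman_rho, naive_spearman(x, y), tolerance = 1e-12)
    expect_equal(co$variance_explained_pct, 100 * naive_pearson(x, y)^2)

    thr <- sample(3:10, 1)
    if (length(unique(y[x >= thr])) == 0 || sum(x >= thr) < 2 ||
        sum(x < thr) < 2) next
    g <- dichotomize_and_compare(x, y, thr)
    expect_equal(g$comparison$mean_difference_days,
                 naive_mean(y[x >= thr]) - naive_mean(y[x < thr]))
    expect_equal(g$comparison$effect_size_d,
                 naive_cohens_d(y[x >= thr], y[x < thr]))
  }
})

test_that("correlation invariances under transforms of rts", {
  set.seed(42)
  x <- sample(4:12, 30, replace = TRUE)
  y <- stats::runif(30, 1, 66)
  base <- correlate(x, y)
  aff <- correlate(x, 3.5 * y + 11)          # positive affine
  expect_equal(aff$pearson_r, base$pearson_r, tolerance = 1e-12)
  mono <- correlate(x, exp(y / 20))          # strictly monotone
  expect_equal(mono$spearman_rho, base$spearman_rho, tolerance = 1e-12)
})

test_that("dichotomization partition is exhaustive and exclusive", {
  set.seed(7)
  x <- sample(1:19, 200, replace = TRUE)
  y <- stats::runif(200, 1, 66)
  for (thr in c(1, 5, 10, 19)) {
    g <- dichotomize_and_compare(x, y, thr)
    expect_identical(g$group_low$n + g$group_high$n, 200L)
    expect_identical(g$group_low$n, sum(x < thr))
    expect_identical(g$group_high$n, sum(x >= thr))
  }
})

test_that("dichotomization degenerate and empty-group contracts", {
  # zero pooled SD with a real difference: d must be NA with a warning,
  # never a silent infinity; the difference itself is still reported
  expect_warning(
    g <- dichotomize_and_compare(c(9, 9, 10, 10), c(20, 20, 30, 30), 10),
    class = "hamscore_degenerate_warning"
  )
  expect_equal(g$comparison$mean_difference_days, 10)
  expect_true(is.na(g$comparison$effect_size_d))

  # equal group means: d = 0
  g2 <- dichotomize_and_compare(c(1, 2, 11, 12), c(5, 9, 5, 9), 10)
  expect_equal(g2$comparison$effect_size_d, 0)

  # an empty group: partition returned, comparison absent
  g3 <- dichotomize_and_compare(c(1, 2, 3), c(5, 9, 7), 10)
  expect_identical(g3$group_high$n, 0L)
  expect_null(g3$comparison)
})

test_that("ks_normality: null held, gross violation caught, bounds", {
  set.seed(1)
  ok <- ks_normality(stats::rnorm(1000))
  expect_gt(ok$p, 0.05)
  set.seed(1)
  bad <- ks_normality(stats::rexp(1000))
  expect_lt(bad$p, 0.05)
  for (s in list(ok, bad)) {
    expect_gte(s$statistic, 0)
    expect_lte(s$statistic, 1)
    expect_gte(s$p, 0)
    expect_lte(s$p, 1)
  }
  expect_error(ks_normality(rep(3, 10)), "constant",
               class = "hamscore_degenerate_error")
  expect_error(ks_normality(c(1, 2, 3)), "n >= 5")
})

test_that("ks_normality statistic matches external reference (frozen)", {
  # D for this fixture computed independently with statsmodels' lilliefors
  x <- c(1.2, 3.4, 2.2, 5.9, 0.4, 2.8, 3.1, 7.7, 1.9, 2.5,
         4.1, 0.9, 6.3, 2.0, 3.3, 1.1, 2.9, 4.8, 0.2, 3.6)
  s <- ks_normality(x)
  expect_equal(s$statistic, 0.1345570006, tolerance = 1e-9)
  # reference p 0.4431 (table-based); same non-significant region
  expect_gt(s$p, 0.1)
  expect_lt(s$p, 0.8)
})

test_that("parameter recovery: configured correlation is recovered at n = 10,000", {
  for (i in seq_along(c(0, 0.2, 0.8))) {
    rho <- c(0, 0.2, 0.8)[i]
    cfg <- synthetic_config(
      n = 10000, seed = 100 + i,
      rts_model = list(type = "calibrated", target_mean = 22.65,
                       target_sd = 11.03, target_r = rho,
                       floor = 1, round = TRUE)
    )
    co <- generate_cohort(cfg)
    est <- correlate(score_records(co)$total, co$rts_days)$pearson_r
    expect_equal(est, rho, tolerance = 0.03)
  }
})

test_that("evaluate_cohort assembles the full analysis", {
  co <- generate_cohort(n = 110, seed = 5)
  ev <- evaluate_cohort(co)
  expect_s3_class(ev, "evaluation_result")
  expect_identical(ev$n, 110L)
  expect_named(ev$normality, c("total_score", "rts_days"))
  expect_true(abs(ev$correlation$pearson_r) <= 1)
  expect_equal(ev$correlation$variance_explained_pct,
               100 * ev$correlation$pearson_r^2)
  expect_identical(ev$groups$group_low$n + ev$groups$group_high$n, 110L)
  expect_output(print(ev), "Pearson")
})
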