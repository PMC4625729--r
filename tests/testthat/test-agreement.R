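test_that("HAA threshold classification treats the boundary as positive", {
  expect_identical(classify_by_haa(10.0, 10), "positive")
  expect_identical(classify_by_haa(9.999, 10), "negative")
  expect_identical(classify_by_haa(6.44, 6.44), "positive")
  expect_error(classify_by_haa(5, 0), "threshold_pct")
  expect_error(classify_by_haa(5, 100), "threshold_pct")
})

test_that("percentile thresholds use the linear-interpolation sample quantile", {
  expect_equal(percentile_threshold(1:100, 95), 95.05)
  expect_equal(percentile_threshold(rep(5, 25), 95), 5)
  x <- c(rlnorm(80, 1, 0.5), seq(0.5, 20, length.out = 20))
  expect_identical(percentile_threshold(x), percentile_threshold(sample(x)))
  expect_error(percentile_threshold(numeric(0)), "no HAA values")
  expect_error(percentile_threshold(1:5), "at least 20")
})

test_that("contingency construction enumerates toy cohorts correctly", {
  co <- toy_cohort(haa_pct = c(12, 4, 11, 3),
                   visual_status = c("ila", "ila", "no_ila", "no_ila"))
  t <- build_contingency(co, 10, "exclude")
  expect_identical(c(t$a, t$b, t$c, t$d), c(1L, 1L, 1L, 1L))

  co_ind <- rbind(co, toy_cohort(haa_pct = c(5, 6),
                                 visual_status = "indeterminate"))
  t_ac <- build_contingency(co_ind, 10, "as_control")
  expect_identical(t_ac$c + t_ac$d, 4L)  # no-ILA row grew by the 2 absorbed
  expect_identical(t_ac$n_indeterminate_absorbed, 2L)
  t_ex <- build_contingency(co_ind, 10, "exclude")
  expect_identical(t_ex$a + t_ex$b + t_ex$c + t_ex$d, 4L)
})

test_that("kappa behaves at its analytic anchors", {
  perfect <- contingency_2x2(50, 0, 0, 50)
  expect_equal(cohen_kappa(perfect)$kappa, 1)
  # joint = product of marginals -> kappa 0
  indep <- contingency_2x2(20, 80, 180, 720)
  expect_equal(cohen_kappa(indep)$kappa, 0)
  # symmetry: swapping rows and columns simultaneously preserves kappa
  t1 <- contingency_2x2(7, 21, 13, 59)
  t2 <- contingency_2x2(59, 13, 21, 7)
  expect_equal(cohen_kappa(t1)$kappa, cohen_kappa(t2)$kappa)
  expect_error(cohen_kappa(contingency_2x2(10, 0, 0, 0)), "undefined")
})

test_that("diagnostic panel handles perfect and missing-denominator cases", {
  all_right <- diagnostic_panel(contingency_2x2(10, 0, 0, 10))
  expect_equal(unlist(all_right[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  no_pos <- diagnostic_panel(contingency_2x2(0, 5, 0, 5))
  expect_true(is.na(no_pos$ppv))
  expect_identical(no_pos$sensitivity, 0)
})

test_that("c-statistic equals brute-force pair counting and Mann-Whitney U", {
  # perfectly separated
  expect_equal(c_statistic(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  # 6-point set with a tie, against exhaustive pair enumeration
  vals <- c(1, 2, 3, 3, 4, 5)
  labs <- c(0, 0, 1, 0, 1, 1)
  pairs <- expand.grid(case = vals[labs == 1], ctrl = vals[labs == 0])
  brute <- mean(ifelse(pairs$case > pairs$ctrl, 1,
                       ifelse(pairs$case == pairs$ctrl, 0.5, 0)))
  expect_equal(c_statistic(vals, labs), brute)
  # Mann-Whitney U equivalence on random instances
  set.seed(42)
  for (i in 1:5) {
    x <- round(rlnorm(60, 1, 0.6), 1)  # rounding forces ties
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    u <- wilcox.test(x[y == 1], x[y == 0], exact = FALSE)$statistic
    expect_equal(c_statistic(x, y), unname(u) / (sum(y) * sum(!y)))
  }
  # null: labels independent of values
  set.seed(7)
  expect_lt(abs(c_statistic(rnorm(4000), rbinom(4000, 1, 0.5)) - 0.5), 0.05)
  expect_error(c_statistic(1:5, c(1, 1, 1, 1, 1)), "both")
})

test_that("threshold sweep matches per-threshold recomputation and is monotone", {
  co <- toy_cohort(haa_pct = c(2, 3, 5, 7, 9, 11, 13, 4),
                   visual_status = c("no_ila", "no_ila", "ila", "no_ila",
                                     "ila", "ila", "ila", "no_ila"))
  grid <- c(4, 6, 8, 10, 12)
  sweep <- threshold_sweep(co, grid)
  expect_identical(nrow(sweep), length(grid))
  for (i in seq_along(grid)) {
    direct <- agreement_stats(build_contingency(co, grid[i], "exclude"),
                              grid[i])
    expect_equal(sweep[i, names(direct)], direct, ignore_attr = TRUE)
  }
  expect_true(all(diff(sweep$sensitivity) <= 0))
  expect_true(all(diff(sweep$specificity) >= 0))
  expect_identical(sum(sweep$best), 1L)
  # single-threshold sweep equals direct computation
  one <- threshold_sweep(co, 8)
  expect_equal(one$kappa, agreement_stats(build_contingency(co, 8))$kappa)
})
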