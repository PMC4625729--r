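test_that("covariate-free logistic OR equals the 2x2 cross-product ratio", {
  # binary exposure encoded as a 1-unit HAA difference
  co <- toy_cohort(
    haa_pct = c(3, 3, 3, 3, 3, 4, 4, 4, 4, 4, 3, 4),
    visual_status = c("ila", "no_ila", "no_ila", "no_ila", "no_ila",
                      "ila", "ila", "ila", "no_ila", "no_ila",
                      "ila", "no_ila"))
  tab <- table(exposed = co$haa_pct == 4, ila = co$visual_status == "ila")
  cross_product <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  fit <- fit_ila_logistic(co, adjustment_set = character(0))
  expect_equal(fit$estimate, unname(cross_product), tolerance = 1e-6)
})

test_that("linear TLC slope matches the normal-equations solution", {
  co <- toy_cohort(haa_pct = c(1, 2, 4, 7, 11),
                   visual_status = "no_ila",
                   tlc_ml = c(6100, 5800, 5400, 4100, 2900))
  X <- cbind(1, co$haa_pct)
  beta <- solve(t(X) %*% X, t(X) %*% co$tlc_ml)
  fit <- fit_tlc_linear(co, adjustment_set = character(0))
  expect_equal(fit$estimate, beta[2], tolerance = 1e-9)
  # zero-noise simulation: adjusted fit recovers the slope to precision
  spec <- cohort_sim_spec(n_subjects = 300, tlc_noise_sd = 0, seed = 21)
  fit0 <- suppressWarnings(fit_tlc_linear(simulate_cohort(spec)))
  expect_equal(fit0$estimate, -351, tolerance = 1e-6)
})

test_that("null odds ratio is recovered with nominal CI behaviour", {
  hits <- 0L
  for (seed in 1:30) {
    # flat HAA effect; intercept raised so the null cohort still has cases
    co <- simulate_cohort(cohort_sim_spec(n_subjects = 1500,
                                          or_per_pct_haa = 1.0,
                                          ila_intercept = -2.2, seed = seed))
    fit <- fit_ila_logistic(co)
    if (fit$ci_low <= 1 && fit$ci_high >= 1) hits <- hits + 1L
  }
  expect_gte(hits, 25L)  # ~95% nominal coverage, binomial slack at 30 reps
})

test_that("stratified estimates match per-stratum 2x2 oracles", {
  lo <- toy_cohort(
    haa_pct = c(3, 3, 3, 4, 4, 4, 3, 4, 3, 4),
    visual_status = c("ila", "no_ila", "no_ila", "ila", "ila", "no_ila",
                      "no_ila", "ila", "no_ila", "no_ila"),
    emph_pct = 1)
  hi <- toy_cohort(
    haa_pct = c(3, 3, 4, 4, 4, 3, 4, 3, 3, 4),
    visual_status = c("ila", "no_ila", "ila", "ila", "ila", "no_ila",
                      "no_ila", "no_ila", "no_ila", "ila"),
    emph_pct = 8)
  co <- rbind(lo, hi)
  co$subject_id <- sprintf("T%03d", seq_len(nrow(co)))
  res <- stratified_effects(co, "emph_pct@5", adjustment_set = character(0))
  for (stratum in list(list(dat = lo, i = 1), list(dat = hi, i = 2))) {
    tab <- table(stratum$dat$haa_pct == 4,
                 stratum$dat$visual_status == "ila")
    cp <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
      (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
    expect_equal(res$strata[[stratum$i]]$estimate, unname(cp),
                 tolerance = 1e-5)
  }
  expect_true(is.finite(res$interaction_p))
  expect_error(stratified_effects(lo, "emph_pct@5",
                                  adjustment_set = character(0)),
               "empty stratum")
})

test_that("stratum-specific generation is recovered within CIs", {
  spec <- cohort_sim_spec(n_subjects = 6000, emph_strata_or = c(1.2, 3.8),
                          seed = 31)
  res <- stratified_effects(simulate_cohort(spec))
  expect_true(res$strata[[1]]$ci_low <= 1.2 && res$strata[[1]]$ci_high >= 1.2)
  expect_true(res$strata[[2]]$ci_low <= 3.8 && res$strata[[2]]$ci_high >= 3.8)
  expect_lt(res$interaction_p, 0.05)
})

test_that("additive genetic model matches hand least-squares on a balanced toy", {
  co <- toy_cohort(haa_pct = c(3.0, 3.4, 3.7, 4.1, 4.6, 5.0),
                   visual_status = "no_ila",
                   genotype = c(0L, 0L, 1L, 1L, 2L, 2L))
  X <- cbind(1, co$genotype)
  beta <- solve(t(X) %*% X, t(X) %*% co$haa_pct)
  fit <- genotype_association(co, "haa_continuous",
                              adjustment_set = character(0))
  expect_equal(fit$estimate, beta[2], tolerance = 1e-9)
  expect_error(genotype_association(toy_cohort(haa_pct = c(3, 4),
                                               visual_status = "no_ila",
                                               genotype = 0L)),
               "monomorphic")
})

test_that("a positive genotype effect is detected more often than the null", {
  null_rej <- alt_rej <- 0L
  for (seed in 1:15) {
    co0 <- simulate_cohort(cohort_sim_spec(n_subjects = 800, seed = seed))
    co1 <- simulate_cohort(cohort_sim_spec(n_subjects = 800,
                                           genotype_haa_beta = 0.3,
                                           seed = seed + 100))
    if (genotype_association(co0, "haa_continuous")$p_value < 0.05)
      null_rej <- null_rej + 1L
    if (genotype_association(co1, "haa_continuous")$p_value < 0.05)
      alt_rej <- alt_rej + 1L
  }
  expect_gt(alt_rej, null_rej)
  expect_gte(alt_rej, 12L)  # strong effect, high power
})

test_that("log-OR bias shrinks as the cohort grows", {
  bias <- vapply(c(500, 2000, 8000), function(n) {
    est <- vapply(1:8, function(seed) {
      co <- simulate_cohort(cohort_sim_spec(n_subjects = n, seed = seed))
      log(fit_ila_logistic(co)$estimate)
    }, numeric(1))
    abs(mean(est) - log(2.3))
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 0.02)
  expect_lt(bias[3], 0.05)
})
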