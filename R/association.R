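# Default covariate adjustment for HAA-outcome models; COPD status is
# proxied by percent emphysema since spirometry is not modelled.
DEFAULT_ADJUSTMENT <- c("age", "sex", "race", "bmi", "pack_years",
                        "current_smoker", "emph_pct")
# Genetic models adjust for the demographic/anthropometric set only.
GENETIC_ADJUSTMENT <- c("age", "sex", "bmi", "pack_years", "current_smoker")

association_result <- function(estimate, ci_low, ci_high, p_value, n_used,
                               adjustment_set, scale,
                               stratum_label = NA_character_) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, n_used = n_used,
                 adjustment_set = adjustment_set, scale = scale,
                 stratum_label = stratum_label),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  lab <- if (is.na(x$stratum_label)) "" else sprintf(" [%s]", x$stratum_label)
  cat(sprintf("<association%s> %s = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d\n",
              lab, x$scale, x$estimate, x$ci_low, x$ci_high, x$p_value,
              x$n_used))
  invisible(x)
}

#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(scale = x$scale, stratum = x$stratum_label,
             estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
             p = x$p_value, n = x$n_used,
             adjustment = paste(x$adjustment_set, collapse = "+"))
}

apply_indeterminate_policy <- function(cohort, policy) {
  vs <- as.character(cohort$visual_status)
  if (policy == "exclude") {
    cohort <- cohort[vs != "indeterminate", , drop = FALSE]
  } else {
    cohort$visual_status <- factor(
      ifelse(vs == "indeterminate", "no_ila", vs), levels = VISUAL_LEVELS)
  }
  cohort
}

check_separation <- function(fit) {
  probs <- fitted(fit)
  if (any(probs > 1 - 1e-10) || any(probs < 1e-10) ||
      any(abs(coef(fit)) > 15, na.rm = TRUE))
    warning("possible complete separation: fitted probabilities at 0/1 or an extreme coefficient",
            call. = FALSE)
  fit
}

wald_ci <- function(fit, term, level = 0.95) {
  est <- coef(fit)[term]
  se <- sqrt(vcov(fit)[term, term])
  z <- qnorm(1 - (1 - level) / 2)
  smry <- summary(fit)$coefficients
  pcol <- grep("^Pr", colnames(smry))
  list(est = unname(est), lo = unname(est - z * se),
       hi = unname(est + z * se), p = unname(smry[term, pcol]))
}

build_formula <- function(outcome, exposure, adjustment_set) {
  rhs <- paste(c(exposure, adjustment_set), collapse = " + ")
  stats::as.formula(paste(outcome, "~", rhs))
}

#' Odds of visual ILA per 1% HAA
#'
#' Fits a covariate-adjusted logistic regression of visual ILA status on
#' HAA% and reports the odds ratio per 1% HAA with a Wald 95% CI.
#' Indeterminate visual reads are either excluded or counted as controls.
#'
#' @param cohort a cohort data.frame (see [simulate_cohort()]).
#' @param adjustment_set character vector of covariate columns.
#' @param indeterminate_policy `"exclude"` or `"as_control"`.
#' @return An `association_result` with `estimate` an odds ratio.
#' @export
fit_ila_logistic <- function(cohort, adjustment_set = DEFAULT_ADJUSTMENT,
                             indeterminate_policy = c("exclude", "as_control")) {
  indeterminate_policy <- match.arg(indeterminate_policy)
  cohort <- validate_cohort(cohort)
  dat <- apply_indeterminate_policy(cohort, indeterminate_policy)
  dat$ila <- as.integer(as.character(dat$visual_status) == "ila")
  if (length(unique(dat$ila)) < 2L)
    stop_named("need both ILA and non-ILA subjects after applying the policy")
  fit <- glm(build_formula("ila", "haa_pct", adjustment_set),
             data = dat, family = binomial())
  check_separation(fit)
  w <- wald_ci(fit, "haa_pct")
  association_result(exp(w$est), exp(w$lo), exp(w$hi), w$p, nrow(dat),
                     adjustment_set, scale = "odds_ratio")
}

#' TLC change per 1% HAA
#'
#' Fits a covariate-adjusted linear regression of CT-derived total lung
#' capacity (ml) on HAA% and reports the slope in ml per 1% HAA with a
#' Wald 95% CI, either in all subjects or restricted to visual-ILA cases.
#'
#' @inheritParams fit_ila_logistic
#' @param subset `"all"` or `"ila_only"`.
#' @return An `association_result` with `estimate` a slope in ml per % HAA.
#' @export
fit_tlc_linear <- function(cohort, adjustment_set = DEFAULT_ADJUSTMENT,
                           subset = c("all", "ila_only")) {
  subset <- match.arg(subset)
  cohort <- validate_cohort(cohort)
  dat <- if (subset == "ila_only")
    cohort[as.character(cohort$visual_status) == "ila", , drop = FALSE]
  else cohort
  if (nrow(dat) == 0L) stop_named("subset '%s' contains no subjects", subset)
  fit <- lm(build_formula("tlc_ml", "haa_pct", adjustment_set), data = dat)
  w <- wald_ci(fit, "haa_pct")
  association_result(w$est, w$lo, w$hi, w$p, nrow(dat), adjustment_set,
                     scale = "ml_per_pct_haa")
}

#' Effect modification of the HAA-ILA association
#'
#' Fits the ILA logistic model separately within two strata (percent
#' emphysema split at 5%, or BMI split at 30) and tests effect modification
#' with the Wald p-value of the HAA-by-stratum interaction term in the
#' pooled model. The stratifying variable is removed from the per-stratum
#' adjustment set.
#'
#' @inheritParams fit_ila_logistic
#' @param stratifier `"emph_pct@5"` or `"bmi@30"`.
#' @return A list with `strata` (two `association_result`s, low stratum
#'   first) and `interaction_p`.
#' @export
stratified_effects <- function(cohort, stratifier = c("emph_pct@5", "bmi@30"),
                               adjustment_set = DEFAULT_ADJUSTMENT,
                               indeterminate_policy = c("exclude", "as_control")) {
  stratifier <- match.arg(stratifier)
  indeterminate_policy <- match.arg(indeterminate_policy)
  cohort <- validate_cohort(cohort)
  var <- if (stratifier == "emph_pct@5") "emph_pct" else "bmi"
  cut <- if (stratifier == "emph_pct@5") 5 else 30
  adj <- setdiff(adjustment_set, var)
  high <- cohort[[var]] >= cut
  labs <- sprintf("%s %s %g", var, c("<", ">="), cut)
  if (!any(high) || all(high))
    stop_named("empty stratum: no subjects with %s %s %g", var,
               if (!any(high)) ">=" else "<", cut)
  strata <- lapply(list(!high, high), function(sel) {
    fit_ila_logistic(cohort[sel, , drop = FALSE], adj, indeterminate_policy)
  })
  strata[[1]]$stratum_label <- labs[1]
  strata[[2]]$stratum_label <- labs[2]
  # pooled interaction model
  dat <- apply_indeterminate_policy(cohort, indeterminate_policy)
  dat$ila <- as.integer(as.character(dat$visual_status) == "ila")
  dat$stratum_high <- as.integer(dat[[var]] >= cut)
  f <- stats::as.formula(paste(
    c("ila ~ haa_pct * stratum_high", adj), collapse = " + "))
  fit <- glm(f, data = dat, family = binomial())
  check_separation(fit)
  ip <- wald_ci(fit, "haa_pct:stratum_high")$p
  list(strata = strata, interaction_p = ip, stratifier = stratifier)
}

#' Single-variant additive genetic association with HAA
#'
#' Tests a biallelic variant (genotype coded 0/1/2 copies of the risk
#' allele, entered as one numeric term — the additive genetic model)
#' against HAA% as a continuous outcome (linear model) or against a binary
#' HAA-threshold outcome (logistic model), adjusted for demographics and
#' smoking.
#'
#' @inheritParams fit_ila_logistic
#' @param outcome `"haa_continuous"` or `"haa_ge_threshold"`.
#' @param threshold_pct HAA threshold for the binary outcome.
#' @param adjustment_set character vector of covariate columns.
#' @return An `association_result`: a per-allele OR for the binary outcome,
#'   or a per-allele difference in HAA% for the continuous outcome.
#' @export
genotype_association <- function(cohort,
                                 outcome = c("haa_continuous",
                                             "haa_ge_threshold"),
                                 threshold_pct = 10,
                                 adjustment_set = GENETIC_ADJUSTMENT) {
  outcome <- match.arg(outcome)
  cohort <- validate_cohort(cohort)
  if (length(unique(cohort$genotype)) < 2L)
    stop_named("monomorphic genotype: no association can be estimated")
  if (outcome == "haa_continuous") {
    fit <- lm(build_formula("haa_pct", "genotype", adjustment_set),
              data = cohort)
    w <- wald_ci(fit, "genotype")
    association_result(w$est, w$lo, w$hi, w$p, nrow(cohort), adjustment_set,
                       scale = "haa_pct_per_allele")
  } else {
    cohort$haa_pos <- as.integer(cohort$haa_pct >= threshold_pct)
    if (length(unique(cohort$haa_pos)) < 2L)
      stop_named("all subjects fall on one side of the %g%% HAA threshold",
                 threshold_pct)
    fit <- glm(build_formula("haa_pos", "genotype", adjustment_set),
               data = cohort, family = binomial())
    check_separation(fit)
    w <- wald_ci(fit, "genotype")
    association_result(exp(w$est), exp(w$lo), exp(w$hi), w$p, nrow(cohort),
                       adjustment_set, scale = "odds_ratio_per_allele")
  }
}
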