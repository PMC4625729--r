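#' Classify scans as ILA-positive by an HAA threshold
#'
#' Positive means HAA% at or above the threshold; the boundary value is
#' positive (a ">= threshold" rule).
#'
#' @param haa_pct numeric vector of HAA percentages in \[0, 100\].
#' @param threshold_pct classification threshold in percent, in (0, 100).
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
classify_by_haa <- function(haa_pct, threshold_pct) {
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1L ||
      threshold_pct <= 0 || threshold_pct >= 100)
    stop_named("'threshold_pct' must lie strictly inside (0, 100)")
  if (any(haa_pct < 0 | haa_pct > 100, na.rm = TRUE))
    stop_named("haa_pct values must lie in [0, 100]")
  ifelse(haa_pct >= threshold_pct, "positive", "negative")
}

#' Sample percentile threshold
#'
#' Linear-interpolation sample percentile (the default type-7 quantile) of
#' the cohort HAA% distribution, used to derive data-driven classification
#' thresholds such as the upper 95th percentile.
#'
#' @param haa_values numeric vector (at least 20 values).
#' @param q percentile in (0, 100).
#' @return The threshold in percent HAA.
#' @export
percentile_threshold <- function(haa_values, q = 95) {
  haa_values <- haa_values[!is.na(haa_values)]
  if (length(haa_values) == 0L) stop_named("no HAA values supplied")
  if (length(haa_values) < 20L)
    stop_named("need at least 20 values for a stable percentile threshold")
  check_number(q, "q", 0, 100)
  unname(quantile(haa_values, q / 100, type = 7))
}

#' 2x2 contingency table of visual ILA vs HAA classification
#'
#' @param a visual-ILA and HAA-positive count.
#' @param b visual-ILA and HAA-negative count.
#' @param c no-ILA and HAA-positive count.
#' @param d no-ILA and HAA-negative count.
#' @param indeterminate_policy how indeterminate visual reads were handled
#'   when the table was built.
#' @param n_indeterminate_absorbed number of indeterminate subjects counted
#'   in the no-ILA row (policy `as_control`) or dropped (policy `exclude`).
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d,
                            indeterminate_policy = c("exclude", "as_control"),
                            n_indeterminate_absorbed = 0L) {
  indeterminate_policy <- match.arg(indeterminate_policy)
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_named("contingency counts must be non-negative integers")
  if (sum(counts) == 0) stop_named("contingency table total is zero")
  structure(list(a = a, b = b, c = c, d = d,
                 indeterminate_policy = indeterminate_policy,
                 n_indeterminate_absorbed = n_indeterminate_absorbed),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("visual ILA", "no ILA"),
                              c("HAA+", "HAA-")))
  print(m)
  cat(sprintf("indeterminate policy: %s (%d absorbed)\n",
              x$indeterminate_policy, x$n_indeterminate_absorbed))
  invisible(x)
}

#' Build a contingency table from a cohort
#'
#' Cross-classifies visual ILA status against the HAA threshold rule.
#' Indeterminate visual reads are either dropped (`exclude`) or counted in
#' the no-ILA row (`as_control`); with `as_control` the no-ILA row grows by
#' the number of indeterminates and the absorbed count is recorded.
#'
#' @param cohort a cohort data.frame (see [simulate_cohort()]).
#' @param threshold_pct HAA threshold in percent.
#' @param indeterminate_policy `"exclude"` or `"as_control"`.
#' @return A [contingency_2x2()].
#' @export
build_contingency <- function(cohort, threshold_pct,
                              indeterminate_policy = c("exclude", "as_control")) {
  indeterminate_policy <- match.arg(indeterminate_policy)
  cohort <- validate_cohort(cohort)
  vs <- as.character(cohort$visual_status)
  ind <- vs == "indeterminate"
  if (indeterminate_policy == "exclude") {
    keep <- !ind
    n_abs <- 0L
  } else {
    keep <- rep(TRUE, length(vs))
    vs[ind] <- "no_ila"
    n_abs <- sum(ind)
  }
  if (!any(keep)) stop_named("no subjects left after applying the policy")
  pos <- classify_by_haa(cohort$haa_pct[keep], threshold_pct) == "positive"
  ila <- vs[keep] == "ila"
  contingency_2x2(a = sum(ila & pos), b = sum(ila & !pos),
                  c = sum(!ila & pos), d = sum(!ila & !pos),
                  indeterminate_policy = indeterminate_policy,
                  n_indeterminate_absorbed = n_abs)
}

#' Cohen's kappa with an asymptotic p-value
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with expected
#' agreement p_e from the row and column marginals, and a two-sided p-value
#' from the asymptotic z-test of kappa = 0 using the large-sample null
#' variance (which depends only on the marginals).
#'
#' @param t a [contingency_2x2()].
#' @return A list with `kappa`, `p`, `z` and `n`.
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  n <- t$a + t$b + t$c + t$d
  po <- (t$a + t$d) / n
  p_row <- c(t$a + t$b, t$c + t$d) / n       # visual: ILA, no-ILA
  p_col <- c(t$a + t$c, t$b + t$d) / n       # HAA:    +, -
  pe <- sum(p_row * p_col)
  if (1 - pe < .Machine$double.eps)
    stop_named("kappa undefined: expected agreement is 1 (degenerate marginals)")
  kappa <- (po - pe) / (1 - pe)
  if (any(p_row == 0) || any(p_col == 0)) {
    z <- NA_real_; p <- NA_real_
  } else {
    var0 <- (pe + pe^2 - sum(p_row * p_col * (p_row + p_col))) /
      (n * (1 - pe)^2)
    z <- kappa / sqrt(var0)
    p <- 2 * pnorm(-abs(z))
  }
  list(kappa = kappa, p = p, z = z, n = n)
}

#' Diagnostic accuracy panel
#'
#' Sensitivity, specificity, positive and negative predictive value of the
#' HAA classification against the visual-assessment reference. A statistic
#' whose denominator is zero is reported as `NA`, never as 0.
#'
#' @param t a [contingency_2x2()].
#' @return A list with `sensitivity`, `specificity`, `ppv`, `npv` (fractions
#'   in \[0, 1\]) and the input counts.
#' @export
diagnostic_panel <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = frac(t$a, t$a + t$b),
       specificity = frac(t$d, t$c + t$d),
       ppv = frac(t$a, t$a + t$c),
       npv = frac(t$d, t$b + t$d),
       a = t$a, b = t$b, c = t$c, d = t$d)
}

#' Agreement summary at one threshold
#'
#' Convenience wrapper combining [cohen_kappa()] and [diagnostic_panel()].
#'
#' @inheritParams diagnostic_panel
#' @param threshold_pct threshold recorded in the output.
#' @return A one-row data.frame.
#' @export
agreement_stats <- function(t, threshold_pct = NA_real_) {
  k <- cohen_kappa(t)
  p <- diagnostic_panel(t)
  data.frame(threshold = threshold_pct, kappa = k$kappa, kappa_p = k$p,
             sensitivity = p$sensitivity, specificity = p$specificity,
             ppv = p$ppv, npv = p$npv,
             youden = p$sensitivity + p$specificity - 1,
             n = k$n)
}

#' Rank-based c-statistic (AUC)
#'
#' Probability that a randomly chosen visual-ILA case has higher HAA% than
#' a randomly chosen control, with ties counted one half — the c-statistic
#' of a single-predictor logistic model and the Mann-Whitney U divided by
#' n1*n0.
#'
#' @param haa_values numeric predictor values.
#' @param ila_labels logical (or 0/1) case indicator.
#' @return AUC in \[0, 1\].
#' @export
c_statistic <- function(haa_values, ila_labels) {
  ila_labels <- as.logical(ila_labels)
  stopifnot(length(haa_values) == length(ila_labels))
  n1 <- sum(ila_labels); n0 <- sum(!ila_labels)
  if (n1 == 0L || n0 == 0L)
    stop_named("c-statistic needs both cases and controls")
  r <- rank(haa_values)  # midranks handle ties as 1/2
  (sum(r[ila_labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sweep agreement statistics over a threshold grid
#'
#' Computes kappa, the diagnostic panel and Youden's J at each threshold of
#' `grid`, for a fixed indeterminate policy. With a ">= threshold" rule,
#' sensitivity is non-increasing and specificity non-decreasing along an
#' increasing grid. The row maximising Youden's J is flagged.
#'
#' @inheritParams build_contingency
#' @param grid numeric vector of thresholds in percent.
#' @return A data.frame, one row per threshold, with a logical `best`
#'   column (maximum Youden's J, ties to the lowest threshold).
#' @export
threshold_sweep <- function(cohort, grid,
                            indeterminate_policy = c("exclude", "as_control")) {
  indeterminate_policy <- match.arg(indeterminate_policy)
  if (length(grid) == 0L) stop_named("threshold grid is empty")
  rows <- lapply(sort(grid), function(th) {
    t <- build_contingency(cohort, th, indeterminate_policy)
    agreement_stats(t, th)
  })
  out <- do.call(rbind, rows)
  out$best <- FALSE
  out$best[which.max(out$youden)] <- TRUE
  rownames(out) <- NULL
  out
}
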