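#' Cohort simulation specification
#'
#' Parameters of the synthetic subject cohort. The marginal HAA%
#' distribution is a shifted log-normal (right-skewed, with a floor
#' reflecting the minimum parenchymal density seen in practice), calibrated
#' so the cohort median falls in the 3-4% range typical of population
#' samples. Visual ILA status is drawn from a three-level multinomial-logit
#' model with baseline "no ILA": the log-odds of definite ILA versus no ILA
#' is linear in HAA% with slope `log(or_per_pct_haa)` plus small covariate
#' terms, and the log-odds of indeterminate status versus no ILA has a
#' deliberately shallower HAA slope, so that counting indeterminates as
#' controls attenuates the fitted HAA-ILA odds ratio while excluding them
#' recovers `or_per_pct_haa` exactly. CT-derived total lung capacity follows
#' a linear model in HAA% with Gaussian error. Genotype is a biallelic
#' variant drawn under Hardy-Weinberg equilibrium; `genotype_haa_beta` is an
#' additive per-allele shift on log-scale HAA (0 = genotype independent of
#' HAA, the null structure).
#'
#' @param n_subjects number of subjects.
#' @param haa_meanlog,haa_sdlog,haa_shift parameters of the shifted
#'   log-normal HAA% distribution: `haa_shift + rlnorm(meanlog, sdlog)`.
#' @param or_per_pct_haa true odds ratio of visual ILA per 1% HAA.
#' @param ila_intercept intercept of the ILA-vs-none logit at HAA = 0.
#' @param or_indeterminate_per_pct HAA odds ratio of the indeterminate-vs-
#'   none logit (shallower than `or_per_pct_haa`).
#' @param indeterminate_intercept intercept of the indeterminate-vs-none
#'   logit.
#' @param tlc_intercept_ml baseline TLC in ml (female, at covariate means).
#' @param tlc_slope_ml_per_pct true TLC change in ml per 1% HAA.
#' @param tlc_noise_sd residual SD of TLC in ml.
#' @param emph_strata_or optional length-2 vector: HAA odds ratios for the
#'   emphysema strata (< 5%, >= 5%), replacing `or_per_pct_haa`.
#' @param bmi_strata_or optional length-2 vector: HAA odds ratios for the
#'   BMI strata (< 30, >= 30).
#' @param risk_allele_freq allele frequency of the risk allele, in (0, 1).
#' @param genotype_haa_beta per-allele additive effect on log(HAA - shift).
#' @param seed RNG seed.
#' @return A validated list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_subjects = 2093,
                            haa_meanlog = log(1.6),
                            haa_sdlog = 0.6,
                            haa_shift = 2.0,
                            or_per_pct_haa = 2.3,
                            ila_intercept = -5.6,
                            or_indeterminate_per_pct = 1.35,
                            indeterminate_intercept = -1.49,
                            tlc_intercept_ml = 5800,
                            tlc_slope_ml_per_pct = -351,
                            tlc_noise_sd = 600,
                            emph_strata_or = NULL,
                            bmi_strata_or = NULL,
                            risk_allele_freq = 0.11,
                            genotype_haa_beta = 0,
                            seed = 1L) {
  check_number(n_subjects, "n_subjects", 1, Inf)
  check_number(or_per_pct_haa, "or_per_pct_haa", .Machine$double.eps, Inf)
  check_number(or_indeterminate_per_pct, "or_indeterminate_per_pct",
               .Machine$double.eps, Inf)
  check_number(risk_allele_freq, "risk_allele_freq", 1e-9, 1 - 1e-9)
  check_number(haa_sdlog, "haa_sdlog", 0, Inf)
  check_number(tlc_noise_sd, "tlc_noise_sd", 0, Inf)
  for (s in list(emph_strata_or, bmi_strata_or))
    if (!is.null(s) && (length(s) != 2L || any(s <= 0)))
      stop_named("strata odds ratios must be two positive values")
  if (!is.null(emph_strata_or) && !is.null(bmi_strata_or))
    stop_named("specify at most one effect-modification stratifier")
  structure(list(
    n_subjects = as.integer(n_subjects),
    haa_meanlog = haa_meanlog, haa_sdlog = haa_sdlog, haa_shift = haa_shift,
    or_per_pct_haa = or_per_pct_haa, ila_intercept = ila_intercept,
    or_indeterminate_per_pct = or_indeterminate_per_pct,
    indeterminate_intercept = indeterminate_intercept,
    tlc_intercept_ml = tlc_intercept_ml,
    tlc_slope_ml_per_pct = tlc_slope_ml_per_pct,
    tlc_noise_sd = tlc_noise_sd,
    emph_strata_or = emph_strata_or, bmi_strata_or = bmi_strata_or,
    risk_allele_freq = risk_allele_freq,
    genotype_haa_beta = genotype_haa_beta,
    seed = seed
  ), class = "cohort_sim_spec")
}

VISUAL_LEVELS <- c("no_ila", "indeterminate", "ila")
COHORT_COLUMNS <- c("subject_id", "haa_pct", "emph_pct", "tlc_ml",
                    "visual_status", "age", "sex", "race", "bmi",
                    "pack_years", "current_smoker", "genotype")

# Covariate coefficients entering the ILA-vs-none logit and the TLC model.
# Small by design: the headline HAA effects dominate, covariates exist so
# that adjusted fits are exercised.
ILA_COV_BETA <- c(age = 0.02, male = 0.25, smoker = 0.20, bmi = 0.03,
                  emph = 0.04)
TLC_COV_BETA <- c(age = -28, male = 1200, bmi = -20)

#' Simulate a synthetic cohort
#'
#' Draws covariates, genotype, HAA%, emphysema%, three-level visual ILA
#' status and TLC for `n_subjects` subjects under the generative model
#' described in [cohort_sim_spec()]. Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return A `data.frame` with columns `subject_id`, `haa_pct`, `emph_pct`,
#'   `tlc_ml`, `visual_status` (factor: no_ila / indeterminate / ila),
#'   `age`, `sex`, `race`, `bmi`, `pack_years`, `current_smoker`,
#'   `genotype` (0/1/2 copies of the risk allele).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  n <- spec$n_subjects
  with_seed(spec$seed, {
    age <- pmin(pmax(rnorm(n, 62, 8), 45), 90)
    sex <- ifelse(runif(n) < 0.5, "male", "female")
    race <- ifelse(runif(n) < 0.75, "white", "nonwhite")
    bmi <- pmin(pmax(rnorm(n, 28.5, 5.5), 15), 55)
    pack_years <- rgamma(n, shape = 1.2, scale = 25)
    current_smoker <- rbinom(n, 1, 0.45)
    emph_pct <- pmin(rlnorm(n, log(1.5), 0.9), 60)
    genotype <- rbinom(n, 2, spec$risk_allele_freq)

    haa_pct <- spec$haa_shift +
      rlnorm(n, spec$haa_meanlog + spec$genotype_haa_beta * genotype,
             spec$haa_sdlog)
    haa_pct <- pmin(haa_pct, 80)

    slope <- rep(log(spec$or_per_pct_haa), n)
    if (!is.null(spec$emph_strata_or))
      slope <- ifelse(emph_pct < 5, log(spec$emph_strata_or[1]),
                      log(spec$emph_strata_or[2]))
    if (!is.null(spec$bmi_strata_or))
      slope <- ifelse(bmi < 30, log(spec$bmi_strata_or[1]),
                      log(spec$bmi_strata_or[2]))

    cov_lp <- ILA_COV_BETA["age"] * (age - 62) +
      ILA_COV_BETA["male"] * (sex == "male") +
      ILA_COV_BETA["smoker"] * current_smoker +
      ILA_COV_BETA["bmi"] * (bmi - 28.5) +
      ILA_COV_BETA["emph"] * (emph_pct - 1.5)
    eta_ila <- spec$ila_intercept + slope * haa_pct + cov_lp
    eta_ind <- spec$indeterminate_intercept +
      log(spec$or_indeterminate_per_pct) * haa_pct
    e1 <- exp(pmin(eta_ila, 30)); e2 <- exp(pmin(eta_ind, 30))
    p_ila <- e1 / (1 + e1 + e2)
    p_ind <- e2 / (1 + e1 + e2)
    if (mean(p_ila) > 0.95 || mean(p_ila) < 1e-4)
      warning("degenerate specification: P(ILA) is systematically near 0 or 1",
              call. = FALSE)
    u <- runif(n)
    visual_status <- ifelse(u < p_ila, "ila",
                            ifelse(u < p_ila + p_ind, "indeterminate",
                                   "no_ila"))

    tlc_ml <- spec$tlc_intercept_ml +
      spec$tlc_slope_ml_per_pct * haa_pct +
      TLC_COV_BETA["age"] * (age - 62) +
      TLC_COV_BETA["male"] * (sex == "male") +
      TLC_COV_BETA["bmi"] * (bmi - 28.5) +
      rnorm(n, 0, spec$tlc_noise_sd)
    tlc_ml <- pmax(tlc_ml, 100)

    data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      haa_pct = haa_pct, emph_pct = emph_pct, tlc_ml = unname(tlc_ml),
      visual_status = factor(visual_status, levels = VISUAL_LEVELS),
      age = age, sex = sex, race = race, bmi = bmi,
      pack_years = pack_years, current_smoker = current_smoker,
      genotype = genotype,
      stringsAsFactors = FALSE
    )
  })
}

#' Validate a cohort table
#'
#' Checks that all required columns are present with admissible values.
#' Called by every consumer of cohort tables; useful directly after editing
#' or importing external data.
#'
#' @param table a data.frame.
#' @return The table, invisibly, with `visual_status` coerced to the
#'   canonical factor levels.
#' @export
validate_cohort <- function(table) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(table))
  if (length(missing_cols))
    stop_named("cohort table is missing required column(s): %s",
               paste(missing_cols, collapse = ", "))
  vs <- as.character(table$visual_status)
  bad <- setdiff(unique(vs), VISUAL_LEVELS)
  if (length(bad))
    stop_named("unknown visual_status level(s): %s (expected %s)",
               paste(bad, collapse = ", "), paste(VISUAL_LEVELS, collapse = ", "))
  if (any(table$haa_pct < 0 | table$haa_pct > 100, na.rm = TRUE))
    stop_named("haa_pct must lie in [0, 100]")
  if (any(!table$genotype %in% c(0L, 1L, 2L)))
    stop_named("genotype must be coded 0/1/2")
  table$visual_status <- factor(vs, levels = VISUAL_LEVELS)
  invisible(table)
}

#' Read and write cohort tables as CSV
#'
#' Plain-text CSV with a header row; categorical levels are stored as fixed
#' strings, so a write/read round trip is lossless for all fields.
#'
#' @param table a cohort data.frame (see [simulate_cohort()]).
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the validated data.frame.
#' @export
write_cohort <- function(table, path) {
  validate_cohort(table)
  out <- table
  out$visual_status <- as.character(out$visual_status)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_named("no such file: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(tab)
  tab$visual_status <- factor(tab$visual_status, levels = VISUAL_LEVELS)
  tab
}
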