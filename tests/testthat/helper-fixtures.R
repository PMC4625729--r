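# Build a minimal valid cohort table from the columns a test cares about;
# everything else gets inert defaults.
toy_cohort <- function(haa_pct, visual_status,
                       tlc_ml = 6000 - 300 * haa_pct,
                       emph_pct = 1, bmi = 27, age = 60, sex = "female",
                       race = "white", pack_years = 10, current_smoker = 0L,
                       genotype = 0L) {
  n <- length(haa_pct)
  data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    haa_pct = haa_pct,
    emph_pct = rep_len(emph_pct, n),
    tlc_ml = rep_len(tlc_ml, n),
    visual_status = factor(rep_len(visual_status, n),
                           levels = c("no_ila", "indeterminate", "ila")),
    age = rep_len(age, n), sex = rep_len(sex, n), race = rep_len(race, n),
    bmi = rep_len(bmi, n), pack_years = rep_len(pack_years, n),
    current_smoker = rep_len(current_smoker, n),
    genotype = rep_len(genotype, n),
    stringsAsFactors = FALSE
  )
}

# Small phantom for unit tests; acceptance tests use the full 128^3 default.
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(48, 48, 48), voxel_spacing = c(2, 2, 2), ...)
}

# A uniform-HU "lung" volume plus an all-true mask, for window arithmetic.
uniform_lung <- function(hu, n = 8) {
  vol <- ct_volume(array(hu, dim = c(n, n, n)), c(1, 1, 1))
  list(vol = vol, mask = array(TRUE, dim = c(n, n, n)))
}

# Printed 2x2 comparison tables of visual ILA vs HAA thresholds used as the
# exact agreement reference surface (counts: a = ILA & HAA+, b = ILA & HAA-,
# c = no-ILA & HAA+, d = no-ILA & HAA-).
reference_tables <- function() {
  list(
    copdgene_10   = list(a = 5,  b = 158, c = 21,  d = 1909,
                         kappa = 0.03, sens = 3,  spec = 99, ppv = 19, npv = 92),
    copdgene_6.44 = list(a = 24, b = 139, c = 80,  d = 1850,
                         kappa = 0.13, sens = 15, spec = 96, ppv = 23, npv = 93),
    fhs_10        = list(a = 46, b = 104, c = 306, d = 1987,
                         kappa = 0.11, sens = 31, spec = 87, ppv = 13, npv = 95),
    fhs_6.44      = list(a = 18, b = 132, c = 105, d = 2188,
                         kappa = 0.08, sens = 12, spec = 95, ppv = 15, npv = 94)
  )
}
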