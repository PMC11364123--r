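# Shared simulated cohorts, built once per test run. The full-scale cohort
# mirrors the study bookkeeping (404 plans on two linacs); the analysis
# grid is 5 mm to keep the simulation tractable (the methods vignette
# discusses the problem sizes).

.cohort_cache <- new.env(parent = emptyenv())

coarse_dose_cfg <- function() list(spacing_mm = 5, half_extent_mm = 115,
                                   penumbra_sigma_mm = 3,
                                   depth_mu_per_mm = 0.004)

full_cohort <- function() {
  if (is.null(.cohort_cache$full)) {
    cfg <- cohort_config(dose = coarse_dose_cfg())
    .cohort_cache$full <- simulate_study(cfg)
  }
  .cohort_cache$full
}

tiny_cohort <- function() {
  if (is.null(.cohort_cache$tiny)) {
    cfg <- cohort_config(
      n_per_site_linac1 = c(head_and_neck = 4, chest_and_abdomen = 3,
                            pelvis = 4, limbs = 2),
      n_per_site_linac2 = c(head_and_neck = 4, chest_and_abdomen = 3,
                            pelvis = 4, limbs = 1),
      seed = 77, dose = coarse_dose_cfg())
    .cohort_cache$tiny <- simulate_study(cfg)
  }
  .cohort_cache$tiny
}
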