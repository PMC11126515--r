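# Small phantom fixtures: 24 x 32 x 32 voxels at 6 mm keeps every phantom
# build under ~50 ms while leaving room for multi-thousand-voxel defects.

tiny_phantom_params <- function(defect_spec = list(), noise_sd = 0,
                                seed = 1L, ...) {
  phantom_params(grid_shape = c(24L, 32L, 32L), spacing_mm = c(6, 6, 6),
                 defect_spec = defect_spec, noise_sd = noise_sd,
                 seed = seed, ...)
}

tiny_wedge <- function(which = 1L) {
  extent <- c(24, 32, 32) * 6
  specs <- list(
    list(apex = c(0.5, 0.45, 0.35), axis = c(0, 0.5, -0.85),
         angle = 70, len = 80),
    list(apex = c(0.55, 0.45, 0.65), axis = c(0, 0.5, 0.85),
         angle = 70, len = 80),
    list(apex = c(0.4, 0.4, 0.6), axis = c(-0.3, 0.6, 0.75),
         angle = 50, len = 70)
  )
  s <- specs[[which]]
  wedge_defect(s$apex * extent, s$axis, s$angle, s$len)
}

# Random phantom parameters for property tests: 1-3 random wedges, random
# residual perfusion, detectability not enforced (properties must hold on
# any input, not only detectable ones).
random_phantom_params <- function(seed, noise_sd = 0.1) {
  set.seed(seed)
  extent <- c(24, 32, 32) * 6
  n_def <- sample(0:3, 1)
  spec <- lapply(seq_len(n_def), function(i) {
    wedge_defect(runif(3, 0.3, 0.7) * extent,
                 rnorm(3), runif(1, 30, 80), runif(1, 40, 100))
  })
  tiny_phantom_params(defect_spec = spec, noise_sd = noise_sd,
                      seed = seed + 1L,
                      defect_multiplier = runif(1, 0.05, 0.3),
                      collateral_fraction = runif(1, 0, 0.1),
                      detectable = FALSE)
}

# A small, fully deterministic cohort table for I/O tests.
toy_cohort <- function() {
  data.frame(
    id = c("A001", "A002", "C001", "K001"),
    group = c("APE", "APE", "CTEPH", "CONTROL"),
    subtype = c(NA, NA, "pCTEPH", NA),
    mpa_dia = c(29.1, 27.3, 35.2, 25.9),
    bronchial_dia = c(1.55, NA, 2.71, NA),
    malp_id_mean_la = c(0.021, 0.033, 0.047, 0.05),
    stringsAsFactors = FALSE
  )
}
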