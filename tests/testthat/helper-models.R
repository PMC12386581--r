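# Shared fixtures: reference models and small constructors used across tests.

mag0_model <- function() reference_model("mag_0kGy")
hon0_model <- function() reference_model("hon_0kGy")

single_motion_model <- function(tau0 = 2.12e-14, ea = 19.55, dm2 = 0.110,
                                frequency_mhz = 25) {
  relaxation_model(list(motion(tau0, ea, dm2)),
                   spectrometer_config(frequency_mhz))
}

# Noiseless series from a model on the default grid.
noiseless_series <- function(model, n_temps = 30, t_min = 80, t_max = 300) {
  simulate_t1_series(model, t_min, t_max, n_temps, noise_cv = 0, seed = 1)
}

.par_from_model_test <- function(f)
  unlist(lapply(f$model$motions, function(m) c(m$tau0, m$ea, m$dm2)))

# Matched Ea estimate for a given reference motion index.
matched_ea <- function(fit, reference, ref_idx) {
  mm <- match_motions(fit$model, reference)
  est <- mm$pairs$est[mm$pairs$ref == ref_idx]
  fit$model$motions[[est]]$ea
}
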