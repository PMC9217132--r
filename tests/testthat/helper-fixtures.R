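# shared fixtures: analysis grid, a time-domain-stable parameter set, and
# reduced-size cohort configurations used across test files

analysis_grid <- function(step = 0.5) freq_grid(seq(1, 35, by = step))

# an in-bounds parameter set whose poles all lie in the left half-plane,
# so the stochastic simulation is stationary (max Re(pole) ~ -1.2 /s)
stable_params <- function() {
  nmm_params(tau_e_ms = 11, tau_i_ms = 10, g_ee = 1.29, g_ii = 1.46)
}

# rejection-sample parameter sets inside the fitting bounds whose
# time-domain realization is stationary and mixes within a 600 s run
draw_stable_params <- function(n, seed, max_re = -0.5) {
  set.seed(seed)
  out <- vector("list", n)
  found <- 0L
  while (found < n) {
    p <- nmm_params(tau_e_ms = runif(1, 5, 30), tau_i_ms = runif(1, 5, 30),
                    g_ee = runif(1, 0.1, 10), g_ii = runif(1, 0.1, 10))
    if (nmm_stability(p)$max_re <= max_re) {
      found <- found + 1L
      out[[found]] <- p
    }
  }
  out
}

# small synthetic cohort for statistics tests: defaults everywhere except
# size, ROI count, and spectral grid
small_cohort_config <- function(n_controls = 12, n_patients = 10,
                                n_rois = 10, grid_step = 1, seed = 1L, ...) {
  cohort_config(n_controls = n_controls, n_patients = n_patients,
                rois = dk68_rois()[seq_len(n_rois)],
                grid = freq_grid(seq(1, 35, by = grid_step)),
                seed = seed, ...)
}

# model spectrum as a regional_spectrum, optionally with additive dB noise
model_spectrum_fixture <- function(params, grid = analysis_grid(),
                                   noise_db = 0, seed = NULL,
                                   subject_id = "S1", roi = "lh_bankssts") {
  s <- model_psd_db(params, grid)
  db <- s$psd_db
  if (noise_db > 0) {
    if (!is.null(seed)) set.seed(seed)
    db <- db + rnorm(length(db), sd = noise_db)
  }
  regional_spectrum(grid, db, subject_id = subject_id, roi = roi)
}
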