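#' Desikan-Killiany cortical ROI labels
#'
#' The 68 cortical region labels of the Desikan-Killiany parcellation
#' (34 per hemisphere, `lh_`/`rh_` prefixed), the regional unit of every
#' analysis in this package.
#'
#' @return Character vector of length 68.
#' @export
dk68_rois <- function() {
  path <- system.file("extdata", "dk68_rois.txt", package = "nmmspectra")
  readLines(path)[-1L]                  # drop the comment header
}

#' Synthetic cohort configuration
#'
#' Defines the generating conditions for a complete synthetic study
#' dataset: per-group regional model parameters, spectra, and PET tracer
#' uptake (SUVR) maps with known couplings to the model parameters.
#'
#' Defaults emulate the study conditions of a resting-state MEG cohort:
#' 35 controls and 20 patients over the 68 Desikan-Killiany ROIs; control
#' parameter means near the reported control-group least-squares means
#' (tau_e 11.8 ms, tau_i 15.4 ms, g_ee 1.7, g_ii 3.7); patient shifts of
#' +4 ms (tau_e), +1 ms (tau_i), +0.3 (g_ee), -0.4 (g_ii); tau SUVR
#' coupled only to the excitatory time-constant and amyloid-beta SUVR
#' only to the inhibitory time-constant; and 1 dB additive spectral noise.
#' SUVR base levels default to the reported cohort averages (tau 1.64,
#' amyloid-beta 1.99).
#'
#' @param n_controls,n_patients Group sizes (>= 2).
#' @param rois Character vector of ROI labels (default [dk68_rois()]).
#' @param control_means,control_sds Named numerics over `tau_e_ms`,
#'   `tau_i_ms`, `g_ee`, `g_ii`: control-group generating means and
#'   between-observation SDs.
#' @param patient_shift Named numeric of additive patient-group mean
#'   shifts for the same four parameters.
#' @param beta_tau_taue Slope of tau SUVR per control-referenced z of
#'   tau_e. @param beta_ab_taui Slope of amyloid-beta SUVR per z of tau_i.
#' @param beta_tau_taui,beta_ab_taue Cross-coupling slopes (default 0,
#'   giving the dissociated ground truth).
#' @param suvr_base Named numeric `c(tau = ..., ab = ...)` of SUVR base
#'   levels. @param suvr_noise_sd Named numeric of SUVR noise SDs.
#' @param spectral_noise_db SD of the additive dB noise on every spectrum
#'   bin.
#' @param roi_effect_sd Optional SD (as a fraction of each parameter's
#'   `control_sds`) of smooth ROI-level random offsets shared by all
#'   subjects; 0 disables spatial structure.
#' @param grid Frequency grid of the generated spectra.
#' @param bounds_lower,bounds_upper Truncation bounds for the generated
#'   parameters (default the fitting bounds).
#' @param g_ei,noise_mode Forward-model settings, see [model_psd_db()].
#' @param seed Integer seed; generation is bit-identical given the
#'   config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 35, n_patients = 20,
                          rois = dk68_rois(),
                          control_means = c(tau_e_ms = 11.8, tau_i_ms = 15.4,
                                            g_ee = 1.7, g_ii = 3.7),
                          control_sds = c(tau_e_ms = 1.5, tau_i_ms = 1.5,
                                          g_ee = 0.35, g_ii = 0.5),
                          patient_shift = c(tau_e_ms = 4, tau_i_ms = 1,
                                            g_ee = 0.3, g_ii = -0.4),
                          beta_tau_taue = 0.2, beta_ab_taui = 0.2,
                          beta_tau_taui = 0, beta_ab_taue = 0,
                          suvr_base = c(tau = 1.64, ab = 1.99),
                          suvr_noise_sd = c(tau = 0.25, ab = 0.25),
                          spectral_noise_db = 1,
                          roi_effect_sd = 0,
                          grid = freq_grid(),
                          bounds_lower = c(tau_e_ms = 5, tau_i_ms = 5,
                                           g_ee = 0.1, g_ii = 0.1),
                          bounds_upper = c(tau_e_ms = 30, tau_i_ms = 30,
                                           g_ee = 10, g_ii = 10),
                          g_ei = 1,
                          noise_mode = c("common", "independent"),
                          seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  par_names <- c("tau_e_ms", "tau_i_ms", "g_ee", "g_ii")
  control_means <- control_means[par_names]
  control_sds <- control_sds[par_names]
  patient_shift <- patient_shift[par_names]
  bounds_lower <- bounds_lower[par_names]
  bounds_upper <- bounds_upper[par_names]
  if (n_controls < 2 || n_patients < 2)
    stop("group sizes must be >= 2", call. = FALSE)
  if (any(is.na(control_means)) || any(is.na(control_sds)) ||
      any(is.na(patient_shift)))
    stop("parameter means/SDs/shifts must name all four parameters",
         call. = FALSE)
  if (any(control_sds <= 0) || any(suvr_noise_sd <= 0) ||
      spectral_noise_db <= 0)
    stop("all SDs must be positive", call. = FALSE)
  for (grp in list(control = control_means,
                   patient = control_means + patient_shift)) {
    low_gap <- bounds_lower - grp
    high_gap <- grp - bounds_upper
    if (any(low_gap > 3 * control_sds) || any(high_gap > 3 * control_sds))
      stop("infeasible truncation: a group mean lies outside the bounds by more than 3 SD",
           call. = FALSE)
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 rois = as.character(rois),
                 control_means = control_means, control_sds = control_sds,
                 patient_shift = patient_shift,
                 beta_tau_taue = beta_tau_taue, beta_ab_taui = beta_ab_taui,
                 beta_tau_taui = beta_tau_taui, beta_ab_taue = beta_ab_taue,
                 suvr_base = suvr_base, suvr_noise_sd = suvr_noise_sd,
                 spectral_noise_db = spectral_noise_db,
                 roi_effect_sd = roi_effect_sd,
                 grid = as.numeric(grid),
                 bounds_lower = bounds_lower, bounds_upper = bounds_upper,
                 g_ei = g_ei, noise_mode = noise_mode,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic study cohort
#'
#' Draws per-subject, per-ROI model parameters (Gaussian around group
#' means, truncated to the fitting bounds), builds their model spectra
#' with additive dB noise, and builds SUVR maps linearly coupled to
#' control-referenced parameter z-scores:
#' `tau_suvr = base + beta_tau_taue * z(tau_e) + noise` and
#' `ab_suvr = base + beta_ab_taui * z(tau_i) + noise` (plus any
#' configured cross-couplings). z-scores are taken against the control
#' draws per ROI. Generation is deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements
#'   `true_params` (data.frame: subject_id, group, roi, four parameters,
#'   and their control-referenced z columns), `spectra` (list of
#'   [regional_spectrum()]), `suvr` (data.frame: subject_id, group, roi,
#'   tau_suvr, ab_suvr), and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  par_names <- c("tau_e_ms", "tau_i_ms", "g_ee", "g_ii")
  subjects <- c(sprintf("C%03d", seq_len(config$n_controls)),
                sprintf("P%03d", seq_len(config$n_patients)))
  groups <- rep(c("control", "patient"),
                c(config$n_controls, config$n_patients))
  n_roi <- length(config$rois)
  n_sub <- length(subjects)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  roi_eff <- matrix(0, n_roi, 4, dimnames = list(config$rois, par_names))
  if (config$roi_effect_sd > 0) {
    raw <- matrix(stats::rnorm(n_roi * 4), n_roi, 4)
    # smooth along the ROI ordering (neighbouring labels share hemisphere
    # and lobe under the packaged ordering)
    sm <- apply(raw, 2, function(x) stats::filter(x, rep(1 / 3, 3),
                                                  circular = TRUE))
    sm <- scale(sm)
    roi_eff <- sweep(sm, 2, config$roi_effect_sd * config$control_sds, `*`)
    dimnames(roi_eff) <- list(config$rois, par_names)
  }

  tab <- expand.grid(roi = config$rois, subject_id = subjects,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- tab[, c("subject_id", "roi")]
  tab$group <- groups[match(tab$subject_id, subjects)]
  n_obs <- nrow(tab)
  for (p in par_names) {
    mu <- config$control_means[[p]] + roi_eff[tab$roi, p] +
      ifelse(tab$group == "patient", config$patient_shift[[p]], 0)
    x <- mu + stats::rnorm(n_obs, sd = config$control_sds[[p]])
    tab[[p]] <- pmin(pmax(x, config$bounds_lower[[p]]),
                     config$bounds_upper[[p]])
  }

  # control-referenced z per ROI
  for (p in par_names) {
    zc <- paste0(sub("_ms$", "", p), "_z")
    ctrl <- tab[tab$group == "control", ]
    m <- tapply(ctrl[[p]], ctrl$roi, mean)
    s <- tapply(ctrl[[p]], ctrl$roi, stats::sd)
    tab[[zc]] <- as.numeric((tab[[p]] - m[tab$roi]) / s[tab$roi])
  }

  suvr <- tab[, c("subject_id", "group", "roi")]
  suvr$tau_suvr <- as.numeric(config$suvr_base[["tau"]] +
    config$beta_tau_taue * tab$tau_e_z +
    config$beta_tau_taui * tab$tau_i_z +
    stats::rnorm(n_obs, sd = config$suvr_noise_sd[["tau"]]))
  suvr$ab_suvr <- as.numeric(config$suvr_base[["ab"]] +
    config$beta_ab_taui * tab$tau_i_z +
    config$beta_ab_taue * tab$tau_e_z +
    stats::rnorm(n_obs, sd = config$suvr_noise_sd[["ab"]]))

  grid <- config$grid
  nbin <- length(grid)
  w <- 2 * pi * grid
  spectra <- vector("list", n_obs)
  for (i in seq_len(n_obs)) {
    db <- .model_db_theta(c(tab$tau_e_ms[i], tab$tau_i_ms[i],
                            tab$g_ee[i], tab$g_ii[i]),
                          w, config$g_ei, config$noise_mode == "common")
    spectra[[i]] <- regional_spectrum(
      grid, db + stats::rnorm(nbin, sd = config$spectral_noise_db),
      subject_id = tab$subject_id[i], roi = tab$roi[i])
  }

  tab <- tab[, c("subject_id", "group", "roi", par_names,
                 "tau_e_z", "tau_i_z", "g_ee_z", "g_ii_z")]
  rownames(tab) <- rownames(suvr) <- NULL
  structure(list(true_params = tab, spectra = spectra, suvr = suvr,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d controls, %d patients, %d ROIs, %d spectra\n",
              x$config$n_controls, x$config$n_patients,
              length(x$config$rois), length(x$spectra)))
  invisible(x)
}

#' Cohort-wide SUVR means
#'
#' Mean tau and amyloid-beta SUVR across all subject-by-ROI records, used
#' as the covariate-fixing points when reporting predicted association
#' fits (each predictor's fit is shown with the other protein held at its
#' cohort average).
#'
#' @param cohort A `synthetic_cohort`, or any data.frame with `tau_suvr`
#'   and `ab_suvr` columns.
#' @return Named numeric `c(tau_suvr = ..., ab_suvr = ...)`.
#' @export
suvr_summary <- function(cohort) {
  suvr <- if (inherits(cohort, "synthetic_cohort")) cohort$suvr else cohort
  if (!is.data.frame(suvr) || nrow(suvr) == 0)
    stop("empty cohort", call. = FALSE)
  c(tau_suvr = mean(suvr$tau_suvr), ab_suvr = mean(suvr$ab_suvr))
}
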