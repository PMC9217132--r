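#' Fit configuration for regional parameter estimation
#'
#' Bundles the optimizer protocol used to estimate the four free model
#' parameters per region: initial values, box bounds, and basin-hopping
#' hyperparameters. Defaults follow the standard protocol: time-constants
#' start at 17 ms within bounds of 5-30 ms, gains start at 0.5 within 0.1-10;
#' basin hopping runs 2000 iterations at temperature 0.1 with step size 4,
#' retrying at step size 6 when an estimate lands on a bound.
#'
#' @param init Named numeric of starting values: `tau_e_ms`, `tau_i_ms`,
#'   `g_ee`, `g_ii`.
#' @param lower,upper Named numerics of box bounds for the same four
#'   parameters.
#' @param n_iterations Number of basin-hopping iterations.
#' @param temperature Metropolis acceptance temperature on the cost scale.
#' @param step_size Half-width of the uniform random displacement applied
#'   to every coordinate between local minimizations.
#' @param retry_step_size Step size used for the rerun triggered by a
#'   bound-hitting estimate.
#' @param bound_tolerance An estimate within `bound_tolerance * (upper -
#'   lower)` of either bound counts as "hitting" it and triggers the retry.
#' @param seed Integer seed making the stochastic search reproducible.
#' @param g_ei Fixed cross-population gain (not optimized).
#' @param noise_mode Forward-model noise wiring, see [model_psd_db()].
#' @param maxit_local Iteration cap for each bounded quasi-Newton (L-BFGS-B)
#'   local minimization inside basin hopping.
#' @param factr_local L-BFGS-B convergence tolerance factor (`factr`); the
#'   default `1e7` resolves the cost to ~2e-9. Larger values (e.g. `1e10`)
#'   trade per-fit polish for speed, useful for large simulated cohorts.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(init = c(tau_e_ms = 17, tau_i_ms = 17,
                                g_ee = 0.5, g_ii = 0.5),
                       lower = c(tau_e_ms = 5, tau_i_ms = 5,
                                 g_ee = 0.1, g_ii = 0.1),
                       upper = c(tau_e_ms = 30, tau_i_ms = 30,
                                 g_ee = 10, g_ii = 10),
                       n_iterations = 2000, temperature = 0.1,
                       step_size = 4, retry_step_size = 6,
                       bound_tolerance = 1e-3, seed = 1L, g_ei = 1,
                       noise_mode = c("common", "independent"),
                       maxit_local = 100L, factr_local = 1e7) {
  noise_mode <- match.arg(noise_mode)
  par_names <- c("tau_e_ms", "tau_i_ms", "g_ee", "g_ii")
  init <- init[par_names]; lower <- lower[par_names]; upper <- upper[par_names]
  if (any(is.na(init)) || any(is.na(lower)) || any(is.na(upper)))
    stop("'init', 'lower', 'upper' must each name tau_e_ms, tau_i_ms, g_ee, g_ii",
         call. = FALSE)
  if (any(lower >= upper) || any(init <= lower) || any(init >= upper))
    stop("bounds must satisfy lower < init < upper for every parameter",
         call. = FALSE)
  hyper <- c(n_iterations = n_iterations, temperature = temperature,
             step_size = step_size, retry_step_size = retry_step_size,
             bound_tolerance = bound_tolerance, maxit_local = maxit_local,
             factr_local = factr_local)
  if (any(hyper <= 0)) stop("all hyperparameters must be positive",
                            call. = FALSE)
  structure(list(init = init, lower = lower, upper = upper,
                 n_iterations = as.integer(n_iterations),
                 temperature = temperature, step_size = step_size,
                 retry_step_size = retry_step_size,
                 bound_tolerance = bound_tolerance,
                 seed = as.integer(seed), g_ei = g_ei,
                 noise_mode = noise_mode,
                 maxit_local = as.integer(maxit_local),
                 factr_local = factr_local),
            class = "fit_config")
}

#' Pearson-correlation cost between dB spectra
#'
#' The optimization cost: the negative Pearson correlation coefficient
#' between an empirical and a model spectrum, both on the dB scale, over
#' the analysis bins. Identical vectors give -1, and the cost is invariant
#' to additive dB offsets (equivalently, multiplicative rescaling of
#' linear power), which is why the noise amplitude is held fixed during
#' fitting.
#'
#' @param empirical_db,model_db Equal-length numeric vectors (>= 3 bins,
#'   neither constant).
#' @return Scalar cost `-r`.
#' @export
pearson_db_cost <- function(empirical_db, model_db) {
  if (length(empirical_db) != length(model_db))
    stop("spectra must have equal length", call. = FALSE)
  if (length(empirical_db) < 3)
    stop("need at least 3 bins to correlate", call. = FALSE)
  if (stats::sd(empirical_db) == 0 || stats::sd(model_db) == 0)
    stop("Pearson correlation undefined for a constant spectrum",
         call. = FALSE)
  -stats::cor(empirical_db, model_db)
}

# fast model dB spectrum for the optimizer: theta = (tau_e_ms, tau_i_ms,
# g_ee, g_ii); returns NULL on numerical degeneracy
.model_db_theta <- function(theta, w, g_ei, common) {
  te <- theta[1] / 1000; ti <- theta[2] / 1000
  Fe <- 1 / (1 + 1i * w * te)^2
  Fi <- 1 / (1 + 1i * w * ti)^2
  ae <- Fe / te; ai <- Fi / ti
  a <- 1i * w + ae * theta[3]
  b <- -ae * g_ei * Fi
  cc <- ai * g_ei * Fe
  d <- 1i * w + ai * theta[4]
  det <- a * d - b * cc
  lin <- if (common) Mod((d - b + a - cc) / det)^2
         else (Mod(d - b)^2 + Mod(a - cc)^2) / Mod(det)^2
  db <- 10 * log10(lin)
  if (any(!is.finite(db))) return(NULL)
  db
}

# one basin-hopping run at a given step size: random coordinate
# displacements around the current minimum, bounded L-BFGS-B local
# minimization, Metropolis acceptance at config$temperature; the whole
# loop runs at C level, drawing from R's RNG (caller seeds it)
.basin_hop <- function(w, emp_c, emp_ss, config, step_size) {
  res <- basin_hop_cpp(w, emp_c, emp_ss, config$g_ei,
                       config$noise_mode == "common",
                       unname(config$init), unname(config$lower),
                       unname(config$upper), config$n_iterations,
                       config$temperature, step_size,
                       config$maxit_local, config$factr_local)
  names(res$par) <- names(config$init)
  res
}

#' Fit the neural mass model to one regional spectrum
#'
#' Estimates `tau_e`, `tau_i`, `g_ee`, `g_ii` by basin-hopping global
#' optimization of [pearson_db_cost()] between the empirical spectrum and
#' the closed-form model spectrum evaluated on the same frequency bins
#' (restricted to the 1-35 Hz analysis band). If any estimated parameter
#' lands on a bound (within `bound_tolerance` of it, relative to the bound
#' width), the search is rerun with `retry_step_size`, and the run with
#' the higher Pearson r is returned with `retried = TRUE`. Results are
#' deterministic given `config$seed`.
#'
#' @param spec A [regional_spectrum()] (needs >= 10 bins in 1-35 Hz).
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `params` ([nmm_params()]),
#'   `pearson_r`, `retried`, `n_cost_evaluations`, `scaling_offset_db`
#'   (mean empirical-minus-model dB offset), `seed`, and the identifiers
#'   of `spec`.
#' @export
fit_region <- function(spec, config = fit_config()) {
  stopifnot(inherits(spec, "regional_spectrum"), inherits(config, "fit_config"))
  keep <- spec$grid >= 1 & spec$grid <= 35
  if (sum(keep) < 10)
    stop("need at least 10 spectrum bins inside 1-35 Hz", call. = FALSE)
  emp <- spec$psd_db[keep]
  w <- 2 * pi * spec$grid[keep]
  if (stats::sd(emp) == 0)
    stop("Pearson correlation undefined for a constant spectrum",
         call. = FALSE)
  common <- config$noise_mode == "common"
  emp_c <- emp - mean(emp)
  emp_ss <- sqrt(sum(emp_c^2))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  run1 <- .basin_hop(w, emp_c, emp_ss, config, config$step_size)
  width <- config$upper - config$lower
  at_bound <- (run1$par - config$lower) <= config$bound_tolerance * width |
              (config$upper - run1$par) <= config$bound_tolerance * width
  retried <- any(at_bound)
  best <- run1
  n_eval <- run1$n_eval
  if (retried) {
    run2 <- .basin_hop(w, emp_c, emp_ss, config, config$retry_step_size)
    n_eval <- n_eval + run2$n_eval
    if (run2$value < best$value) best <- run2
  }
  if (best$value > 1)
    stop("fit failed: model spectrum degenerate at every candidate",
         call. = FALSE)

  theta <- best$par
  params <- nmm_params(tau_e_ms = theta[["tau_e_ms"]],
                       tau_i_ms = theta[["tau_i_ms"]],
                       g_ee = theta[["g_ee"]], g_ii = theta[["g_ii"]],
                       g_ei = config$g_ei, noise_sd = 1)
  model_db <- .model_db_theta(theta, w, config$g_ei, common)
  r <- -pearson_db_cost(emp, model_db)
  structure(list(params = params, pearson_r = r, retried = retried,
                 n_cost_evaluations = n_eval,
                 scaling_offset_db = mean(emp - model_db),
                 seed = config$seed,
                 subject_id = spec$subject_id, roi = spec$roi),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("NMM fit [%s / %s]: r = %.4f%s\n", x$subject_id, x$roi,
              x$pearson_r, if (x$retried) " (retried)" else ""))
  cat(sprintf("  tau_e = %.2f ms, tau_i = %.2f ms, g_ee = %.3f, g_ii = %.3f\n",
              1000 * x$params$tau_e, 1000 * x$params$tau_i,
              x$params$g_ee, x$params$g_ii))
  cat(sprintf("  scaling offset = %.2f dB, %d cost evaluations\n",
              x$scaling_offset_db, x$n_cost_evaluations))
  invisible(x)
}

#' Fit every ROI of one subject
#'
#' Runs [fit_region()] independently for each regional spectrum of a
#' subject and assembles a long-format parameter table. Per-ROI failures
#' are recorded and skipped rather than aborting the subject; the ROI
#' seeds are derived from `config$seed` plus the ROI position so results
#' do not depend on list order beyond labels.
#'
#' @param spectra List of [regional_spectrum()] objects with unique ROI
#'   labels (one subject).
#' @param config A [fit_config()].
#' @param verbose Log per-ROI fit quality and retry events.
#' @return A data.frame with columns `subject_id`, `roi`, `tau_e_ms`,
#'   `tau_i_ms`, `g_ee`, `g_ii`, `pearson_r`, `retried`,
#'   `scaling_offset_db`, `n_cost_evaluations`; failed ROIs are listed in
#'   `attr(., "failures")`.
#' @export
fit_subject <- function(spectra, config = fit_config(), verbose = FALSE) {
  rois <- vapply(spectra, function(s) as.character(s$roi), character(1))
  if (anyDuplicated(rois))
    stop(sprintf("duplicated ROI label(s) within subject: %s",
                 paste(unique(rois[duplicated(rois)]), collapse = ", ")),
         call. = FALSE)
  rows <- vector("list", length(spectra))
  failures <- character(0)
  for (i in seq_along(spectra)) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + i) %% .Machine$integer.max
    res <- try(fit_region(spectra[[i]], cfg_i), silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures, sprintf("%s: %s", rois[i],
                                      attr(res, "condition")$message))
      next
    }
    if (verbose)
      message(sprintf("  %s: r = %.4f%s", rois[i], res$pearson_r,
                      if (res$retried) " [retry]" else ""))
    rows[[i]] <- data.frame(
      subject_id = res$subject_id, roi = res$roi,
      tau_e_ms = 1000 * res$params$tau_e, tau_i_ms = 1000 * res$params$tau_i,
      g_ee = res$params$g_ee, g_ii = res$params$g_ii,
      pearson_r = res$pearson_r, retried = res$retried,
      scaling_offset_db = res$scaling_offset_db,
      n_cost_evaluations = res$n_cost_evaluations,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  if (length(failures) > 0)
    warning(sprintf("%d ROI fit(s) failed: %s", length(failures),
                    paste(failures, collapse = "; ")), call. = FALSE)
  attr(out, "failures") <- failures
  out
}

#' Fit a whole cohort of spectra
#'
#' Convenience wrapper grouping a flat spectra list by subject and calling
#' [fit_subject()] per subject.
#'
#' @param spectra List of [regional_spectrum()] objects (multiple
#'   subjects).
#' @param config A [fit_config()]; subject seeds are offset from
#'   `config$seed` to keep subjects independent yet reproducible.
#' @param verbose Log progress per subject.
#' @return A combined parameter table as in [fit_subject()].
#' @export
fit_cohort <- function(spectra, config = fit_config(), verbose = FALSE) {
  subjects <- vapply(spectra, function(s) as.character(s$subject_id),
                     character(1))
  tabs <- lapply(seq_along(unique(subjects)), function(j) {
    sid <- unique(subjects)[j]
    cfg_j <- config
    cfg_j$seed <- (config$seed + 1000L * j) %% .Machine$integer.max
    if (verbose) message(sprintf("fitting subject %s", sid))
    fit_subject(spectra[subjects == sid], cfg_j, verbose = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
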