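#' Assemble the merged analysis table
#'
#' Joins a fitted (or ground-truth) parameter table, the band-power
#' table, and the SUVR table into one wide subject-by-ROI table carrying
#' control-referenced z-scores for the four model parameters and the
#' four band powers — the input expected by [association_model()] and
#' [run_mediation_suite()].
#'
#' @param params Data.frame: `subject_id`, `group`, `roi`, `tau_e_ms`,
#'   `tau_i_ms`, `g_ee`, `g_ii` (e.g. from [fit_cohort()] joined with
#'   group labels, or `true_params` of a [generate_cohort()]).
#' @param bands Long band table: `subject_id`, `roi`, `band`, `power_db`
#'   (from [band_power_table()]).
#' @param suvr Data.frame: `subject_id`, `roi`, `tau_suvr`, `ab_suvr`.
#' @return Wide data.frame keyed by (subject_id, roi) with parameter
#'   values and z-scores (`tau_e_z`, ...), band-power z-scores
#'   (`delta_theta_z`, `alpha_z`, `beta_z`, `broadband_z`), and SUVR
#'   columns.
#' @export
prepare_analysis_table <- function(params, bands, suvr) {
  for (p in c("tau_e_ms", "tau_i_ms", "g_ee", "g_ii"))
    params <- zscore_vs_controls(params, p)
  grp <- unique(params[, c("subject_id", "group")])
  bands <- merge(bands, grp, by = "subject_id")
  bands <- zscore_vs_controls(bands, "power_db", by = c("roi", "band"),
                              z_col = "power_z")
  wide <- stats::reshape(
    bands[, c("subject_id", "roi", "band", "power_z")],
    idvar = c("subject_id", "roi"), timevar = "band", direction = "wide")
  names(wide) <- sub("^power_z\\.", "", names(wide))
  for (b in band_definitions()$band)
    names(wide)[names(wide) == b] <- paste0(b, "_z")
  out <- merge(params, wide, by = c("subject_id", "roi"))
  out <- merge(out, suvr[, c("subject_id", "roi", "tau_suvr", "ab_suvr")],
               by = c("subject_id", "roi"))
  out[order(out$subject_id, out$roi), , drop = FALSE]
}

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] describing the synthetic dataset
#'   (or `NULL` when `spectra`/`suvr` tables are supplied to
#'   [run_pipeline()] directly).
#' @param fit A [fit_config()].
#' @param fdr_q FDR level of the regional group maps.
#' @param variance Residual-variance structure of the association models.
#' @param ci_method,n_boot Mediation uncertainty settings, see
#'   [mediate()].
#' @param seed Global seed; stage seeds are derived from it.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), fit = fit_config(),
                            fdr_q = 0.10,
                            variance = c("homogeneous", "per_roi"),
                            ci_method = c("sobel", "bootstrap"),
                            n_boot = 1000L, seed = 1L, out_dir = NULL) {
  variance <- match.arg(variance)
  ci_method <- match.arg(ci_method)
  structure(list(cohort = cohort, fit = fit, fdr_q = fdr_q,
                 variance = variance, ci_method = ci_method,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# stable content hash of an R object (written config -> md5)
.config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x, control = "all"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> fit -> z-score -> associations -> group maps ->
#' mediation on a synthetic cohort (or on supplied spectra/SUVR tables)
#' and returns a machine-readable summary. Stages are seeded from
#' `config$seed`, making reruns with the same config bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param spectra Optional list of [regional_spectrum()] objects to
#'   analyze instead of simulating (requires `suvr` and `groups`).
#' @param suvr Optional SUVR table (`subject_id`, `roi`, `tau_suvr`,
#'   `ab_suvr`).
#' @param groups Optional data.frame `subject_id`, `group` when spectra
#'   are supplied.
#' @param verbose Log stage progress.
#' @return A list of class `pipeline_result`: `params` (fitted parameter
#'   table), `analysis` (merged wide table), `associations` (per-measure
#'   coefficient tables), `group_maps`, `mediation` (five-row table),
#'   `suvr_means`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), spectra = NULL,
                         suvr = NULL, groups = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE))
  }

  if (is.null(spectra)) {
    say("stage simulate: generating synthetic cohort")
    cc <- config$cohort
    cc$seed <- (config$seed + cc$seed) %% .Machine$integer.max
    cohort <- stage("simulate", generate_cohort(cc))
    spectra <- cohort$spectra
    suvr <- cohort$suvr
    groups <- unique(cohort$true_params[, c("subject_id", "group")])
  } else {
    if (is.null(suvr) || is.null(groups))
      stop("supplied spectra require 'suvr' and 'groups'", call. = FALSE)
    cohort <- NULL
  }

  say("stage fit: %d spectra", length(spectra))
  fc <- config$fit
  fc$seed <- (config$seed + fc$seed) %% .Machine$integer.max
  params <- stage("fit", fit_cohort(spectra, fc, verbose = verbose))
  params <- merge(params, groups, by = "subject_id")

  say("stage features: band powers and z-scores")
  bands <- stage("features", band_power_table(spectra))
  analysis <- stage("zscore", prepare_analysis_table(params, bands, suvr))

  say("stage associations")
  assoc_measures <- c("tau_e_z", "tau_i_z", "g_ee_z", "g_ii_z",
                      "broadband_z", "delta_theta_z", "alpha_z", "beta_z")
  associations <- lapply(assoc_measures, function(m) {
    a <- stage(paste0("association:", m),
               association_model(analysis, m, variance = config$variance))
    cbind(outcome = m, a$coefficients)
  })
  names(associations) <- assoc_measures
  assoc_table <- do.call(rbind, associations)
  rownames(assoc_table) <- NULL

  say("stage group maps")
  group_maps <- lapply(c("tau_e_ms", "tau_i_ms", "g_ee", "g_ii"),
                       function(m) cbind(measure = m,
                         stage(paste0("group_map:", m),
                               regional_group_map(analysis, m,
                                                  q = config$fdr_q))))
  group_maps <- do.call(rbind, group_maps)
  rownames(group_maps) <- NULL

  say("stage mediation")
  med <- stage("mediation",
               run_mediation_suite(analysis, ci_method = config$ci_method,
                                   n_boot = config$n_boot,
                                   seed = (config$seed + 7L) %%
                                     .Machine$integer.max))

  contrasts <- do.call(rbind, lapply(
    c("tau_e_ms", "tau_i_ms", "g_ee", "g_ii"),
    function(m) stage(paste0("contrast:", m), group_contrast(analysis, m))))

  result <- structure(list(
    params = params, analysis = analysis,
    associations = assoc_table, association_models = associations,
    group_maps = group_maps, mediation = med$table,
    group_contrasts = contrasts,
    suvr_means = suvr_summary(suvr),
    seed = config$seed, config_hash = .config_hash(unclass(config)),
    cohort = cohort), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(seed = config$seed, config_hash = result$config_hash)
    write_table(params[, c("subject_id", "roi", "tau_e_ms", "tau_i_ms",
                           "g_ee", "g_ii", "pearson_r", "retried",
                           "scaling_offset_db", "group")],
                file.path(config$out_dir, "params.csv"), "params", meta)
    write_table(suvr, file.path(config$out_dir, "suvr.csv"), "suvr", meta)
    utils::write.csv(assoc_table,
                     file.path(config$out_dir, "associations.csv"),
                     row.names = FALSE)
    utils::write.csv(group_maps,
                     file.path(config$out_dir, "group_maps.csv"),
                     row.names = FALSE)
    utils::write.csv(med$table,
                     file.path(config$out_dir, "mediation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = result$config_hash,
           package = as.character(utils::packageVersion("nmmspectra")),
           suvr_means = as.list(result$suvr_means),
           group_contrasts = contrasts,
           associations = assoc_table,
           mediation = med$table),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  %d fitted region-spectra, seed %d, config %s\n",
              nrow(x$params), x$seed, substr(x$config_hash, 1, 8)))
  cat("Group contrasts (patient - control):\n")
  print(x$group_contrasts, digits = 3)
  cat("Mediation table:\n")
  print(x$mediation[, c("treatment", "mediator", "outcome", "indirect",
                        "indirect_p")], digits = 3)
  invisible(x)
}
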