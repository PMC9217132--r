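#' Control-referenced z-scores
#'
#' Standardizes a measure against the control cohort, separately within
#' each ROI (and optionally further grouping columns): for every ROI,
#' `z = (value - control mean) / control SD`, applied to all subjects
#' including the controls themselves (whose per-ROI z-scores then have
#' mean 0 and SD 1).
#'
#' @param table Data.frame with columns `subject_id`, `group`
#'   (control/patient), `roi`, and the measure column.
#' @param measure Name of the numeric column to standardize.
#' @param by Grouping columns defining the standardization strata
#'   (default `"roi"`; use `c("roi", "band")` for band-power tables).
#' @param z_col Name of the output column; default strips a trailing
#'   `_ms`/`_db` from `measure` and appends `_z`.
#' @return `table` with the z column added.
#' @export
zscore_vs_controls <- function(table, measure, by = "roi",
                               z_col = NULL) {
  if (!measure %in% names(table))
    stop(sprintf("measure column '%s' not found", measure), call. = FALSE)
  if (!all(by %in% names(table)))
    stop("grouping column(s) missing from table", call. = FALSE)
  if (!"group" %in% names(table) || !any(table$group == "control"))
    stop("table must contain control-group rows", call. = FALSE)
  if (is.null(z_col))
    z_col <- paste0(sub("_(ms|db)$", "", measure), "_z")
  strata <- interaction(table[by], drop = TRUE)
  ctrl <- table$group == "control"
  cnt <- table(factor(strata[ctrl], levels = levels(strata)))
  if (any(cnt < 2))
    stop(sprintf("fewer than 2 controls in stratum: %s",
                 paste(names(cnt)[cnt < 2], collapse = ", ")), call. = FALSE)
  m <- tapply(table[[measure]][ctrl], strata[ctrl], mean)
  s <- tapply(table[[measure]][ctrl], strata[ctrl], stats::sd)
  bad <- names(s)[!is.finite(s) | s == 0]
  if (length(bad) > 0)
    stop(sprintf("zero control SD in stratum: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  key <- as.character(strata)
  table[[z_col]] <- as.numeric((table[[measure]] - m[key]) / s[key])
  table
}

#' Repeated-measures association of a z-scored measure with SUVR
#'
#' Fits the dual-predictor association model used for every neuronal
#' parameter and band-power outcome:
#' `z ~ intercept + tau_suvr + ab_suvr`, with the repeated ROIs within
#' each subject handled either by a subject-level random intercept
#' (`method = "lme"`, the default) or by an exchangeable-correlation
#' marginal model (`method = "gls"`). `variance = "per_roi"` additionally
#' estimates ROI-specific residual variances. t- and p-values use the
#' between-within degrees-of-freedom approximation of the fitter.
#'
#' By default the model is fit on patient rows only, the design under
#' which SUVR predictors are available and interpreted.
#'
#' @param data Data.frame with `subject_id`, `group`, `roi`, the outcome
#'   column, and the predictor columns.
#' @param outcome Name of the z-scored outcome column.
#' @param predictors Character vector of predictor columns (default
#'   `c("tau_suvr", "ab_suvr")`).
#' @param variance `"homogeneous"` (default) or `"per_roi"` residual
#'   variances.
#' @param method `"lme"` (subject random intercept) or `"gls"`
#'   (compound-symmetric marginal correlation).
#' @param subset_group Group to model (`"patient"` by default; `NULL` uses
#'   all rows).
#' @param n_fit_points Number of points per predicted-fit line.
#' @return Object of class `nmm_association`: `coefficients` (estimate,
#'   SE, t, p per predictor), `fits` (predicted lines per predictor with
#'   the other covariates held at their means), `n_subjects`, `n_rois`,
#'   and the fitted `model`.
#' @export
association_model <- function(data, outcome,
                              predictors = c("tau_suvr", "ab_suvr"),
                              variance = c("homogeneous", "per_roi"),
                              method = c("lme", "gls"),
                              subset_group = "patient",
                              n_fit_points = 50) {
  variance <- match.arg(variance)
  method <- match.arg(method)
  need <- c("subject_id", "roi", outcome, predictors)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (!is.null(subset_group) && "group" %in% names(data))
    data <- data[data$group %in% subset_group, , drop = FALSE]
  data <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  if (nrow(data) < length(predictors) + 2)
    stop("not enough complete cases", call. = FALSE)
  if (length(predictors) > 1) {
    cm <- stats::cor(data[predictors])
    if (any(abs(cm[upper.tri(cm)]) > 0.999))
      stop("predictors are collinear (|r| > 0.999)", call. = FALSE)
  }
  data$subject_id <- factor(data$subject_id)
  data$roi <- factor(data$roi)
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + ")))
  wts <- if (variance == "per_roi") nlme::varIdent(form = ~ 1 | roi) else NULL
  fit <- tryCatch({
    if (method == "lme")
      nlme::lme(fml, random = ~ 1 | subject_id, data = data, weights = wts,
                method = "REML",
                control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                           returnObject = FALSE))
    else
      nlme::gls(fml, data = data, weights = wts,
                correlation = nlme::corCompSymm(form = ~ 1 | subject_id),
                method = "REML",
                control = nlme::glsControl(maxIter = 200, msMaxIter = 200))
  }, error = function(e)
    stop(sprintf("association model failed to converge: %s",
                 conditionMessage(e)), call. = FALSE))
  tt <- if (method == "lme") summary(fit)$tTable else summary(fit)$tTable
  cf <- data.frame(term = rownames(tt),
                   estimate = tt[, "Value"],
                   se = tt[, "Std.Error"],
                   t = tt[, "t-value"],
                   p = tt[, "p-value"],
                   row.names = NULL, stringsAsFactors = FALSE)
  # predicted-fit lines: sweep one predictor, fix the others at their means
  fe <- if (method == "lme") nlme::fixef(fit) else stats::coef(fit)
  fits <- lapply(predictors, function(p) {
    xs <- seq(min(data[[p]]), max(data[[p]]), length.out = n_fit_points)
    nd <- as.data.frame(lapply(data[predictors], mean))
    nd <- nd[rep(1L, n_fit_points), , drop = FALSE]
    nd[[p]] <- xs
    yhat <- fe[["(Intercept)"]] +
      as.matrix(nd[predictors]) %*% fe[predictors]
    data.frame(predictor = p, x = xs, fitted = as.numeric(yhat),
               stringsAsFactors = FALSE)
  })
  structure(list(coefficients = cf,
                 fits = do.call(rbind, fits),
                 fixed_at = vapply(data[predictors], mean, numeric(1)),
                 n_subjects = nlevels(data$subject_id),
                 n_rois = nlevels(data$roi),
                 outcome = outcome, variance = variance, method = method,
                 model = fit),
            class = "nmm_association")
}

#' @export
print.nmm_association <- function(x, ...) {
  cat(sprintf("Association model for '%s' (%s, %s residuals)\n",
              x$outcome, x$method, x$variance))
  cat(sprintf("  %d subjects x %d ROIs\n", x$n_subjects, x$n_rois))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Patient-control contrast of a repeated-measures outcome
#'
#' Simple group-contrast mixed model on a per-ROI measure:
#' `value ~ group` with a subject random intercept, reporting the
#' patient-minus-control estimate with its t- and p-value. Used for
#' cohort-level comparisons of band powers and fitted parameters.
#'
#' @param data Data.frame with `subject_id`, `group`, `roi`, and the
#'   measure column.
#' @param measure Name of the outcome column.
#' @return A one-row data.frame: `measure`, `estimate` (patient minus
#'   control), `se`, `t`, `p`.
#' @export
group_contrast <- function(data, measure) {
  need <- c("subject_id", "group", "roi", measure)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  data <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  data$group <- factor(data$group, levels = c("control", "patient"))
  fml <- stats::as.formula(paste(measure, "~ group"))
  fit <- nlme::lme(fml, random = ~ 1 | subject_id, data = data,
                   method = "REML")
  tt <- summary(fit)$tTable
  data.frame(measure = measure,
             estimate = tt["grouppatient", "Value"],
             se = tt["grouppatient", "Std.Error"],
             t = tt["grouppatient", "t-value"],
             p = tt["grouppatient", "p-value"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' FDR-thresholded regional group map
#'
#' Per-ROI unpaired t-tests of patients versus controls on a measure,
#' corrected across ROIs with the Benjamini-Hochberg step-up procedure at
#' FDR level `q` (default 10%). t-values are signed patient minus
#' control.
#'
#' @param data Data.frame with `subject_id`, `group`, `roi`, and the
#'   measure column.
#' @param measure Name of the outcome column.
#' @param q FDR level (default 0.10).
#' @param var_equal Use the pooled-variance Student t-test (default TRUE)
#'   or Welch's t-test.
#' @return Data.frame per ROI: `roi`, `t`, `df`, `p`, `p_bh`,
#'   `significant`.
#' @export
regional_group_map <- function(data, measure, q = 0.10, var_equal = TRUE) {
  need <- c("group", "roi", measure)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  rois <- unique(as.character(data$roi))
  counts <- table(factor(data$roi, levels = rois),
                  factor(data$group, levels = c("control", "patient")))
  bad <- rois[apply(counts, 1, min) < 2]
  if (length(bad) > 0)
    stop(sprintf("fewer than 2 observations per group at ROI(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  res <- lapply(rois, function(r) {
    xp <- data[[measure]][data$roi == r & data$group == "patient"]
    xc <- data[[measure]][data$roi == r & data$group == "control"]
    tt <- stats::t.test(xp, xc, var.equal = var_equal)
    data.frame(roi = r, t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_bh <= q
  rownames(out) <- NULL
  out
}
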