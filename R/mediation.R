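#' Mediation decomposition of a protein effect on band power
#'
#' Product-of-coefficients mediation analysis decomposing the association
#' of a protein burden (tau or amyloid-beta SUVR, the treatment) with a
#' band-power z-score (the outcome) into a direct effect and the part
#' carried by a time-constant z-score (the mediator). Three regressions
#' are fit on the complete cases:
#' \itemize{
#'   \item path a: `mediator ~ treatment + covariates`
#'   \item outcome model: `outcome ~ treatment + mediator + covariates`
#'     giving the direct effect and path b
#'   \item total model: `outcome ~ treatment + covariates`
#' }
#' The indirect (mediated) effect is `a * b`. Under the default
#' `estimator = "ols_product"` the decomposition is exactly additive:
#' `total = direct + indirect`. `estimator = "mixed_product"` swaps each
#' regression for a subject-random-intercept mixed model (approximately
#' additive). Uncertainty for the indirect effect comes from the Sobel
#' first-order SE or from a cluster bootstrap that resamples subjects,
#' keeping each subject's ROI block intact.
#'
#' @param data Data.frame with `subject_id`, optionally `group`, and the
#'   outcome/treatment/mediator/covariate columns.
#' @param outcome,treatment,mediator Column names; the three must be
#'   distinct.
#' @param covariates Character vector of additional adjustment columns
#'   (typically the other protein's SUVR).
#' @param estimator `"ols_product"` (default) or `"mixed_product"`.
#' @param ci_method `"sobel"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (>= 100) when
#'   `ci_method = "bootstrap"`.
#' @param seed Integer seed for the bootstrap.
#' @param subset_group Group to analyze (`"patient"` by default; `NULL`
#'   keeps all rows).
#' @return Object of class `mediation_result`: `effects` (total, direct,
#'   indirect with SE/CI/p), `paths` (a, b with SEs), the spec, and `n`
#'   (complete cases / subjects).
#' @export
mediate <- function(data, outcome, treatment, mediator,
                    covariates = character(0),
                    estimator = c("ols_product", "mixed_product"),
                    ci_method = c("sobel", "bootstrap"),
                    n_boot = 1000L, seed = 1L, subset_group = "patient") {
  estimator <- match.arg(estimator)
  ci_method <- match.arg(ci_method)
  if (mediator == treatment || outcome == mediator || outcome == treatment)
    stop("outcome, treatment, and mediator must be distinct columns",
         call. = FALSE)
  if (ci_method == "bootstrap" && n_boot < 100)
    stop("'n_boot' must be >= 100", call. = FALSE)
  need <- c("subject_id", outcome, treatment, mediator, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (!is.null(subset_group) && "group" %in% names(data))
    data <- data[data$group %in% subset_group, , drop = FALSE]
  data <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  if (nrow(data) < 10)
    stop("need at least 10 complete cases", call. = FALSE)
  if (abs(stats::cor(data[[treatment]], data[[mediator]])) > 0.999)
    stop("mediator and treatment are collinear (|r| > 0.999)", call. = FALSE)

  cov_rhs <- if (length(covariates) > 0)
    paste("+", paste(covariates, collapse = " + ")) else ""
  f_a <- stats::as.formula(paste(mediator, "~", treatment, cov_rhs))
  f_out <- stats::as.formula(paste(outcome, "~", treatment, "+", mediator,
                                   cov_rhs))
  f_tot <- stats::as.formula(paste(outcome, "~", treatment, cov_rhs))

  fit_paths <- function(d) {
    if (estimator == "ols_product") {
      m_a <- stats::lm(f_a, data = d)
      m_o <- stats::lm(f_out, data = d)
      m_t <- stats::lm(f_tot, data = d)
      ct <- function(m) summary(m)$coefficients
      list(a = ct(m_a)[treatment, 1], a_se = ct(m_a)[treatment, 2],
           b = ct(m_o)[mediator, 1], b_se = ct(m_o)[mediator, 2],
           direct = ct(m_o)[treatment, 1], direct_se = ct(m_o)[treatment, 2],
           direct_p = ct(m_o)[treatment, 4],
           total = ct(m_t)[treatment, 1], total_se = ct(m_t)[treatment, 2],
           total_p = ct(m_t)[treatment, 4])
    } else {
      d$subject_id <- factor(d$subject_id)
      fit1 <- function(f) nlme::lme(f, random = ~ 1 | subject_id, data = d,
                                    method = "REML")
      tt <- function(m) summary(m)$tTable
      m_a <- fit1(f_a); m_o <- fit1(f_out); m_t <- fit1(f_tot)
      list(a = tt(m_a)[treatment, "Value"],
           a_se = tt(m_a)[treatment, "Std.Error"],
           b = tt(m_o)[mediator, "Value"],
           b_se = tt(m_o)[mediator, "Std.Error"],
           direct = tt(m_o)[treatment, "Value"],
           direct_se = tt(m_o)[treatment, "Std.Error"],
           direct_p = tt(m_o)[treatment, "p-value"],
           total = tt(m_t)[treatment, "Value"],
           total_se = tt(m_t)[treatment, "Std.Error"],
           total_p = tt(m_t)[treatment, "p-value"])
    }
  }
  est <- fit_paths(data)
  indirect <- est$a * est$b
  sobel_se <- sqrt(est$a^2 * est$b_se^2 + est$b^2 * est$a_se^2)

  ci <- c(NA_real_, NA_real_)
  ind_se <- sobel_se
  ind_p <- 2 * stats::pnorm(-abs(indirect / sobel_se))
  boot <- NULL
  if (ci_method == "bootstrap") {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(as.integer(seed))
    subj <- split(seq_len(nrow(data)), data$subject_id, drop = TRUE)
    boot <- vapply(seq_len(n_boot), function(bi) {
      take <- sample(length(subj), replace = TRUE)
      d <- data[unlist(subj[take], use.names = FALSE), , drop = FALSE]
      # relabel so resampled subjects stay distinct clusters
      d$subject_id <- rep(seq_along(take),
                          times = lengths(subj[take]))
      e <- try(fit_paths(d), silent = TRUE)
      if (inherits(e, "try-error")) NA_real_ else e$a * e$b
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
    ind_se <- stats::sd(boot)
    ind_p <- 2 * min(mean(boot <= 0), mean(boot >= 0)) + 1 / length(boot)
    ind_p <- min(ind_p, 1)
  }

  effects <- data.frame(
    effect = c("total", "direct", "indirect"),
    estimate = c(est$total, est$direct, indirect),
    se = c(est$total_se, est$direct_se, ind_se),
    ci_lo = c(est$total - 1.96 * est$total_se,
              est$direct - 1.96 * est$direct_se,
              if (ci_method == "bootstrap") ci[1] else
                indirect - 1.96 * sobel_se),
    ci_hi = c(est$total + 1.96 * est$total_se,
              est$direct + 1.96 * est$direct_se,
              if (ci_method == "bootstrap") ci[2] else
                indirect + 1.96 * sobel_se),
    p = c(est$total_p, est$direct_p, ind_p),
    stringsAsFactors = FALSE)
  structure(list(effects = effects,
                 paths = data.frame(path = c("a", "b"),
                                    estimate = c(est$a, est$b),
                                    se = c(est$a_se, est$b_se),
                                    stringsAsFactors = FALSE),
                 outcome = outcome, treatment = treatment,
                 mediator = mediator, covariates = covariates,
                 estimator = estimator, ci_method = ci_method,
                 n_obs = nrow(data),
                 n_subjects = length(unique(data$subject_id)),
                 seed = as.integer(seed)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s (mediator %s), %s/%s\n",
              x$treatment, x$outcome, x$mediator, x$estimator, x$ci_method))
  cat(sprintf("  %d observations, %d subjects\n", x$n_obs, x$n_subjects))
  print(x$effects, digits = 4)
  invisible(x)
}

#' The five standard mediation decompositions
#'
#' Runs the fixed hypothesis set linking the two proteinopathies to
#' band-power changes through the time-constants:
#' \enumerate{
#'   \item amyloid-beta -> delta-theta power, mediated by tau_i
#'   \item amyloid-beta -> alpha power, mediated by tau_i
#'   \item amyloid-beta -> beta power, mediated by tau_i
#'   \item tau -> alpha power, mediated by tau_e
#'   \item tau -> beta power, mediated by tau_e
#' }
#' Each model adjusts for the other protein's SUVR.
#'
#' @param data Data.frame containing `subject_id`, the band z columns
#'   (`delta_theta_z`, `alpha_z`, `beta_z`), mediator z columns
#'   (`tau_e_z`, `tau_i_z`), and `tau_suvr`, `ab_suvr`.
#' @param ... Passed to [mediate()] (estimator, ci_method, n_boot, seed,
#'   subset_group).
#' @return A list with `results` (the five `mediation_result` objects)
#'   and `table`, a tidy data.frame with one row per hypothesis and
#'   columns for total/direct/indirect estimates, the indirect SE and p,
#'   and CI bounds.
#' @export
run_mediation_suite <- function(data, ...) {
  hypotheses <- data.frame(
    treatment = c("ab_suvr", "ab_suvr", "ab_suvr", "tau_suvr", "tau_suvr"),
    mediator = c("tau_i_z", "tau_i_z", "tau_i_z", "tau_e_z", "tau_e_z"),
    outcome = c("delta_theta_z", "alpha_z", "beta_z", "alpha_z", "beta_z"),
    stringsAsFactors = FALSE)
  need <- unique(c("subject_id", hypotheses$treatment, hypotheses$mediator,
                   hypotheses$outcome))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop(sprintf("missing measure column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  results <- vector("list", nrow(hypotheses))
  rows <- vector("list", nrow(hypotheses))
  for (i in seq_len(nrow(hypotheses))) {
    h <- hypotheses[i, ]
    other <- if (h$treatment == "ab_suvr") "tau_suvr" else "ab_suvr"
    res <- mediate(data, outcome = h$outcome, treatment = h$treatment,
                   mediator = h$mediator, covariates = other, ...)
    results[[i]] <- res
    ef <- res$effects
    g <- function(e, col) ef[[col]][ef$effect == e]
    rows[[i]] <- data.frame(
      treatment = h$treatment, mediator = h$mediator, outcome = h$outcome,
      total = g("total", "estimate"), total_p = g("total", "p"),
      direct = g("direct", "estimate"), direct_p = g("direct", "p"),
      indirect = g("indirect", "estimate"), indirect_se = g("indirect", "se"),
      indirect_ci_lo = g("indirect", "ci_lo"),
      indirect_ci_hi = g("indirect", "ci_hi"),
      indirect_p = g("indirect", "p"),
      stringsAsFactors = FALSE)
  }
  list(results = results, table = do.call(rbind, rows))
}
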