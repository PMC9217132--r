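# synthetic mediation dataset with known path coefficients a (treatment ->
# mediator) and b (mediator -> outcome), direct effect c, subject blocks
make_mediation_data <- function(n_subj = 12, n_roi = 8, a = 0.5, b = 0.4,
                                direct = 0.3, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("P%02d", 1:n_subj),
                   roi = paste0("roi", 1:n_roi), stringsAsFactors = FALSE)
  n <- nrow(d)
  d$group <- "patient"
  d$treatment <- rnorm(n, 2, 1)
  d$covar <- rnorm(n, 1.6, 0.5)
  d$mediator <- a * d$treatment + rnorm(n, 0, 0.5)
  d$outcome <- direct * d$treatment + b * d$mediator + 0.1 * d$covar +
    rnorm(n, 0, 0.5)
  d
}

test_that("least-squares product estimator is exactly additive", {
  for (seed in 1:5) {
    d <- make_mediation_data(seed = seed, a = runif(1, -1, 1),
                             b = runif(1, -1, 1))
    res <- mediate(d, "outcome", "treatment", "mediator",
                   covariates = "covar")
    ef <- res$effects
    total <- ef$estimate[ef$effect == "total"]
    parts <- sum(ef$estimate[ef$effect %in% c("direct", "indirect")])
    expect_equal(total, parts, tolerance = 1e-8)
    # indirect is the product of the path coefficients
    expect_equal(ef$estimate[ef$effect == "indirect"],
                 prod(res$paths$estimate), tolerance = 1e-12)
  }
})

test_that("known paths are recovered and a null b-path gives a null indirect", {
  d <- make_mediation_data(n_subj = 20, n_roi = 10, a = 0.5, b = 0.4,
                           seed = 3)
  res <- mediate(d, "outcome", "treatment", "mediator",
                 covariates = "covar", ci_method = "bootstrap",
                 n_boot = 200, seed = 9)
  ef <- res$effects
  ind <- ef[ef$effect == "indirect", ]
  expect_gt(ind$estimate, 0.1)
  expect_lt(ind$estimate, 0.3)
  # truth 0.20 inside the cluster-bootstrap CI
  expect_gt(0.20, ind$ci_lo)
  expect_lt(0.20, ind$ci_hi)

  # severed mediator -> outcome path: indirect within 2 SE of zero
  hits <- 0L
  for (seed in 1:6) {
    d0 <- make_mediation_data(n_subj = 14, b = 0, seed = 100 + seed)
    r0 <- mediate(d0, "outcome", "treatment", "mediator",
                  covariates = "covar")
    e0 <- r0$effects[r0$effects$effect == "indirect", ]
    hits <- hits + (abs(e0$estimate) < 2 * e0$se)
  }
  expect_gte(hits, 5L)
})

test_that("indirect sign follows the product of strong paths", {
  for (ab in list(c(0.8, 0.6), c(-0.8, 0.6), c(0.8, -0.6), c(-0.8, -0.6))) {
    d <- make_mediation_data(n_subj = 16, n_roi = 10, a = ab[1], b = ab[2],
                             seed = 7)
    res <- mediate(d, "outcome", "treatment", "mediator")
    pa <- res$paths
    if (all(abs(pa$estimate) > 2 * pa$se)) {
      ind <- res$effects$estimate[res$effects$effect == "indirect"]
      expect_equal(sign(ind), prod(sign(pa$estimate)))
    }
  }
})

test_that("cluster bootstrap is reproducible and validated", {
  d <- make_mediation_data(seed = 11)
  r1 <- mediate(d, "outcome", "treatment", "mediator",
                ci_method = "bootstrap", n_boot = 150, seed = 4)
  r2 <- mediate(d, "outcome", "treatment", "mediator",
                ci_method = "bootstrap", n_boot = 150, seed = 4)
  expect_identical(r1$effects, r2$effects)
  r3 <- mediate(d, "outcome", "treatment", "mediator",
                ci_method = "bootstrap", n_boot = 150, seed = 5)
  expect_false(identical(r1$effects$ci_lo[3], r3$effects$ci_lo[3]))

  expect_error(mediate(d, "outcome", "treatment", "mediator",
                       ci_method = "bootstrap", n_boot = 50), ">= 100")
  expect_error(mediate(d, "outcome", "treatment", "treatment"), "distinct")
  d$mediator <- d$treatment
  expect_error(mediate(d, "outcome", "treatment", "mediator"), "collinear")
})

test_that("mixed-model product estimator agrees with OLS on strong effects", {
  d <- make_mediation_data(n_subj = 16, n_roi = 10, seed = 13)
  # inject subject-level heterogeneity so the random intercept matters
  ranef <- rnorm(16, 0, 0.4)
  d$outcome <- d$outcome + ranef[match(d$subject_id,
                                       sprintf("P%02d", 1:16))]
  r_ols <- mediate(d, "outcome", "treatment", "mediator")
  r_mix <- mediate(d, "outcome", "treatment", "mediator",
                   estimator = "mixed_product")
  i_ols <- r_ols$effects$estimate[r_ols$effects$effect == "indirect"]
  i_mix <- r_mix$effects$estimate[r_mix$effects$effect == "indirect"]
  expect_equal(sign(i_ols), sign(i_mix))
  expect_lt(abs(i_ols - i_mix) / abs(i_ols), 0.5)
})

test_that("the hypothesis suite runs its five fixed decompositions", {
  ch <- generate_cohort(small_cohort_config(n_controls = 10, n_patients = 8,
                                            n_rois = 8, seed = 21))
  bands <- band_power_table(ch$spectra)
  d <- prepare_analysis_table(ch$true_params, bands, ch$suvr)
  out <- run_mediation_suite(d)
  expect_equal(nrow(out$table), 5)
  expect_equal(out$table$treatment,
               c("ab_suvr", "ab_suvr", "ab_suvr", "tau_suvr", "tau_suvr"))
  expect_equal(out$table$mediator,
               c("tau_i_z", "tau_i_z", "tau_i_z", "tau_e_z", "tau_e_z"))
  expect_equal(out$table$outcome,
               c("delta_theta_z", "alpha_z", "beta_z", "alpha_z", "beta_z"))
  expect_length(out$results, 5)

  expect_error(run_mediation_suite(d[, setdiff(names(d), "alpha_z")]),
               "alpha_z")
})
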