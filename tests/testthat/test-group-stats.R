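make_cohort_table <- function(n_ctrl = 6, n_pat = 4, n_roi = 5, seed = 1,
                              shift = 0) {
  set.seed(seed)
  subj <- c(sprintf("C%02d", 1:n_ctrl), sprintf("P%02d", 1:n_pat))
  grp <- rep(c("control", "patient"), c(n_ctrl, n_pat))
  d <- expand.grid(subject_id = subj, roi = paste0("roi", 1:n_roi),
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject_id, subj)]
  d$value <- rnorm(nrow(d)) + ifelse(d$group == "patient", shift, 0)
  d
}

test_that("control-referenced z-scores standardize the control block", {
  d <- make_cohort_table()
  z <- zscore_vs_controls(d, "value")
  ctrl <- z[z$group == "control", ]
  for (r in unique(ctrl$roi)) {
    expect_lt(abs(mean(ctrl$value_z[ctrl$roi == r])), 1e-12)
    expect_equal(sd(ctrl$value_z[ctrl$roi == r]), 1, tolerance = 1e-12)
  }
  # idempotence on the control block: z-scoring the z column again is
  # the identity there
  z2 <- zscore_vs_controls(z, "value_z", z_col = "zz")
  expect_equal(z2$zz[z2$group == "control"],
               z$value_z[z$group == "control"], tolerance = 1e-12)
})

test_that("a two-control-SD excursion scores z = 2 by definition", {
  d <- make_cohort_table(n_pat = 1)
  ctrl <- d[d$group == "control" & d$roi == "roi1", ]
  d$value[d$subject_id == "P01" & d$roi == "roi1"] <-
    mean(ctrl$value) + 2 * sd(ctrl$value)
  z <- zscore_vs_controls(d, "value")
  expect_equal(z$value_z[z$subject_id == "P01" & z$roi == "roi1"], 2,
               tolerance = 1e-12)
})

test_that("z-scoring rejects degenerate control strata", {
  d <- make_cohort_table()
  d$value[d$group == "control" & d$roi == "roi2"] <- 5
  expect_error(zscore_vs_controls(d, "value"), "zero control SD.*roi2")
  expect_error(zscore_vs_controls(d[d$group == "patient", ], "value"),
               "control")
  d2 <- make_cohort_table()
  d2 <- d2[!(d2$group == "control" & d2$roi == "roi1" &
               d2$subject_id != "C01"), ]
  expect_error(zscore_vs_controls(d2, "value"), "fewer than 2 controls")
})

test_that("synthetic patients shift in the configured directions", {
  ch <- generate_cohort(small_cohort_config(n_controls = 14, n_patients = 10,
                                            n_rois = 8, seed = 4))
  tp <- ch$true_params
  pat <- tp[tp$group == "patient", ]
  expect_gt(mean(pat$tau_e_z), 0)
  expect_gt(mean(pat$tau_i_z), 0)
  expect_gt(mean(pat$g_ee_z), 0)
  expect_lt(mean(pat$g_ii_z), 0)
})

test_that("association model recovers configured couplings and nulls", {
  ch <- generate_cohort(cohort_config(seed = 12))
  d <- merge(ch$true_params,
             ch$suvr[, c("subject_id", "roi", "tau_suvr", "ab_suvr")],
             by = c("subject_id", "roi"))
  a_e <- association_model(d, "tau_e_z")
  a_i <- association_model(d, "tau_i_z")
  ce <- a_e$coefficients; ci <- a_i$coefficients
  expect_gt(ce$t[ce$term == "tau_suvr"], 2)
  expect_gt(ci$t[ci$term == "ab_suvr"], 2)
  expect_lt(abs(ce$t[ce$term == "ab_suvr"]), 3)
  expect_lt(abs(ci$t[ci$term == "tau_suvr"]), 3)
  expect_equal(a_e$n_subjects, 20)       # patients only by default
  expect_equal(a_e$n_rois, 68)
  # predicted-fit lines are evaluated with the other covariate at its mean
  expect_equal(unname(a_e$fixed_at["ab_suvr"]),
               mean(d$ab_suvr[d$group == "patient"]), tolerance = 1e-12)
  expect_equal(nrow(a_e$fits), 100)
})

test_that("association model supports marginal and per-ROI variants", {
  ch <- generate_cohort(small_cohort_config(n_controls = 10, n_patients = 8,
                                            n_rois = 6, seed = 9))
  d <- merge(ch$true_params,
             ch$suvr[, c("subject_id", "roi", "tau_suvr", "ab_suvr")],
             by = c("subject_id", "roi"))
  a_gls <- association_model(d, "tau_e_z", method = "gls")
  expect_s3_class(a_gls$model, "gls")
  a_var <- association_model(d, "tau_e_z", variance = "per_roi")
  expect_true(sign(a_var$coefficients$estimate[
    a_var$coefficients$term == "tau_suvr"]) ==
    sign(a_gls$coefficients$estimate[
      a_gls$coefficients$term == "tau_suvr"]))

  # collinear predictors are rejected
  d$ab_suvr <- d$tau_suvr * 2 + 1e-9
  expect_error(association_model(d, "tau_e_z"), "collinear")
})

test_that("purely between-subject outcomes have zero slope on orthogonal predictors", {
  set.seed(3)
  n_subj <- 8; n_roi <- 6
  d <- expand.grid(subject_id = sprintf("P%02d", 1:n_subj),
                   roi = paste0("roi", 1:n_roi), stringsAsFactors = FALSE)
  d$group <- "patient"
  subj_eff <- rnorm(n_subj)
  d$z <- subj_eff[match(d$subject_id, sprintf("P%02d", 1:n_subj))]
  # predictors vary only within subject (centered per subject), hence
  # orthogonal to any subject-constant outcome
  d$tau_suvr <- ave(rnorm(nrow(d)), d$subject_id,
                    FUN = function(x) x - mean(x))
  d$ab_suvr <- ave(rnorm(nrow(d)), d$subject_id,
                   FUN = function(x) x - mean(x))
  a <- association_model(d, "z")
  expect_lt(max(abs(a$coefficients$estimate[
    a$coefficients$term != "(Intercept)"])), 1e-8)
})

test_that("group contrast reports the patient-minus-control difference", {
  d <- make_cohort_table(n_ctrl = 10, n_pat = 8, n_roi = 6, shift = 1.2,
                         seed = 8)
  g <- group_contrast(d, "value")
  expect_equal(g$estimate, 1.2, tolerance = 0.5)
  expect_lt(g$p, 0.01)
})

test_that("BH thresholding matches the brute-force step-up rule", {
  # brute-force step-up: largest k with p_(k) <= k q / m
  bh_brute <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= seq_len(m) * q / m)
    keep <- logical(m)
    if (length(k) > 0) keep[o[seq_len(max(k))]] <- TRUE
    keep
  }
  toy <- c(0.001, 0.01, 0.03, 0.2, 0.9)
  expect_equal(p.adjust(toy, "BH") <= 0.10, bh_brute(toy, 0.10))
  expect_equal(which(p.adjust(toy, "BH") <= 0.10), 1:3)

  set.seed(14)
  for (i in 1:20) {
    p <- runif(30)^2
    expect_equal(p.adjust(p, "BH") <= 0.10, bh_brute(p, 0.10))
  }
})

test_that("regional group maps flag a planted effect and stay monotone in q", {
  d <- make_cohort_table(n_ctrl = 10, n_pat = 10, n_roi = 8, seed = 6)
  ctrl1 <- d$group == "control" & d$roi == "roi3"
  d$value[d$group == "patient" & d$roi == "roi3"] <-
    mean(d$value[ctrl1]) + 5 * sd(d$value[ctrl1]) + rnorm(10, 0, 0.2)
  gm <- regional_group_map(d, "value", q = 0.10)
  expect_true(gm$significant[gm$roi == "roi3"])
  expect_equal(nrow(gm), 8)

  # monotone mask: significant set grows with q
  masks <- lapply(c(0.01, 0.05, 0.10, 0.25),
                  function(q) regional_group_map(d, "value", q)$significant)
  for (i in seq_len(length(masks) - 1))
    expect_true(all(masks[[i]] <= masks[[i + 1]]))

  expect_error(regional_group_map(d[d$group == "patient", ], "value"),
               "fewer than 2")
})
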