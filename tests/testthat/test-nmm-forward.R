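test_that("gamma transfer matches the Fourier transform of the gamma kernel", {
  grid <- analysis_grid()

  # unit-area kernel: DC response is exactly 1
  for (tau in c(0.005, 0.017, 0.03))
    expect_equal(gamma_transfer(tau, 1e-9), 1 + 0i, tolerance = 1e-6)

  # |F| strictly decreasing with frequency
  magn <- Mod(gamma_transfer(0.020, grid))
  expect_true(all(diff(magn) < 0))

  # numeric Fourier transform of the sampled kernel f(t) = (t/tau^2) e^(-t/tau)
  tau <- 0.010
  dt <- 1e-5
  tt <- seq(0, 0.5, by = dt)
  kern <- (tt / tau^2) * exp(-tt / tau)
  f0 <- 10
  numeric_ft <- sum(kern * exp(-1i * 2 * pi * f0 * tt)) * dt
  closed <- gamma_transfer(tau, f0)
  expect_lt(Mod(numeric_ft - closed) / Mod(closed), 1e-3)

  expect_error(gamma_transfer(0, grid), "positive")
  expect_error(gamma_transfer(-0.01, grid), "positive")
})

test_that("local transfer solves the coupled 2x2 system", {
  grid <- analysis_grid()
  w <- 2 * pi * as.numeric(grid)

  # decoupled limit: H_e = 1/(jw + g_ee F_e / tau_e) exactly
  p0 <- nmm_params(tau_e_ms = 14, tau_i_ms = 22, g_ee = 0.8, g_ii = 2,
                   g_ei = 0)
  H <- local_transfer(p0, grid)
  Fe <- gamma_transfer(p0$tau_e, grid)
  expect_equal(H$H_e, 1 / (1i * w + p0$g_ee * Fe / p0$tau_e),
               tolerance = 1e-12)

  # generic complex 2x2 solve() oracle at the canonical starting values
  p <- nmm_params(tau_e_ms = 17, tau_i_ms = 17, g_ee = 0.5, g_ii = 0.5,
                  g_ei = 1)
  H <- local_transfer(p, grid)
  Fe <- gamma_transfer(p$tau_e, grid)
  Fi <- gamma_transfer(p$tau_i, grid)
  for (k in c(1, 20, 45, length(grid))) {
    A <- matrix(c(1i * w[k] + (Fe[k] / p$tau_e) * p$g_ee,
                  (Fi[k] / p$tau_i) * p$g_ei * Fe[k],
                  -(Fe[k] / p$tau_e) * p$g_ei * Fi[k],
                  1i * w[k] + (Fi[k] / p$tau_i) * p$g_ii),
                2, 2)
    x <- solve(A, c(1 + 0i, 1 + 0i))
    expect_equal(H$H_e[k], x[1], tolerance = 1e-12)
    expect_equal(H$H_i[k], x[2], tolerance = 1e-12)
  }

  # degeneracy guard fires and names the offending frequency
  expect_error(local_transfer(p, grid, det_tol = 1e12),
               "singular at frequency")
})

test_that("model PSD has the dB offset, slowing, and continuity properties", {
  grid <- analysis_grid()
  p <- stable_params()

  # noise_sd x10 shifts the dB spectrum by exactly +20 dB
  s1 <- model_psd_db(p, grid)
  p10 <- nmm_params(tau_e_ms = 11, tau_i_ms = 10, g_ee = 1.29, g_ii = 1.46,
                    noise_sd = 10)
  s10 <- model_psd_db(p10, grid)
  d <- s10$psd_db - s1$psd_db
  expect_equal(mean(d), 20, tolerance = 1e-9)
  expect_lt(max(d) - min(d), 1e-9)

  # larger time-constants concentrate power at low frequencies: the
  # fraction of 1-35 Hz linear power above 8 Hz drops (brute-force
  # trapezoidal integration of the linear spectra)
  frac_above8 <- function(tau_ms) {
    s <- model_psd_db(nmm_params(tau_e_ms = tau_ms, tau_i_ms = tau_ms),
                      grid)
    lin <- 10^(s$psd_db / 10)
    trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
    f <- as.numeric(grid)
    trapz(f[f >= 8], lin[f >= 8]) / trapz(f, lin)
  }
  expect_lt(frac_above8(30), frac_above8(10))

  # no hidden branch discontinuities: 1e-6 relative perturbations move
  # the spectrum by < 1e-3 dB everywhere
  base <- model_psd_db(p, grid)$psd_db
  fields <- list(tau_e_ms = 11, tau_i_ms = 10, g_ee = 1.29, g_ii = 1.46)
  for (nm in names(fields)) {
    pert <- fields
    pert[[nm]] <- pert[[nm]] * (1 + 1e-6)
    s2 <- model_psd_db(do.call(nmm_params, pert), grid)$psd_db
    expect_lt(max(abs(s2 - base)), 1e-3)
  }

  # independent-drive wiring adds powers instead of amplitudes
  H <- local_transfer(p, grid)
  si <- model_psd_db(p, grid, noise_mode = "independent")
  expect_equal(si$psd_db, 10 * log10(Mod(H$H_e)^2 + Mod(H$H_i)^2),
               tolerance = 1e-12)
})

test_that("pole analysis separates stationary from divergent regimes", {
  # canonical starting values: right-half-plane resonance
  st <- nmm_stability(nmm_params())
  expect_gt(st$max_re, 0)
  expect_false(st$stable)
  # the stable fixture really is stable
  st2 <- nmm_stability(stable_params())
  expect_lt(st2$max_re, 0)
  expect_length(st2$poles, 10)
})

test_that("time-domain twin is reproducible and flags divergence", {
  # all gains and noise zero: no term survives, signals stay at the
  # initial values
  p0 <- nmm_params(tau_e_ms = 17, tau_i_ms = 17, g_ee = 0, g_ii = 0,
                   g_ei = 0, noise_sd = 0)
  sim <- simulate_time_domain(p0, sample_rate = 200, duration = 10,
                              seed = 1, init = c(0.5, -0.25), substeps = 1)
  expect_equal(length(sim$x_e), 2000)
  expect_true(all(sim$x_e == 0.5))
  expect_true(all(sim$x_i == -0.25))

  # bit-identical traces for a fixed seed
  p <- stable_params()
  s1 <- simulate_time_domain(p, 600, 10, seed = 7)
  s2 <- simulate_time_domain(p, 600, 10, seed = 7)
  expect_identical(s1$x_e, s2$x_e)
  expect_identical(s1$x_i, s2$x_i)
  s3 <- simulate_time_domain(p, 600, 10, seed = 8)
  expect_false(identical(s1$x_e, s3$x_e))

  # unstable parameter regime (canonical starting values) diverges
  expect_error(simulate_time_domain(nmm_params(), 600, 10, seed = 1),
               "unstable")

  expect_error(simulate_time_domain(p, 100, 60), ">= 200")
  expect_error(simulate_time_domain(p, 600, 5), ">= 10")
})

test_that("closed-form spectrum matches the Welch spectrum of a simulation", {
  p <- stable_params()
  sim <- simulate_time_domain(p, sample_rate = 600, duration = 300,
                              seed = 21)
  x <- (sim$x_e + sim$x_i)[-seq_len(20 * 600)]   # drop transient
  emp <- compute_psd_db(x, 600, window_s = 4)
  mod <- model_psd_db(p, freq_grid(emp$grid))
  expect_gt(cor(emp$psd_db, mod$psd_db), 0.99)
  d <- emp$psd_db - mod$psd_db
  expect_lt(sqrt(mean((d - mean(d))^2)), 1)
})

test_that("parameter container validates and round-trips its units", {
  p <- nmm_params(tau_e_ms = 12.5, tau_i_ms = 20, g_ee = 1.5, g_ii = 3)
  expect_equal(p$tau_e, 0.0125)   # stored in seconds
  li <- as.list(p)
  expect_equal(li$tau_e_ms, 12.5)
  expect_equal(as_nmm_params(li)$tau_i, p$tau_i)

  expect_error(nmm_params(tau_e_ms = -1), "positive")
  expect_error(nmm_params(tau_i_ms = 0), "positive")
  expect_error(nmm_params(g_ee = -0.1), "non-negative")
  expect_error(nmm_params(noise_sd = -2), "non-negative")
  expect_error(freq_grid(c(2, 1)), "increasing")
  expect_error(freq_grid(c(-1, 3)), "positive")
})
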