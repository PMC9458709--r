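test_that("the decay model matches its closed forms and a quadrature oracle", {
  m <- decay_model(amplitudes = 100, lifetimes = 500, background = 10)
  expect_equal(model_decay(m, 0), 110)                 # amplitude + background
  expect_equal(model_decay(m, 500), 100 / exp(1) + 10) # value at t = tau
  # delta IRF reproduces the closed-form multi-exponential exactly
  m2 <- decay_model(c(3, 7), c(100, 900))
  t <- seq(0, 4000, by = 7)
  expect_equal(model_decay(m2, t), 3 * exp(-t / 100) + 7 * exp(-t / 900),
               tolerance = 1e-14)
  # Gaussian IRF equals brute-force numerical convolution
  sigma <- 200 * phycofret:::FWHM_TO_SIGMA
  m3 <- decay_model(1, 800, irf_fwhm = 200, irf_center = 600)
  tt <- seq(0, 5000, by = 50)
  oracle <- quadrature_decay(tt, 800, 600, sigma)
  keep <- oracle > max(oracle) * 1e-12   # above quadrature underflow
  expect_lt(max(abs(model_decay(m3, tt)[keep] - oracle[keep]) / oracle[keep]),
            1e-6)
  expect_error(decay_model(1, -5), "lifetimes")
})

test_that("mean lifetimes reconcile with the published component tables", {
  # single component: both means equal the lifetime
  expect_equal(unname(mean_lifetimes(data.frame(amplitude = 2, lifetime = 350))),
               c(350, 350))
  # recombinant-trimer-paper rows: intensity-weighted matches printed <tau>
  wt_na <- mean_lifetimes(data.frame(amplitude = c(0.82, 0.18),
                                     lifetime = c(164, 410)))
  expect_equal(unname(wt_na["tau_mean_intensity"]), 251, tolerance = 0.01)
  k6a_na <- mean_lifetimes(data.frame(amplitude = c(0.77, 0.23),
                                      lifetime = c(163, 499)))
  expect_equal(unname(k6a_na["tau_mean_intensity"]), 324, tolerance = 0.01)
  expect_error(mean_lifetimes(data.frame(amplitude = c(0, 0),
                                         lifetime = c(1, 2))), "zero")
})

test_that("intensity-weighted mean is never below the amplitude-weighted mean", {
  set.seed(17)
  for (i in 1:200) {
    k <- sample(1:4, 1)
    mt <- mean_lifetimes(data.frame(amplitude = runif(k, 0.01, 5),
                                    lifetime = 10^runif(k, 0, 4)))
    expect_gte(mt["tau_mean_intensity"],
               mt["tau_mean_amplitude"] * (1 - 1e-12))
  }
})

test_that("noiseless decays are recovered essentially exactly", {
  sp <- decay_spec(components = list(c(1, 1870)), irf_fwhm = 0, irf_center = 0,
                   n_channels = 2048, channel_width = 5, total_counts = 1e6,
                   noise = "none")
  d <- simulate_decay(sp)
  f <- fit_decay(d$time_ps, d$counts, n_components = 1, irf_fwhm = 0)
  expect_lt(abs(f$components$lifetime - 1870) / 1870, 0.001)
  expect_equal(f$components$rel_amplitude, 1)
  expect_false(f$degenerate)
})

test_that("reconvolution recovers the recombinant-trimer generator parameters", {
  spec <- decay_spec(components = list(c(0.82, 164), c(0.18, 410)),
                     irf_fwhm = 200, n_channels = 4096, channel_width = 1,
                     total_counts = 1e6, seed = 301)
  d <- simulate_decay(spec)
  f <- fit_decay(d$time_ps, d$counts, n_components = 2, irf_fwhm = 200,
                 irf_center = attr(d, "irf_center"))
  expect_lt(abs(f$components$lifetime[1] - 164) / 164, 0.05)
  expect_lt(abs(f$components$lifetime[2] - 410) / 410, 0.05)
  expect_lt(abs(f$components$rel_amplitude[1] - 0.82), 0.05)
  expect_equal(sum(f$components$rel_amplitude), 1, tolerance = 1e-9)
  expect_gte(f$tau_mean_intensity, f$tau_mean_amplitude)
})

test_that("reduced chi-squared of correctly specified Poisson fits sits near 1", {
  chi2 <- vapply(1:10, function(s) {
    spec <- decay_spec(components = list(c(0.82, 164), c(0.18, 410)),
                       irf_fwhm = 200, n_channels = 4096, channel_width = 1,
                       total_counts = 1e6, seed = s)
    d <- simulate_decay(spec)
    fit_decay(d$time_ps, d$counts, 2, 200, attr(d, "irf_center"))$reduced_chi2
  }, numeric(1))
  expect_true(all(chi2 > 0.8 & chi2 < 1.2))
})

test_that("fits are invariant to a co-shifted time origin", {
  spec <- decay_spec(components = list(c(0.82, 164), c(0.18, 410)),
                     irf_fwhm = 200, n_channels = 2048, channel_width = 2,
                     total_counts = 5e5, seed = 41)
  d <- simulate_decay(spec)
  f0 <- fit_decay(d$time_ps, d$counts, 2, 200, attr(d, "irf_center"))
  f1 <- fit_decay(d$time_ps + 750, d$counts, 2, 200,
                  attr(d, "irf_center") + 750)
  expect_equal(f1$components$lifetime, f0$components$lifetime,
               tolerance = 1e-4)
  expect_equal(f1$components$rel_amplitude, f0$components$rel_amplitude,
               tolerance = 1e-4)
})

test_that("pure background is flagged degenerate and invalid inputs are rejected", {
  set.seed(9)
  y <- rpois(800, 40)
  f <- fit_decay((0:799) * 2, y, n_components = 2, irf_fwhm = 0)
  expect_true(f$degenerate)
  expect_equal(f$background, 40, tolerance = 0.1 * 40)
  expect_error(fit_decay((0:9), rpois(10, 5), n_components = 2), "too few")
  expect_error(fit_decay((0:99), c(-1, rpois(99, 5))), "non-negative")
  expect_error(fit_decay((0:499) * 2, rpois(500, 5), n_components = 5))
})

test_that("transient fits recover the picosecond component on a short window", {
  sp <- decay_spec(components = list(c(0.6, 0.2), c(0.4, 2.9)),
                   irf_fwhm = 0.2, irf_center = 0, n_channels = 500,
                   channel_width = 0.005, t_min = -0.5, noise = "gaussian",
                   noise_sigma = 0.01, seed = 71)
  ta <- simulate_transient(sp)
  f <- fit_transient(ta$time_ps, ta$dT, irf_fwhm = 0.2, n_components = 2)
  expect_lt(abs(f$components$lifetime[2] - 2.9) / 2.9, 0.10)
  expect_false(any(f$components$unresolved))
  # amplitude fractions of the generator are recovered
  expect_equal(f$components$rel_amplitude, c(0.6, 0.4), tolerance = 0.05)
})

test_that("components much slower than the window are reported as unresolved lower bounds", {
  sp <- decay_spec(components = list(c(0.6, 0.2), c(0.4, 50)),
                   irf_fwhm = 0.2, irf_center = 0, n_channels = 500,
                   channel_width = 0.005, t_min = -0.5, noise = "gaussian",
                   noise_sigma = 0.01, seed = 72)
  ta <- simulate_transient(sp)
  f <- fit_transient(ta$time_ps, ta$dT, irf_fwhm = 0.2, n_components = 2)
  expect_true(f$components$unresolved[2])
  expect_gt(f$components$lifetime[2], 5)   # lower bound exceeds the window
})

test_that("noiseless transients are recovered exactly and fix_fast is honoured", {
  sp <- decay_spec(components = list(c(1, 1)), irf_fwhm = 0.2, irf_center = 0,
                   n_channels = 600, channel_width = 0.01, t_min = -0.5,
                   noise = "none")
  ta <- simulate_transient(sp)
  f <- fit_transient(ta$time_ps, ta$dT, irf_fwhm = 0.2, n_components = 1)
  expect_lt(abs(f$components$lifetime - 1) / 1, 0.001)

  sp2 <- decay_spec(components = list(c(0.6, 0.2), c(0.4, 2.9)),
                    irf_fwhm = 0.2, irf_center = 0, n_channels = 500,
                    channel_width = 0.005, t_min = -0.5, noise = "gaussian",
                    noise_sigma = 0.01, seed = 73)
  ta2 <- simulate_transient(sp2)
  f2 <- fit_transient(ta2$time_ps, ta2$dT, irf_fwhm = 0.2, n_components = 2,
                      fix_fast = 0.2)
  expect_equal(f2$components$lifetime[1], 0.2)
  expect_lt(abs(f2$components$lifetime[2] - 2.9) / 2.9, 0.10)
})

test_that("a measured IRF histogram reproduces the analytic Gaussian-IRF fit", {
  spec <- decay_spec(components = list(c(0.82, 164), c(0.18, 410)),
                     irf_fwhm = 200, n_channels = 2048, channel_width = 2,
                     total_counts = 1e6, seed = 314)
  d <- simulate_decay(spec)
  sigma <- 200 * phycofret:::FWHM_TO_SIGMA
  irf_meas <- data.frame(time = d$time_ps,
                         counts = dnorm(d$time_ps, attr(d, "irf_center"), sigma))
  fg <- fit_decay(d$time_ps, d$counts, 2, irf_fwhm = 200,
                  irf_center = attr(d, "irf_center"))
  fm <- fit_decay(d$time_ps, d$counts, 2, irf = irf_meas)
  expect_equal(fm$components$lifetime, fg$components$lifetime,
               tolerance = 0.02)
  expect_equal(fm$components$rel_amplitude, fg$components$rel_amplitude,
               tolerance = 0.02)
  expect_error(predict(fm, newtime = 1:10), "Gaussian")
  expect_error(fit_decay(d$time_ps, d$counts, 2,
                         irf = data.frame(time = -5:-1, counts = 1:5)),
               "no positive mass")
})

test_that("quantum-yield ratios propagate uncertainty in quadrature", {
  expect_equal(qy_ratio(0.5, 0.5)$ratio, 1.0)
  r <- qy_ratio(0.613, 0.500)
  expect_equal(r$ratio, 1.226)
  expect_equal(r$enhancement_percent, 22.6, tolerance = 1e-9)
  u <- qy_ratio(0.5, 0.5, 0.05, 0.05)
  expect_equal(u$sd, sqrt(2) * 0.1, tolerance = 1e-9)
  expect_error(qy_ratio(0, 1), "> 0")
})

test_that("decay_fit methods behave like a standard model object", {
  spec <- decay_spec(components = list(c(1, 400)), irf_fwhm = 200,
                     n_channels = 1024, channel_width = 2,
                     total_counts = 2e5, seed = 88)
  d <- simulate_decay(spec)
  f <- fit_decay(d$time_ps, d$counts, 1, 200, attr(d, "irf_center"))
  expect_named(coef(f), c("amplitude1", "lifetime1", "background"))
  expect_equal(length(fitted(f)), nrow(d))
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, newtime = d$time_ps), fitted(f), tolerance = 1e-12)
  expect_equal(length(residuals(f)), nrow(d))
  expect_equal(residuals(f, "raw"), d$counts - fitted(f))
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_equal(length(sims), 2)
  expect_equal(nrow(sims[[1]]), nrow(d))
  expect_identical(simulate(f, 1, seed = 4), simulate(f, 1, seed = 4))
  expect_output(print(summary(f)), "reduced chi")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
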