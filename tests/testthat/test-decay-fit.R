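test_that("a noiseless mono-exponential is recovered exactly", {
  tg <- seq(0, 40, by = 0.05)
  inst <- instrument_model(time_ns = tg, irf = irf_delta(tg),
                           peak_counts = 1e4, noise = "none")
  prof <- oil_profile("x", list(fluorophore_component("a", 440, 20, 5)), 1)
  dec <- simulate_decay(prof, 440, inst)
  fit <- fit_decay(dec, inst$irf, 1)
  expect_equal(fit$lifetimes, 5, tolerance = 1e-6)
  expect_lt(fit$chi2_reduced, 1e-10)
  expect_equal(fit$fractions, 100)
})

test_that("a noiseless two-exponential reconvolution is recovered to 1e-4", {
  tg <- seq(0, 60, by = 0.05)
  g <- irf_gaussian(tg, center = 2, fwhm = 1)
  t0 <- tg - tg[1]
  model <- tresoil:::conv_causal(g$counts / sum(g$counts),
                                 exp(-t0 / 2) + exp(-t0 / 10))
  dec <- decay_curve(tg, 1e4 * model / max(model))
  fit <- fit_decay(dec, g, 2)
  expect_equal(fit$lifetimes, c(2, 10), tolerance = 1e-4)
  expect_equal(fit$amplitudes[1] / fit$amplitudes[2], 1, tolerance = 1e-4)
})

test_that("lifetimes and fractions are invariant to count scaling", {
  tg <- seq(0, 60, by = 0.05)
  inst <- instrument_model(time_ns = tg, irf = irf_gaussian(tg, center = 1),
                           peak_counts = 1e4, noise = "none")
  dec <- simulate_decay(oil_preset("CO"), 440, inst)
  f1 <- fit_decay(dec, inst$irf, 3)
  dec2 <- decay_curve(tg, dec$counts * 3.7, emission_nm = 440)
  f2 <- fit_decay(dec2, inst$irf, 3)
  expect_equal(f2$lifetimes, f1$lifetimes, tolerance = 1e-4)
  expect_equal(f2$fractions, f1$fractions, tolerance = 1e-3)
  expect_equal(f2$amplitudes / f1$amplitudes, rep(3.7, 3), tolerance = 1e-3)
})

test_that("results are invariant to lifetime initialisation order", {
  tg <- seq(0, 60, by = 0.05)
  inst <- quick_decay_instrument(noise = "poisson", t_max = 60)
  dec <- simulate_decay(oil_preset("CO"), 440, inst, seed = 4)
  f1 <- fit_decay(dec, inst$irf, 3, init = list(tau = c(1, 5, 16)))
  f2 <- fit_decay(dec, inst$irf, 3, init = list(tau = c(16, 1, 5)))
  expect_equal(f1$lifetimes, f2$lifetimes, tolerance = 1e-6)
  expect_false(is.unsorted(f1$lifetimes))
})

test_that("fractional contributions follow the intensity-share formula", {
  expect_equal(fractional_contributions(c(1, 1), c(2, 8)), c(20, 80))
  expect_equal(fractional_contributions(3, 7), 100)
  expect_error(fractional_contributions(c(0, 0), c(1, 2)), "zero")
})

test_that("reduced chi-square behaves as a Pearson statistic", {
  expect_equal(reduced_chi_square(c(10, 20, 30, 40), c(10, 20, 30, 40), 2), 0)
  expect_error(reduced_chi_square(1:3, 1:3, 3), "channels")

  # true-model chi2 over Poisson replicates concentrates near 1
  instN <- quick_decay_instrument(noise = "none")
  instP <- quick_decay_instrument(noise = "poisson")
  truth <- simulate_decay(oil_preset("CO"), 440, instN)
  keep <- truth$counts >= 5
  chis <- vapply(1:200, function(s) {
    y <- simulate_decay(oil_preset("CO"), 440, instP, seed = 200 + s)$counts
    reduced_chi_square(y[keep], truth$counts[keep], 7)
  }, 0)
  expect_equal(mean(chis), 1, tolerance = 0.05)
})

test_that("parsimony selection picks the true component number", {
  tg <- seq(0, 40, by = 0.05)
  instP <- instrument_model(time_ns = tg, irf = irf_gaussian(tg, center = 1),
                            peak_counts = 1e4, noise = "poisson")
  mono <- oil_profile("m", list(fluorophore_component("a", 440, 20, 5)), 1)
  dec <- simulate_decay(mono, 440, instP, seed = 11)
  sel <- select_n_components(dec, instP$irf, candidates = c(1, 2, 3))
  expect_equal(as.integer(sel), 1L)

  # close lifetimes at low counts are under-resolved
  lo <- instrument_model(time_ns = tg, irf = irf_gaussian(tg, center = 1),
                         peak_counts = 100, noise = "poisson")
  two <- oil_profile("t", list(fluorophore_component("a", 440, 20, 4),
                               fluorophore_component("b", 445, 20, 5)), c(1, 1))
  dec2 <- simulate_decay(two, 440, lo, seed = 21)
  sel2 <- select_n_components(dec2, lo$irf, candidates = c(1, 2))
  expect_equal(as.integer(sel2), 1L)

  # the recorded F statistic agrees with direct arithmetic on the scan table
  scan <- attr(sel2, "scan")
  f1 <- fit_decay(dec2, lo$irf, 1)
  f2 <- fit_decay(dec2, lo$irf, 2)
  df1 <- f1$n_channels - 3; df2 <- f2$n_channels - 5
  Fref <- ((f1$sse - f2$sse) / (df1 - df2)) / (f2$sse / df2)
  expect_equal(scan$F[1], Fref, tolerance = 1e-8)
  expect_gt(scan$p[1], 0.05)
})

test_that("uncertainties and the fit window are reported", {
  inst <- quick_decay_instrument(noise = "poisson", t_max = 60)
  dec <- simulate_decay(oil_preset("CO"), 440, inst, seed = 2)
  fit <- fit_decay(dec, inst$irf, 3)
  expect_true(all(is.finite(fit$se_lifetimes)))
  expect_true(all(fit$se_lifetimes > 0))
  expect_true(all(abs(fit$lifetimes - oil_decay_reference("CO")$tau) <
                    10 * pmax(fit$se_lifetimes, 0.02)))
  expect_error(fit_decay(dec, inst$irf, 5), "between 1 and 4")
})
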