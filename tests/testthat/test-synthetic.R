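test_that("adulteration series reproduces the sampling designs", {
  expect_length(adulteration_series(0, 0.50, 0.01), 51)
  expect_length(adulteration_series(0, 0.50, 0.05), 11)
  expect_equal(adulteration_series(0, 0, 0.01), 0)
  expect_error(adulteration_series(0, 0.5, 0), "step")
  expect_error(adulteration_series(0.5, 0, 0.01), "lo")
})

test_that("mixture concentrations follow the volumetric mixing rule", {
  sys <- ideal_two_component_system()
  c0 <- mixture_concentrations(0, sys$base, sys$adulterant)
  c1 <- mixture_concentrations(1, sys$base, sys$adulterant)
  ch <- mixture_concentrations(0.5, sys$base, sys$adulterant)
  expect_equal(unname(c0), sys$base$amplitudes)
  expect_equal(unname(c1), sys$adulterant$amplitudes)
  expect_equal(ch, (c0 + c1) / 2)
  expect_error(mixture_concentrations(1.2, sys$base, sys$adulterant), "\\[0, 1\\]")
})

test_that("a mono-exponential decay with a delta pulse has the closed form", {
  tg <- seq(0, 40, by = 0.05)
  inst <- instrument_model(time_ns = tg, irf = irf_delta(tg),
                           peak_counts = 1e4, noise = "none")
  prof <- oil_profile("x", list(fluorophore_component("a", 440, 20, 5)), 1)
  dec <- simulate_decay(prof, 440, inst)
  i0 <- which.max(dec$counts)
  i5 <- i0 + round(5 / 0.05)
  expect_equal(dec$counts[i5] / dec$counts[i0], exp(-1), tolerance = 1e-10)
  expect_error(simulate_decay(prof, 700, inst), "outside")
})

test_that("IRF convolution matches a direct-sum oracle", {
  tg <- seq(0, 10, by = 0.1)
  box <- irf_boxcar(tg, start = 0.5, width = 1.5)
  inst <- instrument_model(time_ns = tg, irf = box, peak_counts = 1e3,
                           noise = "none")
  prof <- oil_profile("x", list(fluorophore_component("a", 440, 20, 3)), 1)
  dec <- simulate_decay(prof, 440, inst)
  k <- box$counts / sum(box$counts)
  ref <- conv_direct(k, exp(-(tg - tg[1]) / 3))
  expect_equal(dec$counts, ref * (max(dec$counts) / max(ref)), tolerance = 1e-10)
})

test_that("peanut oil decays more slowly than camellia oil at 440 nm", {
  inst <- decay_instrument(noise = "none")
  po <- simulate_decay(oil_preset("PO"), 440, inst)
  co <- simulate_decay(oil_preset("CO"), 440, inst)
  late <- po$time_ns > 30
  expect_equal(max(po$counts), max(co$counts)) # equal peak normalisation
  expect_true(all(po$counts[late] > co$counts[late]))
})

test_that("the assembled tensor has the published 51 x 44 x 100 geometry", {
  sys <- oil_system("PO")
  inst <- instrument_model(noise = "none")
  des <- mixture_design(sys$base, sys$adulterant,
                        adulteration_series(0, 0.50, 0.01), prep_cv = 0)
  cube <- simulate_tres_cube(des, inst)
  expect_identical(dim(cube$counts), c(51L, 44L, 100L))
  expect_length(cube$emission_nm, 44)
  expect_length(cube$time_ns, 100)
  expect_error(mixture_design(sys$base, sys$adulterant, numeric(0)), "nonempty")
})

test_that("a single-sample slice is the decay curve up to overall scale", {
  sys <- ideal_two_component_system()
  inst <- instrument_model(noise = "none")
  des <- mixture_design(sys$base, sys$adulterant, 0, prep_cv = 0)
  cube <- simulate_tres_cube(des, inst)
  j <- which(inst$emission_nm == 430)
  slice <- cube$counts[1, j, ]
  dec <- simulate_decay(sys$base, 430, inst)
  expect_equal(slice / max(slice), dec$counts / max(dec$counts),
               tolerance = 1e-10)
})

test_that("noiseless cubes are exactly trilinear in the generator factors", {
  sys <- oil_system("PO")
  inst <- instrument_model(noise = "none")
  des <- mixture_design(sys$base, sys$adulterant, seq(0, 0.5, 0.1), seed = 3)
  cube <- simulate_tres_cube(des, inst)
  mod <- tresoil:::tres_cube_model(des, inst)
  recon <- array(0, dim(cube$counts))
  for (m in seq_len(ncol(mod$scores))) {
    recon <- recon + outer(mod$scores[, m], outer(mod$emission[, m], mod$time[, m]))
  }
  expect_equal(cube$counts, recon, tolerance = 1e-12)
})

test_that("Poisson noise has the model mean", {
  inst <- quick_decay_instrument(noise = "poisson")
  truth <- simulate_decay(oil_preset("CO"), 440,
                          quick_decay_instrument(noise = "none"))
  reps <- vapply(1:200, function(s) {
    simulate_decay(oil_preset("CO"), 440, inst, seed = s)$counts
  }, numeric(length(truth$counts)))
  bright <- truth$counts >= 1e3
  rel <- abs(rowMeans(reps)[bright] - truth$counts[bright]) / truth$counts[bright]
  expect_lt(max(rel), 0.03)
})

test_that("late-time integrated intensity increases with adulteration", {
  # ideal limit: no preparation error and perfectly stable compounds
  sys <- lapply(oil_system("PO"), function(p) {
    p$components <- lapply(p$components, function(cm) {
      cm$variability <- 0
      cm
    })
    p
  })
  inst <- instrument_model(noise = "none")
  des <- mixture_design(sys$base, sys$adulterant, seq(0, 0.5, 0.01), prep_cv = 0)
  cube <- simulate_tres_cube(des, inst)
  late <- cube$time_ns >= 3
  lti <- apply(cube$counts[, , late], 1, sum)
  expect_true(all(diff(lti) > 0))
})

test_that("presets reproduce the published decay parameters", {
  for (nm in c("PO", "SO", "CO")) {
    p <- oil_preset(nm)
    ref <- oil_decay_reference(nm)
    tau <- vapply(p$components, `[[`, 0, "lifetime")
    expect_equal(tau, ref$tau)
    eff <- p$amplitudes * vapply(p$components, function(cm) {
      cm$brightness * exp(-0.5 * ((440 - cm$emission_center) / cm$emission_width)^2)
    }, 0)
    f <- fractional_contributions(eff, tau)
    # printed fractions rescaled to sum 100 (the SO row sums to 99.46)
    expect_equal(f, 100 * ref$f / sum(ref$f), tolerance = 0.1 / 100)
    expect_true(max(abs(f - ref$f)) < 0.3)
  }
})

test_that("component invariants are enforced", {
  expect_error(fluorophore_component("x", 440, 20, -1), "lifetime")
  expect_error(fluorophore_component("x", 440, 0, 1), "width")
  expect_error(oil_profile("x", list(fluorophore_component("a", 440, 20, 1)),
                           c(0)), "not all zero")
})
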