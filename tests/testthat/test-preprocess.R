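test_that("snv matches its closed form and enforces its contract", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(2, 4, 4, 4, 6)
  expect_equal(snv(x), (x - 4) / sqrt(2))
  expect_error(snv(rep(7, 10)), "zero-variance")
  expect_error(snv(5), "at least 2")
  set.seed(1)
  for (n in c(5, 20, 101)) {
    out <- snv(rnorm(n, 10, 3))
    expect_equal(mean(out), 0, tolerance = 1e-12)
    expect_equal(sd(out), 1, tolerance = 1e-12)
  }
})

test_that("Savitzky-Golay interior weights match the least-squares oracle", {
  w_oracle <- savgol_weights_oracle(5, 2)
  expect_equal(w_oracle, c(-3, 12, 17, 12, -3) / 35)
  # extract the package's interior weights from a unit impulse
  e <- numeric(21); e[11] <- 1
  sm <- savgol_smooth(e, 5, 2)
  expect_equal(sm[9:13], rev(w_oracle), tolerance = 1e-12)
})

test_that("Savitzky-Golay reproduces polynomials everywhere", {
  x <- seq_len(30)
  for (i in 1:5) {
    set.seed(i)
    cf <- rnorm(3)
    y <- cf[1] + cf[2] * x + cf[3] * x^2
    expect_equal(savgol_smooth(y, 5, 2), y, tolerance = 1e-9)
  }
  expect_equal(savgol_smooth(rep(4, 12)), rep(4, 12))
  expect_error(savgol_smooth(1:10, window = 4), "odd")
  expect_error(savgol_smooth(1:10, window = 5, polyorder = 5), "polyorder")
  expect_error(savgol_smooth(1:3, window = 5), "shorter")
})

test_that("cube pretreatment preserves shape and known fixed points", {
  sys <- oil_system("PO")
  inst <- instrument_model(noise = "none")
  des <- mixture_design(sys$base, sys$adulterant, seq(0, 0.5, 0.1), prep_cv = 0)
  cube <- simulate_tres_cube(des, inst)
  expect_equal(pretreat_cube(cube, savgol = FALSE, snv_mode = "off"), cube)

  # quadratic-in-wavelength cube is a fixed point of the smoother
  lam <- inst$emission_nm
  quad <- array(0, c(3, length(lam), 4))
  for (i in 1:3) for (k in 1:4) quad[i, , k] <- i + 0.01 * k * (lam - 400)^2
  qc <- tres_cube(quad, 1:3 / 10, lam, inst$time_ns[1:4])
  expect_equal(pretreat_cube(qc)$counts, qc$counts, tolerance = 1e-9)
})

test_that("smoothing brings a Poisson cube closer to the noiseless truth", {
  sys <- oil_system("PO")
  des <- mixture_design(sys$base, sys$adulterant, seq(0, 0.5, 0.1), seed = 5)
  noisy <- simulate_tres_cube(des, instrument_model(noise = "poisson"))
  truth <- tresoil:::tres_cube_model(des, instrument_model(noise = "none"))$counts
  sm <- pretreat_cube(noisy)
  expect_lt(mean((sm$counts - truth)^2), mean((noisy$counts - truth)^2))
})

test_that("snv modes standardise the intended units", {
  sys <- oil_system("PO")
  des <- mixture_design(sys$base, sys$adulterant, seq(0, 0.5, 0.1), seed = 2)
  cube <- simulate_tres_cube(des, instrument_model(noise = "poisson"))
  ps <- pretreat_cube(cube, savgol = FALSE, snv_mode = "per_sample")
  for (i in seq_along(des$fractions)) {
    expect_equal(mean(ps$counts[i, , ]), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(ps$counts[i, , ])), 1, tolerance = 1e-10)
  }
  pf <- pretreat_cube(cube, savgol = FALSE, snv_mode = "per_slice")
  expect_equal(mean(pf$counts[2, , 10]), 0, tolerance = 1e-10)
  expect_equal(sd(pf$counts[2, , 10]), 1, tolerance = 1e-10)
})

test_that("equivalent steady-state spectra integrate the time mode", {
  X <- array(0, c(2, 5, 6))
  X[, , 3] <- matrix(1:10, 2)
  cube <- tres_cube(X, c(0, 0.1), seq(400, 440, 10), seq(0, 0.5, 0.1))
  expect_equal(equivalent_steady_state(cube), matrix(1:10, 2))

  # additivity
  set.seed(9)
  Y <- array(runif(60), c(2, 5, 6))
  cy <- tres_cube(Y, c(0, 0.1), seq(400, 440, 10), seq(0, 0.5, 0.1))
  cxy <- tres_cube(X + Y, c(0, 0.1), seq(400, 440, 10), seq(0, 0.5, 0.1))
  expect_equal(equivalent_steady_state(cxy),
               equivalent_steady_state(cube) + equivalent_steady_state(cy))

  # sample-wise concatenation commutes
  both <- array(0, c(4, 5, 6))
  both[1:2, , ] <- X; both[3:4, , ] <- Y
  cb <- tres_cube(both, c(0, 0.1, 0.2, 0.3), seq(400, 440, 10), seq(0, 0.5, 0.1))
  expect_equal(equivalent_steady_state(cb),
               rbind(equivalent_steady_state(cube), equivalent_steady_state(cy)))
})

test_that("full-capture mono-exponential spectra follow the geometric series", {
  tg <- seq(0, by = 0.05, length.out = 2000) # tau = 2 >> dt, full capture
  inst <- instrument_model(time_ns = tg, irf = irf_delta(tg),
                           peak_counts = 1e4, noise = "none")
  prof <- oil_profile("x", list(fluorophore_component("a", 450, 25, 2)), 1)
  des <- mixture_design(prof, prof, 0, prep_cv = 0)
  cube <- simulate_tres_cube(des, inst)
  spec <- equivalent_steady_state(cube)[1, ]
  shape <- exp(-0.5 * ((inst$emission_nm - 450) / 25)^2)
  geom <- 1 / (1 - exp(-0.05 / 2)) # sum_k exp(-k dt / tau), k >= 0
  pred <- shape * 1e4 * geom / max(shape * 1e4 * geom) * max(spec)
  expect_equal(spec, pred, tolerance = 0.01)
  # and the geometric sum itself is within 1% of tau/dt for tau >= 20 dt
  expect_equal(geom, 2 / 0.05, tolerance = 0.013)
})
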