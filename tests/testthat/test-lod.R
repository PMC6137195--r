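make_groups <- function(means, n = 6, sd = 1, seed = 1) {
  set.seed(seed)
  intensity_groups(seq(0, by = 0.01, length.out = length(means)),
                   lapply(means, function(m) rnorm(n, m, sd)))
}

test_that("identical constant groups show no significant differences", {
  g <- intensity_groups(c(0, 0.01, 0.02), replicate(3, rep(5, 6), simplify = FALSE))
  dt <- duncan_test(g)
  expect_false(any(dt$comparisons$significant))
  lod <- determine_lod(g)
  expect_false(lod$detected)
  expect_true(is.na(lod$lod))
})

test_that("an overwhelming separation is declared significant", {
  set.seed(2)
  reps <- list(rnorm(6, 0, 1), rnorm(6, 0, 1) + 100 * sqrt(1 / 6))
  g <- intensity_groups(c(0, 0.01), reps)
  dt <- duncan_test(g)
  expect_true(all(dt$comparisons$significant))
})

test_that("the two-group decision coincides with an LSD test", {
  for (seed in 1:25) {
    set.seed(seed)
    # deltas straddle the critical boundary to exercise both outcomes
    delta <- runif(1, 0.5, 2.5)
    reps <- list(rnorm(6, 0, 1), rnorm(6, delta, 1))
    g <- intensity_groups(c(0, 0.01), reps)
    dt <- duncan_test(g, alpha = 0.05)
    # independent LSD computation from first principles
    v <- unlist(reps)
    grp <- rep(1:2, each = 6)
    mse <- sum(tapply(v, grp, function(z) sum((z - mean(z))^2))) / 10
    lsd <- qt(0.975, 10) * sqrt(2 * mse / 6)
    lsd_sig <- abs(mean(reps[[1]]) - mean(reps[[2]])) > lsd
    expect_identical(dt$comparisons$significant, lsd_sig)
    # qtukey(., 2, df) = sqrt(2) * qt identity holds to quadrature accuracy
    expect_equal(dt$comparisons$critical, lsd, tolerance = 1e-6)
  }
})

test_that("the noiseless limit detects the smallest nonzero level", {
  sys <- oil_system("PO")
  inst <- instrument_model(noise = "none")
  g <- simulate_intensity_groups(sys$base, sys$adulterant, inst,
                                 seq(0, 0.05, 0.01), seed = 1)
  lod <- determine_lod(g)
  expect_true(lod$detected)
  expect_equal(lod$lod, 1)
})

test_that("overwhelming noise yields the not-detected sentinel", {
  set.seed(4)
  g <- intensity_groups(seq(0, 0.05, 0.01),
                        lapply(1 + seq(0, 0.05, 0.01), function(m) rnorm(6, m, 50)))
  lod <- determine_lod(g)
  expect_false(lod$detected)
})

test_that("the detection limit does not worsen with more photons", {
  sys <- oil_system("PO")
  lods <- vapply(c(1e2, 1e3, 1e4), function(pk) {
    inst <- instrument_model(noise = "poisson", peak_counts = pk)
    g <- simulate_intensity_groups(sys$base, sys$adulterant, inst,
                                   seq(0, 0.10, 0.01), n_replicates = 6,
                                   seed = 7)
    lod <- determine_lod(g)
    if (lod$detected) lod$lod else Inf
  }, 0)
  expect_true(all(diff(lods) <= 0))
  expect_true(is.finite(lods[3]))
})

test_that("the test keeps its size under the null", {
  # two-group case: per-comparison level is exactly alpha (the LSD identity)
  hits2 <- 0L
  for (r in 1:500) {
    set.seed(r)
    g <- intensity_groups(c(0, 0.01), list(rnorm(6), rnorm(6)))
    hits2 <- hits2 + as.integer(any(duncan_test(g)$comparisons$significant))
  }
  se2 <- 2 * sqrt(0.05 * 0.95 / 500)
  expect_gt(hits2 / 500, 0.05 - se2)
  expect_lt(hits2 / 500, 0.05 + se2)

  # multi-group case: the span-dependent critical ranges keep the designated
  # genuine-vs-lowest comparison conservative (never inflated above alpha)
  hits5 <- 0L
  for (r in 1:500) {
    set.seed(r)
    g <- intensity_groups(seq(0, 0.04, 0.01), lapply(1:5, function(i) rnorm(6)))
    tab <- duncan_test(g)$comparisons
    row <- tab[tab$level_1 == 0 & tab$level_2 == 0.01, ]
    hits5 <- hits5 + as.integer(row$significant)
  }
  expect_lt(hits5 / 500, 0.05 + se2)
  expect_gt(hits5 / 500, 0)
})

test_that("detection power increases with the true separation", {
  power <- vapply(c(0, 0.75, 1.5, 3), function(delta) {
    det <- vapply(1:150, function(r) {
      set.seed(1000 * delta + r)
      g <- intensity_groups(c(0, 0.01),
                            list(rnorm(6, 0, 1), rnorm(6, delta, 1)))
      determine_lod(g)$detected
    }, TRUE)
    mean(det)
  }, 0)
  expect_true(all(diff(power) >= 0))
  expect_lt(power[1], 0.2)
  expect_gt(power[4], 0.95)
})

test_that("group containers validate their invariants", {
  expect_error(intensity_groups(c(0, 0.01), list(1:6)), "mismatch")
  expect_error(intensity_groups(0, list(1:6)), "at least 2 groups")
  expect_error(intensity_groups(c(0, 0.01), list(1:6, 3)), "replicates")
  expect_error(determine_lod(intensity_groups(c(0.01, 0.02),
                                              list(1:6, 2:7))), "level 0")
})
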