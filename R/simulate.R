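#' Inclusive arithmetic grid of adulteration levels
#'
#' The adulteration designs used throughout are inclusive grids of volume
#' fractions, e.g. 0-50 % v/v at a 1 % gradient (51 samples) for training and
#' at a 5 % gradient (11 samples) for external testing.
#'
#' @param lo,hi lowest and highest level (volume fraction), `lo <= hi`.
#' @param step positive gradient (volume fraction).
#' @return numeric vector `lo, lo+step, ..., hi`.
#' @export
#' @examples
#' length(adulteration_series(0, 0.50, 0.01)) # 51
adulteration_series <- function(lo, hi, step) {
  if (step <= 0) stop_arg("step must be > 0")
  if (lo > hi) stop_arg("lo must be <= hi")
  lo + step * seq(0, floor((hi - lo) / step + 1e-9))
}

#' Define an adulteration mixture design
#'
#' @param base genuine oil ([oil_profile()]), e.g. camellia oil.
#' @param adulterant adulterating oil over compatible components.
#' @param fractions unique adulteration levels in `[0, 1]` (v/v).
#' @param seed integer seed controlling preparation error and counting noise.
#' @param prep_cv relative standard deviation of the per-sample preparation
#'   error applied multiplicatively to each component concentration
#'   (default 0.01, i.e. 1 % volumetric/gravimetric accuracy; 0 for ideal
#'   mixtures). Independently prepared samples never realise the nominal
#'   mixing rule exactly; this term reproduces that sample-to-sample
#'   heterogeneity.
#' @return An object of class `"mixture_design"`.
#' @export
mixture_design <- function(base, adulterant, fractions, seed = 1L,
                           prep_cv = 0.01) {
  if (length(fractions) < 1L) stop_arg("fractions must be nonempty")
  if (any(fractions < 0 | fractions > 1)) stop_arg("fractions must lie in [0, 1]")
  if (anyDuplicated(fractions)) stop_arg("fractions must be unique")
  if (prep_cv < 0) stop_arg("prep_cv must be >= 0")
  structure(
    list(base = base, adulterant = adulterant,
         fractions = as.numeric(fractions), seed = as.integer(seed),
         prep_cv = prep_cv),
    class = "mixture_design"
  )
}

# Align two profiles on the union of their components (matched by name).
# Returns the component list and the two amplitude vectors over the union.
component_union <- function(base, adulterant) {
  nb <- vapply(base$components, `[[`, "", "name")
  na <- vapply(adulterant$components, `[[`, "", "name")
  nm <- union(nb, na)
  comps <- vector("list", length(nm))
  amp_b <- amp_a <- numeric(length(nm))
  for (i in seq_along(nm)) {
    ib <- match(nm[i], nb)
    ia <- match(nm[i], na)
    comps[[i]] <- if (!is.na(ib)) base$components[[ib]] else adulterant$components[[ia]]
    if (!is.na(ib)) amp_b[i] <- base$amplitudes[ib]
    if (!is.na(ia)) amp_a[i] <- adulterant$amplitudes[ia]
    if (!is.na(ib) && !is.na(ia)) {
      cb <- base$components[[ib]]; ca <- adulterant$components[[ia]]
      if (!isTRUE(all.equal(cb[c("emission_center", "emission_width", "lifetime")],
                            ca[c("emission_center", "emission_width", "lifetime")]))) {
        stop_arg("component '%s' differs between base and adulterant", nm[i])
      }
    }
  }
  list(components = comps, names = nm, base = amp_b, adulterant = amp_a)
}

#' Volumetric mixing of component concentrations
#'
#' Concentrations mix linearly with the adulteration level:
#' `c(x) = (1 - x) * c_base + x * c_adulterant`, taken over the union of the
#' two profiles' components.
#'
#' @param x adulteration level in `[0, 1]` (v/v).
#' @param base,adulterant [oil_profile()]s.
#' @return named nonnegative concentration vector.
#' @export
mixture_concentrations <- function(x, base, adulterant) {
  if (x < 0 || x > 1) stop_arg("x must lie in [0, 1]")
  u <- component_union(base, adulterant)
  stats::setNames((1 - x) * u$base + x * u$adulterant, u$names)
}

# K x M matrix of IRF-convolved mono-exponential time profiles.
component_time_profiles <- function(components, instrument) {
  t0 <- instrument$time_ns - instrument$time_ns[1]
  k <- irf_kernel(instrument$irf)
  vapply(components, function(cm) conv_causal(k, exp(-t0 / cm$lifetime)),
         numeric(length(t0)))
}

# J x M matrix of brightness-weighted emission profiles.
component_emission_profiles <- function(components, wavelength_nm) {
  vapply(components,
         function(cm) cm$brightness * emission_shape(cm, wavelength_nm),
         numeric(length(wavelength_nm)))
}

#' Simulate a single fluorescence decay curve
#'
#' Forward model of a time-correlated single photon counting measurement of
#' one oil at one emission wavelength: a superposition of mono-exponential
#' component decays weighted by concentration, brightness and emission shape,
#' convolved with the IRF, scaled so the brightest channel expects
#' `peak_counts`, and (optionally) Poisson-distributed.
#'
#' @param profile an [oil_profile()].
#' @param wavelength observation wavelength (nm), inside the instrument's
#'   emission range.
#' @param instrument an [instrument_model()].
#' @param seed seed for the counting noise (ignored when `noise = "none"`).
#' @return A [decay_curve()].
#' @export
simulate_decay <- function(profile, wavelength, instrument, seed = NULL) {
  rng <- range(instrument$emission_nm)
  if (wavelength < rng[1] || wavelength > rng[2]) {
    stop_arg("wavelength %.1f nm outside the emission grid [%.1f, %.1f]",
             wavelength, rng[1], rng[2])
  }
  eff <- profile$amplitudes *
    vapply(profile$components, function(cm) {
      cm$brightness * emission_shape(cm, wavelength)
    }, 0)
  ct <- component_time_profiles(profile$components, instrument)
  model <- pmax(drop(ct %*% eff), 0) # clip FFT rounding error
  model <- model * (instrument$peak_counts / max(model))
  counts <- if (instrument$noise == "poisson") {
    with_seed(seed, stats::rpois(length(model), model))
  } else {
    model
  }
  decay_curve(instrument$time_ns, counts, emission_nm = wavelength)
}

#' Construct a TRES data cube
#'
#' A three-way array of photon counts indexed sample x emission wavelength x
#' decay time, with its axis grids and the adulteration level of each sample.
#'
#' @param counts nonnegative I x J x K array.
#' @param fractions length-I adulteration levels (v/v).
#' @param emission_nm length-J wavelength grid (nm).
#' @param time_ns length-K decay-time grid (ns).
#' @param noise noise model used to generate the counts (bookkeeping).
#' @param seed seed used (bookkeeping).
#' @return An object of class `"tres_cube"`.
#' @export
tres_cube <- function(counts, fractions, emission_nm, time_ns,
                      noise = "none", seed = NULL) {
  counts <- as.array(counts)
  storage.mode(counts) <- "double"
  if (length(dim(counts)) != 3L) stop_arg("counts must be a 3-way array")
  if (!identical(dim(counts),
                 c(length(fractions), length(emission_nm), length(time_ns)))) {
    stop_arg("cube dimensions must match grid lengths")
  }
  check_uniform_grid(emission_nm, "emission")
  check_uniform_grid(time_ns, "time")
  structure(
    list(counts = counts, fractions = as.numeric(fractions),
         emission_nm = as.numeric(emission_nm), time_ns = as.numeric(time_ns),
         noise = noise, seed = seed),
    class = "tres_cube"
  )
}

#' @export
print.tres_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("TRES cube: %d samples x %d emission channels x %d time channels\n",
              d[1], d[2], d[3]))
  cat(sprintf("  emission %g-%g nm, decay window %g-%g ns, noise: %s\n",
              min(x$emission_nm), max(x$emission_nm),
              min(x$time_ns), max(x$time_ns), x$noise))
  cat(sprintf("  adulteration levels: %s%%\n",
              paste(utils::head(round(100 * x$fractions, 2), 6), collapse = ", ")))
  invisible(x)
}

# Noiseless expected cube plus its trilinear factors. The cube is exactly
# trilinear: concentrations (with preparation error) x emission bands x
# IRF-convolved decays.
tres_cube_model <- function(design, instrument) {
  u <- component_union(design$base, design$adulterant)
  conc <- t(vapply(design$fractions,
                   function(x) (1 - x) * u$base + x * u$adulterant,
                   numeric(length(u$names))))
  # per-sample concentration heterogeneity: uniform preparation error plus
  # each compound's own stability (both relative standard deviations)
  cv <- sqrt(design$prep_cv^2 +
               vapply(u$components, `[[`, 0, "variability")^2)
  if (any(cv > 0)) {
    err <- with_seed(design$seed + 1000003L,
                     matrix(stats::rnorm(length(conc), 1,
                                         rep(cv, each = nrow(conc))),
                            nrow(conc)))
    conc <- conc * pmax(err, 0)
  }
  B <- component_emission_profiles(u$components, instrument$emission_nm)
  C <- component_time_profiles(u$components, instrument)
  # one global counting scale, calibrated on the pure base oil's peak channel
  scale <- instrument$peak_counts / max(B %*% diag(u$base, length(u$base)) %*% t(C))
  A <- conc * scale
  X1 <- A %*% t(khatri_rao(C, B))
  list(counts = array(X1, c(nrow(conc), nrow(B), nrow(C))),
       scores = A, emission = B, time = C, components = u)
}

#' Simulate a TRES adulteration cube
#'
#' Generates the full sample x emission x time array for a mixture design:
#' the noiseless cube is exactly trilinear (concentrations x emission bands x
#' IRF-convolved decays), globally scaled so the pure base oil's brightest
#' channel expects `peak_counts`, then Poisson noise is applied channel-wise.
#'
#' @param design a [mixture_design()].
#' @param instrument an [instrument_model()].
#' @return A [tres_cube()].
#' @export
simulate_tres_cube <- function(design, instrument) {
  mod <- tres_cube_model(design, instrument)
  counts <- mod$counts
  if (instrument$noise == "poisson") {
    counts <- array(with_seed(design$seed,
                              stats::rpois(length(counts), pmax(counts, 0))),
                    dim(counts))
  }
  tres_cube(counts, design$fractions, instrument$emission_nm,
            instrument$time_ns, noise = instrument$noise, seed = design$seed)
}

#' Simulate replicate intensity summaries for LOD analysis
#'
#' For each adulteration level, draws `n_replicates` independent noisy cubes
#' of that single sample and reduces each to a scalar intensity: the total
#' integrated intensity (default) or the integral over the late part of the
#' decay window, where a long-lifetime adulterant is most visible.
#'
#' @param base,adulterant [oil_profile()]s.
#' @param instrument an [instrument_model()].
#' @param levels adulteration levels (v/v), must include 0 for LOD use.
#' @param n_replicates replicates per level (>= 2).
#' @param summary `"total"` or `"late_window"`.
#' @param late_fraction fraction of the decay window counted as "late".
#' @param seed integer seed.
#' @return An [intensity_groups()] object.
#' @export
simulate_intensity_groups <- function(base, adulterant, instrument, levels,
                                      n_replicates = 6,
                                      summary = c("total", "late_window"),
                                      late_fraction = 0.4, seed = 1L) {
  summary <- match.arg(summary)
  design <- mixture_design(base, adulterant, levels, seed = seed)
  mod <- tres_cube_model(design, instrument)
  K <- length(instrument$time_ns)
  keep <- if (summary == "total") seq_len(K) else seq(ceiling((1 - late_fraction) * K), K)
  reps <- with_seed(seed, lapply(seq_along(levels), function(i) {
    slab <- mod$counts[i, , keep, drop = TRUE]
    vapply(seq_len(n_replicates), function(r) {
      if (instrument$noise == "poisson") {
        sum(stats::rpois(length(slab), pmax(slab, 0)))
      } else {
        sum(slab)
      }
    }, 0)
  }))
  intensity_groups(levels, reps)
}
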