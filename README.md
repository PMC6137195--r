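# tresoil

Chemometric analysis of **time-resolved emission fluorescence (TRES)** for
detecting adulteration of camellia oil with cheaper vegetable oils (peanut,
sunflower). Camellia oil commands a premium and is routinely cut with
look-alike oils; steady-state fluorescence struggles at low adulteration
levels because weak adulterant signals are masked by the dominant
fluorophores. Time-resolved measurement separates fluorophores by lifetime
as well as by emission wavelength, so long-lived adulterant markers remain
visible even at a few percent v/v. The package is for analytical chemists
and chemometricians who want a tested, reproducible implementation of this
workflow — including a synthetic TRES generator, since raw spectra for such
studies are rarely deposited.

## What it implements

A TRES series is a three-way array **Z** (sample x emission wavelength x
decay time; the reference design is 51 x 44 x 100). The analysis chain:

1. **Simulation** — mixtures of Gaussian-band, mono-exponential fluorophores;
   decays convolved with the instrument response function (IRF); Poisson
   counting noise; per-sample preparation/compositional heterogeneity;
   pure-oil presets carrying the published three-lifetime decay parameters.
2. **Pretreatment** — Savitzky–Golay smoothing along the emission mode
   (window 5) and standard normal variate options; equivalent steady-state
   spectra by time integration.
3. **Lifetime fitting** — multi-exponential IRF reconvolution
   `y ~ IRF (*) sum_k alpha_k exp(-t / tau_k)` by weighted
   Levenberg–Marquardt, fractional intensity contributions
   `f_k = 100 alpha_k tau_k / sum(alpha tau)`, reduced chi-square, and
   F-test selection of the component number.
4. **PARAFAC** — trilinear decomposition
   `x_ijk = sum_m a_im b_jm c_km + e_ijk` by alternating least squares with
   swamp-mitigating extrapolation, the core consistency diagnostic
   (CORCONDIA) for factor-number selection, and split-half validation via
   Tucker congruence.
5. **Calibration** — a single-hidden-layer neural network from PARAFAC
   sample scores to adulteration level (% v/v), leave-one-out
   cross-validation, and external-test prediction through projection onto
   the fixed training loadings; RMSEC/RMSECV/RMSEP and R²c/R²cv/R²p.
6. **Detection limit** — Duncan's multiple range test on replicate
   intensity series; the LOD is the lowest level significantly different
   from genuine oil.

## Worked example: lifetimes of camellia oil

```r
library(tresoil)
inst  <- decay_instrument()   # 0-60 ns, 0.05 ns channels, Gaussian IRF (FWHM 1 ns)
decay <- simulate_decay(oil_preset("CO"), 440, inst, seed = 1)
fit   <- fit_decay(decay, inst$irf, n = 3)
fit
#> Reconvolution fit, 3 components (chi2_red = 1.0575, shift = -0.003 ns)
#>  tau_ns se_tau f_pct   alpha
#>   1.107 0.0112 42.17 13630.0
#>   5.177 0.0909 37.64  2601.0
#>  16.785 0.2759 20.19   430.3
select_n_components(decay, inst$irf, candidates = c(2, 3, 4))
#> [1] 3
```

The three recovered lifetimes (1.11, 5.18, 16.79 ns) and intensity shares
(42.2/37.6/20.2 %) match the camellia-oil preset the decay was generated
from (1.09, 5.05, 16.43 ns; 41.7/37.3/21.0 %) within the counting-statistics
uncertainty of a 10^4-peak-count measurement, the reduced chi-square is near
1 as it should be for a correctly weighted fit, and the F-test scan picks
three components.

The full pipeline is one call:

```r
run <- run_pipeline(pipeline_config(adulterant = "PO", seed = 42))
run
#> TRES adulteration analysis (PO into CO), 51 + 11 samples
#>   PARAFAC: 4 factors, explained fraction 0.99995
#>   RMSEC  0.866 %   R2c  0.99654
#>   RMSECV 1.355 %   R2cv 0.99152
#>   RMSEP  1.373 %   R2p  0.99246
#>   LOD: 1% (Duncan's test, alpha = 0.05)
```

That is: 51 training mixtures (0–50 % at 1 % steps) and 11 external test
mixtures (5 % steps) are simulated, decomposed at 4 trilinear factors, and
the score-based network predicts the adulteration level with ~1.4 %
cross-validated and external error; the Duncan's-test detection limit under
these noise conditions is the lowest tested level.

## Layout

- `R/` — implementation (generator, pretreatment, decay fitting, PARAFAC,
  calibration, LOD, text-container IO, pipeline).
- `tests/testthat/` — unit, property and acceptance suites; fixtures are
  generated in code.
- `vignettes/tresoil-methods.Rmd` — the models, defaults, design decisions
  and limitations, in detail.
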