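---
title: "Models and methods behind tresoil"
author: "tresoil authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tresoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tresoil)
```

`tresoil` quantifies adulteration of camellia oil (CO) with cheaper vegetable
oils — peanut (PO) or sunflower (SO) — from time-resolved emission
fluorescence (TRES): fluorescence decays recorded by time-correlated single
photon counting (TCSPC) at a ladder of emission wavelengths. A measurement
series forms a three-way photon-count array, samples x emission wavelength x
decay time, and the analysis chain is

simulate (or load) a TRES cube → pretreat → PARAFAC → ANN calibration →
Duncan's-test detection limit.

This vignette explains each model, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the numerical
choices a maintainer should know about. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The forward model of a TRES measurement

Each fluorophore `k` is modelled with a Gaussian emission band `b_k(lambda)`
(max-normalised at its centre), a mono-exponential lifetime `tau_k`, and a
brightness per unit concentration. Because fluorescence at low optical density
obeys Beer's law, the expected counts are a linear superposition over
fluorophores, convolved with the instrument response function (IRF):

```
S(lambda, t) = IRF (*) sum_k N_k * beta_k * b_k(lambda) * exp(-t / tau_k)
```

Instrument factors that are not separately identifiable (excitation power,
optical path, collection geometry, detector efficiency) are folded into the
brightness `beta_k` and the emission shape; the excitation pulse is folded
into the IRF. Observed counts are Poisson with this mean. A single global
counting scale is calibrated so the pure base oil's brightest channel expects
`peak_counts` (default 1e4, a typical TCSPC peak count); intensity is
therefore comparable across samples, which the detection-limit analysis
relies on.

The default grids reproduce the study geometry: emission 380–600 nm at 5 nm
on a half-open grid — 44 channels — and a 100-channel, 0.05 ns decay window
with the pulse near the window start. The stated 380–600 nm range contains 45
five-nanometre points; the half-open convention `[380, 600)` is the one
consistent with a 51 x 44 x 100 array, and the same convention gives 100 time
channels. The published 55–60 ns time window is read as a sub-window of a
longer acquisition whose origin sits at an instrumental delay; the package
works on the window-relative axis with the pulse at the window start
(`irf_gaussian`, FWHM 1 ns, the width of a typical pulsed 370 nm LED).
Single-decay lifetime work uses a longer axis (`decay_instrument()`, 0–60 ns
at 0.05 ns).

### Pure-oil presets and the published decay rows

`oil_preset("PO"/"SO"/"CO")` builds three-component profiles whose lifetimes
and fractional intensity contributions at 440 nm reproduce the published
decay table for the three pure oils. Amplitudes are solved from the intensity
fractions via `f_k = 100 a_k tau_k / sum(a tau)`, corrected for each band's
emission shape at 440 nm. One wrinkle: the SO row's printed fractions sum to
99.46 %, so a normalised fraction vector cannot match them verbatim; the
presets use the printed values as weights and tests compare against the
fractions rescaled to sum 100.

### Sample-to-sample heterogeneity

Real mixture series never realise the nominal volumetric rule
`c(x) = (1 - x) c_base + x c_adulterant` exactly: each sample is separately
weighed and diluted, and the fluorophore content of an oil (especially
oxidation-sensitive species) drifts between preparations. The generator
models this with a multiplicative, per-sample, per-component error whose
relative standard deviation combines a design-level preparation error
(`prep_cv`, default 0.01) with a per-compound `variability`.

This term is not cosmetic. Under ideal mixing the sample-score mode of the
cube is *exactly* affine in the adulteration level — numerical rank 2
regardless of the number of fluorophores. In that regime the trilinear
decomposition of a four-component cube is practically non-identifiable:
alternating least squares stalls in swamps even on noiseless data, and the
core-consistency diagnostic collapses for any model with more than two
factors, including at the true factors. No published workflow of this kind
could behave as reported on such data, so the generator treats compositional
heterogeneity as an essential feature of real sample series, not an optional
nuisance. The ideal limit remains available (`prep_cv = 0`, zero
variabilities; `run_pipeline` uses it when `noise = "none"`) and is used by
the structural tests (exact trilinearity, monotone late-time signal, affine
scores).

### The default four-component adulteration system

`oil_system()` defines four fluorophores shared by base and adulterant, with
emission centres 420/455/490/530 nm and lifetimes 0.6, 2.5, 7 and ~19 ns
(the long lifetime is the adulterant's published longest component: 18.66 ns
for PO, 19.85 ns for SO). Design rationale:

* **Lifetime spacing.** On a 100 x 0.05 ns window, decays with lifetimes
  5.05 ns and 6.14 ns (the literal mid-lifetime pair of CO and PO) have a
  cosine similarity of 0.9994 — indistinguishable in the time mode. The
  default lifetimes keep the published qualitative contrast (adulterant
  components longer-lived than camellia's) while remaining resolvable on the
  analysis window.
* **Markers nearly absent in the genuine oil.** The two long-lived
  components have base amplitudes 0.05 and 0.03 against 2.4 and 1.8 in the
  adulterant — the classical definition of an adulteration marker. This also
  decouples two competing requirements: factor identifiability needs the
  marker scores to carry appreciable independent variation in absolute
  terms, while calibration error scales with their *relative* variation,
  which for a near-absent marker is proportional to the level `x` itself —
  so low-level predictions stay precise.
* **Variabilities** 0.10/0.08 (short-lived, oxidation-sensitive base
  compounds) and 0.045/0.045 (stable long-lived markers) encode compound
  stability.

## Pretreatment

Savitzky–Golay smoothing (window 5, order 2 — the standard mild smoother;
the window is the published choice, the order the standard one for it) is
applied along the emission mode of every (sample, time) fiber, delegated to
`signal::sgolayfilt`, whose boundary handling evaluates the edge polynomial
fits; the 5-point quadratic interior weights (-3, 12, 17, 12, -3)/35 are
asserted against a first-principles least-squares oracle in the tests.
Smoothing along emission is a linear operator on the emission mode, so it
preserves trilinearity exactly.

SNV is implemented in two variants and **off by default** for cubes headed
into PARAFAC. Applying SNV per emission fiber (the strict reading of
"within the emission wavelength's mode") forces every time slice to mean 0
and unit variance, erasing the decay amplitude the method depends on.
Applying it per sample on the unfolded emission x time matrix removes global
intensity shifts, but the subtracted per-sample mean is itself a rank-one
(ones x ones) trilinear term: it raises the trilinear rank of a
four-component cube to five and rescales the sample scores, contradicting
both the factor number the workflow is meant to recover and the linear
score–concentration relationship. Since the simulated instrument has no
baseline drift, nothing is lost by default; both variants remain available
(`snv_mode = "per_sample"` / `"per_slice"`) for data that need them.

`equivalent_steady_state()` collapses the time mode by summation — the
steady-state spectrum a conventional spectrofluorometer would record, up to
scale.

## Multi-exponential reconvolution fitting

`fit_decay()` fits `counts ~ IRF (*) sum alpha_k exp(-t / tau_k)` by
Levenberg–Marquardt least squares (via `minpack.lm`), with:

* log-parameterised amplitudes and lifetimes (positivity by construction),
  lifetimes reported ascending;
* a fitted IRF shift, bounded at ±0.5 ns (standard TCSPC practice);
* a fit window from the IRF peak to the last channel with ≥ 5 counts, which
  stabilises the tail weights;
* multi-start over scaled log-spaced lifetime grids (3 starts by default),
  amplitudes initialised by a weighted linear solve at fixed lifetimes;
* two weighting passes. The first minimises the Pearson-type statistic with
  observed-count (Neyman) weights `1/max(y, 1)`. Neyman weights overweight
  channels that fluctuate low, which drags the long lifetime down by several
  percent — the bias *grows* with acquisition length as low-count tail
  channels accumulate. A second pass therefore refits with model-based
  weights `1/max(yhat, 1)` from the first solution, which removes the bias
  (the tests recover all nine tabulated lifetimes to well under 1 % in the
  seed average).

Standard errors come from the inverse of the weighted Jacobian's Gram matrix
at the optimum, delta-transformed to natural scale. The reported reduced
chi-square is `sum((y - yhat)^2 / max(y, 1)) / (N - 2n - 1)`.

`select_n_components()` picks the most parsimonious component number that
the data support: the smallest candidate whose fit is not significantly
improved by the next one, by a partial F-test on the weighted residual sums
of squares at level 0.05. A component with vanishing amplitude is flagged as
exceeding the information content.

## PARAFAC, core consistency and split-half validation

`parafac()` minimises `sum((x_ijk - sum_m a_im b_jm c_km)^2)` by alternating
least squares: each mode update is the exact least-squares solve against the
Khatri–Rao product of the other two modes (pseudo-inverse fallback for
ill-conditioned Grams). Emission and time loadings are normalised to unit
columns, scale and sign carried by the scores. Defaults: best of 5 starts
(one SVD-based, four random, seeded), convergence at a relative SSE change
below 1e-8, at most 1500 iterations. Because near-collinear factors make
plain ALS crawl ("swamps"), each iteration tries a line-search extrapolation
along the sweep direction and keeps it only when the SSE decreases — the SSE
trace is therefore non-increasing by construction, which a test asserts
iteration by iteration. A nonnegativity-constrained variant (column-wise
HALS on all three modes) is available via `nonneg = TRUE`; the default is
unconstrained, matching the published analysis which states no constraints.

`corcondia()` computes the least-squares Tucker core implied by the PARAFAC
loadings (mode-wise pseudo-inverses, validated in the tests against a
brute-force solve of the full Kronecker normal equations) and returns
`100 (1 - sum((g - superidentity)^2) / sum(g^2))`.

`select_factors()` scans M = 1..6 and selects the factor number that still
meets the consistency threshold while its successor falls below it — i.e.
the last adequate model before the diagnostic collapses. The threshold
default is 50, following the usual reading of the diagnostic (values well
above 50 acceptable, near zero invalid). At this study's counting statistics
the threshold cannot meaningfully be put at 90: the decay profiles on a 5 ns
window are strongly correlated, so the mode-wise pseudo-inverses amplify
Poisson noise into the core, and even at the generator-truth factors the
consistency of the correct four-factor model fluctuates around 45–90 across
noise realisations — while overfactored models collapse to ~0, so the
collapse rule stays sharp. On machine-precision-exact data an overfactored
model's extra factor is unconstrained and its consistency value is
essentially arbitrary; the overfactoring tests therefore add a little
measurement noise, which is what makes the collapse structural.

`split_half()` refits the model on two disjoint sample subsets (odd/even by
default) and compares emission and time loadings after optimal factor
matching by Tucker congruence (exhaustive matching over permutations, signs
aligned pairwise) — the uniqueness-based validation of the trilinear model.

## ANN calibration

Sample scores (4 inputs by default) feed a single-hidden-layer feed-forward
network — `nnet` with 5 sigmoid hidden units and a linear output — trained
on z-scored inputs and response, best of 3 seeded weight initialisations.
The weight decay default is 5e-3: with ~50 training samples of noisy scores,
the net at 1e-4 decay visibly overfits the leave-one-out folds (cross-
validated error roughly doubles), while 5e-3 is in the usual range for
ridge-type regularisation of small chemometric calibrations. The smallest
net that is nonlinear yet stable was preferred over any architecture search.

Cross-validation is leave-one-out over the 51 training samples (standard at
this sample size). External test samples are never refitted into the
trilinear model; `project_scores()` regresses each new sample's unfolded
matrix onto the fixed Khatri–Rao structure of the training loadings, and the
training standardisation is applied inside `predict()`. Metrics follow the
usual definitions: RMSEC/RMSECV/RMSEP are root mean square errors of
calibration, cross-validation and external prediction (in % v/v), with the
corresponding R². ("RMSECP" in the source material is read as RMSEP.)

## Detection limit by Duncan's multiple range test

`duncan_test()` ranks group means and tests each pair against a critical
range that grows with the number of ranks `p` the pair spans:
`R_p = q(1 - alpha_p, p, df) sqrt(MSE / n)`, with Duncan's protection level
`alpha_p = 1 - (1 - alpha)^(p - 1)`, studentized-range quantiles computed
numerically by `qtukey`, the pooled ANOVA mean square within, and the
harmonic mean replicate count. The textbook containment rule applies. For
two groups the decision is provably identical to an LSD t-test (the
`qtukey(., 2, df) = sqrt(2) qt` identity), which the tests verify
numerically; for a designated pair inside a larger null family the
span-based ranges are conservative (simulated size ~0.03 at alpha 0.05),
which the tests assert as an upper bound rather than exact-alpha
calibration.

`determine_lod()` applies the published rule: the detection limit is the
lowest nonzero level whose replicate intensity group differs significantly
from the genuine-oil group; if none does, a not-detected sentinel is
returned. The intensity summary is the total integrated cube intensity per
replicate by default, with a late-window variant (most sensitive to a
long-lived adulterant) as an option. The source material reports no
replication scheme; the package simulates replicates (default 6 per level)
as repeated instrumental scans of one preparation per level, and a real-data
LOD would need genuine replicate measurements. A zero-variance guard floors
the MSE at 1e-12 of the squared grand mean so the noiseless limit stays
decidable. Because the replicate noise of the original instrument is
unreported, the published 3 % LOD is reproducible only as a procedure, not
as a number; under the default synthetic conditions the pipeline detects 1 %.

## The pipeline and reproducibility

`run_pipeline(pipeline_config())` chains all stages with one master seed
(train cube, test cube and LOD series derive their seeds from it), returns
all six calibration metrics, per-sample predictions, the LOD and a manifest
with sample counts, stage seeds and timings, and — when `out_dir` is set —
persists the cubes (single-file delimited-text container with `#`-header
metadata; lossless round trip) and JSON reports. Identical config + seed
give byte-identical reports. An HDF5 container was considered and set aside:
no HDF5 interface is available to this package's dependency set, and the
text container holds the same datasets and attributes.

Problem sizes used by the shipped checks: the full 51 x 44 x 100 design for
the end-to-end run, the factor scan and split-half validation; 20 noise
realisations per oil for lifetime recovery; 10 for model-order selection;
500 Monte-Carlo runs for the test-size checks; smaller cubes for the
structural PARAFAC oracles.

## Known limitations

* Emission bands are Gaussian and lifetimes wavelength-independent by
  construction; scatter/Raman bands, inner-filter effects (the study diluted
  to OD ≤ 0.1 precisely to avoid them) and detector afterpulsing are not
  simulated. Passing tests therefore say nothing about scatter handling on
  real instruments.
* The four-component system is a model of the study's *statistical*
  structure, not an assignment of real oil fluorophores.
* CORCONDIA at these counting statistics is intrinsically noisy for the
  correct model (see above); the factor-number scan is reliable in the
  collapse it detects, not in the absolute consistency value.
* Global (multi-wavelength) lifetime analysis, lifetime distributions,
  PARAFAC2 and missing-data handling are out of scope.
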