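#' Define a fluorophore component
#'
#' A fluorophore is modelled by a Gaussian emission band (max-normalised to 1
#' at its centre) and a mono-exponential fluorescence lifetime. Brightness is
#' the effective emissive amplitude per unit concentration; instrument factors
#' (collection geometry, detector efficiency, excitation power) that are not
#' separately identifiable are folded into it.
#'
#' @param name character label.
#' @param emission_center centre of the Gaussian emission band (nm).
#' @param emission_width Gaussian sigma of the band (nm), > 0.
#' @param lifetime fluorescence lifetime tau (ns), > 0.
#' @param brightness effective amplitude per unit concentration, >= 0.
#' @param variability relative standard deviation of this compound's
#'   concentration across independently prepared samples (default 0, i.e. a
#'   perfectly stable compound). Oxidation-sensitive fluorophores in real
#'   oils show substantial sample-to-sample variability; stable pigments do
#'   not.
#' @return An object of class `"fluorophore"`.
#' @export
fluorophore_component <- function(name, emission_center, emission_width,
                                  lifetime, brightness = 1, variability = 0) {
  if (lifetime <= 0) stop_arg("lifetime must be > 0")
  if (emission_width <= 0) stop_arg("emission_width must be > 0")
  if (brightness < 0) stop_arg("brightness must be >= 0")
  if (variability < 0) stop_arg("variability must be >= 0")
  structure(
    list(name = as.character(name), emission_center = emission_center,
         emission_width = emission_width, lifetime = lifetime,
         brightness = brightness, variability = variability),
    class = "fluorophore"
  )
}

# Max-normalised Gaussian emission band of one component.
emission_shape <- function(component, wavelength_nm) {
  exp(-0.5 * ((wavelength_nm - component$emission_center) /
                component$emission_width)^2)
}

#' Define an oil fluorescence profile
#'
#' An oil is a weighted mixture of fluorophore components; `amplitudes` are
#' per-component pre-exponential weights (relative concentrations) for the
#' pure oil.
#'
#' @param name label, e.g. `"CO"`.
#' @param components list of [fluorophore_component()] objects.
#' @param amplitudes nonnegative numeric vector, one per component, not all 0.
#' @param reference_nm wavelength (nm) at which single-decay observations of
#'   this oil are referenced (default 440).
#' @return An object of class `"oil_profile"`.
#' @export
oil_profile <- function(name, components, amplitudes, reference_nm = 440) {
  if (length(components) < 1L) stop_arg("need at least one component")
  if (length(amplitudes) != length(components)) {
    stop_arg("amplitudes must match components")
  }
  if (any(amplitudes < 0) || all(amplitudes == 0)) {
    stop_arg("amplitudes must be >= 0 and not all zero")
  }
  structure(
    list(name = as.character(name), components = components,
         amplitudes = as.numeric(amplitudes), reference_nm = reference_nm),
    class = "oil_profile"
  )
}

#' @export
print.oil_profile <- function(x, ...) {
  cat("Oil fluorescence profile:", x$name, "\n")
  tab <- data.frame(
    component = vapply(x$components, `[[`, "", "name"),
    center_nm = vapply(x$components, `[[`, 0, "emission_center"),
    sigma_nm = vapply(x$components, `[[`, 0, "emission_width"),
    tau_ns = vapply(x$components, `[[`, 0, "lifetime"),
    amplitude = x$amplitudes
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

# Published three-component decay parameters of the pure oils at 440 nm:
# lifetimes (ns), intensity fractions (%), and reduced chi-square.
.oil_decay_table <- list(
  PO = list(tau = c(1.57, 6.14, 18.66), f = c(38.79, 42.18, 19.04),
            chi2 = 0.9924),
  SO = list(tau = c(2.25, 6.85, 19.85), f = c(31.28, 46.37, 21.81),
            chi2 = 1.0137),
  CO = list(tau = c(1.09, 5.05, 16.43), f = c(41.65, 37.32, 21.02),
            chi2 = 1.0077)
)

#' Three-component presets for peanut, sunflower and camellia oil
#'
#' Builds a three-fluorophore profile whose lifetimes and fractional intensity
#' contributions at 440 nm reproduce the published decay parameters of peanut
#' oil (PO), sunflower oil (SO) and camellia oil (CO). Amplitudes are solved
#' from the intensity fractions via `f_k = 100 * a_k * tau_k / sum(a * tau)`,
#' corrected for each band's emission shape at 440 nm, so a simulated decay of
#' the preset observed at 440 nm has exactly the tabulated (tau, f).
#'
#' @param name one of `"PO"`, `"SO"`, `"CO"`.
#' @return An [oil_profile()].
#' @export
oil_preset <- function(name = c("PO", "SO", "CO")) {
  name <- match.arg(name)
  row <- .oil_decay_table[[name]]
  centers <- c(425, 445, 475)
  widths <- c(18, 22, 30)
  comps <- lapply(seq_len(3), function(k) {
    fluorophore_component(sprintf("%s%d", name, k), centers[k], widths[k],
                          row$tau[k])
  })
  # intensity fraction f_k ~ a_k * b_k(440) * tau_k  =>  a_k = f_k / (tau_k b_k)
  shape_ref <- vapply(comps, emission_shape, 0, wavelength_nm = 440)
  amps <- (row$f / row$tau) / shape_ref
  oil_profile(name, comps, amps / max(amps), reference_nm = 440)
}

#' Reference decay parameters of the pure-oil presets
#'
#' @param name one of `"PO"`, `"SO"`, `"CO"`.
#' @return list with elements `tau` (ns), `f` (percent) and `chi2`.
#' @export
oil_decay_reference <- function(name = c("PO", "SO", "CO")) {
  .oil_decay_table[[match.arg(name)]]
}

#' Four-fluorophore base/adulterant system for adulteration cubes
#'
#' The default system used by the pipeline: four shared fluorophores with
#' distinct emission centres (420/455/490/530 nm). The short-lifetime pair
#' dominates camellia oil; the long-lifetime pair is the adulterant marker
#' pair, nearly absent in the genuine oil and strongly enriched in the
#' adulterant (the classical definition of an adulteration marker, and the
#' published qualitative contrast: adulterant decays are longer-lived than
#' camellia's). Lifetimes (0.6, 2.5, 7 and ~19 ns) are spread so the four
#' decay profiles remain distinguishable on the 100-channel, 0.05 ns
#' analysis window; the long marker lifetime is the adulterant oil's
#' published longest component (18.66 ns for peanut, 19.85 ns for
#' sunflower). Per-component `variability` reflects compound stability:
#' the oxidation-sensitive short-lived base fluorophores vary most between
#' independently prepared samples.
#'
#' @param adulterant `"PO"` (peanut) or `"SO"` (sunflower).
#' @return list with elements `base` and `adulterant`, both [oil_profile()]s
#'   over the same four components.
#' @export
oil_system <- function(adulterant = c("PO", "SO")) {
  adulterant <- match.arg(adulterant)
  tau_long <- .oil_decay_table[[adulterant]]$tau[3]
  tau_mid <- if (adulterant == "PO") 7 else 7.3
  comps <- list(
    fluorophore_component("shortlived_base", 420, 18, 0.6, variability = 0.10),
    fluorophore_component("midlived_base", 455, 22, 2.5, variability = 0.08),
    fluorophore_component("midlived_marker", 490, 25, tau_mid,
                          variability = 0.045),
    fluorophore_component("longlived_marker", 530, 30, tau_long,
                          variability = 0.045)
  )
  base <- oil_profile("CO", comps, c(1.00, 0.70, 0.05, 0.03))
  adult <- oil_profile(adulterant, comps, c(0.25, 0.55, 2.40, 1.80))
  list(base = base, adulterant = adult)
}
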