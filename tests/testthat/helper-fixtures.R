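# Shared fixtures and independent oracles, all generated in code.

# Direct-sum causal convolution oracle (deliberately loop-based, independent
# of the FFT path used by the package).
conv_direct <- function(a, b) {
  n <- length(b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- seq_len(i)
    out[i] <- sum(a[js] * b[i - js + 1])
  }
  out
}

# Savitzky-Golay interior weights derived from first principles: least-squares
# quadratic fit over the window, evaluated at the centre point.
savgol_weights_oracle <- function(window = 5, polyorder = 2) {
  half <- (window - 1) / 2
  V <- outer(seq(-half, half), 0:polyorder, `^`)
  H <- V %*% solve(crossprod(V), t(V))
  H[half + 1, ]
}

# Generic random trilinear cube with well-conditioned positive factors.
random_cube <- function(I, J, K, M, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(I * M, 0.5, 2), I)
  B <- matrix(stats::runif(J * M, 0.1, 1), J)
  C <- matrix(stats::runif(K * M, 0.1, 1), K)
  X1 <- A %*% t(sapply(seq_len(M), function(m) kronecker(C[, m], B[, m])))
  if (M == 1) X1 <- A %*% t(kronecker(C[, 1], B[, 1]))
  list(X = array(X1, c(I, J, K)), A = A, B = B, C = C)
}

# Small two-fluorophore adulteration system with ideal (variability-free)
# samples; trilinear rank 2 and exactly affine scores.
ideal_two_component_system <- function() {
  comps <- list(
    fluorophore_component("base_f", 430, 20, 1.2),
    fluorophore_component("marker_f", 510, 28, 12)
  )
  list(
    base = oil_profile("CO", comps, c(1, 0.05)),
    adulterant = oil_profile("PO", comps, c(0.3, 1))
  )
}

# Short acquisition instrument for fast decay-fitting tests.
quick_decay_instrument <- function(noise = "none", peak = 1e4, t_max = 40) {
  decay_instrument(t_max = t_max, dt = 0.05, fwhm = 1, peak_counts = peak,
                   noise = noise)
}
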