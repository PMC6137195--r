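# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

# Grid must be strictly increasing with uniform spacing (to float tolerance).
check_uniform_grid <- function(x, what) {
  if (length(x) < 2L) return(invisible(x))
  d <- diff(x)
  if (any(d <= 0)) stop_arg("%s grid must be strictly increasing", what)
  if (max(d) - min(d) > 1e-8 * mean(d)) {
    stop_arg("%s grid must have uniform spacing", what)
  }
  invisible(x)
}

# Causal discrete convolution: out[i] = sum_{j<=i} a[j] * b[i-j+1],
# truncated to length(b). FFT-based; tests check it against a direct sum.
conv_causal <- function(a, b) {
  n <- length(b)
  stopifnot(length(a) == n)
  out <- stats::convolve(a, rev(b), type = "open")[seq_len(n)]
  out
}

# Column-wise Khatri-Rao product, rows of B varying fastest:
# column m is kronecker(A[, m], B[, m]).
khatri_rao <- function(A, B) {
  M <- ncol(A)
  stopifnot(ncol(B) == M)
  out <- matrix(0, nrow(A) * nrow(B), M)
  for (m in seq_len(M)) out[, m] <- as.vector(outer(B[, m], A[, m]))
  out
}

# Mode-n unfolding of a 3-way array, matching R's column-major vec ordering:
# unfold(X, 1) = A %*% t(khatri_rao(C, B)) for X = [[A, B, C]].
unfold <- function(X, mode) {
  d <- dim(X)
  switch(mode,
    matrix(X, d[1], d[2] * d[3]),
    matrix(aperm(X, c(2, 1, 3)), d[2], d[1] * d[3]),
    matrix(aperm(X, c(3, 1, 2)), d[3], d[1] * d[2])
  )
}

# Tucker congruence (uncentred cosine) between two vectors.
tucker_congruence <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

rmse <- function(obs, pred) sqrt(mean((pred - obs)^2))

rsq <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop_arg("R-squared undefined: observed values are constant")
  1 - sum((pred - obs)^2) / ss_tot
}
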