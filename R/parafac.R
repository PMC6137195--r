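# Trilinear (PARAFAC) decomposition by alternating least squares.

as_cube_array <- function(cube) {
  if (inherits(cube, "tres_cube")) cube$counts else as.array(cube)
}

# Symmetric solve with pseudo-inverse fallback for ill-conditioned Grams.
solve_gram <- function(G, RHS) {
  out <- tryCatch(t(solve(G, t(RHS))), error = function(e) NULL)
  if (is.null(out)) out <- RHS %*% MASS::ginv(G)
  out
}

# One unconstrained ALS sweep; factors is list(A, B, C), X1/X2/X3 unfoldings.
als_sweep <- function(fac, X1, X2, X3) {
  A <- fac$A; B <- fac$B; C <- fac$C
  A <- solve_gram(crossprod(B) * crossprod(C), X1 %*% khatri_rao(C, B))
  B <- solve_gram(crossprod(A) * crossprod(C), X2 %*% khatri_rao(C, A))
  C <- solve_gram(crossprod(A) * crossprod(B), X3 %*% khatri_rao(B, A))
  list(A = A, B = B, C = C)
}

# Column-wise HALS sweep with nonnegativity projection on all modes.
als_sweep_nonneg <- function(fac, X1, X2, X3) {
  A <- fac$A; B <- fac$B; C <- fac$C
  upd <- function(F0, Xn, P, Q) {
    G <- crossprod(P) * crossprod(Q)
    W <- Xn %*% khatri_rao(Q, P)
    for (m in seq_len(ncol(F0))) {
      num <- W[, m] - F0 %*% G[, m] + F0[, m] * G[m, m]
      F0[, m] <- pmax(num / max(G[m, m], 1e-12), 0)
    }
    F0
  }
  A <- upd(A, X1, B, C)   # note khatri_rao(C, B) pairs with modes (3, 2)
  B <- upd(B, X2, A, C)
  C <- upd(C, X3, A, B)
  list(A = A, B = B, C = C)
}

# Normalise B and C columns to unit norm, fold scales/signs into A.
normalise_factors <- function(fac) {
  A <- fac$A; B <- fac$B; C <- fac$C
  for (m in seq_len(ncol(A))) {
    nb <- sqrt(sum(B[, m]^2)); nc <- sqrt(sum(C[, m]^2))
    if (nb > 0) { B[, m] <- B[, m] / nb }
    if (nc > 0) { C[, m] <- C[, m] / nc }
    sb <- if (sum(B[, m]) < 0) -1 else 1
    sc <- if (sum(C[, m]) < 0) -1 else 1
    B[, m] <- sb * B[, m]; C[, m] <- sc * C[, m]
    A[, m] <- A[, m] * nb * nc * sb * sc
  }
  list(A = A, B = B, C = C)
}

parafac_init <- function(X1, X2, X3, dims, M, type = c("svd", "random")) {
  type <- match.arg(type)
  if (type == "svd") {
    lead <- function(Xn, nr) {
      u <- svd(Xn, nu = min(M, min(dim(Xn))))$u
      if (ncol(u) < M) u <- cbind(u, matrix(stats::rnorm(nr * (M - ncol(u))), nr))
      u[, seq_len(M), drop = FALSE]
    }
    list(A = lead(X1, dims[1]), B = lead(X2, dims[2]), C = lead(X3, dims[3]))
  } else {
    list(A = matrix(stats::rnorm(dims[1] * M), dims[1]),
         B = matrix(stats::rnorm(dims[2] * M), dims[2]),
         C = matrix(stats::rnorm(dims[3] * M), dims[3]))
  }
}

#' PARAFAC decomposition of a TRES cube
#'
#' Fits the trilinear model
#' `x[i,j,k] = sum_m A[i,m] * B[j,m] * C[k,m] + e[i,j,k]`
#' by alternating least squares, minimising the residual sum of squares.
#' Emission (`B`) and time (`C`) loadings are normalised to unit column norm
#' with the scale carried by the sample scores `A`. The best of `n_starts`
#' initialisations (one SVD-based, the rest random) is returned; the residual
#' never increases across iterations.
#'
#' @param cube a [tres_cube()] or plain 3-way array.
#' @param n_factors number of trilinear factors M, >= 1.
#' @param nonneg constrain all three modes to be nonnegative (HALS updates).
#' @param tol relative change in SSE declaring convergence (default 1e-8).
#' @param max_iter maximum ALS iterations per start (default 1500).
#' @param n_starts number of initialisations (default 5).
#' @param seed seed for the random initialisations.
#' @return An object of class `"parafac"`: `scores` (I x M),
#'   `emission_loadings` (J x M), `time_loadings` (K x M), `sse`,
#'   `explained_fraction`, `sse_trace`, `converged`, `n_iter`.
#' @export
parafac <- function(cube, n_factors, nonneg = FALSE, tol = 1e-8,
                    max_iter = 1500, n_starts = 5, seed = 1L) {
  X <- as_cube_array(cube)
  dims <- dim(X)
  if (n_factors < 1) stop_arg("n_factors must be >= 1")
  lim <- min(dims[1] * dims[2], dims[1] * dims[3], dims[2] * dims[3])
  if (n_factors > lim) stop_arg("n_factors too large for these dimensions")
  X1 <- unfold(X, 1); X2 <- unfold(X, 2); X3 <- unfold(X, 3)
  ss_tot <- sum(X^2)
  M <- as.integer(n_factors)

  sse_of <- function(fac) {
    sum((X1 - fac$A %*% t(khatri_rao(fac$C, fac$B)))^2)
  }

  run_start <- function(init) {
    fac <- init
    if (nonneg) fac <- lapply(fac, abs)
    sweep_fun <- if (nonneg) als_sweep_nonneg else als_sweep
    sse_prev <- Inf
    trace <- numeric(0)
    converged <- FALSE
    it <- 0L
    step <- 1.25 # line-search extrapolation factor (swamp mitigation)
    repeat {
      it <- it + 1L
      fac_old <- fac
      fac <- sweep_fun(fac, X1, X2, X3)
      sse <- sse_of(fac)
      # extrapolate along the sweep direction; keep only if it helps
      if (it > 2L && is.finite(sse_prev)) {
        ext <- list(A = fac$A + step * (fac$A - fac_old$A),
                    B = fac$B + step * (fac$B - fac_old$B),
                    C = fac$C + step * (fac$C - fac_old$C))
        if (nonneg) ext <- lapply(ext, pmax, 0)
        sse_ext <- sse_of(ext)
        if (sse_ext < sse) {
          fac <- ext
          sse <- sse_ext
          step <- min(step * 1.15, 4)
        } else {
          step <- max(step * 0.7, 1.1)
        }
      }
      trace <- c(trace, sse)
      if (is.finite(sse_prev) &&
          (sse_prev - sse) < tol * max(sse_prev, .Machine$double.eps)) {
        converged <- (sse_prev - sse) >= -1e-10 * max(sse_prev, 1)
        break
      }
      if (it >= max_iter) break
      sse_prev <- sse
    }
    list(fac = fac, sse = sse, trace = trace, converged = converged, it = it)
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- with_seed(seed + s - 1L, {
      parafac_init(X1, X2, X3, dims, M, if (s == 1L) "svd" else "random")
    })
    res <- run_start(init)
    if (is.null(best) || res$sse < best$sse) best <- res
  }

  fac <- normalise_factors(best$fac)
  # degeneracy warning: two factors with near-identical (B, C) profiles
  if (M >= 2) {
    for (m1 in seq_len(M - 1)) for (m2 in seq((m1 + 1), M)) {
      cong <- tucker_congruence(fac$B[, m1], fac$B[, m2]) *
        tucker_congruence(fac$C[, m1], fac$C[, m2])
      if (is.finite(cong) && abs(cong) > 0.99) {
        warning(sprintf("degenerate factor pair (%d, %d): |congruence| = %.4f",
                        m1, m2, abs(cong)))
      }
    }
  }

  structure(
    list(n_factors = M, scores = fac$A, emission_loadings = fac$B,
         time_loadings = fac$C, sse = best$sse,
         explained_fraction = 1 - best$sse / ss_tot,
         sse_trace = best$trace, converged = best$converged,
         n_iter = best$it, dims = dims,
         emission_nm = if (inherits(cube, "tres_cube")) cube$emission_nm else NULL,
         time_ns = if (inherits(cube, "tres_cube")) cube$time_ns else NULL),
    class = "parafac"
  )
}

#' @export
print.parafac <- function(x, ...) {
  cat(sprintf("PARAFAC model: %d factors on a %s cube\n", x$n_factors,
              paste(x$dims, collapse = " x ")))
  cat(sprintf("  explained fraction %.6f (SSE %.4g), %d iterations, converged: %s\n",
              x$explained_fraction, x$sse, x$n_iter, x$converged))
  invisible(x)
}

#' @export
summary.parafac <- function(object, ...) {
  print(object)
  sc <- sqrt(colSums(object$scores^2))
  cat("  factor score norms:", paste(signif(sc, 4), collapse = ", "), "\n")
  invisible(object)
}

#' @export
fitted.parafac <- function(object, ...) {
  X1 <- object$scores %*% t(khatri_rao(object$time_loadings, object$emission_loadings))
  array(X1, object$dims)
}

#' @export
residuals.parafac <- function(object, cube, ...) {
  as_cube_array(cube) - fitted(object)
}

#' @export
plot.parafac <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  jx <- if (!is.null(x$emission_nm)) x$emission_nm else seq_len(x$dims[2])
  kx <- if (!is.null(x$time_ns)) x$time_ns else seq_len(x$dims[3])
  graphics::matplot(jx, x$emission_loadings, type = "l", lty = 1,
                    xlab = "emission (nm)", ylab = "loading",
                    main = "emission mode", ...)
  graphics::matplot(kx, x$time_loadings, type = "l", lty = 1,
                    xlab = "time (ns)", ylab = "loading",
                    main = "time mode", ...)
  invisible(x)
}

# Least-squares Tucker core given (possibly rank-deficient) PARAFAC loadings:
# G = X x1 pinv(A) x2 pinv(B) x3 pinv(C).
tucker_core <- function(model, X) {
  PA <- MASS::ginv(model$scores)
  PB <- MASS::ginv(model$emission_loadings)
  PC <- MASS::ginv(model$time_loadings)
  d <- dim(X)
  M <- model$n_factors
  T1 <- array(PA %*% unfold(X, 1), c(M, d[2], d[3]))
  T2 <- array(PB %*% unfold(T1, 2), c(M, M, d[3]))
  T2 <- aperm(T2, c(2, 1, 3))
  T3 <- array(PC %*% unfold(T2, 3), c(M, M, M))
  aperm(T3, c(2, 3, 1))
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Measures how close the least-squares Tucker3 core implied by a PARAFAC
#' solution is to a superidentity (ones on the superdiagonal, zeros
#' elsewhere): `100 * (1 - sum((g - superidentity)^2) / sum(g^2))`. Values
#' near 100 support the chosen number of factors; overfactored models
#' collapse far below.
#'
#' @param model a [parafac()] fit of `cube`.
#' @param cube the cube (or array) the model was fitted to.
#' @return core consistency in percent (<= 100).
#' @export
corcondia <- function(model, cube) {
  X <- as_cube_array(cube)
  if (!identical(dim(X), model$dims)) stop_arg("cube does not match the model")
  G <- tucker_core(model, X)
  M <- model$n_factors
  superI <- array(0, c(M, M, M))
  for (m in seq_len(M)) superI[m, m, m] <- 1
  denom <- sum(G^2)
  if (denom == 0) stop_arg("degenerate loadings: zero Tucker core")
  100 * (1 - sum((G - superI)^2) / denom)
}

#' Choose the number of PARAFAC factors by core consistency
#'
#' Scans `M = 1..max_M`, fitting PARAFAC and computing CORCONDIA at each M,
#' and selects the first M that meets the threshold while its successor falls
#' below it (i.e. the last adequate model before the diagnostic collapses).
#'
#' @param cube a [tres_cube()] or array.
#' @param max_M largest factor number scanned (default 6).
#' @param threshold CORCONDIA acceptance threshold in percent (default 50,
#'   following the usual reading of the diagnostic: values well above 50
#'   indicate an acceptable trilinear model, values near zero an invalid
#'   one).
#' @param ... passed to [parafac()].
#' @return list of class `"factor_scan"`: `selected`, `table` (M, corcondia,
#'   explained fraction).
#' @export
select_factors <- function(cube, max_M = 6, threshold = 50, ...) {
  if (max_M < 1) stop_arg("max_M must be >= 1")
  X <- as_cube_array(cube)
  models <- lapply(seq_len(max_M), function(M) parafac(X, M, ...))
  cc <- vapply(models, corcondia, 0, cube = X)
  expl <- vapply(models, `[[`, 0, "explained_fraction")
  tab <- data.frame(M = seq_len(max_M), corcondia = cc, explained = expl)
  ok <- cc >= threshold
  cand <- which(ok & (c(cc[-1], -Inf) < threshold))
  if (!length(cand)) {
    if (!any(ok)) {
      stop("no factor number reaches the core-consistency threshold; scan: ",
           paste(sprintf("M=%d: %.1f", tab$M, tab$corcondia), collapse = "; "),
           call. = FALSE)
    }
    cand <- max(which(ok))
  }
  structure(list(selected = min(cand), table = tab, threshold = threshold),
            class = "factor_scan")
}

#' @export
print.factor_scan <- function(x, ...) {
  cat(sprintf("Core-consistency factor scan (threshold %.0f%%): selected M = %d\n",
              x$threshold, x$selected))
  print(transform(x$table, corcondia = round(corcondia, 2),
                  explained = round(explained, 6)), row.names = FALSE)
  invisible(x)
}

# Optimal factor matching between two models by total |congruence| over
# emission and time loadings; returns permutation and per-factor congruences
# (sign-aligned so the emission congruence is nonnegative).
match_factors <- function(B1, C1, B2, C2) {
  M <- ncol(B1)
  congB <- outer(seq_len(M), seq_len(M),
                 Vectorize(function(i, j) tucker_congruence(B1[, i], B2[, j])))
  congC <- outer(seq_len(M), seq_len(M),
                 Vectorize(function(i, j) tucker_congruence(C1[, i], C2[, j])))
  perms <- all_permutations(M)
  score <- vapply(perms, function(p) {
    sum(abs(congB[cbind(seq_len(M), p)]) + abs(congC[cbind(seq_len(M), p)]))
  }, 0)
  p <- perms[[which.max(score)]]
  cb <- congB[cbind(seq_len(M), p)]
  cc <- congC[cbind(seq_len(M), p)]
  sgn <- ifelse(cb < 0, -1, 1)
  list(permutation = p, congruence_emission = cb * sgn,
       congruence_time = cc * sgn)
}

#' Split-half validation of a PARAFAC model
#'
#' Exploits the uniqueness of the trilinear decomposition: PARAFAC is fitted
#' independently on two disjoint sample subsets and the emission/time
#' loadings are compared by Tucker congruence after optimal factor matching.
#' Congruences near 1 indicate a stable, correctly specified model.
#'
#' @param cube a [tres_cube()] or array with at least `2 * M` samples per half.
#' @param n_factors number of factors M.
#' @param scheme `"odd_even"` (default) or `"halves"` sample split.
#' @param ... passed to [parafac()].
#' @return list of class `"split_half"`: the two fitted models and per-factor
#'   emission/time congruences.
#' @export
split_half <- function(cube, n_factors, scheme = c("odd_even", "halves"), ...) {
  scheme <- match.arg(scheme)
  X <- as_cube_array(cube)
  I <- dim(X)[1]
  idx <- if (scheme == "odd_even") {
    list(seq(1, I, by = 2), seq(2, I, by = 2))
  } else {
    list(seq_len(I %/% 2), seq(I %/% 2 + 1, I))
  }
  if (min(lengths(idx)) < 2 * n_factors) {
    stop_arg("each half needs at least 2 * M = %d samples", 2 * n_factors)
  }
  m1 <- parafac(X[idx[[1]], , , drop = FALSE], n_factors, ...)
  m2 <- parafac(X[idx[[2]], , , drop = FALSE], n_factors, ...)
  mt <- match_factors(m1$emission_loadings, m1$time_loadings,
                      m2$emission_loadings, m2$time_loadings)
  structure(
    list(half_models = list(m1, m2), scheme = scheme,
         congruence_emission = mt$congruence_emission,
         congruence_time = mt$congruence_time,
         permutation = mt$permutation),
    class = "split_half"
  )
}

#' @export
print.split_half <- function(x, ...) {
  cat(sprintf("Split-half validation (%s): %d factors\n", x$scheme,
              x$half_models[[1]]$n_factors))
  cat("  emission congruence:", paste(round(x$congruence_emission, 4), collapse = ", "), "\n")
  cat("  time congruence:    ", paste(round(x$congruence_time, 4), collapse = ", "), "\n")
  invisible(x)
}
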