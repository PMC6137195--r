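#' Construct a fluorescence decay curve
#'
#' @param time_ns uniform, strictly increasing time grid (ns).
#' @param counts nonnegative per-channel photon counts.
#' @param emission_nm observation wavelength (nm), optional.
#' @return An object of class `"decay_curve"`.
#' @export
decay_curve <- function(time_ns, counts, emission_nm = NA_real_) {
  check_uniform_grid(time_ns, "time")
  if (length(counts) != length(time_ns)) stop_arg("time/counts length mismatch")
  if (any(counts < 0)) stop_arg("counts must be nonnegative")
  structure(
    list(time_ns = as.numeric(time_ns), counts = as.numeric(counts),
         emission_nm = emission_nm),
    class = "decay_curve"
  )
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("Decay curve: %d channels, %g-%g ns (dt = %g ns)",
              length(x$time_ns), min(x$time_ns), max(x$time_ns),
              x$time_ns[2] - x$time_ns[1]))
  if (!is.na(x$emission_nm)) cat(sprintf(", emission %g nm", x$emission_nm))
  cat(sprintf("\n  peak counts %g, total counts %g\n",
              max(x$counts), sum(x$counts)))
  invisible(x)
}

# Model curve on the full grid: IRF (shifted, unit-sum) convolved with a sum
# of exponentials. alpha/tau on natural scale.
multiexp_model_curve <- function(alpha, tau, shift, time_ns, irf) {
  t0 <- time_ns - time_ns[1]
  d <- drop(exp(-outer(t0, tau, "/")) %*% alpha)
  conv_causal(irf_kernel(irf, shift), d)
}

# Poisson (Neyman) weights with unit floor.
decay_weights <- function(counts) 1 / sqrt(pmax(counts, 1))

# Fit window: IRF peak channel .. last channel with >= min_counts counts.
fit_window <- function(decay, irf, min_counts = 5) {
  first <- which.max(irf$counts)
  last <- max(which(decay$counts >= min_counts), first + 1L)
  seq(first, last)
}

# Nonnegative-ish amplitude initialisation at fixed lifetimes: weighted LS
# with a positivity floor.
init_amplitudes <- function(decay, irf, tau, window) {
  t0 <- decay$time_ns - decay$time_ns[1]
  k <- irf_kernel(irf, 0)
  D <- vapply(tau, function(tk) conv_causal(k, exp(-t0 / tk)),
              numeric(length(t0)))
  w <- decay_weights(decay$counts[window])
  a <- tryCatch(
    stats::lsfit(D[window, , drop = FALSE] * w, decay$counts[window] * w,
                 intercept = FALSE)$coefficients,
    error = function(e) rep(max(decay$counts), length(tau))
  )
  pmax(as.numeric(a), max(decay$counts) * 1e-6)
}

#' Multi-exponential reconvolution fit of a decay curve
#'
#' Fits `counts ~ IRF (*) sum_k alpha_k exp(-t / tau_k)` by weighted
#' Levenberg-Marquardt least squares with Poisson (Neyman) weights floored at
#' one count, a free IRF-to-decay shift (standard TCSPC practice), and a
#' multi-start over log-spaced lifetime decades. Lifetimes are reported in
#' ascending order; standard errors come from the weighted Jacobian at the
#' optimum.
#'
#' @param decay a [decay_curve()].
#' @param irf an [irf()] on the same time grid.
#' @param n number of exponential components, 1-4.
#' @param init optional list with starting `tau` (ns) vector.
#' @param n_starts number of multi-start lifetime grids (default 3).
#' @param shift_bound bound (ns) on the fitted IRF shift (default 0.5).
#' @param min_counts tail cut-off: the fit window ends at the last channel
#'   with at least this many counts (default 5).
#' @param seed seed used only if extra random starts are requested.
#' @return An object of class `"decay_fit"`: amplitudes, lifetimes (ns),
#'   fractional intensity contributions (percent), reduced chi-square,
#'   standard errors, fitted IRF shift and the fitted curve.
#' @export
fit_decay <- function(decay, irf, n, init = NULL, n_starts = 3,
                      shift_bound = 0.5, min_counts = 5, seed = NULL) {
  if (n < 1 || n > 4) stop_arg("n must be between 1 and 4")
  npos <- sum(decay$counts > 0)
  if (npos < 4 * n + 2) stop_arg("too few populated channels for n = %d", n)
  window <- fit_window(decay, irf, min_counts)
  npar <- 2L * n + 1L
  if (length(window) <= npar) stop_arg("fit window shorter than parameter count")
  y <- decay$counts[window]
  w <- decay_weights(y)

  # `w` starts as observed-count (Neyman) weights and is replaced by
  # model-based (Pearson) weights in a second pass: pure Neyman weighting
  # overweights downward-fluctuating low-count channels and biases the long
  # lifetimes low by several percent.
  resid_fun <- function(par) {
    alpha <- exp(par[seq_len(n)])
    tau <- exp(par[n + seq_len(n)])
    shift <- par[2 * n + 1]
    m <- multiexp_model_curve(alpha, tau, shift, decay$time_ns, irf)
    (y - m[window]) * w
  }

  # multi-start lifetime grids: a log-spaced decade span, scaled
  base_tau <- exp(seq(log(0.4), log(25), length.out = n))
  scales <- c(1, 0.4, 2.5, 5, 0.15)
  starts <- lapply(seq_len(min(n_starts, length(scales))),
                   function(s) base_tau * scales[s])
  if (n_starts > length(scales)) {
    extra <- with_seed(seed, lapply(seq_len(n_starts - length(scales)), function(s) {
      sort(exp(stats::runif(n, log(0.1), log(50))))
    }))
    starts <- c(starts, extra)
  }
  if (!is.null(init) && !is.null(init$tau)) starts <- c(list(sort(init$tau)), starts)

  lower <- c(rep(-Inf, n), rep(log(1e-3), n), -shift_bound)
  upper <- c(rep(Inf, n), rep(log(1e3), n), shift_bound)
  lm_once <- function(par0) {
    tryCatch(
      minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL
    )
  }

  best <- NULL
  for (tau0 in starts) {
    a0 <- init_amplitudes(decay, irf, tau0, window)
    fit <- lm_once(c(log(a0), log(tau0), 0))
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop_arg("reconvolution fit failed to converge for any start (n = %d)", n)
  }

  # Pearson reweighting pass from the best Neyman solution
  p <- best$par
  mfit <- multiexp_model_curve(exp(p[seq_len(n)]), exp(p[n + seq_len(n)]),
                               p[2 * n + 1], decay$time_ns, irf)
  w <- decay_weights(mfit[window])
  refit <- lm_once(best$par)
  if (!is.null(refit)) best <- refit

  par <- best$par
  alpha <- exp(par[seq_len(n)])
  tau <- exp(par[n + seq_len(n)])
  shift <- par[2 * n + 1]
  se_log <- tryCatch(sqrt(diag(solve(best$hessian))),
                     error = function(e) rep(NA_real_, npar))
  ord <- order(tau)
  alpha <- alpha[ord]; tau <- tau[ord]
  se_alpha <- (alpha * se_log[seq_len(n)][ord])
  se_tau <- (tau * se_log[n + seq_len(n)][ord])
  chi2 <- best$deviance / (length(window) - npar)
  fitted_curve <- multiexp_model_curve(alpha, tau, shift, decay$time_ns, irf)
  small <- alpha < 1e-6 * max(alpha)

  structure(
    list(n_components = n, amplitudes = alpha, lifetimes = tau,
         fractions = fractional_contributions(alpha, tau),
         chi2_reduced = chi2, se_amplitudes = se_alpha, se_lifetimes = se_tau,
         shift = shift, sse = best$deviance, window = window,
         n_channels = length(window), fitted = fitted_curve,
         vanishing_components = which(small), decay = decay, irf = irf,
         converged = best$info %in% 1:4),
    class = "decay_fit"
  )
}

#' Fractional intensity contributions
#'
#' The share of steady-state intensity carried by each decay component:
#' `f_k = 100 * alpha_k * tau_k / sum_j alpha_j * tau_j` (percent).
#'
#' @param alpha amplitudes (or a `"decay_fit"` object).
#' @param tau lifetimes (ns); ignored when `alpha` is a fit object.
#' @return percent vector summing to 100.
#' @export
fractional_contributions <- function(alpha, tau = NULL) {
  if (inherits(alpha, "decay_fit")) {
    tau <- alpha$lifetimes
    alpha <- alpha$amplitudes
  }
  if (all(alpha == 0)) stop_arg("all amplitudes are zero")
  100 * alpha * tau / sum(alpha * tau)
}

#' Reduced chi-square of a fitted decay model
#'
#' Pearson-type goodness of fit with Poisson weights floored at one count:
#' `sum((y - yhat)^2 / max(y, 1)) / (n_channels - n_params)`.
#'
#' @param observed observed counts (fit window).
#' @param expected model counts on the same channels.
#' @param n_params number of fitted parameters.
#' @return reduced chi-square (dimensionless).
#' @export
reduced_chi_square <- function(observed, expected, n_params) {
  if (length(observed) != length(expected)) stop_arg("length mismatch")
  if (length(observed) <= n_params) {
    stop_arg("need more channels than parameters")
  }
  sum((observed - expected)^2 / pmax(observed, 1)) /
    (length(observed) - n_params)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Reconvolution fit, %d components (chi2_red = %.4f, shift = %+.3f ns)\n",
              x$n_components, x$chi2_reduced, x$shift))
  tab <- data.frame(
    tau_ns = round(x$lifetimes, 3),
    se_tau = round(x$se_lifetimes, 4),
    f_pct = round(x$fractions, 2),
    alpha = signif(x$amplitudes, 4)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  window: channels %d-%d (%d used), converged: %s\n",
              min(object$window), max(object$window), object$n_channels,
              object$converged))
  if (length(object$vanishing_components)) {
    cat("  note: component(s)", paste(object$vanishing_components, collapse = ", "),
        "have vanishing amplitude; n may exceed the information content\n")
  }
  invisible(object)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(stats::setNames(object$amplitudes, paste0("alpha", seq_along(object$amplitudes))),
    stats::setNames(object$lifetimes, paste0("tau", seq_along(object$lifetimes))),
    shift = object$shift)
}

#' @export
fitted.decay_fit <- function(object, ...) object$fitted

#' @export
residuals.decay_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- object$decay$counts - object$fitted
  if (type == "weighted") r <- r * decay_weights(object$decay$counts)
  r
}

#' @export
plot.decay_fit <- function(x, log = "y", ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$decay$time_ns, pmax(x$decay$counts, 0.5), pch = ".",
                 log = log, xlab = "time (ns)", ylab = "counts", ...)
  graphics::lines(x$decay$time_ns, pmax(x$fitted, 0.5), col = 2, lwd = 1.5)
  graphics::plot(x$decay$time_ns, residuals(x), type = "h",
                 xlab = "time (ns)", ylab = "weighted residual")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Choose the number of decay components
#'
#' Fits each candidate component number and returns the most parsimonious one
#' that the data support: the smallest candidate whose fit is not
#' significantly improved by the next one (partial F-test on the weighted
#' residual sums of squares at level `alpha`); if every step improves
#' significantly, the largest candidate is returned.
#'
#' @param decay a [decay_curve()].
#' @param irf an [irf()].
#' @param candidates ascending candidate component numbers (default 2:4).
#' @param alpha F-test level (default 0.05).
#' @param ... passed to [fit_decay()].
#' @return selected integer, with the scan table (n, sse, chi2, F, p) as
#'   attribute `"scan"`.
#' @export
select_n_components <- function(decay, irf, candidates = c(2, 3, 4),
                                alpha = 0.05, ...) {
  if (length(candidates) < 1L || is.unsorted(candidates)) {
    stop_arg("candidates must be nonempty and ascending")
  }
  fits <- lapply(candidates, function(n) {
    tryCatch(fit_decay(decay, irf, n, ...), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop_arg("no candidate component number converged")
  candidates <- candidates[ok]
  fits <- fits[ok]
  scan <- data.frame(
    n = candidates,
    sse = vapply(fits, `[[`, 0, "sse"),
    chi2 = vapply(fits, `[[`, 0, "chi2_reduced"),
    F = NA_real_, p = NA_real_
  )
  selected <- candidates[length(candidates)]
  for (i in seq_len(length(candidates) - 1L)) {
    f1 <- fits[[i]]; f2 <- fits[[i + 1L]]
    df1 <- f1$n_channels - (2 * f1$n_components + 1)
    df2 <- f2$n_channels - (2 * f2$n_components + 1)
    dfe <- df1 - df2
    Fstat <- ((f1$sse - f2$sse) / dfe) / (f2$sse / df2)
    p <- stats::pf(max(Fstat, 0), dfe, df2, lower.tail = FALSE)
    scan$F[i] <- Fstat
    scan$p[i] <- p
    if (p > alpha) { selected <- candidates[i]; break }
  }
  structure(selected, scan = scan)
}
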