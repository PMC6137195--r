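# ANN calibration of adulteration level from PARAFAC sample scores.

scale_cols <- function(X, center, scale) {
  sweep(sweep(X, 2, center, "-"), 2, pmax(scale, .Machine$double.eps), "/")
}

# One deterministic nnet training run: best of n_starts seeded random
# initialisations, judged by the training objective.
train_net <- function(x, y, hidden_units, l2, maxit, n_starts, seed) {
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- with_seed(seed * 1000L + s,
                     nnet::nnet(x, y, size = hidden_units, linout = TRUE,
                                decay = l2, maxit = maxit, trace = FALSE))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

#' Calibrate adulteration level from PARAFAC scores
#'
#' Trains a single-hidden-layer feed-forward neural network (tanh-like
#' sigmoid hidden units via `nnet`, linear output, L2 weight decay) mapping
#' PARAFAC sample scores to adulteration level. Inputs and the response are
#' z-scored by training statistics internally; training is deterministic
#' given `seed` (best of `n_starts` seeded weight initialisations).
#'
#' @param scores I x M numeric matrix of sample scores.
#' @param y adulteration levels (percent v/v), length I.
#' @param hidden_units hidden layer size (default 5).
#' @param l2 L2 weight-decay penalty (default 5e-3).
#' @param maxit maximum training iterations (default 2000).
#' @param n_starts random weight initialisations per fit (default 3).
#' @param seed integer seed (default 1).
#' @return An object of class `"tres_calibration"` with the fitted network,
#'   training predictions, `rmsec` and `r2c`.
#' @export
tres_calibrate <- function(scores, y, hidden_units = 5, l2 = 5e-3,
                           maxit = 2000, n_starts = 3, seed = 1L) {
  scores <- as.matrix(scores)
  y <- as.numeric(y)
  if (!all(is.finite(scores)) || !all(is.finite(y))) {
    stop_arg("scores and y must be finite")
  }
  if (nrow(scores) != length(y)) stop_arg("scores/y length mismatch")
  if (nrow(scores) <= ncol(scores)) stop_arg("need more samples than factors")
  if (hidden_units < 1) stop_arg("hidden_units must be >= 1")
  x_center <- colMeans(scores)
  x_scale <- apply(scores, 2, stats::sd)
  y_center <- mean(y)
  y_scale <- max(stats::sd(y), .Machine$double.eps)
  xs <- scale_cols(scores, x_center, x_scale)
  ys <- (y - y_center) / y_scale
  net <- train_net(xs, ys, hidden_units, l2, maxit, n_starts, seed)
  obj <- structure(
    list(net = net, x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale, y = y,
         hidden_units = hidden_units, l2 = l2, maxit = maxit,
         n_starts = n_starts, seed = seed),
    class = "tres_calibration"
  )
  obj$fitted <- predict(obj, scores)
  obj$rmsec <- rmse(y, obj$fitted)
  obj$r2c <- rsq(y, obj$fitted)
  obj
}

#' @export
predict.tres_calibration <- function(object, newscores, ...) {
  newscores <- as.matrix(newscores)
  xs <- scale_cols(newscores, object$x_center, object$x_scale)
  drop(stats::predict(object$net, xs)) * object$y_scale + object$y_center
}

#' @export
print.tres_calibration <- function(x, ...) {
  cat(sprintf("ANN calibration: %d inputs -> %d hidden -> 1 linear output\n",
              length(x$x_center), x$hidden_units))
  cat(sprintf("  RMSEC = %.4f %%, R2c = %.5f (n = %d)\n",
              x$rmsec, x$r2c, length(x$y)))
  invisible(x)
}

#' @export
summary.tres_calibration <- function(object, ...) {
  print(object)
  cat(sprintf("  weight decay %g, max %d iterations, %d starts, seed %d\n",
              object$l2, object$maxit, object$n_starts, object$seed))
  invisible(object)
}

#' @export
residuals.tres_calibration <- function(object, ...) object$y - object$fitted

#' @export
plot.tres_calibration <- function(x, ...) {
  graphics::plot(x$y, x$fitted, xlab = "actual adulteration (%)",
                 ylab = "predicted adulteration (%)", ...)
  graphics::abline(0, 1, col = 2)
  invisible(x)
}

#' Leave-one-out cross-validation of the ANN calibration
#'
#' Each sample is predicted by a network trained on the remaining samples
#' with the same configuration; metrics are computed from the pooled
#' held-out predictions.
#'
#' @inheritParams tres_calibrate
#' @return list with `rmsecv`, `r2cv`, `predictions_cv`.
#' @export
cross_validate <- function(scores, y, hidden_units = 5, l2 = 5e-3,
                           maxit = 2000, n_starts = 3, seed = 1L) {
  scores <- as.matrix(scores)
  y <- as.numeric(y)
  I <- nrow(scores)
  if (I < 3) stop_arg("need at least 3 samples for cross-validation")
  pred <- rep(NA_real_, I)
  for (i in seq_len(I)) {
    fit_i <- tryCatch(
      tres_calibrate(scores[-i, , drop = FALSE], y[-i],
                     hidden_units = hidden_units, l2 = l2, maxit = maxit,
                     n_starts = n_starts, seed = seed + i),
      error = function(e) NULL
    )
    if (is.null(fit_i)) next
    pred[i] <- predict(fit_i, scores[i, , drop = FALSE])
  }
  ok <- is.finite(pred)
  if (!any(ok)) stop_arg("every cross-validation fold failed")
  list(rmsecv = rmse(y[ok], pred[ok]), r2cv = rsq(y[ok], pred[ok]),
       predictions_cv = pred)
}

#' Evaluate a calibration on an external test set
#'
#' @param object a fitted [tres_calibrate()] model.
#' @param scores_test test-sample scores on the training model's factors
#'   (see [project_scores()]).
#' @param y_test known adulteration levels (percent).
#' @return list with `rmsep`, `r2p` (NA when `y_test` is constant) and
#'   `predictions`.
#' @export
evaluate_calibration <- function(object, scores_test, y_test) {
  pred <- predict(object, scores_test)
  r2p <- tryCatch(rsq(y_test, pred), error = function(e) NA_real_)
  list(rmsep = rmse(y_test, pred), r2p = r2p, predictions = pred)
}

#' Project new samples onto a fitted PARAFAC model
#'
#' Holds the emission and time loadings fixed and solves, per new sample, the
#' least-squares regression of the unfolded emission x time matrix onto the
#' Khatri-Rao structure of the loadings; training samples projected onto
#' their own model reproduce their scores.
#'
#' @param model a [parafac()] fit.
#' @param new_cube a [tres_cube()] on the same emission/time grids.
#' @return I_new x M score matrix.
#' @export
project_scores <- function(model, new_cube) {
  X <- as_cube_array(new_cube)
  d <- dim(X)
  if (!identical(d[2:3], model$dims[2:3])) {
    stop_arg("new cube's emission/time grid does not match the model")
  }
  if (inherits(new_cube, "tres_cube") && !is.null(model$emission_nm)) {
    if (max(abs(new_cube$emission_nm - model$emission_nm)) > 1e-9 ||
        max(abs(new_cube$time_ns - model$time_ns)) > 1e-9) {
      stop_arg("new cube's grids differ from the model's grids")
    }
  }
  Z <- khatri_rao(model$time_loadings, model$emission_loadings)
  G <- crossprod(Z)
  RHS <- unfold(X, 1) %*% Z
  solve_gram(G, RHS)
}
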