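# Duncan's multiple range test and the detection-limit rule.

#' Replicate intensity groups
#'
#' Container for the per-level replicate intensity summaries that the
#' detection-limit analysis compares: one group of scalar intensities per
#' adulteration level.
#'
#' @param levels adulteration levels (v/v fractions), one per group.
#' @param replicates list of numeric vectors (>= 2 values each), one per level.
#' @return An object of class `"intensity_groups"`.
#' @export
intensity_groups <- function(levels, replicates) {
  if (length(levels) != length(replicates)) stop_arg("levels/replicates mismatch")
  if (length(levels) < 2L) stop_arg("need at least 2 groups")
  if (anyDuplicated(levels)) stop_arg("levels must be unique")
  if (any(vapply(replicates, length, 0L) < 2L)) {
    stop_arg("every level needs at least 2 replicates")
  }
  ord <- order(levels)
  structure(list(levels = as.numeric(levels)[ord],
                 replicates = lapply(replicates[ord], as.numeric)),
            class = "intensity_groups")
}

#' Duncan's multiple range test
#'
#' Ranks the group means and tests every pair with a critical range that
#' grows with the number of ranks `p` the pair spans:
#' `R_p = q(1 - alpha_p, p, df) * sqrt(MSE / n)`, where `q` is the
#' studentized-range quantile, `alpha_p = 1 - (1 - alpha)^(p - 1)` is
#' Duncan's protection level, `MSE` the pooled within-group mean square from
#' one-way ANOVA, and `n` the (harmonic mean) replicate count. The usual
#' containment rule applies: a pair inside a span already declared
#' non-significant is not declared significant.
#'
#' @param groups an [intensity_groups()] object.
#' @param alpha per-comparison significance level (default 0.05).
#' @return An object of class `"duncan_test"`: group means, `mse`, `df` and
#'   the pairwise comparison table.
#' @export
duncan_test <- function(groups, alpha = 0.05) {
  if (!inherits(groups, "intensity_groups")) {
    stop_arg("groups must be an intensity_groups object")
  }
  g <- length(groups$levels)
  values <- unlist(groups$replicates)
  ns <- vapply(groups$replicates, length, 0L)
  N <- sum(ns)
  means <- vapply(groups$replicates, mean, 0)
  df <- N - g
  sse <- sum(vapply(groups$replicates, function(v) sum((v - mean(v))^2), 0))
  mse <- sse / df
  # variance floor so the noiseless limit keeps a decidable test
  grand <- mean(values)
  mse <- max(mse, 1e-12 * grand^2, .Machine$double.xmin)

  ord <- order(means)
  rank_of <- match(seq_len(g), ord)
  pairs <- utils::combn(g, 2)
  tab <- data.frame(
    level_1 = groups$levels[pairs[1, ]],
    level_2 = groups$levels[pairs[2, ]],
    diff = abs(means[pairs[1, ]] - means[pairs[2, ]]),
    span = abs(rank_of[pairs[1, ]] - rank_of[pairs[2, ]]) + 1L
  )
  n_h <- 2 / (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]])
  tab$critical <- stats::qtukey((1 - alpha)^(tab$span - 1), tab$span, df) *
    sqrt(mse / n_h)
  raw_sig <- tab$diff > tab$critical

  # containment: process descending span; a non-significant span blocks all
  # pairs nested inside it (in rank order)
  sig <- logical(nrow(tab))
  blocked <- list()
  lo <- pmin(rank_of[pairs[1, ]], rank_of[pairs[2, ]])
  hi <- pmax(rank_of[pairs[1, ]], rank_of[pairs[2, ]])
  for (idx in order(-tab$span)) {
    inside <- any(vapply(blocked, function(b) lo[idx] >= b[1] && hi[idx] <= b[2],
                         TRUE))
    sig[idx] <- raw_sig[idx] && !inside
    if (!sig[idx]) blocked[[length(blocked) + 1L]] <- c(lo[idx], hi[idx])
  }
  tab$significant <- sig

  structure(
    list(levels = groups$levels, means = means, n = ns, mse = mse, df = df,
         alpha = alpha, comparisons = tab),
    class = "duncan_test"
  )
}

#' @export
print.duncan_test <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df = %d, MSE = %.4g)\n",
              x$alpha, x$df, x$mse))
  tab <- x$comparisons
  tab$diff <- signif(tab$diff, 5)
  tab$critical <- signif(tab$critical, 5)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Limit of detection from a Duncan's-test series
#'
#' The detection limit is the lowest nonzero adulteration level whose
#' replicate intensity group differs significantly (Duncan's multiple range
#' test at level `alpha`) from the genuine-oil (level 0) group. Returns a
#' not-detected sentinel (`lod = NA`) when no level separates.
#'
#' @param series an [intensity_groups()] object containing level 0.
#' @param alpha significance level (default 0.05).
#' @return list of class `"lod_estimate"`: `lod` (percent v/v or `NA`),
#'   `detected`, and the underlying [duncan_test()].
#' @export
determine_lod <- function(series, alpha = 0.05) {
  if (!any(series$levels == 0)) stop_arg("series must contain level 0 (genuine oil)")
  dt <- duncan_test(series, alpha = alpha)
  tab <- dt$comparisons
  vs0 <- tab[tab$level_1 == 0 | tab$level_2 == 0, ]
  other <- ifelse(vs0$level_1 == 0, vs0$level_2, vs0$level_1)
  sig_levels <- sort(other[vs0$significant])
  lod <- if (length(sig_levels)) 100 * sig_levels[1] else NA_real_
  structure(list(lod = lod, detected = !is.na(lod), alpha = alpha, test = dt),
            class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("Limit of detection: %g%% adulteration (Duncan's test, alpha = %g)\n",
                x$lod, x$alpha))
  } else {
    cat(sprintf("Limit of detection: not detected at any tested level (alpha = %g)\n",
                x$alpha))
  }
  invisible(x)
}
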