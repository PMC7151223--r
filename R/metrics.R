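#' Binomial confidence interval implied by an urn size
#'
#' Central `level` interval for the green count of an urn of `size`
#' marbles tracking a trait `prob`: because a stationary urn is
#' `Binomial(size, prob)`, the interval is known by design — the
#' defining advantage of the urn tracker over Elo-style systems.
#'
#' Two conventions are offered. `"normal"` (default) takes the integers
#' inside the normal-approximation band
#' `size * prob +/- z * sqrt(size * prob * (1 - prob))`; this is the band
#' drawn in rating plots and is slightly anti-conservative.
#' `"exact"` takes equal-tail binomial quantiles, which are conservative
#' because of discreteness.
#'
#' @param size Urn size (marbles).
#' @param prob True trait value(s) in (0, 1); vectorised.
#' @param level Confidence level in (0, 1).
#' @param method `"normal"` or `"exact"`.
#' @return For scalar `prob`, an integer vector `c(lower, upper)`; for
#'   vector `prob`, an integer matrix with columns `lower`, `upper`.
#' @examples
#' binomial_ci(60, 0.5)                    # 23 37
#' binomial_ci(60, 0.5, method = "exact")  # 22 38
#' @export
binomial_ci <- function(size, prob, level = 0.95,
                        method = c("normal", "exact")) {
  method <- match.arg(method)
  if (length(size) != 1L || !is.finite(size) || size < 1L) {
    stop("'size' must be a single positive integer")
  }
  if (!is.numeric(prob) || any(prob <= 0 | prob >= 1)) {
    stop("'prob' must lie strictly inside (0, 1)")
  }
  if (length(level) != 1L || level <= 0 || level >= 1) {
    stop("'level' must lie strictly inside (0, 1)")
  }
  if (method == "normal") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    mu <- size * prob
    hw <- z * sqrt(size * prob * (1 - prob))
    lo <- pmax(0L, as.integer(ceiling(mu - hw)))
    hi <- pmin(as.integer(size), as.integer(floor(mu + hw)))
  } else {
    lo <- stats::qbinom((1 - level) / 2, size, prob)
    hi <- stats::qbinom(1 - (1 - level) / 2, size, prob)
  }
  # a central interval always contains the rounded mean
  lo <- as.integer(pmin(lo, round(size * prob)))
  hi <- as.integer(pmax(hi, round(size * prob)))
  if (length(prob) == 1L) {
    c(lower = lo, upper = hi)
  } else {
    cbind(lower = lo, upper = hi)
  }
}

#' Coverage of the urn-implied confidence interval
#'
#' Fraction of entities whose green count lies inside the central
#' binomial interval computed at their true trait value. Defined only
#' for urn-based ratings; Elo ratings carry no implied interval.
#'
#' @param green Integer vector of final green counts.
#' @param size Urn size shared by the entities.
#' @param true_pi True trait values, aligned with `green`.
#' @param level Confidence level.
#' @param method Interval convention, see [binomial_ci()].
#' @return Proportion in \[0, 1\].
#' @export
coverage <- function(green, size, true_pi, level = 0.95,
                     method = c("normal", "exact")) {
  if (length(green) != length(true_pi)) {
    stop("'green' and 'true_pi' must be aligned (same length)")
  }
  ci <- binomial_ci(size, true_pi, level = level, method = match.arg(method))
  if (length(true_pi) == 1L) ci <- matrix(ci, 1L, 2L)
  mean(green >= ci[, 1L] & green <= ci[, 2L])
}

#' Correlation between true traits and tracked ratings
#'
#' Pearson correlation between the true trait values and the urn
#' proportions, on the probability scale (default) or after transforming
#' both to the logit scale (with a half-marble continuity correction for
#' boundary urns).
#'
#' @param true_pi True trait values on the probability scale.
#' @param green,size Urn green counts and common urn size.
#' @param scale `"probability"` or `"logit"`.
#' @return Scalar correlation.
#' @export
rating_correlation <- function(true_pi, green, size,
                               scale = c("probability", "logit")) {
  scale <- match.arg(scale)
  if (length(true_pi) != length(green)) {
    stop("'true_pi' and 'green' must be aligned (same length)")
  }
  if (length(true_pi) < 3L) stop("need at least 3 entities")
  est <- green / size
  if (stats::sd(true_pi) == 0 || stats::sd(est) == 0) {
    stop("zero variance: correlation undefined")
  }
  if (scale == "logit") {
    stats::cor(log(true_pi / (1 - true_pi)), .clamped_logit(green, size))
  } else {
    stats::cor(true_pi, est)
  }
}

#' Cross-sectional rating-spread trajectory
#'
#' Standard deviation of the ratings across persons and across items at
#' every snapshot of a trajectory. For the urn engine ratings are taken
#' to the logit scale (continuity-corrected); for the Elo engine the raw
#' ratings are already on that scale. A stationary, correctly corrected
#' urn system fluctuates around the spread implied by the true traits,
#' whereas the Elo baseline's spread keeps inflating under adaptive
#' selection.
#'
#' @param trajectory A `"rating_trajectory"` (component of a
#'   [run_experiment()] result) with at least 2 snapshots.
#' @param scale `"logit"` (default) or `"probability"` (urn engine only).
#' @return Data frame with columns `session`, `person_sd`, `item_sd`.
#' @export
sd_trajectory <- function(trajectory, scale = c("logit", "probability")) {
  stopifnot(inherits(trajectory, "rating_trajectory"))
  scale <- match.arg(scale)
  if (length(trajectory$sessions) < 2L) stop("need at least 2 snapshots")
  engine <- attr(trajectory, "engine")
  pm <- trajectory$person
  im <- trajectory$item
  if (engine == "urnings") {
    if (scale == "logit") {
      pm <- .clamped_logit(pm, trajectory$person_size)
      im <- .clamped_logit(im, trajectory$item_size)
    } else {
      pm <- pm / trajectory$person_size
      im <- im / trajectory$item_size
    }
  }
  data.frame(session = trajectory$sessions,
             person_sd = apply(pm, 1L, stats::sd),
             item_sd = apply(im, 1L, stats::sd))
}

#' Calibration table of observed vs model-expected success
#'
#' Bins responses by the difference between the pre-response logit
#' ratings of the person and the item, and compares the observed success
#' rate per bin with the Rasch-expected probability — the standard
#' model-fit diagnostic for a tracked rating system. A well-calibrated
#' tracker puts the observed points on the logistic curve.
#'
#' @param records Data frame with columns `score`, `logit_person`,
#'   `logit_item` (pre-response ratings), as produced by [urnings()] or
#'   [run_experiment()] with `keep_responses = TRUE`.
#' @param n_bins Number of equal-width bins over the logit difference.
#' @return Data frame with `midpoint`, `observed`, `expected`, `count`;
#'   empty bins are dropped and flagged in the `"dropped_bins"`
#'   attribute. Counts sum to the number of records.
#' @export
calibration_bins <- function(records, n_bins = 10L) {
  need <- c("score", "logit_person", "logit_item")
  if (!all(need %in% names(records))) {
    stop("'records' needs columns: ", paste(need, collapse = ", "))
  }
  if (n_bins < 1L) stop("'n_bins' must be >= 1")
  d <- records$logit_person - records$logit_item
  if (n_bins == 1L) {
    breaks <- range(d) + c(-1e-9, 1e-9)
  } else {
    breaks <- seq(min(d) - 1e-9, max(d) + 1e-9, length.out = n_bins + 1L)
  }
  bin <- cut(d, breaks, labels = FALSE, include.lowest = TRUE)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  present <- sort(unique(bin))
  out <- data.frame(
    midpoint = mids[present],
    observed = vapply(present, function(b) mean(records$score[bin == b]),
                      numeric(1)),
    expected = vapply(present, function(b) {
      mean(stats::plogis(d[bin == b]))
    }, numeric(1)),
    count = vapply(present, function(b) sum(bin == b), numeric(1))
  )
  attr(out, "dropped_bins") <- setdiff(seq_len(n_bins), present)
  out
}

#' Compare an urn's time distribution with its implied binomial law
#'
#' Kolmogorov-Smirnov-type maximum distance between the empirical
#' distribution of an entity's green count over (post-burn-in, thinned)
#' snapshots and `Binomial(size, true_pi)`. For a stationary, correctly
#' tracked entity this distance stays below the usual KS critical value;
#' a true-value jump inside the window blows it up.
#'
#' @param green Integer vector of snapshot green counts (at least 100).
#' @param size Urn size.
#' @param true_pi True trait value.
#' @return List with `statistic` (max CDF distance), `n` (snapshots) and
#'   `critical_01` (asymptotic KS critical value at alpha = 0.01;
#'   conservative for discrete distributions).
#' @export
ecdf_compare <- function(green, size, true_pi) {
  if (length(green) < 100L) {
    stop("insufficient data: need at least 100 snapshots")
  }
  if (true_pi <= 0 || true_pi >= 1) stop("'true_pi' must be in (0, 1)")
  support <- 0:size
  fhat <- stats::ecdf(green)(support)
  f0 <- stats::pbinom(support, size, true_pi)
  list(statistic = max(abs(fhat - f0)),
       n = length(green),
       critical_01 = sqrt(-log(0.01 / 2) / 2) / sqrt(length(green)))
}

#' Evaluation report for a simulation experiment
#'
#' Bundles the headline diagnostics of a run: Pearson correlations of
#' true traits with final ratings, the urn-interval coverages (persons
#' and items; `NA` for the Elo engine, which has no implied interval),
#' the rating-spread trajectory, and — when the response log was kept —
#' the calibration table.
#'
#' @param experiment An `"urnings_experiment"`.
#' @param level Confidence level for coverage.
#' @param n_bins Calibration bins.
#' @param ci_method Interval convention, see [binomial_ci()].
#' @return Object of class `"urnings_metrics"`.
#' @export
metrics_report <- function(experiment, level = 0.95, n_bins = 10L,
                           ci_method = "normal") {
  stopifnot(inherits(experiment, "urnings_experiment"))
  truth <- experiment$truth
  if (experiment$engine == "urnings") {
    st <- experiment$state
    pc <- rating_correlation(truth$pi_p, st$u_p, st$n_p)
    ic <- rating_correlation(truth$pi_i, st$u_i, st$n_i)
    pcov <- coverage(st$u_p, st$n_p, truth$pi_p, level, ci_method)
    icov <- coverage(st$u_i, st$n_i, truth$pi_i, level, ci_method)
  } else {
    pc <- stats::cor(truth$theta, unname(experiment$state$person_ratings))
    ic <- stats::cor(truth$beta, unname(experiment$state$item_ratings))
    pcov <- NA_real_
    icov <- NA_real_
  }
  cal <- if (!is.null(experiment$records)) {
    calibration_bins(experiment$records, n_bins)
  }
  structure(list(
    engine = experiment$engine,
    person_correlation = pc, item_correlation = ic,
    person_coverage = pcov, item_coverage = icov,
    level = level,
    sd_trajectory = sd_trajectory(experiment$trajectory),
    calibration = cal
  ), class = "urnings_metrics")
}

#' @export
print.urnings_metrics <- function(x, ...) {
  cat(sprintf("Evaluation report (%s engine)\n", x$engine))
  cat(sprintf("  correlation with true traits: persons %.3f, items %.3f\n",
              x$person_correlation, x$item_correlation))
  if (is.na(x$person_coverage)) {
    cat("  interval coverage: not applicable (no implied interval)\n")
  } else {
    cat(sprintf("  %g%% interval coverage: persons %.1f%%, items %.1f%%\n",
                100 * x$level, 100 * x$person_coverage,
                100 * x$item_coverage))
  }
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration: max |observed - expected| = %.3f over %d bins\n",
                max(abs(x$calibration$observed - x$calibration$expected)),
                nrow(x$calibration)))
  }
  invisible(x)
}
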