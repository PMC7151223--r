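# Evaluation suite: intervals, coverage, correlation, trajectories,
# calibration, distributional comparison.

test_that("binomial_ci reproduces the worked interval and its limits", {
  expect_identical(binomial_ci(60, 0.5), c(lower = 23L, upper = 37L))
  expect_identical(binomial_ci(60, 0.5, method = "exact"),
                   c(lower = 22L, upper = 38L))
  # near-certain level covers the full support (exact convention; the
  # normal band approaches it from inside and stays clamped to [0, n])
  expect_identical(binomial_ci(10, 0.5, level = 0.999, method = "exact"),
                   c(lower = 0L, upper = 10L))
  wide <- binomial_ci(60, 0.5, level = 1 - 1e-12)
  narrow <- binomial_ci(60, 0.5, level = 0.95)
  expect_lte(wide[["lower"]], narrow[["lower"]])
  expect_gte(wide[["upper"]], narrow[["upper"]])
  expect_gte(wide[["lower"]], 0L)
  expect_lte(wide[["upper"]], 60L)
  # central interval contains the rounded mean, for both conventions
  for (p in c(0.02, 0.21, 0.5, 0.77, 0.98)) {
    for (m in c("normal", "exact")) {
      ci <- binomial_ci(60, p, method = m)
      expect_gte(round(60 * p), ci[["lower"]])
      expect_lte(round(60 * p), ci[["upper"]])
    }
  }
  # exact equal-tail quantiles agree with qbinom
  ci <- binomial_ci(200, 0.3, method = "exact")
  expect_identical(unname(ci),
                   as.integer(c(qbinom(0.025, 200, 0.3),
                                qbinom(0.975, 200, 0.3))))
  # vectorised over prob
  m <- binomial_ci(60, c(0.3, 0.5, 0.7))
  expect_identical(dim(m), c(3L, 2L))
  expect_error(binomial_ci(60, 0), "inside")
  expect_error(binomial_ci(60, 0.5, level = 1), "inside")
})

test_that("coverage counts entities inside their implied interval", {
  pi <- c(0.3, 0.5, 0.7)
  expect_identical(coverage(round(60 * pi), 60, pi), 1)
  # far-off urns are outside
  expect_identical(coverage(c(0L, 0L, 60L), 60, pi), 0)
  expect_error(coverage(1:3, 60, c(0.5, 0.5)), "aligned")
})

test_that("rating_correlation behaves on both scales and rejects degeneracy", {
  pi <- plogis(rnorm(50))
  expect_equal(rating_correlation(pi, round(100 * pi), 100), 1,
               tolerance = 0.01)
  u <- round(100 * pi)
  expect_equal(rating_correlation(pi, u, 100, scale = "logit"),
               cor(qlogis(pi), log(pmax(u, .5) / (100 - pmax(u, .5)))),
               tolerance = 1e-10)
  expect_error(rating_correlation(rep(0.5, 10), rep(50L, 10), 100),
               "zero variance")
  expect_error(rating_correlation(c(.2, .4), c(1L, 2L), 10), "at least 3")
})

test_that("sd_trajectory is flat for stationary urnings and rising for elo", {
  # constant ratings give exactly zero SD
  tr <- structure(list(sessions = c(10, 20), person = matrix(3L, 2, 5),
                       item = matrix(4L, 2, 5), person_size = 8L,
                       item_size = 8L),
                  class = "rating_trajectory", engine = "urnings")
  s <- sd_trajectory(tr)
  expect_equal(s$person_sd, c(0, 0))

  # stationary corrected urnings: late-run slope indistinguishable from 0
  cfg <- sim_config(n_players = 60, n_items = 40, player_urn_size = 16,
                    item_urn_size = 32, n_sessions = 8000, thin = 80,
                    seed = 31)
  ex <- run_experiment(cfg)
  s <- sd_trajectory(ex$trajectory)
  late <- s[s$session > 0.5 * max(s$session), ]
  f <- lm(person_sd ~ session, late)
  expect_gt(summary(f)$coefficients[2, 4], 0.01)   # no trend detectable
})

test_that("calibration_bins summarises observed vs expected per logit bin", {
  # perfectly Rasch responses at scale
  set.seed(8)
  n <- 5e4
  lp <- rnorm(n); li <- rnorm(n)
  rec <- data.frame(score = rbinom(n, 1, plogis(lp - li)),
                    logit_person = lp, logit_item = li)
  cal <- calibration_bins(rec, n_bins = 10)
  expect_equal(sum(cal$count), n)
  big <- cal[cal$count >= 500, ]
  expect_true(all(abs(big$observed - big$expected) < 0.05))
  # a bin holding only zero logit differences sits at 0.5 (Rasch symmetry)
  d0 <- rep(c(-2, 0, 2), each = 4000)
  rec0 <- data.frame(score = rbinom(length(d0), 1, plogis(d0)),
                     logit_person = d0, logit_item = 0)
  cal0 <- calibration_bins(rec0, n_bins = 3)
  expect_lt(abs(cal0$observed[2] - 0.5), 0.03)
  expect_equal(cal0$expected[2], 0.5)
  # a single bin is the overall accuracy
  cal1 <- calibration_bins(rec, n_bins = 1)
  expect_identical(nrow(cal1), 1L)
  expect_equal(cal1$observed, mean(rec$score))
})

test_that("ecdf_compare is calibrated under the null and detects jumps", {
  set.seed(13)
  # null calibration: direct binomial draws pass in >= 99% of trials
  pass <- logical(200)
  for (t in seq_len(200)) {
    x <- rbinom(500, 60, 0.6)
    ks <- ecdf_compare(x, 60, 0.6)
    pass[t] <- ks$statistic < ks$critical_01
  }
  expect_gte(mean(pass), 0.99)

  # stationary focal chain passes the same test (thinned past the
  # chain's relaxation time, about one urn size of updates)
  u <- focal_chain(0.6, 0.5, 60, n_i = 32, n_items = 80,
                   n_samples = 400, thin = 60, seed = 77)
  ks <- ecdf_compare(u, 60, 0.6)
  expect_lt(ks$statistic, ks$critical_01)

  # a trait jump inside the window breaks the comparison
  u_pre <- focal_chain(0.25, 0.5, 60, n_samples = 200, thin = 25, seed = 5)
  u_post <- focal_chain(0.8, 0.5, 60, n_samples = 200, thin = 25, seed = 6)
  ks_j <- ecdf_compare(c(u_pre, u_post), 60, 0.8)
  expect_gt(ks_j$statistic, ks_j$critical_01)

  expect_error(ecdf_compare(rbinom(50, 60, 0.5), 60, 0.5), "insufficient")
})

test_that("correlation improves with urn size", {
  # tracking error shrinks as urns grow, so true-vs-estimate correlation
  # is ordered in n; averaged over seeds to tame run noise
  sizes <- c(16L, 60L, 200L)
  mean_rho <- sapply(sizes, function(n) {
    mean(sapply(1:3, function(s) {
      cfg <- sim_config(n_players = 40, n_items = 30, player_urn_size = n,
                        item_urn_size = n, n_sessions = 4000, thin = 2000,
                        seed = 100 + s)
      ex <- run_experiment(cfg)
      rating_correlation(ex$truth$pi_p, ex$state$u_p, ex$state$n_p)
    }))
  })
  expect_true(all(diff(mean_rho) > 0))
})

test_that("metrics_report bundles the diagnostics and guards the elo engine", {
  cfg <- sim_config(n_players = 20, n_items = 20, player_urn_size = 16,
                    item_urn_size = 16, n_sessions = 1500, thin = 150,
                    keep_responses = TRUE, seed = 4)
  mr <- metrics_report(run_experiment(cfg))
  expect_s3_class(mr, "urnings_metrics")
  expect_true(abs(mr$person_correlation) <= 1)
  expect_true(mr$person_coverage >= 0 && mr$person_coverage <= 1)
  expect_equal(sum(mr$calibration$count), 15000)
  # same inputs, same report (pure function)
  mr2 <- metrics_report(run_experiment(cfg))
  expect_identical(mr[-which(names(mr) == "sd_trajectory")],
                   mr2[-which(names(mr) == "sd_trajectory")])

  cfg_e <- sim_config(n_players = 20, n_items = 20, n_sessions = 300,
                      engine = "elo", thin = 30, seed = 4)
  mre <- metrics_report(run_experiment(cfg_e))
  expect_true(is.na(mre$person_coverage))   # no implied interval for elo
  expect_true(is.na(mre$item_coverage))
})
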