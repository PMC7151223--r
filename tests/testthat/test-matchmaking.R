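# Adaptive item selection and the acceptance-correction ratio.

test_that("match_weights follows the normal kernel on logit differences", {
  # player logit 0 vs items at logit differences 0 and 1, sd 1:
  # densities (0.3989, 0.2420) -> normalized (0.6224, 0.3776)
  w <- match_weights(urn(30, 60), list(urn(100, 200), urn(146, 200)),
                     match_config())
  expect_equal(sum(w), 1)
  ref <- dnorm(c(0, log(146 / 54))) # kernel at the exact logit diffs
  expect_equal(w, ref / sum(ref), tolerance = 1e-12)

  # identical items -> uniform; adaptive off -> uniform regardless
  expect_equal(match_weights(urn(10, 60), rep(list(urn(77, 200)), 4),
                             match_config()), rep(0.25, 4))
  expect_equal(match_weights(urn(10, 60),
                             list(urn(1, 200), urn(199, 200), urn(77, 200)),
                             match_config(adaptive = FALSE)),
               rep(1 / 3, 3))
  expect_error(match_weights(urn(10, 60), list(), match_config()),
               "non-empty")
})

test_that("kernel weights at logit differences 0 and 1 match the worked example", {
  # integer urns cannot hit a logit difference of exactly 1, so exercise
  # the weighting kernel directly: densities (0.3989, 0.2420) normalise
  # to (0.6224, 0.3776)
  w <- urnings:::.match_weights_vec(0, c(0, 1), offset = 0, sd = 1)
  expect_equal(w, c(0.6224, 0.3776), tolerance = 1e-3)
  expect_equal(w, dnorm(c(0, 1)) / sum(dnorm(c(0, 1))), tolerance = 1e-12)
})

test_that("select_item samples according to the weights", {
  set.seed(31)
  items <- list(urn(60, 200), urn(100, 200), urn(140, 200))
  cfg <- match_config()
  w <- match_weights(urn(30, 60), items, cfg)
  n <- 2e4
  picks <- replicate(n, select_item(urn(30, 60), items, cfg))
  freq <- tabulate(picks, 3) / n
  for (j in 1:3) {
    se <- sqrt(w[j] * (1 - w[j]) / n)
    expect_lt(abs(freq[j] - w[j]), 4 * se)
  }
  expect_identical(select_item(urn(30, 60), items[2], cfg), 1L)
})

test_that("match_ratio agrees with brute-force normalisation and is reversible", {
  items <- list(urn(2, 8), urn(5, 8), urn(7, 8))
  player <- urn(3, 8)
  cfg <- match_config(kernel_sd = 1)
  pr <- propose(player, items[[2]], observed = 1, expected = 0)

  # brute force: recompute both normalized weights from scratch
  clamp_logit <- function(u, n) { g <- min(max(u, .5), n - .5); log(g / (n - g)) }
  wts <- function(lp, lis) { d <- lp - lis; g <- dnorm(d); g / sum(g) }
  li_cur <- sapply(items, function(u) clamp_logit(u$green, u$size))
  m_cur <- wts(clamp_logit(3, 8), li_cur)[2]
  li_new <- li_cur; li_new[2] <- clamp_logit(4, 8)
  m_new <- wts(clamp_logit(4, 8), li_new)[2]
  expect_equal(match_ratio(player, items, 2L, pr, cfg), m_new / m_cur,
               tolerance = 1e-10)

  # reversibility: ratio(u -> u*) * ratio(u* -> u) = 1
  player_new <- urn(pr$player_proposed, 8)
  items_new <- items; items_new[[2]] <- urn(pr$item_proposed, 8)
  back <- propose(player_new, items_new[[2]], observed = 0, expected = 1)
  expect_equal(back$player_proposed, player$green)
  r1 <- match_ratio(player, items, 2L, pr, cfg)
  r2 <- match_ratio(player_new, items_new, 2L, back, cfg)
  expect_equal(r1 * r2, 1, tolerance = 1e-12)

  # identity proposal and non-adaptive selection both give exactly 1
  pr0 <- propose(player, items[[2]], 1, 1)
  expect_identical(match_ratio(player, items, 2L, pr0, cfg), 1)
  expect_identical(match_ratio(player, items, 2L, pr,
                               match_config(adaptive = FALSE)), 1)
})

test_that("match_weights is permutation-equivariant", {
  items <- list(urn(2, 8), urn(5, 8), urn(7, 8), urn(4, 8))
  cfg <- match_config(target_logit_offset = 0.3)
  w <- match_weights(urn(3, 8), items, cfg)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(match_weights(urn(3, 8), items[perm], cfg), w[perm])
})

test_that("adaptive selection with offset 0 yields about 50% observed success", {
  cfg <- sim_config(n_players = 40, n_items = 40, player_urn_size = 32,
                    item_urn_size = 64, n_sessions = 2500, thin = 250,
                    keep_responses = TRUE, seed = 17)
  ex <- run_experiment(cfg)
  late <- ex$records[ex$records$timestamp > 10000, ]
  expect_lt(abs(mean(late$score) - 0.5), 0.05)
})

test_that("match_config validates its parameters", {
  expect_error(match_config(kernel_sd = 0), "positive")
  expect_error(match_config(kernel_sd = -1), "positive")
  expect_error(match_config(target_logit_offset = Inf), "finite")
})
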