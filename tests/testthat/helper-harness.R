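# Shared fixtures, all generated in code.

# A small Rasch-governed response log.
toy_log <- function(n = 200L, n_players = 4L, n_items = 6L, seed = 7L) {
  set.seed(seed)
  theta <- rnorm(n_players)
  beta <- rnorm(n_items)
  p <- sample.int(n_players, n, replace = TRUE)
  i <- sample.int(n_items, n, replace = TRUE)
  data.frame(user_id = paste0("p", p), item_id = paste0("i", i),
             score = rbinom(n, 1L, plogis(theta[p] - beta[i])),
             timestamp = seq_len(n), stringsAsFactors = FALSE)
}

# Chain of one focal player's green count against a pool of items with
# true value pi_i, uniform (non-adaptive) selection. Because every pair
# update conserves the pair's green total, a closed system constrains the
# joint law to a fixed global total; with a pool much larger than the
# focal urn that constraint is negligible and the focal marginal is
# Binomial(n_p, pi_p). Returns thinned post-burn-in focal counts.
focal_chain <- function(pi_p, pi_i, n_p, n_i = 32L, n_items = 80L,
                        n_samples = 2000L, thin = 10L, seed = 1L) {
  set.seed(seed)
  items <- paste0("i", seq_len(n_items))
  # start the focal urn at its equilibrium count: the global green total
  # is conserved, so an off-equilibrium start would tilt every marginal
  st <- urnings_state("p", items, n_p, n_i,
                      initial = list(person = round(n_p * pi_p),
                                     item = rep(n_i %/% 2L, n_items)),
                      match = match_config(adaptive = FALSE),
                      seed = seed + 104729L)
  burn <- 3L * max(n_p, n_i)
  draw <- function() {
    i <- sample.int(n_items, 1L)
    apply_update(st, "p", items[i], simulate_response(pi_p, pi_i))
  }
  for (s in seq_len(burn)) draw()
  out <- integer(n_samples)
  for (k in seq_len(n_samples)) {
    for (s in seq_len(thin)) draw()
    out[k] <- st$u_p
  }
  out
}

# Chi-square goodness of fit of integer samples against Binomial(n, p),
# pooling support cells until every expected count is >= 5.
binom_gof_p <- function(x, n, p) {
  probs <- dbinom(0:n, n, p)
  obs <- tabulate(x + 1L, nbins = n + 1L)
  m <- length(x)
  # pool from both tails inward
  lo <- 1L
  while (m * sum(probs[seq_len(lo)]) < 5 && lo < n) lo <- lo + 1L
  hi <- n + 1L
  while (m * sum(probs[hi:(n + 1L)]) < 5 && hi > lo + 1L) hi <- hi - 1L
  cells <- c(list(seq_len(lo)),
             as.list(if (hi > lo + 1L) (lo + 1L):(hi - 1L) else integer(0)),
             list(hi:(n + 1L)))
  e <- vapply(cells, function(ix) sum(probs[ix]), numeric(1))
  o <- vapply(cells, function(ix) sum(obs[ix]), numeric(1))
  keep <- e > 0
  stat <- sum((o[keep] - m * e[keep])^2 / (m * e[keep]))
  pchisq(stat, df = sum(keep) - 1L, lower.tail = FALSE)
}

# Cross-sectional probability-scale rating SD implied by stationary
# binomial urns for a set of true traits.
implied_rating_sd <- function(pi, n) {
  sqrt(stats::var(pi) + mean(pi * (1 - pi)) / n)
}

# Mean cross-sectional SD (probability scale) of person ratings over the
# final fraction of a trajectory.
late_person_sd <- function(ex, frac = 0.5) {
  tr <- ex$trajectory
  s <- sd_trajectory(tr, scale = "probability")
  keep <- s$session > (1 - frac) * max(s$session)
  mean(s$person_sd[keep])
}
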