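# The "game of chance" view of the Rasch model: the person and the item
# each draw a marble (green with probability pi_p resp. pi_i) until the
# colours differ; the person wins if theirs was the green one. The win
# probability conditional on differing colours is
#   pi_p (1 - pi_i) / (pi_p (1 - pi_i) + pi_i (1 - pi_p)),
# identical to the Rasch probability at (logit pi_p, logit pi_i).
# Draws are taken directly from this conditional distribution rather than
# via the literal rejection loop, which is distribution-equivalent but
# need not terminate at the boundary.

# win probability of the conditional game; NaN when both probabilities sit
# at the same boundary (the rejection loop would never stop)
.game_prob <- function(pi_p, pi_i) {
  a <- pi_p * (1 - pi_i)
  b <- pi_i * (1 - pi_p)
  a / (a + b)
}

#' Simulate a response from the Rasch game of chance
#'
#' Draws a binary outcome with success probability
#' `pi_p (1 - pi_i) / (pi_p (1 - pi_i) + pi_i (1 - pi_p))` — the win
#' probability of the marble-drawing game, equal to the Rasch probability
#' of a correct response at abilities/difficulties `logit(pi_p)`,
#' `logit(pi_i)`.
#'
#' @param pi_p Person success parameter(s) in \[0, 1\].
#' @param pi_i Item parameter(s) in \[0, 1\]. `pi_p` and `pi_i` must not
#'   both be 0 or both 1 (the game is degenerate there).
#' @return Integer vector of 0/1 outcomes, one per input pair.
#' @examples
#' set.seed(1)
#' mean(simulate_response(rep(0.7, 1e4), 0.3))  # close to 0.8448
#' @export
simulate_response <- function(pi_p, pi_i) {
  if (!is.numeric(pi_p) || !is.numeric(pi_i) ||
      any(pi_p < 0 | pi_p > 1) || any(pi_i < 0 | pi_i > 1)) {
    stop("'pi_p' and 'pi_i' must be probabilities in [0, 1]")
  }
  k <- max(length(pi_p), length(pi_i))
  pi_p <- rep_len(pi_p, k)
  pi_i <- rep_len(pi_i, k)
  if (any((pi_p == 0 & pi_i == 0) | (pi_p == 1 & pi_i == 1))) {
    stop("degenerate game: 'pi_p' and 'pi_i' both at the same boundary")
  }
  as.integer(stats::runif(k) < .game_prob(pi_p, pi_i))
}

# expected-outcome win probability from finite urns (Algorithm-2 game);
# doubles throughout (integer products overflow for very large urns)
.xstar_prob <- function(u_p, n_p, u_i, n_i) {
  a <- as.numeric(u_p) * (n_i - u_i)
  b <- as.numeric(n_p - u_p) * u_i
  if (a + b == 0) {
    stop("degenerate game: both urns all-green or both all-red")
  }
  a / (a + b)
}

#' Expected match outcome from two finite urns
#'
#' Plays the marble game with the current urn compositions instead of the
#' true traits: the result `X*` is 1 with probability
#' `u_p (n_i - u_i) / (u_p (n_i - u_i) + (n_p - u_p) u_i)`. `X*` is the
#' Urnings analogue of the Elo expected score, except that it is a binary
#' draw rather than an expectation.
#'
#' @param player,item `"urn"` objects for the person and the item.
#' @return Integer 0 or 1.
#' @examples
#' set.seed(1)
#' expected_outcome(urn(30, 60), urn(100, 200))  # fair coin here
#' @export
expected_outcome <- function(player, item) {
  player <- .as_urn(player, "player")
  item <- .as_urn(item, "item")
  p <- .xstar_prob(player$green, player$size, item$green, item$size)
  as.integer(stats::runif(1L) < p)
}
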