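#' Matchmaking configuration
#'
#' Adaptive item selection targets items whose current rating sits close
#' to the player's: selection weight is proportional to a normal density
#' evaluated at the difference between the logits of the two ratings.
#' With `target_logit_offset = 0` the expected success probability of a
#' selected pair is about 50%; a positive offset targets easier items.
#'
#' @param target_logit_offset Centre of the selection kernel on the
#'   logit-difference scale. Default 0 (approx. 50% success).
#' @param kernel_sd Standard deviation of the normal selection kernel on
#'   the logit scale; must be positive. Default 1.
#' @param adaptive If `FALSE`, items are selected uniformly at random and
#'   the matchmaking correction is a no-op.
#' @return An object of class `"match_config"`.
#' @export
match_config <- function(target_logit_offset = 0, kernel_sd = 1,
                         adaptive = TRUE) {
  if (!is.numeric(kernel_sd) || length(kernel_sd) != 1L || kernel_sd <= 0) {
    stop("'kernel_sd' must be a single positive number")
  }
  if (!is.numeric(target_logit_offset) || length(target_logit_offset) != 1L ||
      !is.finite(target_logit_offset)) {
    stop("'target_logit_offset' must be a single finite number")
  }
  structure(list(target_logit_offset = as.numeric(target_logit_offset),
                 kernel_sd = as.numeric(kernel_sd),
                 adaptive = isTRUE(adaptive)),
            class = "match_config")
}

# normalized selection weights from logit ratings; stable under large
# logit differences (log-space normalisation)
.match_weights_vec <- function(lp, li, offset, sd) {
  d <- (lp - li - offset) / sd
  z <- -0.5 * d * d
  w <- exp(z - max(z))
  w / sum(w)
}

.urn_list_parts <- function(items) {
  if (inherits(items, "urn")) items <- list(items)
  if (!is.list(items) || length(items) == 0L ||
      !all(vapply(items, inherits, logical(1), "urn"))) {
    stop("'items' must be a non-empty list of \"urn\" objects")
  }
  list(green = vapply(items, `[[`, numeric(1), "green"),
       size = vapply(items, `[[`, numeric(1), "size"))
}

#' Adaptive item-selection weights
#'
#' Probability of each candidate item being matched to the player:
#' proportional to `dnorm` of the difference between the logits of the
#' player's and the item's urn proportions (minus the target offset),
#' normalised over the candidate pool. Urn proportions are
#' continuity-corrected by half a marble so boundary urns remain
#' selectable. With `config$adaptive = FALSE` the weights are uniform.
#'
#' @param player An `"urn"` object for the player.
#' @param items Non-empty list of `"urn"` objects, the candidate pool.
#' @param config A [match_config()].
#' @return Numeric probability vector summing to 1, one entry per item.
#' @examples
#' w <- match_weights(urn(30, 60), list(urn(100, 200), urn(146, 200)),
#'                    match_config())
#' @export
match_weights <- function(player, items, config = match_config()) {
  player <- .as_urn(player, "player")
  stopifnot(inherits(config, "match_config"))
  parts <- .urn_list_parts(items)
  k <- length(parts$green)
  if (!config$adaptive) return(rep(1 / k, k))
  lp <- .clamped_logit(player$green, player$size)
  li <- .clamped_logit(parts$green, parts$size)
  .match_weights_vec(lp, li, config$target_logit_offset, config$kernel_sd)
}

#' Select an item for a player
#'
#' Samples one index from the candidate pool with probabilities given by
#' [match_weights()].
#'
#' @inheritParams match_weights
#' @return Integer index into `items`.
#' @export
select_item <- function(player, items, config = match_config()) {
  w <- match_weights(player, items, config)
  sample.int(length(w), 1L, prob = w)
}

#' Matchmaking probability ratio for the acceptance correction
#'
#' The probability `M[p,i]` of item `i` being matched to player `p`
#' changes when an update proposal moves the two urns; the acceptance
#' probability of the proposal must be multiplied by
#' `M[p,i](proposed) / M[p,i](current)` to keep the binomial invariant
#' distribution under adaptive selection. Both numerator and denominator
#' are normalised over the full candidate pool, with the player's urn and
#' item `i`'s urn set to their proposed respectively current values.
#'
#' @param player Current player `"urn"`.
#' @param items List of `"urn"`s — the full candidate pool.
#' @param item_index Position of the matched item within `items`.
#' @param proposal An `"urnings_proposal"` from [propose()].
#' @param config A [match_config()]; with `adaptive = FALSE` the ratio is
#'   exactly 1.
#' @return Positive scalar ratio.
#' @export
match_ratio <- function(player, items, item_index, proposal,
                        config = match_config()) {
  player <- .as_urn(player, "player")
  stopifnot(inherits(config, "match_config"),
            inherits(proposal, "urnings_proposal"))
  parts <- .urn_list_parts(items)
  k <- length(parts$green)
  if (item_index < 1L || item_index > k) stop("'item_index' out of range")
  if (!config$adaptive) return(1)
  li <- .clamped_logit(parts$green, parts$size)
  lp_cur <- .clamped_logit(player$green, player$size)
  w_cur <- .match_weights_vec(lp_cur, li, config$target_logit_offset,
                              config$kernel_sd)
  if (w_cur[item_index] == 0) {
    stop("current matchmaking probability is zero; cannot form ratio")
  }
  lp_prop <- .clamped_logit(proposal$player_proposed, player$size)
  li_prop <- li
  li_prop[item_index] <- .clamped_logit(proposal$item_proposed,
                                        parts$size[item_index])
  w_prop <- .match_weights_vec(lp_prop, li_prop, config$target_logit_offset,
                               config$kernel_sd)
  w_prop[item_index] / w_cur[item_index]
}
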