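#' Build an update proposal from observed and expected outcomes
#'
#' After a game with observed outcome `X` and urn-drawn expected outcome
#' `X*`, the proposed move exchanges marbles between the two urns:
#' `u_p* = u_p + X - X*` and `u_i* = u_i - X + X*`. The pair's total
#' green count is conserved; when `X == X*` the proposal equals the
#' current state.
#'
#' @param player,item Current `"urn"` objects.
#' @param observed,expected Binary outcomes `X` and `X*`.
#' @return An object of class `"urnings_proposal"` with elements
#'   `player_proposed`, `item_proposed`, `observed`, `expected`.
#' @examples
#' propose(urn(2, 4), urn(2, 4), observed = 1, expected = 0)
#' @export
propose <- function(player, item, observed, expected) {
  player <- .as_urn(player, "player")
  item <- .as_urn(item, "item")
  if (!observed %in% c(0L, 1L) || !expected %in% c(0L, 1L)) {
    stop("'observed' and 'expected' must be 0 or 1")
  }
  observed <- as.integer(observed)
  expected <- as.integer(expected)
  u_p_star <- player$green + observed - expected
  u_i_star <- item$green - observed + expected
  if (u_p_star < 0L || u_p_star > player$size ||
      u_i_star < 0L || u_i_star > item$size) {
    # unreachable when 'expected' came from expected_outcome() on these urns
    stop("internal invariant violated: proposal leaves urn bounds")
  }
  structure(list(player_proposed = u_p_star, item_proposed = u_i_star,
                 observed = observed, expected = expected),
            class = "urnings_proposal")
}

# raw acceptance ratio (before the min(1, .) cap); Inf when the proposed
# state makes the expected-outcome game degenerate (denominator 0)
.accept_ratio <- function(u_p, n_p, u_i, n_i, u_p_star, u_i_star) {
  num <- as.numeric(u_p) * (n_i - u_i) + as.numeric(n_p - u_p) * u_i
  den <- as.numeric(u_p_star) * (n_i - u_i_star) +
    as.numeric(n_p - u_p_star) * u_i_star
  if (den == 0) Inf else num / den
}

#' Metropolis-Hastings acceptance probability of a proposal
#'
#' The proposal is accepted with probability
#' `min(1, [u_p(n_i - u_i) + (n_p - u_p) u_i] /
#'         [u_p*(n_i - u_i*) + (n_p - u_p*) u_i*])`.
#' This correction removes the dependence of one urn's invariant
#' distribution on its opponents, making each urn's stationary law
#' exactly `Binomial(n, pi)`. A zero denominator (the proposed state has
#' no valid expected-outcome game) gives probability 1.
#'
#' @param player,item Current `"urn"` objects.
#' @param proposal An `"urnings_proposal"`.
#' @return Acceptance probability in (0, 1\].
#' @examples
#' pr <- propose(urn(2, 4), urn(2, 4), 1, 0)
#' acceptance_probability(urn(2, 4), urn(2, 4), pr)  # 0.8
#' @export
acceptance_probability <- function(player, item, proposal) {
  player <- .as_urn(player, "player")
  item <- .as_urn(item, "item")
  stopifnot(inherits(proposal, "urnings_proposal"))
  min(1, .accept_ratio(player$green, player$size, item$green, item$size,
                       proposal$player_proposed, proposal$item_proposed))
}

#' @rdname acceptance_probability
#' @param match_ratio Matchmaking probability ratio
#'   `M[p,i](proposed) / M[p,i](current)` from [match_ratio()]; under
#'   adaptive item selection the acceptance probability becomes
#'   `min(1, ratio * match_ratio)`. Must be positive.
#' @export
acceptance_probability_matched <- function(player, item, proposal,
                                           match_ratio) {
  player <- .as_urn(player, "player")
  item <- .as_urn(item, "item")
  stopifnot(inherits(proposal, "urnings_proposal"))
  if (!is.numeric(match_ratio) || length(match_ratio) != 1L ||
      is.na(match_ratio) || match_ratio <= 0) {
    stop("'match_ratio' must be a single positive number")
  }
  r <- .accept_ratio(player$green, player$size, item$green, item$size,
                     proposal$player_proposed, proposal$item_proposed)
  min(1, r * match_ratio)
}

# pick a compensating core item for an anchoring exchange, or NA if none
# is eligible. delta_green is the net change just committed on item i:
# +1 -> some other member must give up a green; -1 -> must give up a red.
.anchor_pick <- function(state, i, delta_green, u) {
  cand <- state$core_idx[state$core_idx != i]
  if (delta_green > 0L) {
    cand <- cand[state$u_i[cand] >= 1L]
  } else {
    cand <- cand[state$u_i[cand] <= state$n_i - 1L]
  }
  if (!length(cand)) return(NA_integer_)
  cand[floor(u * length(cand)) + 1L]
}

#' Rebalance the core subset after an anchored item update
#'
#' When an accepted update changes the green count of a core-subset item
#' by `delta_green` (+1 or -1), a compensating member is drawn uniformly
#' among eligible core items (excluding the updated one, and having a
#' marble of the colour to be swapped out) and given the opposite
#' exchange, so the subset's total green count — the fixed point of the
#' measurement scale — is restored.
#'
#' @param state An `"urnings_state"` with a core subset.
#' @param item_id Id of the just-updated core item.
#' @param delta_green Net green change just committed on `item_id`, +1 or
#'   -1.
#' @return The compensating item's id, invisibly. Errors (class
#'   `"urnings_anchor_stall"`) when no member can compensate.
#' @export
anchor_core_subset <- function(state, item_id, delta_green) {
  stopifnot(inherits(state, "urnings_state"))
  if (!length(state$core_idx)) stop("state has no core subset")
  i <- .item_index(state, item_id)
  if (!i %in% state$core_idx) stop("'item_id' is not a core-subset member")
  if (!delta_green %in% c(-1L, 1L)) stop("'delta_green' must be -1 or +1")
  j <- .anchor_pick(state, i, delta_green, .stream_draw(state$ustream, 1L))
  if (is.na(j)) {
    state$anchor_stalls <- state$anchor_stalls + 1L
    stop(structure(class = c("urnings_anchor_stall", "error", "condition"),
                   list(message = "no eligible compensating core item",
                        call = sys.call())))
  }
  state$u_i[j] <- state$u_i[j] - as.integer(delta_green)
  state$l_i[j] <- .clamped_logit(state$u_i[j], state$n_i)
  invisible(state$item_ids[j])
}

# Internal single-update kernel working on indices. Consumes exactly two
# stream uniforms per call (expected-outcome draw, accept draw) plus one
# when an anchoring exchange fires, so matched runs stay draw-aligned.
# Returns 1L accept, 0L reject, -1L skipped (degenerate game).
.update_idx <- function(state, p, i, x) {
  u_p <- state$u_p[p]; n_p <- state$n_p
  u_i <- state$u_i[i]; n_i <- state$n_i
  state$counts_p[p] <- state$counts_p[p] + 1L
  state$counts_i[i] <- state$counts_i[i] + 1L
  dr <- .stream_draw(state$ustream, 2L)

  a <- as.numeric(u_p) * (n_i - u_i)
  b <- as.numeric(n_p - u_p) * u_i
  if (a + b == 0) {           # both urns degenerate in the same direction
    state$skips <- state$skips + 1L
    return(-1L)
  }
  xs <- as.integer(dr[1L] < a / (a + b))
  if (x == xs) {              # identity proposal: always accepted
    state$accepts <- state$accepts + 1L
    return(1L)
  }
  u_p_s <- u_p + x - xs
  u_i_s <- u_i - x + xs
  den <- u_p_s * (n_i - u_i_s) + (n_p - u_p_s) * u_i_s
  r <- if (den == 0) Inf else (a + b) / den
  if (state$use_mm) {
    r <- r * .match_ratio_idx(state, p, i, u_p_s, u_i_s)
  }
  if (dr[2L] >= r) {          # reject (r >= 1 always accepts)
    state$rejects <- state$rejects + 1L
    return(0L)
  }
  if (state$has_core && i %in% state$core_idx) {
    delta <- u_i_s - u_i
    j <- .anchor_pick(state, i, delta, .stream_draw(state$ustream, 1L))
    if (is.na(j)) {           # anchoring stall: roll the whole update back
      state$anchor_stalls <- state$anchor_stalls + 1L
      state$rejects <- state$rejects + 1L
      return(0L)
    }
    state$u_i[j] <- state$u_i[j] - delta
    state$l_i[j] <- .clamped_logit1(state$u_i[j], n_i)
  }
  state$u_p[p] <- u_p_s
  state$u_i[i] <- u_i_s
  state$l_p[p] <- .clamped_logit1(u_p_s, n_p)
  state$l_i[i] <- .clamped_logit1(u_i_s, n_i)
  state$accepts <- state$accepts + 1L
  1L
}

# matchmaking ratio on state indices, for the hot loop; mirrors
# match_ratio() but works off the cached clamped logits
.match_ratio_idx <- function(state, p, i, u_p_s, u_i_s) {
  off <- state$mm_off
  sd <- state$mm_sd
  li <- state$l_i
  d <- (state$l_p[p] - li - off) / sd
  g_cur <- exp(-0.5 * d * d)
  s_cur <- sum(g_cur)
  if (g_cur[i] == 0) return(0)    # numerator will also be ~0; reject
  lp_s <- .clamped_logit1(u_p_s, state$n_p)
  li_s <- li
  li_s[i] <- .clamped_logit1(u_i_s, state$n_i)
  d2 <- (lp_s - li_s - off) / sd
  g_prop <- exp(-0.5 * d2 * d2)
  (g_prop[i] / sum(g_prop)) / (g_cur[i] / s_cur)
}

#' Apply one Urnings update to a live state
#'
#' Performs the full update step for one observed response: draw the
#' expected outcome `X*` from the two urns, build the marble-exchange
#' proposal, compute the Metropolis-Hastings acceptance probability
#' (including the matchmaking ratio when adaptive selection with
#' correction is active), accept or reject, and — for core-subset items —
#' rebalance the subset. Rejected updates leave the urns untouched;
#' per-entity update counters advance either way.
#'
#' @param state An `"urnings_state"` (modified in place).
#' @param person_id,item_id Entity identifiers present in the state.
#' @param observed Binary observed outcome.
#' @return Invisibly, a list with `accepted` (logical) and `skipped`
#'   (logical; `TRUE` when both urns were degenerate in the same
#'   direction and no update was possible).
#' @export
apply_update <- function(state, person_id, item_id, observed) {
  stopifnot(inherits(state, "urnings_state"))
  if (!observed %in% c(0L, 1L)) stop("'observed' must be 0 or 1")
  p <- .person_index(state, person_id)
  i <- .item_index(state, item_id)
  code <- .update_idx(state, p, i, as.integer(observed))
  invisible(list(accepted = code == 1L, skipped = code == -1L))
}
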