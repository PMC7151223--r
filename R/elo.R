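#' Elo Rating System baseline
#'
#' A minimal person-vs-item Elo Rating System (ERS): after each response
#' the person's rating moves by `K (S - E(S))` and the item's rating by
#' the opposite amount, with `E(S)` the Rasch/logistic expected score.
#' The ERS is included as the reference tracker: it has no known error
#' distribution, and under adaptive item selection its cross-sectional
#' rating variance inflates over time — the two drawbacks the Urnings
#' system removes.
#'
#' @param person_ids,item_ids Character vectors of unique identifiers.
#' @param k K-factor (positive); the rating value of a single game.
#' @param initial Initial rating for every person and item (default 0).
#' @return An object of class `"elo_state"`: list with named numeric
#'   vectors `person_ratings` and `item_ratings` and the `k` factor.
#' @export
elo_state <- function(person_ids, item_ids, k = 0.25, initial = 0) {
  person_ids <- as.character(person_ids)
  item_ids <- as.character(item_ids)
  if (anyDuplicated(person_ids) || anyDuplicated(item_ids)) {
    stop("person and item ids must be unique")
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("'k' must be a single positive number")
  }
  if (!is.finite(initial)) stop("'initial' must be finite")
  structure(list(
    person_ratings = stats::setNames(rep(as.numeric(initial),
                                         length(person_ids)), person_ids),
    item_ratings = stats::setNames(rep(as.numeric(initial),
                                       length(item_ids)), item_ids),
    k = as.numeric(k)
  ), class = "elo_state")
}

#' @rdname elo_state
#' @param theta,beta Ratings on the logit scale.
#' @details `elo_expected_score()` is the logistic expected score
#'   `exp(theta - beta) / (1 + exp(theta - beta))`, identical to
#'   [rasch_probability()].
#' @export
elo_expected_score <- function(theta, beta) {
  rasch_probability(theta, beta)
}

#' @rdname elo_state
#' @param state An `"elo_state"`.
#' @param person_id,item_id Identifiers present in the state.
#' @param score Observed binary score `S`.
#' @details `elo_update()` applies the anti-symmetric pair update, so the
#'   sum of the person's and the item's rating is conserved per update.
#' @export
elo_update <- function(state, person_id, item_id, score) {
  stopifnot(inherits(state, "elo_state"))
  if (!score %in% c(0L, 1L)) stop("'score' must be 0 or 1")
  pid <- as.character(person_id)
  iid <- as.character(item_id)
  if (!pid %in% names(state$person_ratings)) {
    stop(sprintf("unknown person id '%s'", pid))
  }
  if (!iid %in% names(state$item_ratings)) {
    stop(sprintf("unknown item id '%s'", iid))
  }
  e <- stats::plogis(state$person_ratings[[pid]] - state$item_ratings[[iid]])
  d <- state$k * (score - e)
  state$person_ratings[[pid]] <- state$person_ratings[[pid]] + d
  state$item_ratings[[iid]] <- state$item_ratings[[iid]] - d
  state
}

#' @export
print.elo_state <- function(x, ...) {
  cat(sprintf("Elo Rating System state: %d persons, %d items, K = %g\n",
              length(x$person_ratings), length(x$item_ratings), x$k))
  invisible(x)
}
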