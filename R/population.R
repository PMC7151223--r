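#' Draw a Rasch population of true traits
#'
#' Person abilities and item difficulties are drawn i.i.d. from normal
#' distributions on the logit scale; the corresponding success
#' parameters are their inverse logits. These true values drive response
#' generation in simulation studies and are what the tracked ratings are
#' evaluated against.
#'
#' @param n_players,n_items Population sizes.
#' @param ability,difficulty Length-2 numeric `(mean, sd)` on the logit
#'   scale; sds must be strictly positive.
#' @return Object of class `"rasch_population"`: list with `theta`,
#'   `beta` (logit scale) and `pi_p`, `pi_i` (probability scale).
#' @examples
#' set.seed(1)
#' pop <- rasch_population(500, 100)
#' @export
rasch_population <- function(n_players, n_items,
                             ability = c(0, 1), difficulty = c(0, 1)) {
  if (n_players < 1L || n_items < 1L) stop("population sizes must be >= 1")
  if (length(ability) != 2L || length(difficulty) != 2L ||
      ability[2L] <= 0 || difficulty[2L] <= 0) {
    stop("'ability' and 'difficulty' must be (mean, sd) with sd > 0")
  }
  theta <- stats::rnorm(n_players, ability[1L], ability[2L])
  beta <- stats::rnorm(n_items, difficulty[1L], difficulty[2L])
  structure(list(theta = theta, beta = beta,
                 pi_p = stats::plogis(theta), pi_i = stats::plogis(beta)),
            class = "rasch_population")
}

#' @export
print.rasch_population <- function(x, ...) {
  cat(sprintf(
    "Rasch population: %d players (mean theta %.2f), %d items (mean beta %.2f)\n",
    length(x$theta), mean(x$theta), length(x$beta), mean(x$beta)))
  invisible(x)
}

#' Simulation study configuration
#'
#' Defaults reproduce the reference simulation design: 500 players and
#' 100 items with standard-normal logit-scale traits, person urns of 60
#' and item urns of 200 marbles initialised half green, 1,000,000
#' sessions in which a uniformly random player answers 10 adaptively
#' selected items (normal selection kernel with SD 1 targeting ~50%
#' success), with the matchmaking acceptance correction on.
#'
#' @param n_players,n_items Population sizes.
#' @param player_urn_size,item_urn_size Urn sizes (even, for the
#'   half-green start).
#' @param n_sessions Number of sessions.
#' @param items_per_session Items answered per session.
#' @param ability,difficulty `(mean, sd)` of logit-scale traits.
#' @param jump Optional `list(player =, session =, new_theta =)`: at the
#'   start of the given session the player's true ability switches to
#'   `new_theta` (an abrupt learning event, used to study tracking lag).
#' @param engine `"urnings"` or `"elo"`.
#' @param elo_k K-factor when `engine = "elo"`.
#' @param match A [match_config()].
#' @param correct_matchmaking Apply the matchmaking acceptance ratio
#'   (Urnings engine only). Switching it off under adaptive selection
#'   demonstrates rating variance inflation.
#' @param core_items Optional ids (of `1:n_items`) forming an anchored
#'   core subset.
#' @param thin Record a ratings snapshot every `thin` sessions.
#' @param keep_responses Keep the full response log (memory-hungry at
#'   full scale; default off).
#' @param seed Integer seed; all randomness in [run_experiment()] derives
#'   from it.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_players = 500L, n_items = 100L,
                       player_urn_size = 60L, item_urn_size = 200L,
                       n_sessions = 1000000L, items_per_session = 10L,
                       ability = c(0, 1), difficulty = c(0, 1),
                       jump = NULL,
                       engine = c("urnings", "elo"), elo_k = 0.25,
                       match = match_config(),
                       correct_matchmaking = TRUE,
                       core_items = NULL,
                       thin = 1000L, keep_responses = FALSE,
                       seed = 1L) {
  engine <- match.arg(engine)
  counts <- c(n_players, n_items, n_sessions, items_per_session, thin)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    stop("population, session and thinning counts must be positive")
  }
  if (length(ability) != 2L || length(difficulty) != 2L ||
      ability[2L] <= 0 || difficulty[2L] <= 0) {
    stop("'ability' and 'difficulty' must be (mean, sd) with sd > 0")
  }
  stopifnot(inherits(match, "match_config"))
  if (!is.null(jump)) {
    if (!is.list(jump) ||
        !all(c("player", "session", "new_theta") %in% names(jump))) {
      stop("'jump' must be list(player = , session = , new_theta = )")
    }
    if (jump$player < 1 || jump$player > n_players) {
      stop("'jump$player' out of range")
    }
  }
  structure(list(
    n_players = as.integer(n_players), n_items = as.integer(n_items),
    player_urn_size = as.integer(player_urn_size),
    item_urn_size = as.integer(item_urn_size),
    n_sessions = as.integer(n_sessions),
    items_per_session = as.integer(items_per_session),
    ability = as.numeric(ability), difficulty = as.numeric(difficulty),
    jump = jump, engine = engine, elo_k = as.numeric(elo_k),
    match = match, correct_matchmaking = isTRUE(correct_matchmaking),
    core_items = core_items,
    thin = as.integer(thin), keep_responses = isTRUE(keep_responses),
    seed = as.integer(seed)
  ), class = "sim_config")
}
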