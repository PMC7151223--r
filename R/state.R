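#' Create a live Urnings system state
#'
#' The state holds one urn per person and per item, per-entity update
#' counters, optional core-subset membership, the matchmaking
#' configuration, and the seeded uniform stream that drives the
#' Metropolis-Hastings update. It is an environment, so update functions
#' modify it in place.
#'
#' @param person_ids,item_ids Character vectors of unique identifiers.
#' @param player_urn_size,item_urn_size Urn sizes (marbles) for the two
#'   entity classes. Each class has a single fixed size.
#' @param initial Either `"half"` (all urns start at 50% green; requires
#'   even sizes) or a list with integer vectors `person` and `item` of
#'   explicit initial green counts.
#' @param core_items Optional character vector of item ids forming the
#'   core subset whose total green count is held constant (scale
#'   anchoring).
#' @param match A [match_config()]. Replayed logs should use
#'   `adaptive = FALSE` (the selection rule that produced a historical
#'   log is unknown, so no matchmaking correction can be applied).
#' @param correct_matchmaking Apply the matchmaking probability ratio in
#'   the acceptance step when `match$adaptive` is `TRUE`.
#' @param seed Integer seed of the update stream.
#' @return An environment of class `"urnings_state"`.
#' @export
urnings_state <- function(person_ids, item_ids,
                          player_urn_size = 60L, item_urn_size = 200L,
                          initial = "half", core_items = NULL,
                          match = match_config(adaptive = FALSE),
                          correct_matchmaking = TRUE,
                          seed = 1L) {
  person_ids <- as.character(person_ids)
  item_ids <- as.character(item_ids)
  if (anyDuplicated(person_ids) || anyDuplicated(item_ids)) {
    stop("person and item ids must be unique")
  }
  n_p <- as.integer(player_urn_size)
  n_i <- as.integer(item_urn_size)
  if (n_p < 1L || n_i < 1L) stop("urn sizes must be >= 1")
  stopifnot(inherits(match, "match_config"))

  P <- length(person_ids)
  I <- length(item_ids)
  if (identical(initial, "half")) {
    if (n_p %% 2L || n_i %% 2L) {
      stop("equal-split initialisation needs even urn sizes; ",
           "pass explicit initial counts instead")
    }
    u_p <- rep(n_p %/% 2L, P)
    u_i <- rep(n_i %/% 2L, I)
  } else {
    if (!is.list(initial) || !all(c("person", "item") %in% names(initial))) {
      stop("'initial' must be \"half\" or list(person = , item = )")
    }
    u_p <- as.integer(rep_len(initial$person, P))
    u_i <- as.integer(rep_len(initial$item, I))
    if (any(u_p < 0L | u_p > n_p) || any(u_i < 0L | u_i > n_i)) {
      stop("initial green counts outside [0, urn size]")
    }
  }

  core_idx <- integer(0)
  if (!is.null(core_items)) {
    core_idx <- match(as.character(core_items), item_ids)
    if (anyNA(core_idx)) stop("unknown item id in 'core_items'")
    if (length(core_idx) < 2L) stop("a core subset needs at least 2 items")
  }

  e <- new.env(parent = emptyenv())
  e$version <- "1"
  e$person_ids <- person_ids
  e$item_ids <- item_ids
  e$n_p <- n_p
  e$n_i <- n_i
  e$u_p <- u_p
  e$u_i <- u_i
  e$l_p <- .clamped_logit(u_p, n_p)
  e$l_i <- .clamped_logit(u_i, n_i)
  e$counts_p <- integer(P)
  e$counts_i <- integer(I)
  e$accepts <- 0L
  e$rejects <- 0L
  e$skips <- 0L
  e$anchor_stalls <- 0L
  e$core_idx <- core_idx
  e$core_total <- sum(u_i[core_idx])
  e$match <- match
  e$correct_matchmaking <- isTRUE(correct_matchmaking)
  # hot-path caches
  e$use_mm <- match$adaptive && isTRUE(correct_matchmaking)
  e$mm_off <- match$target_logit_offset
  e$mm_sd <- match$kernel_sd
  e$has_core <- length(core_idx) > 0L
  e$ustream <- .new_stream(seed)
  e$stream_seed <- as.integer(seed)
  class(e) <- "urnings_state"
  e
}

#' @export
print.urnings_state <- function(x, ...) {
  cat(sprintf(paste0(
    "Urnings system state: %d persons (urn size %d), %d items (urn size %d)\n",
    "  updates: %d accepted, %d rejected, %d skipped\n"),
    length(x$person_ids), x$n_p, length(x$item_ids), x$n_i,
    x$accepts, x$rejects, x$skips))
  if (length(x$core_idx)) {
    cat(sprintf("  core subset: %d items, %d green marbles (anchored)\n",
                length(x$core_idx), x$core_total))
  }
  invisible(x)
}

.person_index <- function(state, id) {
  p <- match(as.character(id), state$person_ids)
  if (is.na(p)) stop(sprintf("unknown person id '%s'", id))
  p
}

.item_index <- function(state, id) {
  i <- match(as.character(id), state$item_ids)
  if (is.na(i)) stop(sprintf("unknown item id '%s'", id))
  i
}

#' Urn ratings held in a state
#'
#' @param state An `"urnings_state"`.
#' @param entity `"person"` or `"item"`.
#' @return Data frame with id, green count, urn size, rating (green /
#'   size) and update count.
#' @export
state_ratings <- function(state, entity = c("person", "item")) {
  stopifnot(inherits(state, "urnings_state"))
  entity <- match.arg(entity)
  if (entity == "person") {
    data.frame(id = state$person_ids, green = state$u_p,
               size = rep(state$n_p, length(state$u_p)),
               rating = state$u_p / state$n_p, updates = state$counts_p,
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = state$item_ids, green = state$u_i,
               size = rep(state$n_i, length(state$u_i)),
               rating = state$u_i / state$n_i, updates = state$counts_i,
               stringsAsFactors = FALSE)
  }
}

#' Save or restore an Urnings state
#'
#' Serialises the complete system state — urns, counters, core subset,
#' matchmaking configuration, the update stream's generator state, and
#' the global RNG state — to plain JSON, so a tracking run can be
#' suspended and resumed with bit-identical results.
#'
#' @param state An `"urnings_state"`.
#' @param path File path.
#' @return `save_state` returns `path` invisibly; `load_state` returns a
#'   restored `"urnings_state"` (and reinstates the saved global RNG
#'   state).
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "urnings_state"))
  grng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  obj <- list(
    format = "urnings_state", version = state$version,
    person_ids = state$person_ids, item_ids = state$item_ids,
    n_p = state$n_p, n_i = state$n_i,
    u_p = state$u_p, u_i = state$u_i,
    counts_p = state$counts_p, counts_i = state$counts_i,
    accepts = state$accepts, rejects = state$rejects,
    skips = state$skips, anchor_stalls = state$anchor_stalls,
    core_items = state$item_ids[state$core_idx],
    match = unclass(state$match),
    correct_matchmaking = state$correct_matchmaking,
    stream_seed = state$stream_seed,
    stream = .stream_snapshot(state$ustream),
    global_rng = if (is.null(grng)) NULL else as.integer(grng)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("corrupted or unreadable state file: ",
                         conditionMessage(e))
                  })
  if (!identical(obj$format, "urnings_state")) {
    stop("not an urnings state file")
  }
  if (!identical(obj$version, "1")) {
    stop(sprintf("state file version '%s' is not supported by this release",
                 obj$version))
  }
  e <- urnings_state(
    obj$person_ids, obj$item_ids, obj$n_p, obj$n_i,
    initial = list(person = obj$u_p, item = obj$u_i),
    core_items = if (length(obj$core_items)) obj$core_items else NULL,
    match = do.call(match_config, obj$match[c("target_logit_offset",
                                              "kernel_sd", "adaptive")]),
    correct_matchmaking = obj$correct_matchmaking,
    seed = obj$stream_seed
  )
  e$counts_p <- as.integer(obj$counts_p)
  e$counts_i <- as.integer(obj$counts_i)
  e$accepts <- as.integer(obj$accepts)
  e$rejects <- as.integer(obj$rejects)
  e$skips <- as.integer(obj$skips)
  e$anchor_stalls <- as.integer(obj$anchor_stalls)
  e$ustream <- .stream_restore(obj$stream)
  if (!is.null(obj$global_rng)) {
    assign(".Random.seed", as.integer(obj$global_rng), envir = globalenv())
  }
  e
}
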