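#' Fit Urnings ratings to a response log
#'
#' Replays an ordered person-by-item response stream through the urn
#' tracker: every person and item is an urn initialised half green, and
#' each response triggers one Metropolis-Hastings marble exchange. The
#' green proportion of an urn estimates the inverse-logit trait, with a
#' known `Binomial(n, pi)` error law once the entity has passed burn-in.
#' Replay applies no matchmaking correction: for a historical log the
#' selection rule that produced it is unknown, so the correction cannot
#' be formed.
#'
#' @param data A `"response_log"` from [read_response_log()], or any data
#'   frame with columns `user_id`, `item_id`, `score` (0/1) and
#'   `timestamp`. Rows are replayed in timestamp order (stably sorted if
#'   needed).
#' @param player_urn_size,item_urn_size Urn sizes; even numbers, since
#'   urns start at 50% green. Larger urns mean more precision but slower
#'   tracking of trait changes — urn size is the accuracy dial, playing
#'   the role the K-factor plays in Elo systems.
#' @param seed Integer seed for the update draws; a refit with the same
#'   seed and data is bit-identical.
#' @param core_items Optional item ids whose total green count is held
#'   constant (scale anchoring over time).
#' @param burn_in Updates an entity must have received before its rating
#'   is treated as stationary; default three times its urn size.
#' @param thin Trajectory snapshot spacing in responses; default about
#'   1000 snapshots over the log.
#' @return An object of class `"urnings"` with components `person` and
#'   `item` (rating tables), `records` (the replayed log with pre-update
#'   logit ratings, one-step-ahead fitted probabilities and acceptance
#'   flags), `trajectory`, `acceptance_rate`, `burn_in`, `state` (the
#'   live final state) and `call`. Supports `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict`, `plot` and `simulate`.
#' @examples
#' set.seed(7)
#' toy <- data.frame(user_id = sample(letters[1:4], 200, TRUE),
#'                   item_id = sample(LETTERS[1:6], 200, TRUE),
#'                   score = rbinom(200, 1, 0.5), timestamp = 1:200)
#' fit <- urnings(toy, player_urn_size = 8, item_urn_size = 8)
#' coef(fit)
#' @export
urnings <- function(data, player_urn_size = 30L, item_urn_size = 80L,
                    seed = 1L, core_items = NULL, burn_in = NULL,
                    thin = NULL) {
  cl <- match.call()
  need <- c("user_id", "item_id", "score", "timestamp")
  if (!all(need %in% names(data))) {
    stop("'data' needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(data$score %in% c(0L, 1L))) stop("'score' must be 0/1")
  if (is.unsorted(order(data$timestamp))) data <- data[order(data$timestamp), ]
  persons <- unique(as.character(data$user_id))
  items <- unique(as.character(data$item_id))
  state <- urnings_state(persons, items,
                         player_urn_size = player_urn_size,
                         item_urn_size = item_urn_size,
                         core_items = core_items,
                         match = match_config(adaptive = FALSE),
                         seed = as.integer(seed) + 104729L)
  R <- nrow(data)
  p_idx <- match(as.character(data$user_id), persons)
  i_idx <- match(as.character(data$item_id), items)
  score <- as.integer(data$score)
  if (is.null(thin)) thin <- max(1L, R %/% 1000L)
  n_snap <- R %/% thin
  person_snap <- matrix(0L, n_snap, length(persons))
  item_snap <- matrix(0L, n_snap, length(items))
  lp0 <- numeric(R); li0 <- numeric(R); acc <- integer(R)
  si <- 0L
  for (r in seq_len(R)) {
    p <- p_idx[r]; i <- i_idx[r]
    lp0[r] <- state$l_p[p]
    li0[r] <- state$l_i[i]
    acc[r] <- .update_idx(state, p, i, score[r])
    if (r %% thin == 0L) {
      si <- si + 1L
      person_snap[si, ] <- state$u_p
      item_snap[si, ] <- state$u_i
    }
  }
  if (is.null(burn_in)) {
    burn_in <- c(person = 3L * state$n_p, item = 3L * state$n_i)
  } else {
    burn_in <- c(person = as.integer(burn_in[[1L]]),
                 item = as.integer(burn_in[[length(burn_in)]]))
  }
  records <- data.frame(
    user_id = as.character(data$user_id), item_id = as.character(data$item_id),
    score = score, timestamp = data$timestamp,
    logit_person = lp0, logit_item = li0,
    fitted = stats::plogis(lp0 - li0),
    accepted = acc == 1L, stringsAsFactors = FALSE)
  tot <- state$accepts + state$rejects
  structure(list(
    person = state_ratings(state, "person"),
    item = state_ratings(state, "item"),
    records = records,
    trajectory = structure(
      list(sessions = seq_len(n_snap) * thin,
           person = person_snap, item = item_snap,
           person_size = state$n_p, item_size = state$n_i),
      class = "rating_trajectory", engine = "urnings"),
    acceptance_rate = state$accepts / max(tot, 1L),
    skips = state$skips,
    burn_in = burn_in,
    seed = as.integer(seed),
    state = state,
    call = cl
  ), class = "urnings")
}

#' @export
print.urnings <- function(x, ...) {
  cat("Urnings ratings fit\n")
  cat(sprintf("  %d responses, %d persons (urn size %d), %d items (urn size %d)\n",
              nrow(x$records), nrow(x$person), x$state$n_p,
              nrow(x$item), x$state$n_i))
  cat(sprintf("  acceptance rate %.3f; burn-in %d/%d updates (person/item)\n",
              x$acceptance_rate, x$burn_in[["person"]], x$burn_in[["item"]]))
  invisible(x)
}

#' @export
summary.urnings <- function(object, ...) {
  ps <- object$person; is_ <- object$item
  out <- list(
    n_responses = nrow(object$records),
    n_persons = nrow(ps), n_items = nrow(is_),
    sizes = c(person = object$state$n_p, item = object$state$n_i),
    acceptance_rate = object$acceptance_rate,
    skips = object$skips,
    person_quartiles = stats::quantile(ps$rating),
    item_quartiles = stats::quantile(is_$rating),
    prop_past_burnin = c(
      person = mean(ps$updates >= object$burn_in[["person"]]),
      item = mean(is_$updates >= object$burn_in[["item"]])),
    brier = mean((object$records$score - object$records$fitted)^2)
  )
  class(out) <- "summary.urnings"
  out
}

#' @export
print.summary.urnings <- function(x, ...) {
  cat("Urnings ratings fit\n")
  cat(sprintf("  %d responses by %d persons (urn %d) to %d items (urn %d)\n",
              x$n_responses, x$n_persons, x$sizes[["person"]],
              x$n_items, x$sizes[["item"]]))
  cat(sprintf("  MH acceptance rate %.3f; %d degenerate games skipped\n",
              x$acceptance_rate, x$skips))
  cat(sprintf("  past burn-in: %.0f%% of persons, %.0f%% of items\n",
              100 * x$prop_past_burnin[["person"]],
              100 * x$prop_past_burnin[["item"]]))
  cat("  person rating quartiles:\n")
  print(round(x$person_quartiles, 3))
  cat("  item rating quartiles:\n")
  print(round(x$item_quartiles, 3))
  cat(sprintf("  one-step-ahead Brier score: %.4f\n", x$brier))
  invisible(x)
}

#' @export
coef.urnings <- function(object, entity = c("person", "item"),
                         scale = c("probability", "logit"), ...) {
  entity <- match.arg(entity)
  scale <- match.arg(scale)
  tab <- object[[entity]]
  est <- if (scale == "logit") {
    .clamped_logit(tab$green, tab$size[1L])
  } else {
    tab$rating
  }
  stats::setNames(est, tab$id)
}

#' @export
fitted.urnings <- function(object, ...) {
  object$records$fitted
}

#' @export
residuals.urnings <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$records$score - object$records$fitted
  if (type == "pearson") {
    f <- object$records$fitted
    r <- r / sqrt(f * (1 - f))
  }
  r
}

#' Predict success probabilities from fitted ratings
#'
#' @param object An `"urnings"` fit.
#' @param newdata Optional data frame with columns `user_id` and
#'   `item_id`; defaults to the one-step-ahead fitted probabilities of
#'   the training log.
#' @param type `"prob"` for the Rasch success probability, `"logit"` for
#'   the logit difference.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.urnings <- function(object, newdata = NULL,
                            type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "prob") object$records$fitted
           else stats::qlogis(object$records$fitted))
  }
  lp <- coef(object, "person", "logit")[as.character(newdata$user_id)]
  li <- coef(object, "item", "logit")[as.character(newdata$item_id)]
  if (anyNA(lp) || anyNA(li)) stop("unknown person or item id in 'newdata'")
  d <- unname(lp - li)
  if (type == "prob") stats::plogis(d) else d
}

#' Plot method for Urnings fits
#'
#' `which = "trajectory"` draws the rating trajectory of one entity with
#' the urn-implied confidence band around it; `which = "calibration"`
#' draws observed success rates per logit-difference bin against the
#' logistic curve.
#'
#' @param x An `"urnings"` fit.
#' @param which `"trajectory"` or `"calibration"`.
#' @param id Entity id for the trajectory plot (default: first person).
#' @param entity `"person"` or `"item"` for the trajectory plot.
#' @param level Confidence level of the band.
#' @param n_bins Bins for the calibration plot.
#' @param ... Passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.urnings <- function(x, which = c("trajectory", "calibration"),
                         id = NULL, entity = c("person", "item"),
                         level = 0.95, n_bins = 10L, ...) {
  which <- match.arg(which)
  if (which == "calibration") {
    cal <- calibration_bins(x$records, n_bins)
    graphics::plot(cal$midpoint, cal$observed, pch = 16,
                   xlab = "logit(person rating) - logit(item rating)",
                   ylab = "P(correct)", ylim = c(0, 1), ...)
    grid_x <- seq(min(cal$midpoint), max(cal$midpoint), length.out = 200)
    graphics::lines(grid_x, stats::plogis(grid_x), col = "blue")
    return(invisible(x))
  }
  entity <- match.arg(entity)
  tab <- x[[entity]]
  if (is.null(id)) id <- tab$id[1L]
  k <- match(as.character(id), tab$id)
  if (is.na(k)) stop(sprintf("unknown %s id '%s'", entity, id))
  mat <- x$trajectory[[entity]]
  n <- if (entity == "person") x$trajectory$person_size else x$trajectory$item_size
  r <- mat[, k] / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(r * (1 - r), 1 / n) / n)
  graphics::plot(x$trajectory$sessions, r, type = "l", ylim = c(0, 1),
                 xlab = "response index", ylab = "rating (green / size)",
                 main = sprintf("%s %s", entity, id), ...)
  graphics::lines(x$trajectory$sessions, pmin(1, r + z * se), lty = 3)
  graphics::lines(x$trajectory$sessions, pmax(0, r - z * se), lty = 3)
  invisible(x)
}

#' Simulate response streams from fitted ratings
#'
#' Draws binary responses for the observed person-item pairs at the
#' one-step-ahead fitted probabilities — a quick parametric-bootstrap
#' device for checking fit statistics.
#'
#' @param object An `"urnings"` fit.
#' @param nsim Number of replicate streams.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of 0/1 draws, one row per
#'   training record.
#' @export
simulate.urnings <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- object$records$fitted
  out <- as.data.frame(
    vapply(seq_len(nsim), function(s) stats::rbinom(length(f), 1L, f),
           integer(length(f))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
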