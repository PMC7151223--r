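#' Read a response log from CSV
#'
#' Parses a person-by-item response stream with columns `user_id`,
#' `item_id`, `score`, `timestamp` (names remappable via `dialect`),
#' recodes non-numeric score symbols (e.g. a question-mark "no answer"
#' treated as incorrect), drops unparseable rows with a warning, applies
#' optional filters, and returns the records stably sorted by timestamp
#' (file order breaks ties).
#'
#' @param path CSV file with a header row.
#' @param dialect Named character vector mapping the canonical column
#'   names `user_id`, `item_id`, `score`, `timestamp` to the file's
#'   column names.
#' @param min_responses Keep only users with at least this many (valid,
#'   in-window) responses.
#' @param date_range Optional length-2 vector; rows with timestamps
#'   outside `[date_range[1], date_range[2]]` are dropped.
#' @param recode Optional named vector recoding score symbols before
#'   numeric conversion, e.g. `c("?" = 0)`.
#' @return A data frame of class `"response_log"` with canonical column
#'   names, integer 0/1 `score`, and attributes `skipped_rows` and
#'   `source`.
#' @export
read_response_log <- function(path,
                              dialect = c(user_id = "user_id",
                                          item_id = "item_id",
                                          score = "score",
                                          timestamp = "timestamp"),
                              min_responses = 1L,
                              date_range = NULL,
                              recode = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  need <- c("user_id", "item_id", "score", "timestamp")
  if (!all(need %in% names(dialect))) {
    stop("'dialect' must name columns for: ", paste(need, collapse = ", "))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(unname(dialect[need]), names(raw))
  if (length(missing_cols)) {
    stop("format error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(user_id = raw[[dialect[["user_id"]]]],
                   item_id = raw[[dialect[["item_id"]]]],
                   score = raw[[dialect[["score"]]]],
                   timestamp = raw[[dialect[["timestamp"]]]],
                   stringsAsFactors = FALSE)
  if (!is.null(recode)) {
    hit <- df$score %in% names(recode)
    df$score[hit] <- as.character(recode[df$score[hit]])
  }
  score_num <- suppressWarnings(as.numeric(df$score))
  ok <- !is.na(score_num) & score_num %in% c(0, 1)
  skipped <- sum(!ok)
  if (skipped > 0L) {
    warning(sprintf("skipped %d row(s) with unparseable or non-binary scores",
                    skipped))
  }
  df <- df[ok, , drop = FALSE]
  df$score <- as.integer(score_num[ok])
  ts_num <- suppressWarnings(as.numeric(df$timestamp))
  if (!anyNA(ts_num)) df$timestamp <- ts_num
  if (!is.null(date_range)) {
    if (length(date_range) != 2L) stop("'date_range' must have length 2")
    df <- df[df$timestamp >= date_range[1L] & df$timestamp <= date_range[2L],
             , drop = FALSE]
  }
  df <- df[order(df$timestamp), , drop = FALSE]    # stable: ties keep file order
  if (min_responses > 1L) {
    tab <- table(df$user_id)
    keep <- names(tab)[tab >= min_responses]
    df <- df[df$user_id %in% keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("response_log", "data.frame"),
            skipped_rows = skipped, source = path)
}

#' Write a response log to CSV
#'
#' @param x Data frame with columns `user_id`, `item_id`, `score`,
#'   `timestamp` (e.g. the `records` component of a simulation run).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_response_log <- function(x, path) {
  need <- c("user_id", "item_id", "score", "timestamp")
  if (!all(need %in% names(x))) {
    stop("'x' needs columns: ", paste(need, collapse = ", "))
  }
  utils::write.csv(x[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
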