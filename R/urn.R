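#' Construct an urn
#'
#' An urn is the basic rating container of the Urnings system: `size`
#' marbles of which `green` are green. The proportion `green / size` is
#' the current rating, an estimate of the inverse-logit trait `pi`.
#' When the tracked trait is stationary the green count has invariant
#' distribution `Binomial(size, pi)`, which is what makes the rating's
#' standard error known by construction.
#'
#' @param green Number of green marbles (integer, `0 <= green <= size`).
#' @param size Total number of marbles (integer, `>= 1`).
#' @return An object of class `"urn"`: a list with elements `green` and
#'   `size`.
#' @examples
#' u <- urn(30, 60)
#' proportion(u)  # 0.5
#' @export
urn <- function(green, size) {
  if (length(green) != 1L || length(size) != 1L ||
      !is.finite(green) || !is.finite(size) ||
      green != round(green) || size != round(size)) {
    stop("'green' and 'size' must be single integers")
  }
  green <- as.integer(green)
  size <- as.integer(size)
  if (size < 1L) stop("'size' must be >= 1")
  if (green < 0L || green > size) stop("'green' must lie in [0, size]")
  structure(list(green = green, size = size), class = "urn")
}

#' @rdname urn
#' @param x An `"urn"` object.
#' @export
proportion <- function(x) {
  stopifnot(inherits(x, "urn"))
  x$green / x$size
}

#' @export
print.urn <- function(x, ...) {
  cat(sprintf("Urn: %d green / %d marbles (rating %.3f)\n",
              x$green, x$size, x$green / x$size))
  invisible(x)
}

.as_urn <- function(x, what = "urn") {
  if (!inherits(x, "urn")) stop(sprintf("'%s' must be an \"urn\" object", what))
  x
}
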