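# Small shared helpers.

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds away from zero), used for the
#' climate-zone percentage matrix so that rounded rows can sum to slightly
#' more or less than 100 (e.g. 101 for a 27-species group with counts
#' 5/4/14/1/3).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stopifnot() with a readable message
.check <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Seed handling: generators set the seed themselves so that identical
# (config, seed) pairs give identical tables.
.set_seed <- function(seed) {
  .check(is.null(seed) || (is.numeric(seed) && length(seed) == 1 && is.finite(seed)),
         "'seed' must be a single finite number or NULL")
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Standard error of the mean; NA-safe, 0 for a single value.
.se <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n <= 1) return(0)
  stats::sd(x) / sqrt(n)
}
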