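# Soft-bound fossil calibration densities.
#
# A calibration places mass 1 - 2*tail uniformly between t_min and t_max
# (ages in units of 100 My) and exactly `tail` mass (default 2.5%) beyond
# each bound, decaying monotonically and continuously:
#   * below t_min: a power tail  h * (t / t_min)^p  on (0, t_min], with p
#     chosen so the tail mass is exact; requires h * t_min > tail, i.e.
#     the bound must sit far enough from 0 to carry the tail mass;
#   * above t_max: an exponential tail  h * exp(-lambda (t - t_max)) with
#     lambda = h / tail.
# Both tails have closed-form CDFs, so the density can be sampled by
# inversion and prior-reproduction checks are exact.

#' Construct a soft-bound calibration
#'
#' @param node_label label of the calibrated node in the tree.
#' @param t_min,t_max hard core bounds, `0 <= t_min < t_max`, in 100 My.
#' @param tail probability mass beyond each bound (default 0.025).
#' @return a `calibration` object with the derived tail parameters.
#' @examples
#' cal <- calibration("root", 5.8, 12.3)
#' @export
calibration <- function(node_label, t_min, t_max, tail = 0.025) {
  .check(t_min >= 0 && t_min < t_max, "need 0 <= t_min < t_max")
  .check(tail > 0 && tail < 0.5, "'tail' must be in (0, 0.5)")
  h <- (1 - 2 * tail) / (t_max - t_min)
  .check(h * t_min > tail,
         "t_min too close to 0 to carry the lower tail mass; widen the core or lower 'tail'")
  structure(list(node_label = node_label, t_min = t_min, t_max = t_max,
                 tail = tail, height = h,
                 power = h * t_min / tail - 1,   # lower-tail exponent
                 lambda = h / tail),             # upper-tail decay rate
            class = "calibration")
}

#' Soft-bound calibration density, log scale
#'
#' Finite for every `t > 0`; errors on non-positive ages.
#'
#' @param t positive ages (vectorized).
#' @param cal a [calibration()].
#' @return log-density values.
#' @export
calibration_logdensity <- function(t, cal) {
  .check(inherits(cal, "calibration"), "'cal' must come from calibration()")
  .check(all(t > 0), "ages must be positive")
  log(dcalibration(t, cal))
}

#' Soft-bound calibration density
#'
#' @inheritParams calibration_logdensity
#' @return density values.
#' @export
dcalibration <- function(t, cal) {
  h <- cal$height
  ifelse(t < cal$t_min,
         h * (t / cal$t_min)^cal$power,
         ifelse(t <= cal$t_max, h,
                h * exp(-cal$lambda * (t - cal$t_max))))
}

#' Soft-bound calibration CDF
#'
#' @inheritParams calibration_logdensity
#' @return cumulative probabilities.
#' @export
pcalibration <- function(t, cal) {
  a <- cal$tail
  h <- cal$height
  ifelse(t <= 0, 0,
         ifelse(t < cal$t_min,
                a * (t / cal$t_min)^(cal$power + 1),
                ifelse(t <= cal$t_max,
                       a + h * (t - cal$t_min),
                       1 - a * exp(-cal$lambda * (t - cal$t_max)))))
}

#' Soft-bound calibration quantile function
#'
#' @param p probabilities in (0, 1).
#' @param cal a [calibration()].
#' @return ages.
#' @export
qcalibration <- function(p, cal) {
  .check(all(p > 0 & p < 1), "'p' must be in (0, 1)")
  a <- cal$tail
  h <- cal$height
  ifelse(p < a,
         cal$t_min * (p / a)^(1 / (cal$power + 1)),
         ifelse(p <= 1 - a,
                cal$t_min + (p - a) / h,
                cal$t_max - log((1 - p) / a) / cal$lambda))
}

#' Sample from a soft-bound calibration density
#'
#' Inverse-CDF sampling.
#'
#' @param n number of draws.
#' @param cal a [calibration()].
#' @return numeric vector of ages.
#' @export
rcalibration <- function(n, cal) {
  qcalibration(stats::runif(n), cal)
}

# Coerce a calibration table (node_label, t_min, t_max[, tail]) into a
# named list of calibration objects.
.as_calibration_list <- function(calibrations) {
  if (inherits(calibrations, "calibration")) calibrations <- list(calibrations)
  if (is.data.frame(calibrations)) {
    tail <- if ("tail" %in% names(calibrations)) calibrations$tail else
      rep(0.025, nrow(calibrations))
    calibrations <- lapply(seq_len(nrow(calibrations)), function(i) {
      calibration(calibrations$node_label[i], calibrations$t_min[i],
                  calibrations$t_max[i], tail[i])
    })
  }
  .check(all(vapply(calibrations, inherits, logical(1), "calibration")),
         "calibrations must be calibration() objects or a node_label/t_min/t_max table")
  stats::setNames(calibrations,
                  vapply(calibrations, `[[`, character(1), "node_label"))
}
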