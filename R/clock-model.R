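# Relaxed-clock model components: hyperpriors, rate prior, branch-length
# expectations and the approximate (Gaussian) branch-length likelihood.

#' Relaxed-clock model container
#'
#' Independent-rates model: each branch rate is i.i.d. log-normal with the
#' mean-preserving parameterization `log r ~ Normal(log mu - sigma2/2,
#' sigma2)`, so `E[r] = mu`.  Hyperpriors (read as shape/rate): `mu ~
#' Gamma(2, 20)` (mean 0.1 substitutions per site per 100 My) and `sigma2
#' ~ Gamma(1, 10)`.
#'
#' @param mu mean rate (> 0).
#' @param sigma2 log-scale rate variance (>= 0).
#' @param rates per-branch rates (all > 0).
#' @param mu_shape,mu_rate,s2_shape,s2_rate gamma hyperprior parameters.
#' @return a `clock_model` list.
#' @export
clock_model <- function(mu, sigma2, rates,
                        mu_shape = 2, mu_rate = 20,
                        s2_shape = 1, s2_rate = 10) {
  .check(mu > 0, "'mu' must be positive")
  .check(sigma2 >= 0, "'sigma2' must be >= 0")
  .check(all(rates > 0), "all branch rates must be positive")
  .check(all(c(mu_shape, mu_rate, s2_shape, s2_rate) > 0),
         "hyperprior parameters must be positive")
  structure(list(mu = mu, sigma2 = sigma2, rates = rates,
                 mu_shape = mu_shape, mu_rate = mu_rate,
                 s2_shape = s2_shape, s2_rate = s2_rate),
            class = "clock_model")
}

#' Log-density of the clock prior
#'
#' Sum of the gamma hyperprior log-densities for `mu` and `sigma2` and the
#' independent log-normal log-densities of the branch rates.  In the
#' degenerate strict-clock limit `sigma2 = 0` the rate prior is a point
#' mass at `mu`: the log-density is `+Inf` if every rate equals `mu` and
#' `-Inf` otherwise.
#'
#' @param model a [clock_model()].
#' @return scalar log-density.
#' @export
clock_prior_logdensity <- function(model) {
  .check(inherits(model, "clock_model"), "'model' must come from clock_model()")
  gam <- stats::dgamma(model$mu, shape = model$mu_shape, rate = model$mu_rate,
                       log = TRUE) +
    stats::dgamma(model$sigma2, shape = model$s2_shape, rate = model$s2_rate,
                  log = TRUE)
  if (model$sigma2 == 0) {
    return(if (all(model$rates == model$mu)) Inf else -Inf)
  }
  gam + sum(stats::dlnorm(model$rates,
                          meanlog = log(model$mu) - model$sigma2 / 2,
                          sdlog = sqrt(model$sigma2), log = TRUE))
}

#' Expected branch lengths under a clock model
#'
#' The clock identity: expected substitutions per site on a branch are
#' `rate x duration` (durations in 100 My).
#'
#' @param tree an `ape` phylo with edge lengths equal to branch durations.
#' @param model a [clock_model()] whose `rates` align with `tree$edge`.
#' @return numeric vector of expected lengths, one per edge.
#' @export
expected_branch_lengths <- function(tree, model) {
  .check(inherits(tree, "phylo"), "'tree' must be an ape phylo")
  .check(length(model$rates) == nrow(tree$edge),
         "need one rate per branch")
  model$rates * tree$edge.length
}

#' Approximate branch-length log-likelihood
#'
#' Independent Gaussian approximation: each observed branch-length estimate
#' `b_hat` is normal around the model's expected length with the estimate's
#' variance, `sum(-(b_hat - b)^2 / (2 v) - log(2 pi v) / 2)`.
#'
#' @param branch_data data.frame with `observed_length` and `variance`
#'   (all variances > 0), aligned with `expected`.
#' @param expected expected branch lengths (same order).
#' @return scalar log-likelihood.
#' @export
approx_loglik <- function(branch_data, expected) {
  .check(all(c("observed_length", "variance") %in% names(branch_data)),
         "branch_data needs 'observed_length' and 'variance'")
  .check(nrow(branch_data) == length(expected),
         "branch data and expectations must align per branch")
  .check(all(branch_data$variance > 0), "branch-length variances must be > 0")
  sum(stats::dnorm(branch_data$observed_length, mean = expected,
                   sd = sqrt(branch_data$variance), log = TRUE))
}
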