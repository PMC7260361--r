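# Soft-bound calibrations, clock priors, the approximate likelihood, the
# dating MCMC and chronogram summaries.

test_that("soft-bound density has exact tail masses and a flat core", {
  cal <- calibration("root", 5.8, 12.3)
  lo <- stats::integrate(function(t) dcalibration(t, cal), 0, 5.8)$value
  hi <- stats::integrate(function(t) dcalibration(t, cal), 12.3, Inf)$value
  tot <- stats::integrate(function(t) dcalibration(t, cal), 0, Inf,
                          rel.tol = 1e-9)$value
  expect_equal(lo, 0.025, tolerance = 1e-6)
  expect_equal(hi, 0.025, tolerance = 1e-6)
  expect_equal(tot, 1, tolerance = 1e-6)
  expect_equal(dcalibration((5.8 + 12.3) / 2, cal), 0.95 / 6.5,
               tolerance = 1e-12)
  # continuity at both bounds, finite log-density everywhere on t > 0
  eps <- 1e-9
  expect_equal(dcalibration(5.8 - eps, cal), dcalibration(5.8 + eps, cal),
               tolerance = 1e-6)
  expect_equal(dcalibration(12.3 - eps, cal), dcalibration(12.3 + eps, cal),
               tolerance = 1e-6)
  expect_true(all(is.finite(calibration_logdensity(
    c(0.001, 1, 5.8, 9, 12.3, 50), cal))))
  expect_error(calibration_logdensity(-1, cal), "positive")
})

test_that("calibration CDF, quantile and sampler are mutually consistent", {
  cal <- calibration("x", 2, 7, tail = 0.025)
  p <- c(0.001, 0.024, 0.025, 0.3, 0.5, 0.975, 0.999)
  expect_equal(pcalibration(qcalibration(p, cal), cal), p, tolerance = 1e-12)
  set.seed(5)
  x <- rcalibration(5000, cal)
  expect_lt(abs(mean(x < 2) - 0.025), 0.01)
  expect_lt(abs(mean(x > 7) - 0.025), 0.01)
  ks <- stats::ks.test(x, function(t) pcalibration(t, cal))
  expect_gt(ks$p.value, 0.01)
})

test_that("a lower bound too close to zero is rejected", {
  expect_error(calibration("x", 0.001, 5), "lower tail")
})

test_that("clock prior matches closed-form gamma and log-normal densities", {
  model <- clock_model(mu = 0.08, sigma2 = 0.2, rates = c(0.05, 0.1, 0.2))
  hand_gamma <- function(x, shape, rate)
    shape * log(rate) - lgamma(shape) + (shape - 1) * log(x) - rate * x
  hand_lnorm <- function(r, mu, s2) {
    m <- log(mu) - s2 / 2
    -log(r) - 0.5 * log(2 * pi * s2) - (log(r) - m)^2 / (2 * s2)
  }
  expected <- hand_gamma(0.08, 2, 20) + hand_gamma(0.2, 1, 10) +
    sum(hand_lnorm(c(0.05, 0.1, 0.2), 0.08, 0.2))
  expect_equal(clock_prior_logdensity(model), expected, tolerance = 1e-10)
})

test_that("the rate prior is mean-preserving and degenerates at sigma2 = 0", {
  set.seed(6)
  r <- rlnorm(1e5, log(0.1) - 0.15 / 2, sqrt(0.15))
  expect_lt(abs(mean(r) - 0.1), 3 * sd(r) / sqrt(1e5))
  strict_ok <- clock_model(0.1, 0, rates = rep(0.1, 4))
  expect_equal(clock_prior_logdensity(strict_ok), Inf)
  strict_bad <- clock_model(0.1, 0, rates = c(0.1, 0.2))
  expect_equal(clock_prior_logdensity(strict_bad), -Inf)
})

test_that("expected branch lengths obey the clock identities", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  model <- clock_model(0.1, 0, rates = rep(0.1, nrow(tr$edge)))
  b <- expected_branch_lengths(tr, model)
  expect_equal(b, tr$edge.length * 0.1)
  # rate-time confounding: double ages, halve rates
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  model2 <- clock_model(0.05, 0, rates = rep(0.05, nrow(tr$edge)))
  expect_equal(expected_branch_lengths(tr2, model2), b)
  # strict clock: equal root-to-tip sums
  tr$edge.length <- b
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:3]), rep(0.2, 3))
})

test_that("approximate likelihood is a Gaussian in the branch lengths", {
  bd <- data.frame(observed_length = c(0.1, 0.3), variance = c(0.01, 0.04))
  at_opt <- approx_loglik(bd, c(0.1, 0.3))
  expect_equal(at_opt, -0.5 * sum(log(2 * pi * c(0.01, 0.04))),
               tolerance = 1e-12)
  one <- data.frame(observed_length = 0.1, variance = 0.01)
  expect_equal(approx_loglik(one, 0.2) - approx_loglik(one, 0.1), -0.5,
               tolerance = 1e-12)
  # monotone decay away from the optimum, one coordinate at a time
  lls <- vapply(seq(0.1, 0.5, by = 0.1), function(b)
    approx_loglik(one, b), numeric(1))
  expect_true(all(diff(lls) < 0))
  # scaling all variances by c shifts the optimum log-likelihood by -n/2 log c
  bd_scaled <- bd
  bd_scaled$variance <- bd$variance * 4
  expect_equal(approx_loglik(bd_scaled, c(0.1, 0.3)) - at_opt,
               -0.5 * 2 * log(4), tolerance = 1e-12)
  expect_error(approx_loglik(data.frame(observed_length = 1, variance = 0), 1),
               "> 0")
})

test_that("the sampler refuses unidentifiable or ill-referenced setups", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_error(run_dating_mcmc(tr, calibration("n5", 0.5, 1.5),
                               settings = mcmc_settings(200, 50, 1, 1)),
               "root must carry a calibration")
  expect_error(run_dating_mcmc(tr, calibration("nope", 1, 3),
                               settings = mcmc_settings(200, 50, 1, 1)),
               "not present")
})

test_that("prior-only sampling matches the calibration core mass", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  fit <- run_dating_mcmc(tr, calibration("n4", 4, 6),
                         settings = mcmc_settings(12000, 2000, 5, chains = 1,
                                                  seed = 2))
  x <- fit$chains[[1]][, "n4"]
  expect_equal(mean(x >= 4 & x <= 6), 0.95, tolerance = 0.025)
  expect_equal(mean(x), 5, tolerance = 0.1)
  # nested node stays below the root at all times
  expect_true(all(fit$chains[[1]][, "n5"] < fit$chains[[1]][, "n4"]))
})

test_that("two chains with different seeds agree on a simulated dataset", {
  sim <- gen_chronology(chrono_sim_config(n_tips = 8, root_age = 5,
                                          sigma2 = 0.05), seed = 21)
  fit <- run_dating_mcmc(sim$tree, calibration("n9", 4, 6), sim$branch_data,
                         mcmc_settings(6000, 1500, 3, chains = 2, seed = 11))
  s <- summarize_chronogram(fit, tol = 0.02)
  expect_true(s$converged)
  expect_lte(s$max_discrepancy, 0.02)
  expect_true(all(s$node_summary$hpd_lower <= s$node_summary$mean_age))
  expect_true(all(s$node_summary$hpd_upper >= s$node_summary$mean_age))
})

test_that("identical chains give zero discrepancy and a pass", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  fit <- run_dating_mcmc(tr, calibration("n4", 4, 6),
                         settings = mcmc_settings(2000, 500, 2, chains = 1,
                                                  seed = 3))
  fit$chains[[2]] <- fit$chains[[1]]
  s <- summarize_chronogram(fit)
  expect_true(s$converged)
  expect_equal(s$max_discrepancy, 0)
})

test_that("the HPD of a near-uniform marginal is the central 95%", {
  set.seed(8)
  x <- runif(5000)
  h <- hpd_interval(x, 0.95)
  expect_equal(unname(h[["upper"]] - h[["lower"]]), 0.95, tolerance = 0.02)
})

test_that("annotated chronograms round-trip through Newick", {
  sim <- gen_chronology(chrono_sim_config(n_tips = 6), seed = 31)
  fit <- run_dating_mcmc(sim$tree, calibration("n7", 4, 6), sim$branch_data,
                         mcmc_settings(3000, 1000, 4, chains = 2, seed = 5))
  s <- summarize_chronogram(fit)
  f <- tempfile(fileext = ".nwk")
  write_chronogram(s, f)
  back <- read_chronogram(f)
  expect_equal(back$node_summary$node, s$node_summary$node)
  expect_equal(back$node_summary$mean_age, s$node_summary$mean_age,
               tolerance = 1e-4)
  expect_equal(back$node_summary$hpd_upper, s$node_summary$hpd_upper,
               tolerance = 1e-4)
  expect_equal(ape::Ntip(back$tree), 6)
  unlink(f)
})

test_that("strict-clock mode recovers the generating rate on clean data", {
  sim <- gen_chronology(chrono_sim_config(n_tips = 8, root_age = 5, mu = 0.1,
                                          sigma2 = 0, noise_var = 0), seed = 41)
  bd <- sim$branch_data
  bd$variance <- 1e-6
  fit <- run_dating_mcmc(sim$tree, calibration("n9", 4, 6), bd,
                         mcmc_settings(6000, 1500, 3, chains = 2, seed = 7,
                                       fix_sigma2 = TRUE))
  pooled <- do.call(rbind, fit$chains)
  # posterior rate ~ total observed length / total duration at the
  # posterior ages; with the root pinned near truth this is near mu
  expect_equal(mean(pooled[, "mean_rate"]), 0.1, tolerance = 0.05)
  expect_true(all(pooled[, "sigma2"] == 0))
})
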