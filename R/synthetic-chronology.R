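# Synthetic time trees with independent log-normal branch rates.
#
# Time is measured in units of 100 My throughout (the reporting convention
# of the dated tree); leaves sit at age 0 and ages increase into the past.
# Branch rates are i.i.d. log-normal with the mean-preserving
# parameterization log r ~ Normal(log mu - sigma2/2, sigma2), so E[r] = mu
# for every rate-variance sigma2.

#' Chronology simulation configuration
#'
#' @param n_tips number of tips (>= 3).
#' @param root_age root age in units of 100 My (> 0).
#' @param mu mean branch rate (substitutions per site per 100 My).
#' @param sigma2 log-scale rate variance of the independent-rates model
#'   (>= 0; 0 is a strict clock).
#' @param noise_var Gaussian observation variance added to expected branch
#'   lengths (>= 0).
#' @param truncate_noise logical; truncate noisy observed lengths at 0
#'   (default `TRUE`, physical branch-length estimates).  Set `FALSE` to
#'   simulate from exactly the untruncated Gaussian observation model the
#'   dating engine's approximate likelihood assumes -- required for
#'   simulation-based calibration checks, where any model mismatch
#'   (including truncation) would be confounded with sampler error.
#' @param calibrations optional calibration table
#'   (`node_label`, `t_min`, `t_max`) carried through to the output.
#' @param age_model `"conditional_uniform"` (default; each internal node
#'   age uniform on (0, parent age), matching the dating engine's prior on
#'   uncalibrated nodes) or `"coalescent"` (coalescent node depths rescaled
#'   to the root age).
#' @return a validated `chrono_sim_config` list.
#' @export
chrono_sim_config <- function(n_tips = 8, root_age = 5, mu = 0.1,
                              sigma2 = 0.1, noise_var = 1e-4,
                              calibrations = NULL,
                              age_model = c("conditional_uniform", "coalescent"),
                              truncate_noise = TRUE) {
  age_model <- match.arg(age_model)
  .check(n_tips >= 3, "'n_tips' must be >= 3")
  .check(root_age > 0, "'root_age' must be positive")
  .check(mu > 0, "'mu' must be positive")
  .check(sigma2 >= 0, "'sigma2' must be >= 0")
  .check(noise_var >= 0, "'noise_var' must be >= 0")
  if (!is.null(calibrations)) {
    .check(all(calibrations$t_min < calibrations$t_max),
           "calibration t_min must be < t_max")
    .check(all(calibrations$t_min >= 0), "calibration bounds must be >= 0")
  }
  structure(list(n_tips = as.integer(n_tips), root_age = root_age, mu = mu,
                 sigma2 = sigma2, noise_var = noise_var,
                 calibrations = calibrations, age_model = age_model,
                 truncate_noise = isTRUE(truncate_noise)),
            class = "chrono_sim_config")
}

# Node ages of an ultrametric phylo: distance from root to node, subtracted
# from tree height.
.node_ages_from_phylo <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths) - depths
  ages[seq_len(ape::Ntip(tree))] <- 0
  ages[seq_len(n_node)]
}

# Assign internal node ages top-down: root fixed, every other internal node
# uniform on (0, parent age).  Children are visited after parents.
.conditional_uniform_ages <- function(tree, root_age) {
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  ages <- numeric(n_tip + tree$Nnode)
  ages[root] <- root_age
  # cladewise edge order visits parents before children
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child > n_tip) {
      ages[child] <- stats::runif(1, 0, ages[tree$edge[e, 1]])
    }
  }
  ages
}

#' Simulate a time tree, branch rates and observed branch lengths
#'
#' Draws a random rooted binary topology, node ages (children strictly
#' younger than parents, leaves at age 0), i.i.d. log-normal branch rates,
#' expected branch lengths `rate x duration`, and observed lengths with
#' additive Gaussian noise truncated at 0.
#'
#' @param config a [chrono_sim_config()].
#' @param seed integer seed.
#' @return list with `tree` (an `ape` phylo; edge lengths are branch
#'   durations in 100 My, internal nodes labelled `n<index>`), `ages`
#'   (named node ages), `rates` (per edge), `branch_data` (data.frame
#'   `branch_id`, `duration`, `expected_length`, `observed_length`,
#'   `variance`) and the `config`.
#' @examples
#' sim <- gen_chronology(chrono_sim_config(n_tips = 5, sigma2 = 0), seed = 1)
#' @export
gen_chronology <- function(config = chrono_sim_config(), seed = NULL) {
  .check(inherits(config, "chrono_sim_config"),
         "'config' must come from chrono_sim_config()")
  .set_seed(seed)
  n_tip <- config$n_tips
  tree <- ape::rcoal(n_tip, tip.label = sprintf("t%d", seq_len(n_tip)))
  tree$node.label <- sprintf("n%d", n_tip + seq_len(tree$Nnode))
  if (config$age_model == "coalescent") {
    ages <- .node_ages_from_phylo(tree)
    ages <- ages * config$root_age / max(ages)
  } else {
    ages <- .conditional_uniform_ages(tree, config$root_age)
  }
  # rebuild edge lengths as durations from the assigned ages
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  n_edge <- nrow(tree$edge)
  rates <- if (config$sigma2 == 0) {
    rep(config$mu, n_edge)
  } else {
    stats::rlnorm(n_edge, log(config$mu) - config$sigma2 / 2,
                  sqrt(config$sigma2))
  }
  expected <- rates * tree$edge.length
  observed <- if (config$noise_var > 0) {
    noisy <- expected + stats::rnorm(n_edge, 0, sqrt(config$noise_var))
    if (config$truncate_noise) pmax(0, noisy) else noisy
  } else expected
  all_labels <- c(tree$tip.label, tree$node.label)
  names(ages) <- all_labels
  branch_data <- data.frame(branch_id = all_labels[tree$edge[, 2]],
                            duration = tree$edge.length,
                            expected_length = expected,
                            observed_length = observed,
                            variance = config$noise_var)
  list(tree = tree, ages = ages, rates = rates, branch_data = branch_data,
       config = config)
}
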