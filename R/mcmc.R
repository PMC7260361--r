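# Metropolis-within-Gibbs sampler for node dating on a fixed rooted
# topology.
#
# Target: p(ages, rates, mu, sigma2 | data) proportional to
#   prod_cal cal(t_node)                      soft-bound calibrations
#   x prod_{v internal, v != root} 1/t_parent(v)   conditional-uniform ages
#   x Gamma(mu) Gamma(sigma2) prod_b LogNormal(r_b | mu, sigma2)
#   x prod_b Normal(b_hat_b | r_b * duration_b, v_b)   approximate likelihood
# subject to parent age > child age everywhere (enforced by proposal
# rejection).  With `branch_data = NULL` the sampler targets the prior
# alone; the marginal of a calibrated root then reproduces the calibration
# density exactly, which the tests exploit.
#
# Node ages use sliding-window proposals, rates and hyperparameters
# log-scale multiplier proposals.  Two likelihood-invariant mixing moves
# handle the rate-time ridges the single-site updates cannot cross: a
# joint scale move (all ages times c, all rates and mu divided by c), and
# a compensated age move (one node age slides while its adjacent branch
# rates are rescaled to keep the expected branch lengths fixed).  Step
# sizes are auto-tuned during burn-in toward 20-40% acceptance.
#
# The chain body is deliberately written with flat local arrays, scalar
# piecewise densities and per-sweep batched uniforms: the sampler is run
# hundreds of times in the simulation-calibration experiments, so
# interpreter overhead in this loop dominates their cost.

#' MCMC settings for the dating sampler
#'
#' @param iterations total iterations per chain.
#' @param burnin iterations discarded (and used for step-size tuning);
#'   must be < `iterations`.
#' @param sample_every thinning interval (>= 1).
#' @param chains number of chains (default 2; two or more are needed for
#'   the convergence check in [summarize_chronogram()]).
#' @param seed master seed; chain `i` uses `seed + i - 1`.
#' @param fix_sigma2 logical; `TRUE` fixes `sigma2 = 0` (strict clock:
#'   all branch rates equal `mu`).
#' @param w_age,w_rate,w_mu,w_s2,w_scale initial proposal step sizes
#'   (tuned during burn-in).
#' @return an `mcmc_settings` list.
#' @export
mcmc_settings <- function(iterations = 20000, burnin = 5000,
                          sample_every = 10, chains = 2, seed = 1,
                          fix_sigma2 = FALSE,
                          w_age = 0.5, w_rate = 0.5, w_mu = 0.3, w_s2 = 0.7,
                          w_scale = 0.2) {
  .check(burnin >= 0 && burnin < iterations, "'burnin' must be < 'iterations'")
  .check(sample_every >= 1, "'sample_every' must be >= 1")
  .check(chains >= 1, "need at least one chain (two for convergence checks)")
  .check(all(c(w_age, w_rate, w_mu, w_s2, w_scale) > 0),
         "step sizes must be positive")
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 sample_every = as.integer(sample_every),
                 chains = as.integer(chains), seed = seed,
                 fix_sigma2 = isTRUE(fix_sigma2),
                 w_age = w_age, w_rate = w_rate, w_mu = w_mu, w_s2 = w_s2,
                 w_scale = w_scale),
            class = "mcmc_settings")
}

# log-normal rate log-density, vectorized, mean-preserving parameterization
.rate_logprior <- function(r, mu, sigma2) {
  m <- log(mu) - sigma2 / 2
  -log(r) - (log(r) - m)^2 / (2 * sigma2) - 0.5 * log(2 * pi * sigma2)
}

.gauss_ll <- function(obs, mean, v) {
  -(obs - mean)^2 / (2 * v) - 0.5 * log(2 * pi * v)
}

# Single chain.  `pre` holds the preprocessed tree structure.
.run_chain <- function(pre, settings, chain_seed) {
  set.seed(as.integer(chain_seed))
  root <- pre$root
  internal <- pre$internal
  n_int <- length(internal)
  n_edge <- pre$n_edge
  has_data <- !is.null(pre$obs)
  strict <- settings$fix_sigma2

  # flat locals: the chain body runs hot
  obs <- pre$obs
  vvar <- pre$vvar
  parent <- pre$parent
  parent_edge <- pre$parent_edge
  parent_of <- pre$parent_of
  child_of <- pre$child_of
  children <- pre$children
  child_edges <- pre$child_edges
  n_ic <- pre$n_internal_children
  mu_shape <- pre$mu_shape; mu_rate <- pre$mu_rate
  s2_shape <- pre$s2_shape; s2_rate <- pre$s2_rate

  # calibrations indexed by node number; log-height precomputed
  cal_at <- vector("list", pre$n_nodes)
  for (nd in names(pre$cals)) {
    cal <- pre$cals[[nd]]
    cal$log_h <- log(cal$height)
    cal_at[[as.integer(nd)]] <- cal
  }
  cal_nodes <- which(!vapply(cal_at, is.null, logical(1)))
  cal_ld <- function(cal, t) {
    if (t < cal$t_min) {
      cal$log_h + cal$power * (log(t) - log(cal$t_min))
    } else if (t <= cal$t_max) {
      cal$log_h
    } else {
      cal$log_h - cal$lambda * (t - cal$t_max)
    }
  }

  # --- initialization ---------------------------------------------------
  ages <- numeric(pre$n_nodes)
  root_cal <- cal_at[[root]]
  t_root0 <- (root_cal$t_min + root_cal$t_max) / 2
  depth_frac <- (max(pre$depth) + 1 - pre$depth) / (max(pre$depth) + 1)
  ages[internal] <- t_root0 * depth_frac[internal]
  ages[root] <- t_root0
  mu <- 0.1
  sigma2 <- if (strict) 0 else 0.05
  rates <- rep(mu, n_edge)

  w_age <- rep(settings$w_age * t_root0 / 4, pre$n_nodes)
  w_comp <- rep(settings$w_age * t_root0 / 4, pre$n_nodes)
  w_rate <- settings$w_rate
  w_mu <- settings$w_mu
  w_s2 <- settings$w_s2
  w_scale <- settings$w_scale

  # acceptance bookkeeping per block for tuning
  acc <- list(age = numeric(pre$n_nodes), age_n = numeric(pre$n_nodes),
              comp = numeric(pre$n_nodes), comp_n = numeric(pre$n_nodes),
              rate = 0, rate_n = 0, mu = 0, mu_n = 0, s2 = 0, s2_n = 0,
              scale = 0, scale_n = 0)

  n_keep <- floor((settings$iterations - settings$burnin) / settings$sample_every)
  keep_cols <- c(pre$labels[internal], "mu", "sigma2", "mean_rate")
  samples <- matrix(NA_real_, n_keep, length(keep_cols),
                    dimnames = list(NULL, keep_cols))
  k <- 0L

  for (iter in seq_len(settings$iterations)) {
    # --- node ages ------------------------------------------------------
    u_prop <- stats::runif(n_int, -1, 1)
    u_acc <- log(stats::runif(n_int))
    for (i in seq_len(n_int)) {
      v <- internal[i]
      kids <- children[[v]]
      lower <- max(ages[kids])
      upper <- if (v == root) Inf else ages[parent[v]]
      t_old <- ages[v]
      t_new <- t_old + u_prop[i] * w_age[v]
      acc$age_n[v] <- acc$age_n[v] + 1
      if (t_new <= lower || t_new >= upper) next
      cal <- cal_at[[v]]
      delta <- if (is.null(cal)) 0 else cal_ld(cal, t_new) - cal_ld(cal, t_old)
      if (n_ic[v] > 0) delta <- delta - n_ic[v] * (log(t_new) - log(t_old))
      if (has_data) {
        pe <- parent_edge[v]
        if (!is.na(pe)) {
          up <- ages[parent[v]]
          r <- rates[pe]
          delta <- delta +
            ((obs[pe] - r * (up - t_old))^2 - (obs[pe] - r * (up - t_new))^2) /
              (2 * vvar[pe])
        }
        ce <- child_edges[[v]]
        rc <- rates[ce]
        oc <- obs[ce]
        ac <- ages[child_of[ce]]
        delta <- delta + sum(((oc - rc * (t_old - ac))^2 -
                                (oc - rc * (t_new - ac))^2) / (2 * vvar[ce]))
      }
      if (u_acc[i] < delta) {
        ages[v] <- t_new
        acc$age[v] <- acc$age[v] + 1
      }
    }

    # --- compensated age moves ------------------------------------------
    # slide one node age and rescale the rates of its adjacent branches so
    # every expected branch length (hence the likelihood) is unchanged;
    # only the age prior, rate prior and the Jacobian of the rate
    # rescaling enter the acceptance ratio
    if (!strict && has_data) {
      u_prop <- stats::runif(n_int, -1, 1)
      u_acc <- log(stats::runif(n_int))
      for (i in seq_len(n_int)) {
        v <- internal[i]
        lower <- max(ages[children[[v]]])
        upper <- if (v == root) Inf else ages[parent[v]]
        t_old <- ages[v]
        t_new <- t_old + u_prop[i] * w_comp[v]
        acc$comp_n[v] <- acc$comp_n[v] + 1
        if (t_new <= lower || t_new >= upper) next
        pe <- parent_edge[v]
        ce <- child_edges[[v]]
        adj <- if (is.na(pe)) ce else c(pe, ce)
        dur_old <- ages[parent_of[adj]] - ages[child_of[adj]]
        dur_new <- dur_old
        if (!is.na(pe)) dur_new[1] <- ages[parent[v]] - t_new
        ci <- seq.int(length(adj) - length(ce) + 1L, length(adj))
        dur_new[ci] <- t_new - ages[child_of[ce]]
        r_old <- rates[adj]
        r_new <- r_old * dur_old / dur_new
        cal <- cal_at[[v]]
        delta <- if (is.null(cal)) 0 else cal_ld(cal, t_new) - cal_ld(cal, t_old)
        if (n_ic[v] > 0) delta <- delta - n_ic[v] * (log(t_new) - log(t_old))
        delta <- delta +
          sum(.rate_logprior(r_new, mu, sigma2) -
                .rate_logprior(r_old, mu, sigma2)) +
          sum(log(dur_old / dur_new))
        if (u_acc[i] < delta) {
          ages[v] <- t_new
          rates[adj] <- r_new
          acc$comp[v] <- acc$comp[v] + 1
        }
      }
    }

    # --- branch rates ---------------------------------------------------
    # element-wise multiplier MH: given ages and hyperparameters the rate
    # full conditionals are independent across branches, so all branches
    # can be proposed and accepted in one vectorized block
    if (!strict) {
      eps <- stats::runif(n_edge, -w_rate, w_rate)
      r_new <- rates * exp(eps)
      delta <- .rate_logprior(r_new, mu, sigma2) -
        .rate_logprior(rates, mu, sigma2) + eps
      if (has_data) {
        dur <- ages[parent_of] - ages[child_of]
        delta <- delta + ((obs - rates * dur)^2 - (obs - r_new * dur)^2) /
          (2 * vvar)
      }
      accept <- log(stats::runif(n_edge)) < delta
      rates[accept] <- r_new[accept]
      acc$rate <- acc$rate + sum(accept)
      acc$rate_n <- acc$rate_n + n_edge
    }

    # --- mean rate mu ---------------------------------------------------
    eps <- stats::runif(1, -w_mu, w_mu)
    mu_new <- mu * exp(eps)
    delta <- stats::dgamma(mu_new, mu_shape, rate = mu_rate, log = TRUE) -
      stats::dgamma(mu, mu_shape, rate = mu_rate, log = TRUE) + eps
    if (strict) {
      if (has_data) {
        dur <- ages[parent_of] - ages[child_of]
        delta <- delta + sum(((obs - mu * dur)^2 - (obs - mu_new * dur)^2) /
                               (2 * vvar))
      }
    } else {
      delta <- delta + sum(.rate_logprior(rates, mu_new, sigma2) -
                             .rate_logprior(rates, mu, sigma2))
    }
    acc$mu_n <- acc$mu_n + 1
    if (log(stats::runif(1)) < delta) {
      mu <- mu_new
      if (strict) rates <- rep(mu, n_edge)
      acc$mu <- acc$mu + 1
    }

    # --- rate variance sigma2 -------------------------------------------
    if (!strict) {
      eps <- stats::runif(1, -w_s2, w_s2)
      s2_new <- sigma2 * exp(eps)
      delta <- stats::dgamma(s2_new, s2_shape, rate = s2_rate, log = TRUE) -
        stats::dgamma(sigma2, s2_shape, rate = s2_rate, log = TRUE) + eps +
        sum(.rate_logprior(rates, mu, s2_new) -
              .rate_logprior(rates, mu, sigma2))
      acc$s2_n <- acc$s2_n + 1
      if (log(stats::runif(1)) < delta) {
        sigma2 <- s2_new
        acc$s2 <- acc$s2 + 1
      }
    }

    # --- joint rate-time scale move -------------------------------------
    # ages[internal] *= c, mu /= c, rates /= c.  The conditional-uniform
    # terms cancel the age Jacobian and the rate prior cancels the rate
    # Jacobian exactly, leaving only the calibration and mu-prior terms.
    eps <- stats::runif(1, -w_scale, w_scale)
    cfac <- exp(eps)
    mu_new <- mu / cfac
    delta <- stats::dgamma(mu_new, mu_shape, rate = mu_rate, log = TRUE) -
      stats::dgamma(mu, mu_shape, rate = mu_rate, log = TRUE)
    for (v in cal_nodes) {
      delta <- delta + cal_ld(cal_at[[v]], ages[v] * cfac) -
        cal_ld(cal_at[[v]], ages[v])
    }
    acc$scale_n <- acc$scale_n + 1
    if (log(stats::runif(1)) < delta) {
      ages[internal] <- ages[internal] * cfac
      mu <- mu_new
      rates <- if (strict) rep(mu, n_edge) else rates / cfac
      acc$scale <- acc$scale + 1
    }

    # --- step-size tuning during burn-in --------------------------------
    if (iter <= settings$burnin && iter %% 100 == 0) {
      tune <- function(w, a, n) {
        if (n == 0) return(w)
        rate <- a / n
        if (rate > 0.4) w * 1.4 else if (rate < 0.2) w / 1.4 else w
      }
      for (v in internal) {
        w_age[v] <- tune(w_age[v], acc$age[v], acc$age_n[v])
        w_comp[v] <- tune(w_comp[v], acc$comp[v], acc$comp_n[v])
      }
      w_rate <- tune(w_rate, acc$rate, acc$rate_n)
      w_mu <- tune(w_mu, acc$mu, acc$mu_n)
      w_s2 <- tune(w_s2, acc$s2, acc$s2_n)
      w_scale <- tune(w_scale, acc$scale, acc$scale_n)
      acc$age[] <- 0; acc$age_n[] <- 0
      acc$comp[] <- 0; acc$comp_n[] <- 0
      acc$rate <- acc$rate_n <- acc$mu <- acc$mu_n <- acc$s2 <- acc$s2_n <- 0
      acc$scale <- acc$scale_n <- 0
    }

    # --- sampling -------------------------------------------------------
    if (iter > settings$burnin &&
        (iter - settings$burnin) %% settings$sample_every == 0 && k < n_keep) {
      k <- k + 1L
      samples[k, ] <- c(ages[internal], mu, sigma2, mean(rates))
    }
  }
  acc_rates <- list(
    age = ifelse(acc$age_n > 0, acc$age / acc$age_n, NA)[internal],
    comp = ifelse(acc$comp_n > 0, acc$comp / acc$comp_n, NA)[internal],
    rate = if (acc$rate_n > 0) acc$rate / acc$rate_n else NA,
    mu = if (acc$mu_n > 0) acc$mu / acc$mu_n else NA,
    s2 = if (acc$s2_n > 0) acc$s2 / acc$s2_n else NA,
    scale = if (acc$scale_n > 0) acc$scale / acc$scale_n else NA)
  list(samples = samples[seq_len(k), , drop = FALSE], acceptance = acc_rates)
}

# Preprocess the topology, data and calibrations into flat arrays.
.prepare_dating <- function(tree, calibrations, branch_data,
                            mu_shape = 2, mu_rate = 20,
                            s2_shape = 1, s2_rate = 10) {
  .check(inherits(tree, "phylo"), "'tree' must be an ape phylo")
  .check(ape::is.rooted(tree), "the topology must be rooted")
  .check(ape::is.binary(tree), "the topology must be binary")
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  if (is.null(tree$node.label)) {
    tree$node.label <- sprintf("n%d", n_tip + seq_len(tree$Nnode))
  }
  labels <- c(tree$tip.label, tree$node.label)
  root <- n_tip + 1L
  edge <- tree$edge
  n_edge <- nrow(edge)
  parent <- rep(NA_integer_, n_nodes)
  parent[edge[, 2]] <- edge[, 1]
  parent_edge <- rep(NA_integer_, n_nodes)
  parent_edge[edge[, 2]] <- seq_len(n_edge)
  children <- lapply(seq_len(n_nodes), function(v) edge[edge[, 1] == v, 2])
  child_edges <- lapply(seq_len(n_nodes), function(v) which(edge[, 1] == v))
  internal <- root:n_nodes
  n_internal_children <- vapply(seq_len(n_nodes), function(v)
    sum(children[[v]] > n_tip), numeric(1))
  depth <- rep(0L, n_nodes)
  tr_pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(n_edge)) {
    depth[tr_pre$edge[e, 2]] <- depth[tr_pre$edge[e, 1]] + 1L
  }

  cal_list <- .as_calibration_list(calibrations)
  .check(all(names(cal_list) %in% labels),
         "calibration on a node label not present in the tree")
  cal_nodes <- match(names(cal_list), labels)
  .check(all(cal_nodes > n_tip), "calibrations must reference internal nodes")
  cals <- stats::setNames(cal_list, cal_nodes)
  .check(as.character(root) %in% names(cals),
         "the root must carry a calibration (an age ceiling is required for identifiability)")

  obs <- vvar <- NULL
  if (!is.null(branch_data)) {
    .check(all(c("branch_id", "observed_length", "variance") %in%
                 names(branch_data)), "branch_data needs branch_id, observed_length, variance")
    idx <- match(labels[edge[, 2]], branch_data$branch_id)
    .check(!anyNA(idx), "branch_data must cover every branch (keyed by child label)")
    obs <- branch_data$observed_length[idx]
    vvar <- branch_data$variance[idx]
    .check(all(vvar > 0), "branch-length variances must be > 0")
  }
  list(tree = tree, n_tip = n_tip, n_nodes = n_nodes, n_edge = n_edge,
       root = root, labels = labels, parent = parent,
       parent_edge = parent_edge, parent_of = edge[, 1], child_of = edge[, 2],
       children = children, child_edges = child_edges, internal = internal,
       n_internal_children = n_internal_children, depth = depth,
       cals = cals, obs = obs, vvar = vvar,
       mu_shape = mu_shape, mu_rate = mu_rate,
       s2_shape = s2_shape, s2_rate = s2_rate)
}

#' Bayesian node dating by MCMC
#'
#' Samples node ages, branch rates and clock hyperparameters on a fixed
#' rooted binary topology under the independent log-normal rates model with
#' soft-bound calibrations and the approximate Gaussian branch-length
#' likelihood.  With `branch_data = NULL` the sampler targets the prior
#' alone.  The root must carry a calibration; a run without any age
#' ceiling is refused as unidentifiable.
#'
#' @param tree rooted binary `ape` phylo; internal nodes are labelled
#'   `n<index>` if unlabelled.
#' @param calibrations a [calibration()], a list of them, or a data.frame
#'   with `node_label`, `t_min`, `t_max` (ages in 100 My).
#' @param branch_data data.frame `branch_id` (child node/tip label),
#'   `observed_length`, `variance`; or `NULL` for prior-only sampling.
#' @param settings an [mcmc_settings()].
#' @return a `dating_mcmc` object: `chains` (list of sample matrices with
#'   one column per internal node age plus `mu`, `sigma2`, `mean_rate`),
#'   `acceptance`, `tree`, `calibrations`, `settings`.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
#' fit <- run_dating_mcmc(tr, calibration("n4", 1, 3),
#'                        settings = mcmc_settings(2000, 500, 5, seed = 1))
#' @export
run_dating_mcmc <- function(tree, calibrations, branch_data = NULL,
                            settings = mcmc_settings()) {
  .check(inherits(settings, "mcmc_settings"),
         "'settings' must come from mcmc_settings()")
  pre <- .prepare_dating(tree, calibrations, branch_data)
  chains <- lapply(seq_len(settings$chains), function(i) {
    .run_chain(pre, settings, settings$seed + i - 1)
  })
  structure(list(chains = lapply(chains, `[[`, "samples"),
                 acceptance = lapply(chains, `[[`, "acceptance"),
                 tree = pre$tree, node_labels = pre$labels[pre$internal],
                 calibrations = pre$cals, settings = settings,
                 has_data = !is.null(branch_data)),
            class = "dating_mcmc")
}

#' @export
print.dating_mcmc <- function(x, ...) {
  cat(sprintf("Node-dating MCMC: %d chain(s) x %d samples, %d internal nodes, %s\n",
              length(x$chains), nrow(x$chains[[1]]), length(x$node_labels),
              if (x$has_data) "with branch data" else "prior only"))
  invisible(x)
}
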