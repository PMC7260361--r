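# Posterior summaries of a dating run: means, HPD intervals, effective
# sample sizes, a two-chain convergence report and an annotated chronogram.

#' Effective sample size of an MCMC trace
#'
#' `n / (1 + 2 * sum(rho_k))`, summing autocorrelations until the first
#' non-positive one.
#'
#' @param x numeric trace.
#' @return effective sample size (capped at `length(x)`).
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  cut <- which(rho <= 0)[1]
  if (!is.na(cut)) rho <- rho[seq_len(cut - 1)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Summarize a dating run into a chronogram
#'
#' Pools the post-burn-in samples of all chains into per-node posterior
#' mean ages and HPD intervals, reports per-chain means, effective sample
#' sizes and a convergence verdict (largest between-chain discrepancy in
#' posterior mean node age, relative to the width of the root calibration
#' core), and builds an annotated time tree whose node labels carry
#' `label|mean|lower|upper`.
#'
#' @param fit a `dating_mcmc` from [run_dating_mcmc()] with >= 2 chains.
#' @param mass HPD mass (default 0.95).
#' @param tol convergence tolerance: chains agree if every node's
#'   between-chain mean difference is below `tol` times the root
#'   calibration core width (default 0.02).
#' @return list with `node_summary` (data.frame: node, mean, HPD bounds,
#'   per-chain means, ESS), `converged`, `max_discrepancy` (relative),
#'   `tree` (annotated phylo, edge lengths = posterior mean durations),
#'   and `mass`.
#' @export
summarize_chronogram <- function(fit, mass = 0.95, tol = 0.02) {
  .check(inherits(fit, "dating_mcmc"), "'fit' must come from run_dating_mcmc()")
  .check(length(fit$chains) >= 2, "need at least two chains to summarize")
  cols <- colnames(fit$chains[[1]])
  .check(all(vapply(fit$chains, function(ch) identical(colnames(ch), cols),
                    logical(1))), "chains have unequal parameterization")
  nodes <- fit$node_labels
  pooled <- do.call(rbind, fit$chains)
  root_cal <- fit$calibrations[[1]]
  cal_width <- root_cal$t_max - root_cal$t_min
  summ <- lapply(nodes, function(nd) {
    x <- pooled[, nd]
    hpd <- hpd_interval(x, mass)
    chain_means <- vapply(fit$chains, function(ch) mean(ch[, nd]), numeric(1))
    data.frame(node = nd, mean_age = mean(x),
               hpd_lower = hpd[["lower"]], hpd_upper = hpd[["upper"]],
               ess = sum(vapply(fit$chains, function(ch)
                 effective_sample_size(ch[, nd]), numeric(1))),
               chain_spread = max(chain_means) - min(chain_means))
  })
  node_summary <- do.call(rbind, summ)
  rownames(node_summary) <- NULL
  max_disc <- max(node_summary$chain_spread) / cal_width
  tree <- fit$tree
  n_tip <- ape::Ntip(tree)
  ages <- c(rep(0, n_tip), node_summary$mean_age)
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  tree$node.label <- sprintf("%s|%.6g|%.6g|%.6g", node_summary$node,
                             node_summary$mean_age, node_summary$hpd_lower,
                             node_summary$hpd_upper)
  list(node_summary = node_summary, converged = max_disc <= tol,
       max_discrepancy = max_disc, tree = tree, mass = mass)
}

#' Write / read an annotated chronogram
#'
#' The chronogram is serialized as Newick with `label|mean|lower|upper`
#' internal node labels; [read_chronogram()] round-trips it back into a
#' tree plus a node-age table.
#'
#' @param summary result of [summarize_chronogram()].
#' @param file path to write to.
#' @return `file`, invisibly.
#' @export
write_chronogram <- function(summary, file) {
  ape::write.tree(summary$tree, file = file)
  invisible(file)
}

#' @rdname write_chronogram
#' @param file path of a chronogram written by [write_chronogram()].
#' @return for `read_chronogram()`: list with `tree` and `node_summary`
#'   (node, mean_age, hpd_lower, hpd_upper).
#' @export
read_chronogram <- function(file) {
  tree <- ape::read.tree(file)
  parts <- strsplit(tree$node.label, "|", fixed = TRUE)
  .check(all(lengths(parts) == 4), "node labels are not label|mean|lower|upper")
  node_summary <- data.frame(
    node = vapply(parts, `[`, character(1), 1),
    mean_age = as.numeric(vapply(parts, `[`, character(1), 2)),
    hpd_lower = as.numeric(vapply(parts, `[`, character(1), 3)),
    hpd_upper = as.numeric(vapply(parts, `[`, character(1), 4)))
  list(tree = tree, node_summary = node_summary)
}
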