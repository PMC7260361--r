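# Independent brute-force oracles used to validate the package's own
# implementations.  These deliberately use the most direct computation
# available, not the code paths they check.

# Spearman's rho as Pearson on average ranks.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Dunn z statistic for groups i vs j from first principles.
oracle_dunn_z <- function(groups, i, j) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  tie_sizes <- table(pooled)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  A <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  (mean(r[idx == i]) - mean(r[idx == j])) /
    sqrt(A * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
}

# Narrowest window containing ceiling(mass * n) sorted samples, by
# exhaustive search.
oracle_hpd <- function(samples, mass) {
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(s[1], s[n])
  best_w <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < best_w - 1e-15) {
      best_w <- w
      best <- c(s[i], s[i + m - 1])
    }
  }
  best
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments,
# counting pairwise wins directly.
oracle_mwu_exact <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  N <- length(pooled)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  combos <- utils::combn(N, n_a)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(u_all <= u_obs + 1e-12), mean(u_all >= u_obs - 1e-12)))
}

# Exact Kruskal-Wallis permutation p by enumeration (small N only).
oracle_kw_exact <- function(groups) {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  N <- length(pooled)
  r <- rank(pooled)
  tie_corr <- 1 - sum(table(pooled)^3 - table(pooled)) / (N^3 - N)
  h_of <- function(assign) {
    rm <- tapply(r, assign, mean)
    (12 / (N * (N + 1)) * sum(sizes * (rm - (N + 1) / 2)^2)) / tie_corr
  }
  h_obs <- h_of(rep(seq_along(groups), sizes))
  hits <- 0; total <- 0
  recurse <- function(remaining, g, assign) {
    if (g == length(sizes)) {
      assign[remaining] <- g
      total <<- total + 1
      if (h_of(assign) >= h_obs - 1e-12) hits <<- hits + 1
      return(invisible(NULL))
    }
    for (s in utils::combn(remaining, sizes[g], simplify = FALSE)) {
      assign2 <- assign
      assign2[s] <- g
      recurse(setdiff(remaining, s), g + 1, assign2)
    }
  }
  recurse(seq_len(N), 1, integer(N))
  hits / total
}

# A tiny handmade plaque-count table: one species, one condition,
# triplicates at the given days.
make_tiny_survival <- function(counts_by_day, volume_ul = 10,
                               cells_per_ml = 1e4, form = "spore",
                               species = "spA", condition = "22C_wet") {
  days <- as.numeric(names(counts_by_day))
  do.call(rbind, lapply(seq_along(days), function(i) {
    cnt <- counts_by_day[[i]]
    data.frame(species_id = species, taxon_group = "1", form = form,
               condition = condition, day = days[i],
               replicate = seq_along(cnt), volume_ul = volume_ul,
               plaque_count = cnt, cells_per_ml = cells_per_ml)
  }))
}
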