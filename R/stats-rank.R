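# Self-contained rank statistics used throughout the pipeline.
#
# All statistics use average ranks for ties and tie-corrected variances.
# Small-sample exact p-values are computed by full enumeration; the
# enumeration code is deliberately simple so that it can be checked against
# hand computation.

# All permutations of 1..n as an (n! x n) matrix.  Only used for n <= 8.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), matrix(setdiff(seq_len(n), k)[sub], rows))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

.new_cor_result <- function(rho, p, n, method, undefined = FALSE) {
  structure(list(rho = rho, p_value = p, n = n, method = method,
                 undefined = undefined),
            class = "dictyfit_cor")
}

#' @export
print.dictyfit_cor <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("%s correlation: undefined (constant input), n = %d\n",
                x$method, x$n))
  } else {
    cat(sprintf("%s correlation: rho = %.4f, p = %.4g, n = %d\n",
                x$method, x$rho, x$p_value, x$n))
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank-order correlation with average ranks for ties: the Pearson
#' correlation of the rank vectors.  For `n <= 8` (or when `exact = TRUE`)
#' the two-sided p-value is computed by full enumeration of the `n!`
#' permutations of one rank vector; otherwise from the t approximation with
#' `n - 2` degrees of freedom.
#'
#' A constant input vector leaves the correlation undefined; the result is
#' returned with `undefined = TRUE` and `NA` estimates rather than a number.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @param exact logical; force or forbid the exact permutation p-value.
#'   Default: exact for `n <= 8`.
#' @return a `dictyfit_cor` object: `rho`, `p_value`, `n`, `method`,
#'   `undefined`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
#' @export
spearman_rho <- function(x, y, exact = NULL) {
  .check(length(x) == length(y), "'x' and 'y' must have equal length")
  n <- length(x)
  .check(n >= 3, "need at least 3 paired observations")
  .check(all(is.finite(x)) && all(is.finite(y)), "inputs must be finite")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(.new_cor_result(NA_real_, NA_real_, n, "Spearman", undefined = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (is.null(exact)) exact <- n <= 8
  if (exact && n <= 8) {
    perms <- .permutations(n)
    rho_perm <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  .new_cor_result(rho, p, n, "Spearman")
}

#' Pearson correlation (same result container as [spearman_rho()])
#'
#' @inheritParams spearman_rho
#' @return a `dictyfit_cor` object.
#' @export
pearson_r <- function(x, y) {
  .check(length(x) == length(y), "'x' and 'y' must have equal length")
  n <- length(x)
  .check(n >= 3, "need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(.new_cor_result(NA_real_, NA_real_, n, "Pearson", undefined = TRUE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  .new_cor_result(r, p, n, "Pearson")
}

# Tie-correction bookkeeping for a pooled sample: sum of (t^3 - t) over tie
# groups, and the Kruskal-Wallis correction factor.
.tie_term <- function(pooled) {
  t_sizes <- table(pooled)
  sum(t_sizes^3 - t_sizes)
}

.new_rank_test <- function(statistic, p, n, tie_correction, method,
                           df = NA_integer_, degenerate = FALSE,
                           p_exact = NA_real_) {
  structure(list(statistic = statistic, p_value = p, n = n,
                 tie_correction = tie_correction, df = df,
                 degenerate = degenerate, p_exact = p_exact, method = method),
            class = "dictyfit_ranktest")
}

#' @export
print.dictyfit_ranktest <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s: degenerate data (all values identical); no test\n",
                x$method))
    return(invisible(x))
  }
  cat(sprintf("%s: statistic = %.4f, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = "/")))
  if (!is.na(x$p_exact))
    cat(sprintf("  exact permutation p = %.4g\n", x$p_exact))
  invisible(x)
}

# Tie-corrected H for a rank vector split by a group factor.
.kw_statistic <- function(ranks, grp_index, N, tie_corr) {
  rank_means <- tapply(ranks, grp_index, mean)
  n_i <- tabulate(grp_index)
  h <- 12 / (N * (N + 1)) * sum(n_i * (rank_means - (N + 1) / 2)^2)
  h / tie_corr
}

# Enumerate all distinct assignments of indices 1..N into groups of the given
# sizes, calling fun(grp_index) for each.  Used only for small N.
.enum_partitions <- function(sizes, fun) {
  N <- sum(sizes)
  k <- length(sizes)
  grp <- integer(N)
  recurse <- function(remaining, g) {
    if (g == k) {
      grp[remaining] <<- k
      fun(grp)
      return(invisible(NULL))
    }
    sel <- utils::combn(remaining, sizes[g], simplify = FALSE)
    for (s in sel) {
      grp[s] <<- g
      recurse(setdiff(remaining, s), g + 1L)
    }
  }
  recurse(seq_len(N), 1L)
}

#' Kruskal-Wallis rank test ("ANOVA on ranks")
#'
#' Tie-corrected H statistic over two or more groups, with a chi-square
#' p-value (`df = groups - 1`).  For total `N <= 10` an exact permutation
#' p-value (full enumeration of rank assignments) is additionally available
#' via `exact = TRUE`.
#'
#' If all values across all groups are identical the ranks carry no
#' information (the tie-correction factor is 0); the result is flagged
#' `degenerate` with `NA` statistics.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty,
#'   total N >= 3).
#' @param exact logical; also compute the exact permutation p (N <= 10 only).
#' @return a `dictyfit_ranktest` object: `statistic` (tie-corrected H),
#'   `p_value`, `df`, `n`, `tie_correction`, `degenerate`, `p_exact`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  .check(is.list(groups) && length(groups) >= 2, "need a list of >= 2 groups")
  n_i <- lengths(groups)
  .check(all(n_i >= 1), "every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  .check(all(is.finite(pooled)), "inputs must be finite")
  N <- length(pooled)
  .check(N >= 3, "need at least 3 observations in total")
  tie_corr <- 1 - .tie_term(pooled) / (N^3 - N)
  if (tie_corr <= 0) {
    return(.new_rank_test(NA_real_, NA_real_, n_i, 0,
                          "Kruskal-Wallis", df = length(groups) - 1L,
                          degenerate = TRUE))
  }
  ranks <- rank(pooled)
  grp_index <- rep.int(seq_along(groups), n_i)
  h <- .kw_statistic(ranks, grp_index, N, tie_corr)
  p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  p_exact <- NA_real_
  if (exact) {
    .check(N <= 10, "exact permutation p only offered for N <= 10")
    hits <- 0L
    total <- 0L
    .enum_partitions(n_i, function(grp) {
      h_perm <- .kw_statistic(ranks, grp, N, tie_corr)
      total <<- total + 1L
      if (h_perm >= h - 1e-12) hits <<- hits + 1L
    })
    p_exact <- hits / total
  }
  .new_rank_test(h, p, n_i, tie_corr, "Kruskal-Wallis",
                 df = length(groups) - 1L, p_exact = p_exact)
}

#' Dunn's pairwise post-hoc test on pooled ranks
#'
#' Follow-up to [kruskal_wallis()]: for every pair of groups, the z statistic
#' is the difference in mean pooled ranks divided by its tie-corrected
#' standard error `sqrt((N(N+1)/12 - T/(12(N-1))) * (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t)` over tie groups.  Two-sided normal p-values; optional
#' Holm adjustment.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @param adjust `"none"` (default, a raw P-matrix) or `"holm"`.
#' @return list with `p_matrix` (symmetric, unit diagonal), `z_matrix`,
#'   `adjust`, and `n` per group.  Group names are taken from `names(groups)`.
#' @examples
#' dunn_pairwise(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(2, 3, 4)))
#' @export
dunn_pairwise <- function(groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  .check(is.list(groups) && length(groups) >= 2, "need a list of >= 2 groups")
  n_i <- lengths(groups)
  .check(all(n_i >= 1), "every group must be non-empty")
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  ranks <- rank(pooled)
  grp_index <- rep.int(seq_len(k), n_i)
  rank_means <- tapply(ranks, grp_index, mean)
  A <- N * (N + 1) / 12 - .tie_term(pooled) / (12 * (N - 1))
  z <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se <- sqrt(A * (1 / n_i[i] + 1 / n_i[j]))
      zij <- if (se > 0) (rank_means[i] - rank_means[j]) / se else 0
      z[i, j] <- z[j, i] <- zij
    }
  }
  p <- 2 * stats::pnorm(-abs(z))
  diag(p) <- 1
  if (adjust == "holm") {
    upper <- upper.tri(p)
    p[upper] <- stats::p.adjust(p[upper], method = "holm")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  list(p_matrix = p, z_matrix = z, adjust = adjust, n = stats::setNames(n_i, labels))
}

#' Mann-Whitney U test (two-sample rank test)
#'
#' U counts pairs where a value in `a` exceeds one in `b` (ties count 1/2).
#' For pooled `n <= 12` (default) the two-sided p-value is exact, by
#' enumeration of all `choose(n_a + n_b, n_a)` group assignments
#' (`p = min(1, 2 * min(P(U <= u), P(U >= u)))`); otherwise a normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact logical; default exact for `n_a + n_b <= 12`.
#' @return a `dictyfit_ranktest` with `statistic = U` (for sample `a`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  .check(length(a) >= 1 && length(b) >= 1, "both samples must be non-empty")
  .check(all(is.finite(a)) && all(is.finite(b)), "inputs must be finite")
  n_a <- length(a)
  n_b <- length(b)
  N <- n_a + n_b
  if (is.null(exact)) exact <- N <= 12
  u_stat <- function(x, y) {
    sum(vapply(x, function(v) sum(v > y) + 0.5 * sum(v == y), numeric(1)))
  }
  u <- u_stat(a, b)
  pooled <- c(a, b)
  tie_corr <- 1 - .tie_term(pooled) / (N^3 - N)
  if (exact) {
    .check(N <= 12, "exact p only offered for n_a + n_b <= 12")
    sel <- utils::combn(N, n_a, simplify = FALSE)
    u_all <- vapply(sel, function(idx) u_stat(pooled[idx], pooled[-idx]),
                    numeric(1))
    p <- min(1, 2 * min(mean(u_all <= u + 1e-12), mean(u_all >= u - 1e-12)))
    return(.new_rank_test(u, p, c(n_a, n_b), tie_corr,
                          "Mann-Whitney (exact)"))
  }
  mu <- n_a * n_b / 2
  sigma2 <- n_a * n_b / 12 * ((N + 1) - .tie_term(pooled) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(.new_rank_test(u, 1, c(n_a, n_b), tie_corr,
                          "Mann-Whitney (normal)", degenerate = TRUE))
  }
  # continuity correction toward the mean
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  if (u == mu) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  .new_rank_test(u, p, c(n_a, n_b), tie_corr, "Mann-Whitney (normal)")
}

#' Highest posterior density interval from samples
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples.  When several windows tie on width, the one with the
#' smallest lower bound is returned.
#'
#' @param samples numeric vector, `n >= 20`.
#' @param mass interval mass in (0, 1); default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(0:999, mass = 0.95) # (0, 949)
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  .check(is.numeric(samples) && length(samples) >= 20,
         "need at least 20 samples for an HPD interval")
  .check(mass > 0 && mass < 1, "'mass' must be in (0, 1)")
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  lo_idx <- seq_len(n - m + 1)
  widths <- s[lo_idx + m - 1] - s[lo_idx]
  i <- which.min(widths) # which.min takes the first (smallest lower bound) on ties
  c(lower = s[i], upper = s[i + m - 1])
}
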