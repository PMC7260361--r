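# From plaque counts to survival curves, relative fitness, and taxon-group
# comparisons.

#' Survival fractions from plaque counts
#'
#' The surviving fraction of one plated replicate is
#' `plaque_count / cells_plated`, with `cells_plated = cells_per_ml *
#' volume_ul / 1000` (100 cells for a 10 ul aliquot of a 10^4 cells/ml
#' suspension).  Fractions above 1 (counting noise) are kept, not clipped,
#' and flagged.
#'
#' @param observations data.frame of plaque-count observations with columns
#'   `species_id`, `taxon_group`, `form`, `condition`, `day`, `replicate`,
#'   `volume_ul`, `plaque_count`, `cells_per_ml` (as produced by
#'   [gen_survival()]).
#' @return data.frame (one row per species x form x condition x day) with
#'   `mean_fraction`, `sd_fraction`, `n_replicates`, `any_over_one`.
#' @examples
#' obs <- gen_survival(seed = 1)
#' curves <- survival_fractions(obs)
#' @export
survival_fractions <- function(observations) {
  need <- c("species_id", "taxon_group", "form", "condition", "day",
            "replicate", "volume_ul", "plaque_count", "cells_per_ml")
  missing <- setdiff(need, names(observations))
  .check(length(missing) == 0,
         paste("observations are missing column(s):",
               paste(missing, collapse = ", ")))
  obs <- observations
  .check(all(obs$plaque_count >= 0), "plaque counts must be >= 0")
  cells <- obs$cells_per_ml * obs$volume_ul / 1000
  .check(all(cells > 0), "zero cells plated for at least one observation")
  key <- interaction(obs$species_id, obs$form, obs$condition, obs$day,
                     obs$replicate, drop = TRUE)
  .check(!anyDuplicated(key),
         "duplicate replicate keys (species x form x condition x day x replicate)")
  obs$fraction <- obs$plaque_count / cells
  agg <- stats::aggregate(
    fraction ~ species_id + taxon_group + form + condition + day, data = obs,
    FUN = function(x) c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
                        n = length(x), over = any(x > 1)))
  out <- agg[, c("species_id", "taxon_group", "form", "condition", "day")]
  out$mean_fraction <- agg$fraction[, "mean"]
  out$sd_fraction <- agg$fraction[, "sd"]
  out$n_replicates <- as.integer(agg$fraction[, "n"])
  out$any_over_one <- agg$fraction[, "over"] > 0
  out <- out[order(out$species_id, out$form, out$condition, out$day), ]
  rownames(out) <- NULL
  class(out) <- c("survival_curves", "data.frame")
  out
}

#' Relative fitness of spores and cysts
#'
#' At every post-baseline timepoint the normalizing denominator is the mean
#' survival fraction over *all spore curves* -- all species, all storage
#' conditions.  Every curve (spore and cyst alike) is divided by that
#' denominator, and the normalized values are averaged per species x form x
#' condition over the post-baseline timepoints (default: the six days
#' 1, 7, 30, 91, 182, 365; day 0 serves as a plating-efficiency control).
#' The standard error uses the number of timepoints with a defined
#' normalized value.
#'
#' By construction the fitness values of spores average to 1 at each
#' timepoint (weighted per timepoint), so values above 1 mark
#' better-than-average and below 1 worse-than-average survivors.
#'
#' A timepoint whose spore denominator is 0 is dropped from the average
#' with a warning.
#'
#' @param curves a survival-curve table from [survival_fractions()].
#' @param timepoints days to average over; default all post-baseline days
#'   present in `curves`.
#' @return data.frame (one row per species x form x condition) with
#'   `fitness`, `se`, `n_timepoints`; the per-timepoint spore denominators
#'   are attached as attribute `"denominators"`.
#' @examples
#' fit <- relative_fitness(survival_fractions(gen_survival(seed = 1)))
#' @export
relative_fitness <- function(curves, timepoints = NULL) {
  .check(all(c("species_id", "form", "condition", "day", "mean_fraction")
             %in% names(curves)), "'curves' must come from survival_fractions()")
  if (is.null(timepoints)) {
    timepoints <- sort(unique(curves$day))
    timepoints <- timepoints[timepoints > 0]
  }
  .check(length(timepoints) >= 1, "no post-baseline timepoints to average over")
  cur <- curves[curves$day %in% timepoints, ]
  spores <- cur[cur$form == "spore", ]
  denom <- tapply(spores$mean_fraction, factor(spores$day, levels = timepoints),
                  mean)
  denom <- stats::setNames(as.vector(denom), dimnames(denom)[[1]])
  .check(!anyNA(denom),
         "every timepoint needs at least one spore curve for the denominator")
  zero <- denom == 0
  if (any(zero)) {
    warning("spore denominator is 0 at day(s) ",
            paste(timepoints[zero], collapse = ", "),
            "; dropped from the fitness average", call. = FALSE)
    timepoints <- timepoints[!zero]
    denom <- denom[!zero]
    cur <- cur[cur$day %in% timepoints, ]
  }
  cur$normalized <- cur$mean_fraction / denom[as.character(cur$day)]
  agg <- stats::aggregate(
    normalized ~ species_id + taxon_group + form + condition, data = cur,
    FUN = function(x) c(mean = mean(x), se = .se(x), n = length(x)))
  out <- agg[, c("species_id", "taxon_group", "form", "condition")]
  out$fitness <- agg$normalized[, "mean"]
  out$se <- agg$normalized[, "se"]
  out$n_timepoints <- as.integer(agg$normalized[, "n"])
  out <- out[order(out$species_id, out$form, out$condition), ]
  rownames(out) <- NULL
  attr(out, "denominators") <- denom
  attr(out, "timepoints") <- timepoints
  class(out) <- c("fitness_table", "data.frame")
  out
}

# Default pooling: one pool per major taxon group for spores, one pool over
# all cysts; minor-group spores are left out of the pools (but they do
# contribute to the normalization denominator upstream).
.default_pooling <- function(taxon_group, form) {
  ifelse(form == "cyst", "c",
         ifelse(taxon_group %in% c("1", "2", "3", "4"),
                paste0("grp", taxon_group), NA_character_))
}

#' Taxon-group comparison of relative fitness
#'
#' Pools relative-fitness values per treatment condition -- by default one
#' pool per major taxon group for spores plus one pool over all cysts --
#' and compares pools by Kruskal-Wallis ("ANOVA on ranks") with a Dunn
#' pairwise P-matrix.
#'
#' @param fitness a fitness table from [relative_fitness()].
#' @param pooling function `(taxon_group, form) -> pool label or NA`
#'   (NA excludes the species from pooling); default as described.
#' @param adjust p-value adjustment for the pairwise matrix: `"none"`
#'   (default, a raw P-matrix) or `"holm"`.
#' @param min_pool minimum pool size entering the tests (default 2);
#'   smaller pools are excluded and reported.
#' @return named list (one element per condition), each with `pools`
#'   (mean, SE, n per pool), `kruskal` (a `dictyfit_ranktest`), `p_matrix`
#'   (Dunn) and `excluded` (pools below `min_pool`).
#' @examples
#' fit <- relative_fitness(survival_fractions(gen_survival(seed = 1)))
#' cmp <- group_fitness_comparison(fit)
#' cmp$m20C_wet$pools
#' @export
group_fitness_comparison <- function(fitness, pooling = .default_pooling,
                                     adjust = c("none", "holm"),
                                     min_pool = 2) {
  adjust <- match.arg(adjust)
  .check(inherits(fitness, "fitness_table") ||
           all(c("taxon_group", "form", "condition", "fitness") %in% names(fitness)),
         "'fitness' must come from relative_fitness()")
  fitness$pool <- pooling(fitness$taxon_group, fitness$form)
  conditions <- unique(fitness$condition)
  out <- lapply(conditions, function(cond) {
    sub <- fitness[fitness$condition == cond & !is.na(fitness$pool), ]
    groups <- split(sub$fitness, sub$pool)
    sizes <- lengths(groups)
    excluded <- names(groups)[sizes < min_pool]
    groups <- groups[sizes >= min_pool]
    pools <- data.frame(pool = names(groups),
                        mean = vapply(groups, mean, numeric(1)),
                        se = vapply(groups, .se, numeric(1)),
                        n = lengths(groups))
    rownames(pools) <- NULL
    kw <- if (length(groups) >= 2) kruskal_wallis(groups) else NULL
    pm <- if (length(groups) >= 2) dunn_pairwise(groups, adjust = adjust)$p_matrix
          else NULL
    list(condition = cond, pools = pools, kruskal = kw, p_matrix = pm,
         excluded = excluded)
  })
  stats::setNames(out, conditions)
}
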