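# Climate-zone ranking, the coldest-climate percentage matrix, and
# climate-fitness correlations.

#' Climate-zone ranks of a species record
#'
#' Zones are ranked 1-5 from tropical to arctic/alpine.  A species isolated
#' from a range of zones is reduced to its coldest (maximum rank) and
#' warmest (minimum rank) zone.
#'
#' @param records data.frame with a `zones` column (`;`-separated labels
#'   from [climate_zones()]).
#' @return `records` with `coldest_rank` and `warmest_rank` added (and
#'   `coldest_zone` recomputed from the ranks).
#' @examples
#' climate_ranks(data.frame(zones = "temperate;subarctic/subalpine"))
#' @export
climate_ranks <- function(records) {
  .check("zones" %in% names(records), "records need a 'zones' column")
  zones <- climate_zones()
  parsed <- strsplit(records$zones, ";", fixed = TRUE)
  .check(all(lengths(parsed) >= 1), "every species needs at least one zone")
  unknown <- setdiff(unique(unlist(parsed)), zones)
  .check(length(unknown) == 0,
         paste("unknown climate zone label(s):", paste(unknown, collapse = ", ")))
  ranks <- lapply(parsed, function(z) match(z, zones))
  records$coldest_rank <- vapply(ranks, max, numeric(1))
  records$warmest_rank <- vapply(ranks, min, numeric(1))
  records$coldest_zone <- zones[records$coldest_rank]
  records
}

#' Coldest-climate percentage matrix per taxon group
#'
#' For each taxon group, the percentage of species whose *coldest* zone of
#' isolation falls in each of the five climate zones, rounded half away
#' from zero (so rounded rows may sum to slightly off 100; e.g. 101 for a
#' 27-species group with counts 5/4/14/1/3).  Species without a recorded
#' climate are excluded from the denominators; empty groups are omitted
#' with a warning.
#'
#' @param records data.frame with `species_id`, `taxon_group`, `zones`.
#' @param digits decimal places for the rounded matrix (default 0).
#' @return integer-rounded matrix (groups x zones, coldest zone first, as
#'   conventionally displayed) with attributes `"unrounded"` (exact
#'   percentages) and `"counts"`.
#' @examples
#' build_table1(gen_ecology(deterministic = TRUE))
#' @export
build_table1 <- function(records, digits = 0) {
  .check(all(c("taxon_group", "zones") %in% names(records)),
         "records need 'taxon_group' and 'zones'")
  keep <- !is.na(records$zones) & nzchar(records$zones)
  dropped <- sum(!keep)
  if (dropped > 0) {
    warning(dropped, " species without recorded climate excluded", call. = FALSE)
  }
  records <- climate_ranks(records[keep, ])
  zones <- climate_zones()
  groups <- unique(records$taxon_group)
  counts <- t(vapply(groups, function(g) {
    tabulate(records$coldest_rank[records$taxon_group == g], nbins = 5)
  }, numeric(5)))
  dimnames(counts) <- list(groups, zones)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("empty group(s) omitted: ", paste(groups[empty], collapse = ", "),
            call. = FALSE)
    counts <- counts[!empty, , drop = FALSE]
  }
  pct <- 100 * sweep(counts, 1, rowSums(counts), "/")
  # display convention: coldest zone leftmost
  pct <- pct[, rev(zones), drop = FALSE]
  counts <- counts[, rev(zones), drop = FALSE]
  out <- round_half_away(pct, digits)
  attr(out, "unrounded") <- pct
  attr(out, "counts") <- counts
  out
}

#' Correlation of climate rank with spore fitness
#'
#' Spearman correlation between a species' coldest (or warmest) climate
#' rank and its *spore* relative fitness at one storage condition.
#'
#' @param records climate records (`species_id`, `zones`).
#' @param fitness table from [relative_fitness()].
#' @param condition storage condition (default wet frost, `"m20C_wet"`).
#' @param extreme `"coldest"` (default) or `"warmest"`.
#' @return a `dictyfit_cor` object.
#' @export
climate_fitness_correlation <- function(records, fitness,
                                        condition = "m20C_wet",
                                        extreme = c("coldest", "warmest")) {
  extreme <- match.arg(extreme)
  records <- climate_ranks(records)
  fit <- fitness[fitness$condition == condition & fitness$form == "spore", ]
  merged <- merge(records[, c("species_id", "coldest_rank", "warmest_rank")],
                  fit[, c("species_id", "fitness")], by = "species_id")
  .check(nrow(merged) >= 3, "need at least 3 species shared between tables")
  x <- if (extreme == "coldest") merged$coldest_rank else merged$warmest_rank
  spearman_rho(x, merged$fitness, exact = FALSE)
}
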