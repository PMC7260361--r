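# Synthetic climate-of-isolation rosters.
#
# Each species is assigned the coldest climate zone it has been isolated
# from by a multinomial draw over the five-zone vocabulary, optionally
# extended with warmer zones to form a range.  The default zone
# probabilities are the per-group count fractions consistent with the
# published percentage matrix of coldest isolation climates (group 4:
# 5/4/14/1/3 of 27 species from arctic/alpine down to tropical).

#' Climate-zone vocabulary, warmest to coldest
#'
#' `tropical` (rank 1), `subtropical` (2), `temperate` (3),
#' `subarctic/subalpine` (4), `arctic/alpine` (5).
#'
#' @return character vector of the five zone labels in rank order.
#' @export
climate_zones <- function() {
  c("tropical", "subtropical", "temperate", "subarctic/subalpine",
    "arctic/alpine")
}

#' Default group sizes for the 85-species ecology roster
#'
#' Group 4 has 27 species and the remaining 58 split as 17 / 27 / 13 / 1
#' over groups 1, 2, 3 and the minor groups -- the only integer split
#' consistent with every rounded percentage of the coldest-climate matrix.
#'
#' @return named integer vector.
#' @export
default_group_sizes <- function() {
  c("1" = 17L, "2" = 27L, "3" = 13L, "4" = 27L, "minor" = 1L)
}

#' Default coldest-zone probabilities per taxon group
#'
#' Rows are taxon groups, columns the five zones warmest to coldest; each
#' row sums to 1.  Values are the per-group zone counts divided by group
#' size (e.g. group 4: 3/1/14/4/5 of 27 from tropical to arctic/alpine,
#' i.e. five of 27 group 4 species from arctic or alpine tundra).
#'
#' @return numeric matrix (groups x zones).
#' @export
default_zone_probabilities <- function() {
  counts <- rbind(
    "1" = c(8, 0, 6, 3, 0),
    "2" = c(10, 6, 9, 1, 1),
    "3" = c(2, 6, 4, 1, 0),
    "4" = c(3, 1, 14, 4, 5),
    "minor" = c(0, 0, 1, 0, 0)
  )
  colnames(counts) <- climate_zones()
  sweep(counts, 1, rowSums(counts), "/")
}

#' Generate a synthetic species climate roster
#'
#' Assigns each species a coldest zone (multinomial over the group's zone
#' probabilities) and, with probability `range_probability`, a range
#' extending down to a uniformly chosen warmer zone.  In deterministic mode
#' no sampling occurs: each group gets exactly its expected zone counts
#' (`probabilities * group size`), which must then be whole numbers, and
#' ranges are suppressed.
#'
#' @param group_sizes named vector of species counts per taxon group;
#'   groups of size 0 yield no rows.
#' @param zone_probabilities matrix of per-group zone probabilities (rows
#'   must sum to 1 within 1e-9).
#' @param seed integer seed (ignored in deterministic mode).
#' @param deterministic logical; use expected counts instead of sampling.
#' @param range_probability probability that a sampled species' record is a
#'   range of zones rather than a single zone.
#' @param roster optional species roster (`species_id`, `taxon_group`, as
#'   from [default_roster()]); when given, records are generated for
#'   exactly those species (ids preserved, zones drawn from each species'
#'   group probabilities) and `group_sizes` is ignored.  Use this to build
#'   a climate table that joins onto survival-fitness tables.
#' @return data.frame with `species_id`, `taxon_group`, `zones`
#'   (`;`-separated labels) and `coldest_zone`.
#' @examples
#' eco <- gen_ecology(deterministic = TRUE)
#' table(eco$taxon_group)
#' @export
gen_ecology <- function(group_sizes = default_group_sizes(),
                        zone_probabilities = default_zone_probabilities(),
                        seed = NULL, deterministic = FALSE,
                        range_probability = 0.5, roster = NULL) {
  if (!is.null(roster)) {
    .check(all(c("species_id", "taxon_group") %in% names(roster)),
           "'roster' needs species_id and taxon_group")
    .check(!deterministic, "deterministic mode is incompatible with a roster")
    .check(all(roster$taxon_group %in% rownames(zone_probabilities)),
           "every roster group needs a row of zone probabilities")
    .check(all(abs(rowSums(zone_probabilities) - 1) < 1e-9),
           "zone probabilities must sum to 1 per group")
    zones <- climate_zones()
    .set_seed(seed)
    n <- nrow(roster)
    coldest <- vapply(roster$taxon_group, function(g)
      sample(seq_along(zones), 1, prob = zone_probabilities[g, ]), integer(1))
    out <- data.frame(species_id = roster$species_id,
                      taxon_group = roster$taxon_group,
                      coldest_zone = zones[coldest])
    widen <- stats::runif(n) < range_probability & coldest > 1
    warmest <- ifelse(widen,
                      vapply(coldest, function(cz)
                        if (cz > 1) sample(seq_len(cz - 1), 1) else 1L,
                        integer(1)),
                      coldest)
    out$zones <- vapply(seq_len(n), function(i)
      paste(zones[warmest[i]:coldest[i]], collapse = ";"), character(1))
    return(out[, c("species_id", "taxon_group", "zones", "coldest_zone")])
  }
  .check(all(group_sizes >= 0), "group sizes must be non-negative")
  .check(!is.null(names(group_sizes)), "'group_sizes' must be named by group")
  .check(all(names(group_sizes) %in% rownames(zone_probabilities)),
         "every group needs a row of zone probabilities")
  .check(all(abs(rowSums(zone_probabilities) - 1) < 1e-9),
         "zone probabilities must sum to 1 per group")
  .check(all(zone_probabilities >= 0), "zone probabilities must be >= 0")
  zones <- climate_zones()
  .check(identical(colnames(zone_probabilities), zones),
         "zone probability columns must be the five climate zones in rank order")
  if (!deterministic) .set_seed(seed)
  rows <- lapply(names(group_sizes), function(g) {
    n <- group_sizes[[g]]
    if (n == 0) return(NULL)
    p <- zone_probabilities[g, ]
    if (deterministic) {
      counts <- p * n
      .check(all(abs(counts - round(counts)) < 1e-9),
             paste0("deterministic mode needs whole expected counts for group ", g))
      coldest <- rep(seq_along(zones), round(counts))
    } else {
      coldest <- sample(seq_along(zones), n, replace = TRUE, prob = p)
    }
    out <- data.frame(species_id = sprintf("eco_g%s_sp%d", g, seq_len(n)),
                      taxon_group = g,
                      coldest_zone = zones[coldest])
    out$zones <- zones[coldest]
    if (!deterministic && range_probability > 0) {
      widen <- stats::runif(n) < range_probability & coldest > 1
      warmest <- ifelse(widen,
                        vapply(coldest, function(cz)
                          if (cz > 1) sample(seq_len(cz - 1), 1) else 1L,
                          integer(1)),
                        coldest)
      out$zones <- vapply(seq_len(n), function(i) {
        paste(zones[warmest[i]:coldest[i]], collapse = ";")
      }, character(1))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("species_id", "taxon_group", "zones", "coldest_zone")]
}
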