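# Synthetic per-cell TEM morphometry.
#
# Each generated row is one sectioned cell.  Positive measurements (widths,
# areas, diameters, the aspect ratio) are log-normal with a mean-preserving
# parameterization; bounded fractions (electron density of wall layers on a
# 0-255 gray scale, per-cell mitochondrion-feature fractions) are beta with
# mean/dispersion parameterization; organelle counts are rounded
# log-normals.  A dispersion of exactly 0 is the degenerate no-noise case:
# every cell takes its group mean.

# Per-cell primitive features and the family they are drawn from.
.MORPHO_PRIMITIVES <- c(
  wall_layer1_width = "lognormal",
  wall_layer2_width = "lognormal",
  wall_layer3_width = "lognormal",
  wall_layer1_gray = "beta255",
  wall_layer2_gray = "beta255",
  wall_layer3_gray = "beta255",
  cell_cross_section_area = "lognormal",
  granule_count = "count",
  granule_diam = "lognormal",
  vesicle_count = "count",
  vesicle_total_area = "lognormal",
  mito_crenate_fraction = "beta",
  mito_closed_cristae_fraction = "beta",
  mito_ribosome_fringe_fraction = "beta",
  polar_granule_fraction = "beta",
  heterochromatin_fraction = "beta",
  aspect_ratio = "lognormal"
)

#' The 20 per-species ultrastructural features
#'
#' Species-level feature names produced by [species_feature_summary()]:
#' wall widths (total and up to three layers), wall-layer electron density,
#' cell cross-section area, granule count / mean diameter / area fraction,
#' vesicle count / total area / area fraction, three mitochondrion feature
#' fractions, polar-granule and heterochromatin fractions, and the cell
#' aspect ratio.
#'
#' @return character vector of length 20.
#' @export
morphometry_features <- function() {
  c("wall_total_width", "wall_layer1_width", "wall_layer2_width",
    "wall_layer3_width", "wall_layer1_gray", "wall_layer2_gray",
    "wall_layer3_gray", "cell_cross_section_area", "granule_count",
    "granule_diam_mean", "granule_area_fraction", "vesicle_count",
    "vesicle_total_area", "vesicle_area_fraction", "mito_crenate_fraction",
    "mito_closed_cristae_fraction", "mito_ribosome_fringe_fraction",
    "polar_granule_fraction", "heterochromatin_fraction", "aspect_ratio")
}

#' Default morphometry group profiles
#'
#' Per taxon group x form: mean and dispersion for every per-cell primitive
#' feature (widths in um, areas in um^2, gray on 0-255).  The defaults
#' encode the observed group contrasts: spore walls have three layers and
#' cyst walls at most two; group 2 spores have the thickest and group 3 the
#' thinnest walls; group 4 spores are the most compacted (small
#' cross-section, small dispersed granules, few vesicles, crenate
#' ribosome-fringed mitochondria with closed cristae); cysts are the least
#' condensed, with large granule and vesicle contributions.
#'
#' @param dispersion baseline dispersion applied to every feature
#'   (default 0.18 for log-normal features; beta features use
#'   `dispersion / 4`).  Set to 0 for noise-free cells.
#' @return data.frame with `taxon_group`, `form`, `feature`, `mean`,
#'   `dispersion`.
#' @export
default_morphometry_profiles <- function(dispersion = 0.18) {
  .check(dispersion >= 0, "'dispersion' must be >= 0")
  base <- function(group, form, means) {
    data.frame(taxon_group = group, form = form,
               feature = names(means), mean = unname(means),
               dispersion = ifelse(.MORPHO_PRIMITIVES[names(means)] %in%
                                     c("beta", "beta255"),
                                   dispersion / 4, dispersion))
  }
  spore_means <- function(l1, l2, l3, area, gcount, gdiam, vcount, varea,
                          crenate, cristae, fringe, polar, aspect) {
    c(wall_layer1_width = l1, wall_layer2_width = l2, wall_layer3_width = l3,
      wall_layer1_gray = 170, wall_layer2_gray = 90, wall_layer3_gray = 150,
      cell_cross_section_area = area,
      granule_count = gcount, granule_diam = gdiam,
      vesicle_count = vcount, vesicle_total_area = varea,
      mito_crenate_fraction = crenate,
      mito_closed_cristae_fraction = cristae,
      mito_ribosome_fringe_fraction = fringe,
      polar_granule_fraction = polar,
      heterochromatin_fraction = 0.5, aspect_ratio = aspect)
  }
  rbind(
    base("1", "spore", spore_means(0.04, 0.09, 0.03, 7, 12, 0.22, 10, 0.50,
                                   0.15, 0.20, 0.10, 0.80, 1.5)),
    base("2", "spore", spore_means(0.06, 0.16, 0.06, 7, 12, 0.22, 9, 0.45,
                                   0.15, 0.20, 0.10, 0.80, 1.5)),
    base("3", "spore", spore_means(0.03, 0.06, 0.02, 6, 12, 0.22, 9, 0.40,
                                   0.75, 0.30, 0.10, 0.80, 1.5)),
    base("4", "spore", spore_means(0.05, 0.11, 0.04, 5, 8, 0.12, 4, 0.10,
                                   0.90, 0.85, 0.80, 0.25, 1.6)),
    base("minor", "spore", spore_means(0.04, 0.10, 0.03, 7, 12, 0.22, 9, 0.45,
                                       0.15, 0.20, 0.10, 0.80, 1.4)),
    do.call(rbind, lapply(.TAXON_GROUPS, function(g) {
      base(g, "cyst",
           c(wall_layer1_width = 0.05, wall_layer2_width = 0.05,
             wall_layer3_width = 0, wall_layer1_gray = 140,
             wall_layer2_gray = 100, wall_layer3_gray = 0,
             cell_cross_section_area = 9,
             granule_count = 10, granule_diam = 0.25,
             vesicle_count = 14, vesicle_total_area = 1.2,
             mito_crenate_fraction = 0.10,
             mito_closed_cristae_fraction = 0.15,
             mito_ribosome_fringe_fraction = 0.05,
             polar_granule_fraction = 0.50,
             heterochromatin_fraction = 0.5, aspect_ratio = 1.05))
    }))
  )
}

# One draw of n values from the primitive's family, mean-preserving;
# dispersion 0 is the degenerate point mass at the mean.
.draw_feature <- function(family, mean, dispersion, n) {
  if (dispersion == 0 || mean == 0 ||
      (family %in% c("beta", "beta255") && mean %in% c(0, 1, 255))) {
    return(rep(mean, n))
  }
  switch(family,
    lognormal = stats::rlnorm(n, log(mean) - dispersion^2 / 2, dispersion),
    count = round(stats::rlnorm(n, log(mean) - dispersion^2 / 2, dispersion)),
    beta = {
      stats::rbeta(n, mean / dispersion, (1 - mean) / dispersion)
    },
    beta255 = {
      m <- mean / 255
      255 * stats::rbeta(n, m / dispersion, (1 - m) / dispersion)
    },
    stop("unknown feature family: ", family))
}

#' Generate a synthetic per-cell morphometry table
#'
#' For every roster species (and every dormant form it makes) draws
#' `n_cells_per_species` sectioned cells from the group profile.  Granule
#' diameters are drawn per granule and stored as a `;`-joined string so
#' that [derive_area_fractions()] can recompute combined granule areas from
#' individual circular cross-sections.
#'
#' @param group_profiles profile table (see
#'   [default_morphometry_profiles()]); must contain every primitive
#'   feature for every taxon group x form it covers, with dispersions >= 0.
#' @param n_cells_per_species cells per species (default 10).
#' @param seed integer seed.
#' @param roster species roster (see [default_roster()]).
#' @return data.frame with one row per cell.
#' @examples
#' cells <- gen_morphometry(seed = 1)
#' @export
gen_morphometry <- function(group_profiles = default_morphometry_profiles(),
                            n_cells_per_species = 10, seed = NULL,
                            roster = default_roster()) {
  .check(all(group_profiles$dispersion >= 0), "profile dispersion must be >= 0")
  .check(n_cells_per_species >= 1, "need at least one cell per species")
  .set_seed(seed)
  units <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    data.frame(species_id = roster$species_id[i],
               taxon_group = roster$taxon_group[i],
               form = if (roster$has_cyst[i]) .FORMS else "spore")
  }))
  rows <- lapply(seq_len(nrow(units)), function(i) {
    g <- units$taxon_group[i]
    f <- units$form[i]
    prof <- group_profiles[group_profiles$taxon_group == g &
                             group_profiles$form == f, ]
    missing <- setdiff(names(.MORPHO_PRIMITIVES), prof$feature)
    .check(length(missing) == 0,
           paste0("profile for group ", g, " ", f, " is missing feature(s): ",
                  paste(missing, collapse = ", ")))
    n <- n_cells_per_species
    cell <- data.frame(species_id = units$species_id[i], taxon_group = g,
                       form = f, cell_index = seq_len(n))
    for (feat in names(.MORPHO_PRIMITIVES)) {
      if (feat == "granule_diam") next
      p <- prof[prof$feature == feat, ]
      cell[[feat]] <- .draw_feature(.MORPHO_PRIMITIVES[[feat]], p$mean,
                                    p$dispersion, n)
    }
    # spore walls have <= 3 layers, cyst walls <= 2
    if (f == "cyst") cell$wall_layer3_width <- 0
    cell$wall_total_width <- cell$wall_layer1_width + cell$wall_layer2_width +
      cell$wall_layer3_width
    pd <- prof[prof$feature == "granule_diam", ]
    cell$granule_diameters <- vapply(cell$granule_count, function(cnt) {
      if (cnt < 1) return("")
      d <- .draw_feature("lognormal", pd$mean, pd$dispersion, cnt)
      paste(formatC(d, digits = 8, format = "g"), collapse = ";")
    }, character(1))
    cell
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
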