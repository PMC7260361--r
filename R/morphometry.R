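# Aggregation of per-cell TEM measurements into per-species features, and
# their relation to fitness and taxon group.

# Parse a ";"-joined diameter string into a numeric vector.
.parse_diameters <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Granule and vesicle area fractions of a cell cross-section
#'
#' Granules are treated as circular in cross-section: their combined area
#' is `sum(pi * d_i^2 / 4)` over the measured diameters.  Fractions are the
#' combined areas divided by the wall-exclusive cell cross-section area.
#' A fraction above 1 is a measurement inconsistency: it is capped at 1
#' with a warning.
#'
#' @param records per-cell morphometry data.frame with columns
#'   `granule_diameters` (`;`-joined), `vesicle_total_area` and
#'   `cell_cross_section_area`.
#' @return `records` with columns `granule_area_fraction` and
#'   `vesicle_area_fraction` added, and `granule_diam_mean` if diameters
#'   are present.
#' @examples
#' rec <- data.frame(granule_diameters = "1;1;1;1",
#'                   vesicle_total_area = 10, cell_cross_section_area = 100)
#' derive_area_fractions(rec)
#' @export
derive_area_fractions <- function(records) {
  .check(all(c("granule_diameters", "vesicle_total_area",
               "cell_cross_section_area") %in% names(records)),
         "records need granule_diameters, vesicle_total_area, cell_cross_section_area")
  .check(all(records$cell_cross_section_area > 0),
         "cell cross-section area must be positive")
  diams <- lapply(records$granule_diameters, .parse_diameters)
  .check(all(vapply(diams, function(d) all(d >= 0), logical(1))),
         "granule diameters must be >= 0")
  g_area <- vapply(diams, function(d) sum(pi * d^2 / 4), numeric(1))
  records$granule_diam_mean <- vapply(diams, function(d)
    if (length(d)) mean(d) else 0, numeric(1))
  records$granule_area_fraction <- g_area / records$cell_cross_section_area
  records$vesicle_area_fraction <-
    records$vesicle_total_area / records$cell_cross_section_area
  over <- records$granule_area_fraction > 1 | records$vesicle_area_fraction > 1
  if (any(over)) {
    warning(sum(over), " cell(s) with area fraction > 1; capped at 1",
            call. = FALSE)
    records$granule_area_fraction <- pmin(records$granule_area_fraction, 1)
    records$vesicle_area_fraction <- pmin(records$vesicle_area_fraction, 1)
  }
  records
}

#' Per-species means of the 20 ultrastructural features
#'
#' Averages every feature over the measured cells of each species x form;
#' per-cell fractions (e.g. the fraction of mitochondria with a crenate
#' outline) become per-species mean fractions.  Wall layer widths are kept
#' per layer so they can be displayed as a stacked bar whose layer means
#' sum to the mean total width.
#'
#' @param records per-cell table from [gen_morphometry()] (area fractions
#'   are derived on the fly if absent).
#' @param min_cells warn for species measured on fewer cells (default 10).
#' @return data.frame, one row per species x form, with `species_id`,
#'   `taxon_group`, `form`, `n_cells` and the 20 features of
#'   [morphometry_features()].
#' @examples
#' feats <- species_feature_summary(gen_morphometry(seed = 1))
#' @export
species_feature_summary <- function(records, min_cells = 10) {
  .check(nrow(records) > 0, "no morphometry records")
  if (!all(c("granule_area_fraction", "vesicle_area_fraction") %in%
             names(records))) {
    records <- derive_area_fractions(records)
  }
  feats <- morphometry_features()
  missing <- setdiff(feats, names(records))
  .check(length(missing) == 0,
         paste("records are missing feature(s):", paste(missing, collapse = ", ")))
  key <- paste(records$species_id, records$form, sep = "\r")
  split_idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(split_idx, function(idx) {
    sub <- records[idx, ]
    out <- data.frame(species_id = sub$species_id[1],
                      taxon_group = sub$taxon_group[1],
                      form = sub$form[1], n_cells = nrow(sub))
    for (f in feats) out[[f]] <- mean(sub[[f]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  low <- out$n_cells < min_cells
  if (any(low)) {
    warning(sum(low), " species measured on fewer than ", min_cells,
            " cells", call. = FALSE)
  }
  out[order(out$species_id, out$form), ]
}

#' Correlate ultrastructural features with relative fitness
#'
#' Spearman (default) or Pearson correlation of each per-species feature
#' with relative fitness at one storage condition (default wet frost,
#' `m20C_wet`).  By default a species' feature values are matched to the
#' fitness of the same dormant form (`fitness_form = "matched"`);
#' `"spore"` restricts to spore fitness, `"pooled"` averages a species'
#' fitness over its forms.
#'
#' @param features table from [species_feature_summary()].
#' @param fitness table from [relative_fitness()].
#' @param condition storage condition (default `"m20C_wet"`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param fitness_form `"matched"`, `"spore"` (spore features against
#'   spore fitness only) or `"pooled"`.
#' @param alpha significance threshold for the direction flag (default 0.05).
#' @return data.frame (one row per feature, ordered by rho): `feature`,
#'   `rho`, `p_value`, `n`, `direction` (`"positive"`/`"negative"` when
#'   `p < alpha`, else `"ns"`).
#' @export
feature_fitness_correlation <- function(features, fitness,
                                        condition = "m20C_wet",
                                        method = c("spearman", "pearson"),
                                        fitness_form = c("matched", "spore", "pooled"),
                                        alpha = 0.05) {
  method <- match.arg(method)
  fitness_form <- match.arg(fitness_form)
  fit <- fitness[fitness$condition == condition, ]
  .check(nrow(fit) > 0, paste("no fitness values at condition", condition))
  if (fitness_form == "spore") {
    fit <- fit[fit$form == "spore", ]
    merged <- merge(features[features$form == "spore", ],
                    fit[, c("species_id", "fitness")], by = "species_id")
  } else if (fitness_form == "pooled") {
    pooled <- stats::aggregate(fitness ~ species_id, data = fit, FUN = mean)
    merged <- merge(features, pooled, by = "species_id")
  } else {
    merged <- merge(features, fit[, c("species_id", "form", "fitness")],
                    by = c("species_id", "form"))
  }
  .check(nrow(merged) >= 3, "need at least 3 species shared between tables")
  cor_fun <- if (method == "spearman") spearman_rho else pearson_r
  res <- lapply(morphometry_features(), function(f) {
    x <- merged[[f]]
    ok <- is.finite(x) & is.finite(merged$fitness)
    r <- if (sum(ok) >= 3) cor_fun(x[ok], merged$fitness[ok])
         else .new_cor_result(NA_real_, NA_real_, sum(ok), method, undefined = TRUE)
    data.frame(feature = f, rho = r$rho, p_value = r$p_value, n = r$n,
               direction = if (!r$undefined && !is.na(r$p_value) &&
                                 r$p_value < alpha) {
                 if (r$rho > 0) "positive" else "negative"
               } else "ns")
  })
  out <- do.call(rbind, res)
  out[order(-out$rho, na.last = TRUE), ]
}

#' Group-versus-rest contrasts of ultrastructural features
#'
#' For every feature and taxon group with at least `min_species` species,
#' a two-sided Mann-Whitney test of the group's per-species values against
#' all other species; groups significantly above the rest are flagged
#' `"higher"`, below `"lower"` (at `alpha`, default 0.05).  Groups too
#' small to test are flagged `"untestable"`.
#'
#' @param features table from [species_feature_summary()].
#' @param grouping vector of group labels aligned with `features` rows;
#'   default `taxon_group`.
#' @param min_species minimum group size to test (default 2).
#' @param alpha significance threshold.
#' @return data.frame with one row per feature x group: `group_mean`,
#'   `rest_mean`, `p_value`, `flag`.
#' @export
group_feature_contrast <- function(features, grouping = NULL,
                                   min_species = 2, alpha = 0.05) {
  if (is.null(grouping)) grouping <- features$taxon_group
  .check(length(grouping) == nrow(features),
         "'grouping' must align with the feature table rows")
  groups <- unique(grouping)
  .check(length(groups) >= 2, "need at least 2 groups")
  rows <- list()
  for (f in morphometry_features()) {
    for (g in groups) {
      val_g <- features[[f]][grouping == g]
      val_rest <- features[[f]][grouping != g]
      if (length(val_g) < min_species || length(val_rest) < min_species) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, group = g, n = length(val_g),
          group_mean = mean(val_g), rest_mean = mean(val_rest),
          p_value = NA_real_, flag = "untestable")
        next
      }
      mw <- mann_whitney_u(val_g, val_rest)
      flag <- if (!mw$degenerate && !is.na(mw$p_value) && mw$p_value < alpha) {
        if (mean(val_g) > mean(val_rest)) "higher" else "lower"
      } else "ns"
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group = g, n = length(val_g),
        group_mean = mean(val_g), rest_mean = mean(val_rest),
        p_value = mw$p_value, flag = flag)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
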