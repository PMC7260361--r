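# Synthetic plaque-assay survival data.
#
# The generator emulates the storage experiment: dormant cells at a nominal
# 10^4 cells/ml are stored under four climate-mimicking conditions and
# plated clonally at a fixed schedule of timepoints; every viable cell gives
# one countable plaque.  True survival follows a Weibull decay with plateau,
#   S(t) = s_inf + (1 - s_inf) * exp(-(t / tau)^k),
# which captures both the fast death of cysts in dry frost and the long
# tails of hardy spores; plaque counts are binomial draws with the number of
# cells plated as size.

.CONDITIONS <- c("22C_wet", "4C_wet", "m20C_wet", "m20C_dry")
.FORMS <- c("spore", "cyst")
.TAXON_GROUPS <- c("1", "2", "3", "4", "minor")

#' Default species roster for the survival assay
#'
#' Five spore-forming species per major taxon group plus two minor-group
#' species; five species in groups 1-3 additionally form cysts (group 4
#' lost encystment).
#'
#' @return data.frame with `species_id`, `taxon_group`, `has_cyst`.
#' @export
default_roster <- function() {
  major <- do.call(rbind, lapply(c("1", "2", "3", "4"), function(g) {
    data.frame(species_id = sprintf("g%s_sp%d", g, 1:5),
               taxon_group = g, has_cyst = FALSE)
  }))
  minor <- data.frame(species_id = c("min_sp1", "min_sp2"),
                      taxon_group = "minor", has_cyst = FALSE)
  roster <- rbind(major, minor)
  cyst_formers <- c("g1_sp1", "g1_sp2", "g2_sp1", "g2_sp2", "g3_sp1")
  roster$has_cyst <- roster$species_id %in% cyst_formers
  roster
}

#' Default survival-decay parameters
#'
#' One row per taxon group x form x condition with Weibull-plateau
#' parameters (`tau` = characteristic time in days, `k` = shape,
#' `s_inf` = survival plateau).  The defaults encode the qualitative
#' structure of the assay: spores and cysts are comparable at 22 C, spores
#' do best just above and below 0 C, group 4 spores have the largest frost
#' half-lives (group 2 second, groups 1 and 3 lowest), group 4 spores keep
#' a survival plateau in dry frost, and cysts lose viability within days of
#' dry frost.  Group differences are concentrated at the frost conditions;
#' at 22 C and 4 C the groups are near-equivalent, mirroring the absence of
#' climate correlations for warm storage.
#'
#' @return data.frame with `taxon_group`, `form`, `condition`, `tau`, `k`,
#'   `s_inf`.
#' @export
default_decay_params <- function() {
  spore <- rbind(
    data.frame(taxon_group = "1", condition = .CONDITIONS,
               tau = c(70, 280, 80, 15), k = c(0.9, 0.8, 0.8, 0.7),
               s_inf = c(0, 0, 0, 0.01)),
    data.frame(taxon_group = "2", condition = .CONDITIONS,
               tau = c(75, 320, 220, 30), k = c(0.9, 0.8, 0.8, 0.7),
               s_inf = c(0, 0, 0, 0.05)),
    data.frame(taxon_group = "3", condition = .CONDITIONS,
               tau = c(65, 260, 70, 12), k = c(0.9, 0.8, 0.8, 0.7),
               s_inf = c(0, 0, 0, 0.01)),
    data.frame(taxon_group = "4", condition = .CONDITIONS,
               tau = c(72, 340, 420, 60), k = c(0.9, 0.8, 0.8, 0.7),
               s_inf = c(0, 0, 0, 0.15)),
    data.frame(taxon_group = "minor", condition = .CONDITIONS,
               tau = c(70, 300, 120, 20), k = c(0.9, 0.8, 0.8, 0.7),
               s_inf = c(0, 0, 0, 0.02))
  )
  spore$form <- "spore"
  cyst <- do.call(rbind, lapply(.TAXON_GROUPS, function(g) {
    data.frame(taxon_group = g, condition = .CONDITIONS,
               tau = c(100, 60, 25, 1.5), k = c(0.9, 0.9, 1.0, 1.2),
               s_inf = 0)
  }))
  cyst$form <- "cyst"
  out <- rbind(spore, cyst)
  out[, c("taxon_group", "form", "condition", "tau", "k", "s_inf")]
}

#' Default aliquot volume per storage day
#'
#' 10 ul for early timepoints, increased to 20, 30 or 40 ul late so that
#' enough plaques emerge for reliable counting.
#'
#' @param days timepoint schedule.
#' @return named numeric vector (ul per day).
#' @export
default_volume_schedule <- function(days = c(0, 1, 7, 30, 91, 182, 365)) {
  vol <- ifelse(days <= 30, 10, ifelse(days <= 91, 20, ifelse(days <= 182, 30, 40)))
  stats::setNames(vol, days)
}

#' Survival-assay simulation configuration
#'
#' @param roster species roster (see [default_roster()]).
#' @param conditions storage conditions; must be a subset of
#'   `22C_wet, 4C_wet, m20C_wet, m20C_dry`.
#' @param schedule storage days; strictly increasing, must include day 0.
#' @param decay decay-parameter table (see [default_decay_params()]).
#' @param cells_per_ml nominal suspension density (default 1e4).
#' @param volume_schedule ul plated per day (see [default_volume_schedule()]).
#' @param replicates plating replicates per timepoint (default 3).
#' @param tau_jitter_sd per-species log-normal jitter (sd on the log scale)
#'   applied once per species x form to `tau`, giving realistic
#'   between-species variation within a taxon group.  0 disables it.
#' @param climate optional climate records for the roster species
#'   (`species_id`, `zones`; see [gen_ecology()] with a roster).  When
#'   given, each species' frost `tau` (conditions `m20C_wet`, `m20C_dry`)
#'   is multiplied by `exp(climate_coupling * (coldest_rank - 3))`:
#'   species isolated from colder zones are hardier in frost, warm-storage
#'   survival is untouched.
#' @param climate_coupling log-scale frost-hardiness gain per climate rank
#'   unit (default 0.35; only used when `climate` is given).
#' @return a validated `survival_sim_config` list.
#' @export
survival_sim_config <- function(roster = default_roster(),
                                conditions = .CONDITIONS,
                                schedule = c(0, 1, 7, 30, 91, 182, 365),
                                decay = default_decay_params(),
                                cells_per_ml = 1e4,
                                volume_schedule = default_volume_schedule(schedule),
                                replicates = 3,
                                tau_jitter_sd = 0.25,
                                climate = NULL,
                                climate_coupling = 0.35) {
  .check(all(conditions %in% .CONDITIONS),
         paste("unknown condition label; allowed:", paste(.CONDITIONS, collapse = ", ")))
  .check(all(diff(schedule) > 0) && schedule[1] == 0,
         "'schedule' must be strictly increasing and include day 0")
  .check(all(decay$tau > 0), "decay 'tau' must be positive")
  .check(all(decay$k > 0), "decay shape 'k' must be positive")
  .check(all(decay$s_inf >= 0 & decay$s_inf <= 1), "'s_inf' must be in [0, 1]")
  .check(all(decay$form %in% .FORMS), "unknown form label in decay table")
  .check(is.numeric(replicates) && length(replicates) == 1 &&
           replicates == as.integer(replicates) && replicates >= 1,
         "'replicates' must be a positive integer")
  .check(all(as.character(schedule) %in% names(volume_schedule)),
         "'volume_schedule' must cover every scheduled day")
  .check(cells_per_ml > 0, "'cells_per_ml' must be positive")
  .check(tau_jitter_sd >= 0, "'tau_jitter_sd' must be >= 0")
  if (!is.null(climate)) {
    .check(all(c("species_id", "zones") %in% names(climate)),
           "'climate' needs species_id and zones")
    .check(all(roster$species_id %in% climate$species_id),
           "'climate' must cover every roster species")
  }
  structure(list(roster = roster, conditions = conditions, schedule = schedule,
                 decay = decay, cells_per_ml = cells_per_ml,
                 volume_schedule = volume_schedule,
                 replicates = as.integer(replicates),
                 tau_jitter_sd = tau_jitter_sd,
                 climate = climate, climate_coupling = climate_coupling),
            class = "survival_sim_config")
}

# True survival fraction under the Weibull-plateau decay.
.survival_prob <- function(day, tau, k, s_inf) {
  x <- ifelse(day == 0, 0, (day / tau)^k)
  s_inf + (1 - s_inf) * exp(-x)
}

#' Generate a synthetic plaque-count survival table
#'
#' One row per species x available form x condition x day x replicate.
#' Plaque counts are binomial with size equal to the number of cells plated
#' for that aliquot volume and success probability given by the
#' Weibull-plateau survival curve for the species' group, form and
#' condition.  Identical `(config, seed)` pairs give identical tables.
#'
#' @param config a [survival_sim_config()].
#' @param seed integer seed (required for reproducibility; `NULL` leaves
#'   the RNG state untouched).
#' @return data.frame of survival observations with columns `species_id`,
#'   `taxon_group`, `form`, `condition`, `day`, `replicate`, `volume_ul`,
#'   `cells_plated`, `plaque_count`, `cells_per_ml`, `true_survival`.
#' @examples
#' obs <- gen_survival(seed = 1)
#' head(obs)
#' @export
gen_survival <- function(config = survival_sim_config(), seed = NULL) {
  .check(inherits(config, "survival_sim_config"),
         "'config' must come from survival_sim_config()")
  .set_seed(seed)
  roster <- config$roster
  forms_of <- function(has_cyst) if (has_cyst) .FORMS else "spore"
  units <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    data.frame(species_id = roster$species_id[i],
               taxon_group = roster$taxon_group[i],
               form = forms_of(roster$has_cyst[i]))
  }))
  # one tau jitter per species x form, shared across conditions
  jit <- if (config$tau_jitter_sd > 0) {
    exp(stats::rnorm(nrow(units), -config$tau_jitter_sd^2 / 2,
                     config$tau_jitter_sd))
  } else rep(1, nrow(units))
  units$tau_mult <- jit

  grid <- merge(units,
                expand.grid(condition = config$conditions,
                            day = config$schedule,
                            replicate = seq_len(config$replicates),
                            stringsAsFactors = FALSE),
                by = NULL)
  key <- c("taxon_group", "form", "condition")
  dec <- config$decay
  idx <- match(interaction(grid[key], drop = FALSE),
               interaction(dec[key], drop = FALSE))
  .check(!anyNA(idx), "decay table is missing a taxon_group x form x condition row")
  grid$tau <- dec$tau[idx] * grid$tau_mult
  if (!is.null(config$climate)) {
    ranks <- climate_ranks(config$climate)
    rank_of <- stats::setNames(ranks$coldest_rank, ranks$species_id)
    frost <- grid$condition %in% c("m20C_wet", "m20C_dry")
    mult <- exp(config$climate_coupling * (rank_of[grid$species_id] - 3))
    grid$tau[frost] <- grid$tau[frost] * mult[frost]
  }
  grid$k <- dec$k[idx]
  grid$s_inf <- dec$s_inf[idx]
  grid$volume_ul <- unname(config$volume_schedule[as.character(grid$day)])
  grid$cells_plated <- round(config$cells_per_ml * grid$volume_ul / 1000)
  grid$true_survival <- .survival_prob(grid$day, grid$tau, grid$k, grid$s_inf)
  ord <- order(grid$species_id, grid$form, grid$condition, grid$day, grid$replicate)
  grid <- grid[ord, ]
  grid$plaque_count <- stats::rbinom(nrow(grid), grid$cells_plated,
                                     grid$true_survival)
  grid$cells_per_ml <- config$cells_per_ml
  rownames(grid) <- NULL
  grid[, c("species_id", "taxon_group", "form", "condition", "day",
           "replicate", "volume_ul", "cells_plated", "plaque_count",
           "cells_per_ml", "true_survival")]
}
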