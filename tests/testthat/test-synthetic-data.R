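# The four seeded generators: determinism, distributional structure and
# the embedded biological orderings.

test_that("all generators are deterministic under a fixed seed", {
  expect_identical(gen_survival(seed = 1), gen_survival(seed = 1))
  expect_identical(gen_morphometry(seed = 1), gen_morphometry(seed = 1))
  expect_identical(gen_ecology(seed = 1), gen_ecology(seed = 1))
  s1 <- gen_chronology(seed = 1)
  s2 <- gen_chronology(seed = 1)
  expect_identical(s1$branch_data, s2$branch_data)
  expect_identical(s1$ages, s2$ages)
})

test_that("survival counts respect the plating arithmetic and S(0) = 1", {
  obs <- gen_survival(seed = 3)
  expect_true(all(obs$plaque_count <= obs$cells_plated))
  expect_true(all(obs$plaque_count >= 0))
  # day 0: survival is exactly 1, so every cell plates as a plaque
  d0 <- obs[obs$day == 0, ]
  expect_true(all(d0$plaque_count == d0$cells_plated))
  expect_true(all(d0$cells_plated == 100))  # 10 ul of 1e4 cells/ml
})

test_that("binomial sampling reproduces a known survival probability", {
  # one species, no tau jitter: S(day) is exact, counts ~ Binomial(100, S)
  roster <- data.frame(species_id = "s1", taxon_group = "1", has_cyst = FALSE)
  cfg <- survival_sim_config(roster = roster, conditions = "22C_wet",
                             replicates = 200, tau_jitter_sd = 0)
  obs <- gen_survival(cfg, seed = 5)
  dec <- default_decay_params()
  p <- dec[dec$taxon_group == "1" & dec$form == "spore" &
             dec$condition == "22C_wet", ]
  for (d in c(7, 91)) {
    s_true <- p$s_inf + (1 - p$s_inf) * exp(-(d / p$tau)^p$k)
    sub <- obs[obs$day == d, ]
    n_cells <- sum(sub$cells_plated)
    se <- sqrt(s_true * (1 - s_true) / n_cells)
    expect_lt(abs(sum(sub$plaque_count) / n_cells - s_true), 4 * se)
  }
})

test_that("no-decay parameters give full recovery at every timepoint", {
  roster <- data.frame(species_id = "s1", taxon_group = "1", has_cyst = FALSE)
  dec <- expand.grid(taxon_group = "1", form = c("spore", "cyst"),
                     condition = c("22C_wet", "4C_wet", "m20C_wet", "m20C_dry"),
                     stringsAsFactors = FALSE)
  dec$tau <- Inf; dec$k <- 1; dec$s_inf <- 1
  cfg <- survival_sim_config(roster = roster, decay = dec, tau_jitter_sd = 0)
  obs <- gen_survival(cfg, seed = 9)
  expect_true(all(obs$plaque_count == obs$cells_plated))
})

test_that("cysts lose viability within days of dry frost", {
  obs <- gen_survival(seed = 7)
  cy <- obs[obs$form == "cyst" & obs$condition == "m20C_dry" & obs$day >= 7, ]
  expect_gt(nrow(cy), 0)
  expect_true(all(cy$true_survival < 0.01))
  expect_lt(mean(cy$plaque_count), 1)
})

test_that("unknown labels and bad replicate counts are rejected", {
  expect_error(survival_sim_config(conditions = "30C_wet"), "condition")
  expect_error(survival_sim_config(replicates = 2.5), "integer")
  dec <- default_decay_params()
  dec$form[1] <- "plasmodium"
  expect_error(survival_sim_config(decay = dec), "form")
})

test_that("morphometry dispersion 0 collapses every cell to its group mean", {
  prof <- default_morphometry_profiles(dispersion = 0)
  cells <- gen_morphometry(prof, n_cells_per_species = 3, seed = 1)
  one <- cells[cells$species_id == "g2_sp1" & cells$form == "spore", ]
  pick <- function(f) prof$mean[prof$taxon_group == "2" & prof$form == "spore" &
                                  prof$feature == f]
  expect_equal(one$wall_layer2_width, rep(pick("wall_layer2_width"), 3))
  expect_equal(one$cell_cross_section_area,
               rep(pick("cell_cross_section_area"), 3))
  expect_equal(one$mito_crenate_fraction,
               rep(pick("mito_crenate_fraction"), 3))
  expect_equal(one$wall_total_width,
               rep(pick("wall_layer1_width") + pick("wall_layer2_width") +
                     pick("wall_layer3_width"), 3))
})

test_that("morphometry profiles embed the wall contrasts and layer caps", {
  cells <- gen_morphometry(seed = 4)
  feats <- species_feature_summary(cells)
  sp <- feats[feats$form == "spore", ]
  walls <- tapply(sp$wall_total_width, sp$taxon_group, mean)[c("1", "2", "3", "4")]
  expect_equal(names(which.max(walls)), "2")
  expect_equal(names(which.min(walls)), "3")
  # cyst walls have at most two layers
  expect_true(all(cells$wall_layer3_width[cells$form == "cyst"] == 0))
})

test_that("morphometry rejects incomplete profiles and negative dispersion", {
  prof <- default_morphometry_profiles()
  expect_error(gen_morphometry(prof[prof$feature != "granule_count", ],
                               seed = 1), "missing feature")
  prof$dispersion[3] <- -0.1
  expect_error(gen_morphometry(prof, seed = 1), "dispersion")
})

test_that("ecology deterministic mode reproduces the configured counts", {
  eco <- gen_ecology(deterministic = TRUE)
  sizes <- default_group_sizes()
  expect_equal(nrow(eco), sum(sizes))
  counts <- table(eco$taxon_group)
  for (g in names(sizes)) expect_equal(unname(counts[g]), unname(sizes[g]))
  # group 4: exactly 5 of 27 arctic/alpine
  g4 <- eco[eco$taxon_group == "4", ]
  expect_equal(sum(g4$coldest_zone == "arctic/alpine"), 5)
})

test_that("ecology handles empty groups and rejects bad probabilities", {
  sizes <- c("1" = 0L, "4" = 5L)
  eco <- gen_ecology(group_sizes = sizes, seed = 1)
  expect_equal(nrow(eco), 5)
  expect_false("1" %in% eco$taxon_group)
  expect_error(gen_ecology(group_sizes = c("1" = -2L)), "non-negative")
  zp <- default_zone_probabilities()
  zp["2", 1] <- zp["2", 1] + 0.05
  expect_error(gen_ecology(zone_probabilities = zp), "sum to 1")
})

test_that("sampled zone frequencies match the configured multinomial", {
  zp <- matrix(c(0.1, 0.2, 0.4, 0.2, 0.1), 1,
               dimnames = list("4", climate_zones()))
  eco <- gen_ecology(group_sizes = c("4" = 10000L), zone_probabilities = zp,
                     seed = 12, range_probability = 0)
  freq <- table(factor(eco$coldest_zone, levels = climate_zones())) / 10000
  for (z in climate_zones()) {
    p <- zp[1, z]
    expect_lt(abs(freq[[z]] - p), 3 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("time trees are valid and strict-clock trees are ultrametric", {
  for (s in 1:5) {
    sim <- gen_chronology(chrono_sim_config(n_tips = 7), seed = s)
    expect_true(all(sim$tree$edge.length > 0))  # parent age > child age
    expect_true(all(sim$ages >= 0))
    expect_equal(max(sim$ages), 5)
  }
  sim <- gen_chronology(chrono_sim_config(n_tips = 6, sigma2 = 0,
                                          noise_var = 0), seed = 2)
  expect_true(all(sim$rates == 0.1))
  # expected substitutions root-to-tip are equal for all tips
  tr <- sim$tree
  tr$edge.length <- sim$branch_data$expected_length
  depths <- ape::node.depth.edgelength(tr)[seq_len(6)]
  expect_equal(depths, rep(0.1 * 5, 6), tolerance = 1e-12)
})

test_that("simulated branch rates have mean mu (mean-preserving log-normal)", {
  sim <- gen_chronology(chrono_sim_config(n_tips = 5001, mu = 0.1,
                                          sigma2 = 0.1), seed = 3)
  r <- sim$rates  # 10 000 rates
  se <- stats::sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 0.1), 3 * se)
})

test_that("chronology config rejects invalid variances", {
  expect_error(chrono_sim_config(sigma2 = -0.1), "sigma2")
  expect_error(chrono_sim_config(noise_var = -1), "noise_var")
  expect_error(chrono_sim_config(n_tips = 4, root_age = -1), "root_age")
})
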