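# Plaque counts -> survival fractions -> relative fitness -> group
# comparisons.

test_that("survival fractions follow the plating arithmetic", {
  obs <- make_tiny_survival(list("0" = c(50, 45, 55)))
  cur <- survival_fractions(obs)
  expect_equal(cur$mean_fraction, 0.5)
  expect_equal(cur$sd_fraction, 0.05)
  expect_equal(cur$n_replicates, 3L)
  # 30 ul aliquot: 300 cells, 150 plaques -> 0.5
  obs30 <- make_tiny_survival(list("91" = 150), volume_ul = 30)
  expect_equal(survival_fractions(obs30)$mean_fraction, 0.5)
  # extinct sample
  obs0 <- make_tiny_survival(list("365" = c(0, 0, 0)))
  cur0 <- survival_fractions(obs0)
  expect_equal(cur0$mean_fraction, 0)
  expect_equal(cur0$sd_fraction, 0)
})

test_that("fractions above 1 are kept and flagged, not clipped", {
  obs <- make_tiny_survival(list("0" = c(110, 95, 101)))
  cur <- survival_fractions(obs)
  expect_true(cur$any_over_one)
  expect_equal(cur$mean_fraction, mean(c(1.10, 0.95, 1.01)))
})

test_that("duplicate replicates and zero plated cells are rejected", {
  obs <- make_tiny_survival(list("0" = c(50, 45)))
  dup <- rbind(obs, obs[1, ])
  expect_error(survival_fractions(dup), "duplicate")
  obs$volume_ul <- 0
  expect_error(survival_fractions(obs), "zero cells")
})

test_that("a single constant spore curve self-normalizes to fitness 1", {
  counts <- as.list(stats::setNames(rep(list(c(50, 50, 50)), 7),
                                    c(0, 1, 7, 30, 91, 182, 365)))
  cur <- survival_fractions(make_tiny_survival(counts))
  fit <- relative_fitness(cur)
  expect_equal(fit$fitness, 1)
  expect_equal(fit$se, 0)
  expect_equal(fit$n_timepoints, 6L)  # day 0 excluded
})

test_that("two constant spore curves split around the all-spore mean", {
  days <- c(0, 1, 7, 30, 91, 182, 365)
  hi <- make_tiny_survival(as.list(stats::setNames(rep(list(60), 7), days)),
                           species = "hi")
  lo <- make_tiny_survival(as.list(stats::setNames(rep(list(20), 7), days)),
                           species = "lo")
  fit <- relative_fitness(survival_fractions(rbind(hi, lo)))
  expect_equal(attr(fit, "denominators"),
               stats::setNames(rep(0.4, 6), c(1, 7, 30, 91, 182, 365)))
  expect_equal(fit$fitness[fit$species_id == "hi"], 1.5)
  expect_equal(fit$fitness[fit$species_id == "lo"], 0.5)
})

test_that("spore fitness averages to exactly 1 on complete synthetic data", {
  for (s in 1:3) {
    fit <- relative_fitness(survival_fractions(gen_survival(seed = s)))
    sp <- fit[fit$form == "spore", ]
    expect_equal(mean(sp$fitness), 1, tolerance = 1e-12)
  }
})

test_that("cysts are normalized against the spore denominator", {
  days <- c(0, 1, 7, 30, 91, 182, 365)
  spore <- make_tiny_survival(as.list(stats::setNames(rep(list(40), 7), days)),
                              species = "sp", form = "spore")
  cyst <- make_tiny_survival(as.list(stats::setNames(rep(list(20), 7), days)),
                             species = "cy", form = "cyst")
  fit <- relative_fitness(survival_fractions(rbind(spore, cyst)))
  expect_equal(fit$fitness[fit$form == "cyst"], 0.5)
  expect_equal(fit$fitness[fit$form == "spore"], 1)
})

test_that("relative fitness is invariant to a joint count/density rescaling", {
  obs <- gen_survival(seed = 4)
  fit1 <- relative_fitness(survival_fractions(obs))
  obs2 <- obs
  obs2$plaque_count <- obs$plaque_count * 10
  obs2$cells_per_ml <- obs$cells_per_ml * 10
  fit2 <- relative_fitness(survival_fractions(obs2))
  expect_equal(fit1$fitness, fit2$fitness, tolerance = 1e-12)
})

test_that("a zero spore denominator drops the timepoint with a warning", {
  days <- c(0, 1, 7)
  counts <- list("0" = 50, "1" = 50, "7" = 0)
  cur <- survival_fractions(make_tiny_survival(counts))
  expect_warning(fit <- relative_fitness(cur), "denominator is 0")
  expect_equal(fit$n_timepoints, 1L)
  expect_equal(fit$fitness, 1)
})

test_that("group comparison pools groups per condition with a P-matrix", {
  fit <- relative_fitness(survival_fractions(gen_survival(seed = 1)))
  cmp <- group_fitness_comparison(fit)
  expect_setequal(names(cmp), c("22C_wet", "4C_wet", "m20C_wet", "m20C_dry"))
  frost <- cmp$m20C_wet
  expect_setequal(frost$pools$pool, c("c", "grp1", "grp2", "grp3", "grp4"))
  expect_false(any(grepl("minor", frost$pools$pool)))
  expect_s3_class(frost$kruskal, "dictyfit_ranktest")
  expect_true(isSymmetric(frost$p_matrix))
  # group 4 spores lead at both frost conditions on default parameters
  expect_equal(frost$pools$pool[which.max(frost$pools$mean)], "grp4")
  dry <- cmp$m20C_dry
  expect_equal(dry$pools$pool[which.max(dry$pools$mean)], "grp4")
})

test_that("identical fitness in every pool surfaces the degenerate signal", {
  fit <- data.frame(species_id = sprintf("s%d", 1:8),
                    taxon_group = rep(c("1", "2"), each = 4),
                    form = "spore", condition = "22C_wet",
                    fitness = 1, se = 0, n_timepoints = 6L)
  class(fit) <- c("fitness_table", "data.frame")
  cmp <- group_fitness_comparison(fit)
  expect_true(cmp$`22C_wet`$kruskal$degenerate)
})

test_that("small pools are excluded and reported", {
  fit <- data.frame(species_id = sprintf("s%d", 1:5),
                    taxon_group = c("1", "1", "1", "1", "2"),
                    form = "spore", condition = "22C_wet",
                    fitness = c(1, 2, 3, 4, 5), se = 0, n_timepoints = 6L)
  class(fit) <- c("fitness_table", "data.frame")
  cmp <- group_fitness_comparison(fit)
  expect_equal(cmp$`22C_wet`$excluded, "grp2")
  expect_null(cmp$`22C_wet`$kruskal)
})

test_that("two-pool Dunn p agrees with Mann-Whitney within 0.02", {
  # for two pools the Dunn z and the Mann-Whitney z are algebraically
  # identical; the residual difference is the continuity correction
  set.seed(17)
  for (i in 1:5) {
    a <- rnorm(20)
    b <- rnorm(20, mean = 1)
    p_dunn <- dunn_pairwise(list(a = a, b = b))$p_matrix[1, 2]
    p_mwu <- mann_whitney_u(a, b, exact = FALSE)$p_value
    expect_lt(abs(p_dunn - p_mwu), 0.02)
  }
})
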