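test_that("species pool covers requested families with sane composition", {
  pool <- generate_species_pool(37, seed = 11)
  expect_equal(nrow(pool), 37)
  expect_setequal(unique(pool$family), food_items())
  expect_equal(sum(pool$mean_rel_biomass), 1, tolerance = 1e-12)
  expect_false(anyDuplicated(pool$barcode) > 0)
  expect_true(all(pool$cp >= 0 & pool$cp <= 100))
  # nutritional contrast the simulation is built around
  expect_gt(min(pool$cp[pool$family == "forbs"]),
            max(pool$cp[pool$family == "Poaceae"]))
  expect_lt(max(pool$ndf[pool$family == "forbs"]),
            min(pool$ndf[pool$family == "Poaceae"]))
})

test_that("species pool handles degenerate and invalid inputs", {
  one <- generate_species_pool(1, family_weights = c(Poaceae = 1), seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_rel_biomass, 1)
  expect_error(generate_species_pool(3), "at least the number")
  expect_error(generate_species_pool(10, family_weights = c(Poaceae = 0.7)),
               "sum to 1")
  expect_error(generate_species_pool(10, family_weights = c(0.5, 0.5)),
               "named")
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(generate_species_pool(20, seed = 42),
                   generate_species_pool(20, seed = 42))
  pool <- generate_species_pool(10, seed = 1)
  d <- trial_design(plots_per_strategy = 1, periods = 1)
  expect_identical(generate_quadrats(pool, d, seed = 7),
                   generate_quadrats(pool, d, seed = 7))
  diets <- generate_animal_diets(pool, setNames(rep(1 / 6, 6), food_items()),
                                 seed = 3)
  expect_identical(generate_reads(diets, pool, depth = 500, seed = 9),
                   generate_reads(diets, pool, depth = 500, seed = 9))
})

test_that("quadrat surveys have the right layout and recover the pool mean", {
  pool <- generate_species_pool(12, seed = 5)
  d <- trial_design()
  q <- generate_quadrats(pool, d, quadrats_per_plot = 10, seed = 6)
  # 10 quadrats x 3 replicate plots = 30 quadrats per grazing unit and period
  per_unit <- dplyr::summarise(
    dplyr::group_by(q, unit, period),
    n = dplyr::n_distinct(paste(plot, quadrat)), .groups = "drop")
  expect_true(all(per_unit$n == 30))
  # every plot/period has exactly one record per species per quadrat
  counts <- dplyr::count(q, plot, period, species_id)
  expect_true(all(counts$n == 10))

  # enormous concentration: per-quadrat composition collapses to pool mean
  q1 <- generate_quadrats(pool, trial_design(plots_per_strategy = 1, periods = 1),
                          quadrats_per_plot = 2, dispersion = 1e9, seed = 8)
  one <- q1[q1$plot == "LA_1" & q1$quadrat == 1, ]
  expect_equal(one$biomass / sum(one$biomass),
               pool$mean_rel_biomass[match(one$species_id, pool$species_id)],
               tolerance = 1e-3)
})

test_that("mean family share converges to the configured share", {
  shares <- c(Poaceae = 0.6, forbs = 0.4)
  pool <- generate_species_pool(
    6, family_weights = c(Poaceae = 0.5, forbs = 0.5),
    family_shares = shares, seed = 21)
  d <- trial_design(strategies = "LA", plots_per_strategy = 1, periods = 1)
  q <- generate_quadrats(pool, d, quadrats_per_plot = 2000,
                         dispersion = 150, seed = 22)
  fam <- dplyr::summarise(
    dplyr::group_by(dplyr::inner_join(q, tiny_family_map(pool), by = "species_id"),
                    quadrat, item),
    share = sum(biomass), .groups = "drop_last")
  fam <- dplyr::mutate(fam, share = share / sum(share))
  mean_poa <- mean(fam$share[fam$item == "Poaceae"])
  expect_equal(mean_poa, 0.6, tolerance = 0.01)
})

test_that("diet generator follows the availability-times-preference law", {
  expect_equal(
    unname(expected_diet(c(forbs = 0.1, Poaceae = 0.9),
                         c(forbs = 9, Poaceae = 1))),
    c(0.5, 0.5))
  av <- c(Poaceae = 0.7, forbs = 0.3)
  expect_equal(expected_diet(av), av)  # neutral preference
  expect_error(expected_diet(c(Poaceae = 0.5, forbs = 0.2)), "sum to 1")

  pool <- generate_species_pool(8, family_weights = c(Poaceae = 0.5, forbs = 0.5),
                                seed = 2)
  diets <- generate_animal_diets(pool, av, c(forbs = 9),
                                 animals = paste0("a", 1:4),
                                 concentration = 1e8, seed = 3)
  fam <- diet_by_family(diets)
  expect_equal(fam$prop[fam$family == "forbs"],
               rep(unname(expected_diet(av, c(forbs = 9))["forbs"]), 4),
               tolerance = 1e-3)
  sums <- dplyr::summarise(dplyr::group_by(diets, animal),
                           s = sum(prop), .groups = "drop")
  expect_equal(sums$s, rep(1, 4), tolerance = 1e-9)
})

test_that("read tables are multinomial at the requested depth", {
  pool <- tiny_pool()
  mono <- tibble::tibble(animal = "a1", species_id = "gr1",
                         family = "Poaceae", prop = 1)
  r <- generate_reads(mono, pool, depth = 1000, seed = 4)
  expect_equal(nrow(r), 1)
  expect_equal(r$reads, 1000L)
  expect_equal(unname(attr(r, "sequences")[r$asv_id]), strrep("ACGT", 10))

  two <- tibble::tibble(animal = "a1", species_id = c("gr1", "fb1"),
                        family = c("Poaceae", "forbs"), prop = c(0.6, 0.4))
  deep <- generate_reads(two, pool, depth = 1e5, seed = 5)
  p_hat <- deep$reads[deep$asv_id == "ASV0001"] / 1e5
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / 1e5))
  expect_error(generate_reads(two, pool, depth = 0), ">= 1")
})

test_that("fecal chemistry inverts the marker and digestibility relations", {
  truth <- tibble::tibble(animal = "a1", period = 1, fo = 200,
                          ash = 25, fom = 150, omd = 0.7, omi = 500)
  fs <- generate_fecal_samples(truth, dose = 2.5, noise_cv = 0)
  expect_equal(fs$tio2_conc, 2.5 / 200)
  expect_equal(fs$ash, 25)
  expect_equal(omd_from_fcp(fs$fcp), 0.7, tolerance = 1e-12)
  # asymptote is unreachable: inversion must refuse it
  bad <- dplyr::mutate(truth, omd = 0.899)
  expect_error(generate_fecal_samples(bad, noise_cv = 0), "invertible")
  low <- dplyr::mutate(truth, omd = 0.2)
  expect_error(generate_fecal_samples(low, noise_cv = 0), "invertible")
})

test_that("accelerometer traces have the stated length and bout structure", {
  sim <- generate_accel_trace(duration_h = 13, sample_rate = 1, seed = 31)
  expect_equal(nrow(sim$trace), 46800)  # 13 h x 3600 s at 1 Hz
  expect_setequal(unique(sim$states), c("grazing", "nongrazing"))
  expect_equal(sum(sim$bouts$end - sim$bouts$start), 46800)

  none <- generate_accel_trace(bout_means = c(grazing = 0, nongrazing = 900),
                               duration_h = 1, seed = 32)
  expect_true(all(none$states == "nongrazing"))
  cls <- classify_behavior(dynamic_component(none$trace))
  expect_true(all(cls$label == "nongrazing"))
  expect_equal(daily_grazing_time(cls), 0)
})
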