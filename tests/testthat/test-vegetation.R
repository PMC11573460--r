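test_that("relative abundance normalizes biomass", {
  rec <- tibble::tibble(species_id = c("A", "B", "C"), biomass = c(5, 3, 2))
  expect_equal(relative_abundance(rec)$p, c(0.5, 0.3, 0.2))
  expect_equal(relative_abundance(rec[1, ])$p, 1)
  expect_error(
    relative_abundance(tibble::tibble(species_id = "A", biomass = 0)),
    "empty community")
  # quadrats pool by summing before normalization
  two_quadrats <- tibble::tibble(species_id = c("A", "B", "A", "B"),
                                 biomass = c(1, 0, 3, 4))
  expect_equal(relative_abundance(two_quadrats)$p, c(0.5, 0.5))
})

test_that("Shannon index matches closed forms and is maximal at uniformity", {
  expect_equal(shannon_index(1), 0)
  expect_equal(shannon_index(rep(0.25, 4)), log(4))
  expect_equal(shannon_index(c(0.5, 0.3, 0.2)), 1.02965301406457, tolerance = 1e-10)
  expect_equal(shannon_index(c(0.5, 0.5, 0)), log(2))  # zeros ignored
  expect_error(shannon_index(c(-0.1, 1.1)), "non-negative")

  withr::with_seed(99, {
    for (s in 2:6) {
      p <- as.vector(rdirichlet_test(s))
      expect_equal(shannon_index(p), shannon_index(sample(p)))
      expect_lte(shannon_index(p), log(s) + 1e-12)
    }
  })
})

test_that("food-item availability is a simplex over the item universe", {
  fm <- tibble::tibble(species_id = c("g", "f"), item = c("Poaceae", "forbs"))
  rec <- tibble::tibble(species_id = c("g", "f"), biomass = c(1, 1))
  vra <- food_item_availability(rec, fm)
  expect_equal(vra$item, food_items())
  expect_equal(vra$vra[vra$item == "Poaceae"], 0.5)
  expect_equal(vra$vra[vra$item == "forbs"], 0.5)
  expect_equal(sum(vra$vra), 1, tolerance = 1e-12)

  only_grass <- food_item_availability(rec[1, ], fm)
  expect_equal(only_grass$vra, as.numeric(food_items() == "Poaceae"))
  expect_error(
    food_item_availability(tibble::tibble(species_id = "x", biomass = 1), fm),
    "x")
})

test_that("default simulated communities keep named families above 81%", {
  pool <- generate_species_pool(37, seed = 13)
  q <- generate_quadrats(pool, trial_design(), seed = 14)
  # pooled over all quadrats, the five named families dominate the biomass
  vra <- food_item_availability(q, tiny_family_map(pool))
  named <- sum(vra$vra[vra$item != "forbs"])
  expect_gt(named, 0.81)
  expect_lte(vra$vra[vra$item == "forbs"], 0.19)
})

test_that("community nutrients are biomass-weighted means within bounds", {
  nut <- tibble::tibble(species_id = c("A", "B"), cp = c(8, 16),
                        ndf = c(50, 60), adf = c(30, 40))
  rec <- tibble::tibble(species_id = c("A", "B"), biomass = c(3, 1))
  cn <- community_nutrients(rec, nut)
  expect_equal(cn$community_cp, 10)  # (3*8 + 1*16) / 4
  expect_equal(community_nutrients(rec[1, ], nut)$community_cp, 8)
  eq <- community_nutrients(tibble::tibble(species_id = c("A", "B"),
                                           biomass = c(1, 1)), nut)
  expect_equal(eq$community_cp, 12)
  expect_error(
    community_nutrients(tibble::tibble(species_id = "C", biomass = 1), nut),
    "C")
})

test_that("vegetation summary is internally consistent", {
  pool <- generate_species_pool(10, seed = 17)
  d <- trial_design(strategies = c("LA", "EA"), plots_per_strategy = 2,
                    periods = 2)
  q <- generate_quadrats(pool, d, quadrats_per_plot = 4, seed = 18)
  nut <- pool[, c("species_id", "cp", "ndf", "adf")]
  fm <- tiny_family_map(pool)
  veg <- summarize_vegetation(q, nut, fm)
  expect_equal(nrow(veg), 4 * 2)
  vra_cols <- paste0("vra_", food_items())
  expect_true(all(vra_cols %in% names(veg)))
  expect_equal(rowSums(veg[vra_cols]), rep(1, nrow(veg)), tolerance = 1e-9)
  expect_true(all(veg$shannon >= 0 & veg$shannon <= log(veg$richness) + 1e-12))
  expect_true(all(veg$community_cp >= min(pool$cp) &
                    veg$community_cp <= max(pool$cp)))

  # availability from the summary equals recomputing on the pooled records
  one <- q[q$plot == "LA_1" & q$period == 1, ]
  direct <- food_item_availability(one, fm)
  long <- availability_long(veg)
  slice <- long[long$plot == "LA_1" & long$period == 1, ]
  expect_equal(slice$p, direct$vra, tolerance = 1e-12)
})
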