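test_that("exact-match assignment enforces unique 100% identity", {
  ref <- c(spA = "ACGTACGT", spB = "GGGGCCCC", spC = "ACGTACGA",
           spD = "TTTTAAAA", spE = "TTTTAAAA")  # D and E share a barcode
  asv <- c(x1 = "acgtacgt",      # lowercase exact match to spA
           x2 = "ACGTACGC",      # one mismatch: unassigned
           x3 = "TTTTAAAA",      # matches two species: ambiguous
           x4 = "GGGGCCCC")
  tax <- assign_exact(asv, ref)
  expect_equal(tax$species_id, c("spA", NA, NA, "spB"))
  expect_equal(tax$status, c("assigned", "unassigned", "ambiguous", "assigned"))
  expect_error(assign_exact(asv, character(0)), "empty reference")
  expect_error(assign_exact(c(x = "ACGN"), ref), "non-ACGT")
})

test_that("DRA normalizes assigned reads within food items", {
  counts <- tibble::tibble(
    sample = "s1", asv_id = c("a1", "a2", "a3", "a4"),
    reads = c(60L, 30L, 10L, 100L))
  tax <- tibble::tibble(asv_id = c("a1", "a2", "a3"),
                        species_id = c("g", "c", "f"))
  fm <- tibble::tibble(species_id = c("g", "c", "f"),
                       item = c("Poaceae", "Cyperaceae", "forbs"))
  dra <- compute_dra(counts, tax, fm)
  expect_equal(dra$dra[match(c("Poaceae", "Cyperaceae", "forbs"), dra$item)],
               c(0.6, 0.3, 0.1))
  expect_equal(sum(dra$dra), 1, tolerance = 1e-12)
  # a4 is unassigned: excluded from the denominator, reported as a fraction
  expect_equal(attr(dra, "unassigned")$unassigned_fraction, 0.5)

  solo <- compute_dra(counts[1, ], tax, fm)
  expect_equal(solo$dra[solo$item == "Poaceae"], 1)
  none <- tibble::tibble(sample = "s9", asv_id = "zz", reads = 10L)
  expect_error(compute_dra(none, tax, fm), "s9")
})

test_that("diet nutrients are DRA-weighted means", {
  nut <- tibble::tibble(item = c("Poaceae", "forbs"), cp = c(10, 20),
                        ndf = c(40, 60), adf = c(30, 25))
  half <- tibble::tibble(sample = "s", item = c("Poaceae", "forbs"),
                         dra = c(0.5, 0.5))
  expect_equal(diet_nutrients(half, nut)$diet_cp, 15)
  quarters <- dplyr::mutate(half, dra = c(0.25, 0.75))
  expect_equal(diet_nutrients(quarters, nut)$diet_ndf, 55)
  mono <- tibble::tibble(sample = "s", item = "forbs", dra = 1)
  expect_equal(diet_nutrients(mono, dplyr::mutate(nut, cp = c(10, 18.2)))$diet_cp,
               18.2)
  expect_error(
    diet_nutrients(tibble::tibble(sample = "s", item = "Fabaceae", dra = 1),
                   nut),
    "Fabaceae")
})

test_that("diet nutrients are invariant to refining items with equal values", {
  nut <- tibble::tibble(item = c("A", "B"), cp = c(12, 18),
                        ndf = c(50, 40), adf = c(30, 28))
  coarse <- tibble::tibble(sample = "s", item = c("A", "B"), dra = c(0.4, 0.6))
  nut_fine <- tibble::tibble(item = c("A1", "A2", "B"), cp = c(12, 12, 18),
                             ndf = c(50, 50, 40), adf = c(30, 30, 28))
  fine <- tibble::tibble(sample = "s", item = c("A1", "A2", "B"),
                         dra = c(0.15, 0.25, 0.6))
  expect_equal(diet_nutrients(coarse, nut), diet_nutrients(fine, nut_fine))
})

test_that("bootstrap richness matches enumeration and rarefaction theory", {
  expect_equal(bootstrap_richness(c(A = 100), depth = 5), 1)
  expect_equal(bootstrap_richness(c(A = 3, B = 2, C = 5), depth = 10), 3)
  # {2,2} at depth 2: enumeration over C(4,2)=6 subsamples gives 1 + 4/6
  est <- bootstrap_richness(c(A = 2, B = 2), depth = 2, iterations = 4000,
                            seed = 61)
  expect_equal(est, 1 + 4 / 6, tolerance = 0.03)
  expect_error(bootstrap_richness(c(A = 2, B = 2), depth = 5), "exceeds")
  expect_error(bootstrap_richness(c(A = 2.5), depth = 1), "integers")
})

test_that("bootstrap richness agrees with the hypergeometric expectation", {
  withr::with_seed(62, {
    for (i in 1:12) {
      counts <- rpois(sample(3:8, 1), lambda = sample(2:10, 1)) + 1L
      depth <- sample(seq_len(sum(counts) - 1), 1)
      it <- 800
      est <- bootstrap_richness(counts, depth, iterations = it)
      exact <- as.numeric(suppressWarnings(vegan::rarefy(t(counts), depth)))
      # Monte-Carlo SE of the mean richness estimate
      draws_sd <- sqrt(max(length(counts) / 4, 0.25))
      expect_equal(est, exact, tolerance = max(3 * draws_sd / sqrt(it), 1e-6))
    }
  })
})

test_that("DRA recovers true family diets from deep simulated reads", {
  pool <- generate_species_pool(15, seed = 63)
  av <- setNames(rep(1 / 6, 6), food_items())
  diets <- generate_animal_diets(pool, av, c(forbs = 4),
                                 animals = paste0("s", 1:3), seed = 64)
  reads <- generate_reads(diets, pool, depth = 2e4, seed = 65)
  tax <- assign_exact(attr(reads, "sequences"), pool_reference(pool))
  dra <- compute_dra(reads, tax, tiny_family_map(pool))
  truth <- diet_by_family(diets)
  j <- dplyr::inner_join(dra, truth,
                         by = c(sample = "animal", item = "family"))
  se <- sqrt(j$prop * (1 - j$prop) / 2e4)
  expect_true(all(abs(j$dra - j$prop) <= pmax(3 * se, 1e-3)))
})

test_that("diet_composition ties DRA, nutrients and richness together", {
  pool <- generate_species_pool(12, seed = 66)
  av <- setNames(rep(1 / 6, 6), food_items())
  diets <- generate_animal_diets(pool, av, animals = paste0("s", 1:4),
                                 seed = 67)
  reads <- generate_reads(diets, pool, depth = 3000, seed = 68)
  tax <- assign_exact(attr(reads, "sequences"), pool_reference(pool))
  nut <- dplyr::summarise(
    dplyr::group_by(pool, item = family),
    cp = mean(cp), ndf = mean(ndf), adf = mean(adf), .groups = "drop")
  comp <- diet_composition(reads, tax, tiny_family_map(pool), nut,
                           iterations = 100, seed = 69)
  expect_equal(nrow(comp), 4)
  expect_equal(attr(comp, "depth"), 3000)  # min assigned depth
  expect_equal(rowSums(comp[paste0("dra_", food_items())]), rep(1, 4),
               tolerance = 1e-9)
  obs_rich <- dplyr::count(reads, sample)
  expect_true(all(comp$richness <=
                    dplyr::left_join(comp, obs_rich, by = "sample")$n + 1e-9))
  expect_true(all(comp$diet_cp >= min(pool$cp) & comp$diet_cp <= max(pool$cp)))
})
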