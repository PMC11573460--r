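# Synthetic species pool: the botanical ground truth every other simulated
# layer is built on.

# Default simulation parameters. Family biomass shares put the five named
# families above 81% of standing biomass with graminoid dominance, the
# structure typical of Leymus/Stipa steppe; nutrient ranges give forbs and
# legumes clearly higher crude protein and lower fibre than grasses.
default_family_shares <- function() {
  c(Poaceae = 0.55, Cyperaceae = 0.10, Rosaceae = 0.10,
    Amaryllidaceae = 0.04, Fabaceae = 0.04, forbs = 0.17)
}

default_family_weights <- function() {
  # Probability that a random species in the pool belongs to each item;
  # forbs are species-rich relative to their biomass share.
  c(Poaceae = 0.28, Cyperaceae = 0.08, Rosaceae = 0.11,
    Amaryllidaceae = 0.05, Fabaceae = 0.11, forbs = 0.37)
}

default_nutrient_ranges <- function() {
  list(
    Poaceae        = list(cp = c(7, 11),  ndf = c(58, 68), adf = c(30, 38)),
    Cyperaceae     = list(cp = c(9, 13),  ndf = c(52, 62), adf = c(28, 34)),
    Rosaceae       = list(cp = c(11, 15), ndf = c(42, 52), adf = c(26, 32)),
    Amaryllidaceae = list(cp = c(12, 16), ndf = c(40, 50), adf = c(24, 30)),
    Fabaceae       = list(cp = c(16, 22), ndf = c(35, 45), adf = c(24, 30)),
    forbs          = list(cp = c(13, 19), ndf = c(36, 46), adf = c(24, 32))
  )
}

#' Generate a synthetic plant species pool
#'
#' Builds the ground-truth species list a simulated grazing trial draws on:
#' each species gets a food item (family), CP/NDF/ADF contents drawn
#' uniformly within per-family ranges, a unique DNA barcode, and a mean
#' relative biomass. Family biomass shares follow `family_shares`; within a
#' family, species shares are a Dirichlet split. With the default ranges,
#' every forb has higher CP and lower NDF than every grass.
#'
#' @param n_species Number of species; must be at least the number of
#'   families in `family_weights`.
#' @param family_weights Named probability vector over food items giving the
#'   chance a species belongs to each; every named item is represented at
#'   least once. Defaults to a forb-rich, graminoid-dominated pool.
#' @param nutrient_ranges Named list of per-family `list(cp=, ndf=, adf=)`
#'   min/max ranges (percent of dry matter).
#' @param family_shares Named simplex of family biomass shares.
#' @param barcode_length Length of the simulated barcode sequences.
#' @param seed Optional integer seed; fixing it fixes the pool exactly.
#' @return A tibble with columns `species_id`, `family`, `cp`, `ndf`, `adf`,
#'   `mean_height` (cm), `barcode`, `mean_rel_biomass` (sums to 1).
#' @export
#' @examples
#' pool <- generate_species_pool(37, seed = 1)
#' sum(pool$mean_rel_biomass)
generate_species_pool <- function(n_species = 37,
                                  family_weights = default_family_weights(),
                                  nutrient_ranges = default_nutrient_ranges(),
                                  family_shares = default_family_shares(),
                                  barcode_length = 120,
                                  seed = NULL) {
  if (is.null(names(family_weights)) || any(!nzchar(names(family_weights)))) {
    stop("`family_weights` must be a named vector of food items")
  }
  assert_simplex(family_weights, "family_weights")
  fams <- names(family_weights)
  if (n_species < length(fams)) {
    stop("`n_species` must be at least the number of requested families")
  }
  shares <- family_shares[fams]
  if (any(is.na(shares))) stop("`family_shares` missing an entry for a requested family")
  shares <- shares / sum(shares)

  with_seed_if(seed, {
    # Guarantee one species per family, allocate the rest multinomially.
    counts <- rep(1L, length(fams))
    extra <- n_species - length(fams)
    if (extra > 0) {
      counts <- counts + as.integer(rmultinom(1, extra, prob = family_weights))
    }
    family <- rep(fams, counts)

    ranges <- nutrient_ranges[family]
    draw_in <- function(key) {
      vapply(ranges, function(r) runif(1, r[[key]][1], r[[key]][2]), numeric(1))
    }
    cp <- draw_in("cp"); ndf <- draw_in("ndf"); adf <- draw_in("adf")

    barcode <- random_barcodes(n_species, barcode_length)

    # Family share split among member species, mildly uneven.
    within <- unlist(lapply(counts, function(k) drop(rdirichlet(1, rep(3, k)))))
    mrb <- rep(shares, counts) * within
    mrb <- mrb / sum(mrb)

    tibble::tibble(
      species_id = sprintf("sp%02d", seq_len(n_species)),
      family = family,
      cp = unname(cp), ndf = unname(ndf), adf = unname(adf),
      mean_height = round(runif(n_species, 5, 40), 1),
      barcode = barcode,
      mean_rel_biomass = unname(mrb)
    )
  })
}

# Unique random A/C/G/T strings.
random_barcodes <- function(n, len) {
  draw <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

#' Reference barcode sequences of a species pool
#'
#' @param pool A species pool from [generate_species_pool()].
#' @return Named character vector (names are species ids) of uppercase
#'   barcode sequences, suitable as the reference for [assign_exact()].
#' @export
pool_reference <- function(pool) {
  require_cols(pool, c("species_id", "barcode"), "species pool")
  setNames(toupper(pool$barcode), pool$species_id)
}
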