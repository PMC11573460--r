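# Synthetic field layers: trial layout, quadrat surveys, animal diets and
# metabarcoding read tables.

#' Define the layout of a simulated grazing trial
#'
#' Encodes the standard design: four animal strategies — lambs alone (LA),
#' lambs in mixed grazing (LM), ewes in mixed grazing (EM), ewes alone (EA) —
#' where LM and EM animals share the same physical plots (the MIX grazing
#' unit), three replicate plots per unit, and three sampling periods.
#'
#' @param strategies Character vector of animal strategies.
#' @param plots_per_strategy Replicate plots per grazing unit.
#' @param periods Number of sampling periods.
#' @param animals_per_plot Focal (sampled) animals per strategy and plot.
#' @return An object of class `trial_design`: a list with `strategies`,
#'   `periods`, a `plots` tibble (plot, unit) and an `animals` tibble
#'   (animal, strategy, plot).
#' @export
#' @examples
#' d <- trial_design()
#' nrow(d$animals)  # 4 strategies x 3 plots x 3 animals = 36
trial_design <- function(strategies = c("LA", "LM", "EM", "EA"),
                         plots_per_strategy = 3,
                         periods = 3,
                         animals_per_plot = 3) {
  stopifnot(plots_per_strategy >= 1, periods >= 1, animals_per_plot >= 1)
  unknown <- setdiff(strategies, c("LA", "LM", "EM", "EA"))
  if (length(unknown) > 0) {
    stop("unknown strategies: ", paste(unknown, collapse = ", "))
  }
  unit_of <- function(s) ifelse(s %in% c("LM", "EM"), "MIX", s)
  units <- unique(unit_of(strategies))
  plots <- tibble::tibble(
    unit = rep(units, each = plots_per_strategy),
    plot = paste0(rep(units, each = plots_per_strategy), "_",
                  rep(seq_len(plots_per_strategy), length(units)))
  )
  animals <- tidyr::expand_grid(
    strategy = strategies,
    rep = seq_len(plots_per_strategy),
    k = seq_len(animals_per_plot)
  )
  animals$plot <- paste0(unit_of(animals$strategy), "_", animals$rep)
  animals$animal <- sprintf("%s%d_a%d", animals$strategy, animals$rep, animals$k)
  structure(
    list(strategies = strategies, periods = periods, plots = plots,
         animals = animals[, c("animal", "strategy", "plot")]),
    class = "trial_design"
  )
}

#' Simulate vegetation quadrat surveys
#'
#' Draws per-quadrat species biomass from a compositional model: quadrat
#' total dry biomass is lognormal, and the species split is a Dirichlet draw
#' centred on the pool's mean relative biomass with concentration
#' `dispersion`. Larger `dispersion` means quadrats closer to the pool mean.
#'
#' @param pool Species pool from [generate_species_pool()].
#' @param design A [trial_design()].
#' @param quadrats_per_plot Quadrats clipped per plot and period (default 10,
#'   i.e. 30 per grazing unit and period with three replicate plots).
#' @param dispersion Dirichlet concentration (total) of the quadrat
#'   composition around the pool mean; must be positive.
#' @param total_meanlog,total_sdlog Lognormal parameters of quadrat total dry
#'   biomass in grams per 0.25 m^2 quadrat.
#' @param seed Optional integer seed.
#' @return Tibble of quadrat records: `unit`, `plot`, `period`, `quadrat`,
#'   `species_id`, `biomass` (g dry matter per quadrat), `height` (cm).
#' @export
generate_quadrats <- function(pool, design = trial_design(),
                              quadrats_per_plot = 10,
                              dispersion = 150,
                              total_meanlog = log(35), total_sdlog = 0.3,
                              seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (quadrats_per_plot < 1) stop("`quadrats_per_plot` must be >= 1")
  assert_positive(dispersion, "dispersion")
  alpha <- dispersion * pool$mean_rel_biomass
  keys <- tidyr::expand_grid(
    plot = design$plots$plot,
    period = seq_len(design$periods),
    quadrat = seq_len(quadrats_per_plot)
  )
  with_seed_if(seed, {
    comp <- rdirichlet(nrow(keys), matrix(alpha, nrow(keys), length(alpha),
                                          byrow = TRUE))
    totals <- rlnorm(nrow(keys), total_meanlog, total_sdlog)
    heights <- pmax(1, matrix(rep(pool$mean_height, each = nrow(keys)),
                              nrow(keys)) + rnorm(nrow(keys) * nrow(pool), 0, 2))
    out <- keys[rep(seq_len(nrow(keys)), each = nrow(pool)), ]
    out$species_id <- rep(pool$species_id, nrow(keys))
    out$biomass <- as.vector(t(comp * totals))
    out$height <- round(as.vector(t(heights)), 1)
    out <- dplyr::left_join(out, design$plots, by = "plot")
    tibble::as_tibble(out[, c("unit", "plot", "period", "quadrat",
                              "species_id", "biomass", "height")])
  })
}

#' Expected diet composition under a preference model
#'
#' The expected proportion of food item f in the diet is proportional to
#' availability(f) x preference(f), renormalized. With all preferences equal
#' the expected diet equals availability (neutral selection, Jacobs' D = 0
#' for every item in expectation).
#'
#' @param availability Named simplex of item availability.
#' @param preference Named positive weights per item (default all 1).
#' @return Named simplex of expected diet proportions.
#' @export
#' @examples
#' expected_diet(c(forbs = 0.1, Poaceae = 0.9), c(forbs = 9, Poaceae = 1))
expected_diet <- function(availability, preference = NULL) {
  assert_simplex(availability, "availability")
  if (is.null(names(availability))) stop("`availability` must be named by item")
  # items not named in `preference` default to weight 1 (neutral)
  preference <- build_preference(preference, names(availability))
  assert_positive(preference, "preference")
  w <- availability * preference
  w / sum(w)
}

#' Simulate ground-truth animal diets
#'
#' Each animal's family-level diet is a Dirichlet draw around the expected
#' diet implied by availability and preference (see [expected_diet()]); the
#' family proportion is then spread over the member species in proportion to
#' their mean relative biomass within the family.
#'
#' @param pool Species pool.
#' @param availability Named simplex over food items.
#' @param preference Named positive item weights; default neutral.
#' @param animals Character vector of animal (or sample) identifiers.
#' @param concentration Dirichlet concentration of individual diets around
#'   the expectation; larger values mean less between-animal variation.
#' @param seed Optional integer seed.
#' @return Tibble of species-level true diets: `animal`, `species_id`,
#'   `family`, `prop`; proportions sum to 1 within animal. The expected
#'   family diet is attached as attribute `"expected"`.
#' @export
generate_animal_diets <- function(pool, availability, preference = NULL,
                                  animals = paste0("a", 1:9),
                                  concentration = 80, seed = NULL) {
  assert_positive(concentration, "concentration")
  exp_diet <- expected_diet(availability, preference)
  fams <- names(exp_diet)
  miss <- setdiff(fams[exp_diet > 0], unique(pool$family))
  if (length(miss) > 0) {
    stop("pool has no species for item(s): ", paste(miss, collapse = ", "))
  }
  # Species split within family, proportional to pool mean biomass.
  split <- pool[, c("species_id", "family", "mean_rel_biomass")]
  split <- dplyr::mutate(
    dplyr::group_by(split, .data$family),
    within = .data$mean_rel_biomass / sum(.data$mean_rel_biomass)
  )
  split <- dplyr::ungroup(split)

  with_seed_if(seed, {
    fam_draw <- rdirichlet(length(animals),
                           matrix(concentration * exp_diet[fams],
                                  length(animals), length(fams), byrow = TRUE))
    colnames(fam_draw) <- fams
    fam_tbl <- tibble::as_tibble(fam_draw)
    fam_tbl$animal <- animals
    long <- tidyr::pivot_longer(fam_tbl, -"animal",
                                names_to = "family", values_to = "fam_prop")
    out <- dplyr::inner_join(long, split, by = "family",
                             relationship = "many-to-many")
    out$prop <- out$fam_prop * out$within
    out <- out[, c("animal", "species_id", "family", "prop")]
    out <- dplyr::arrange(out, .data$animal, .data$species_id)
    attr(out, "expected") <- exp_diet
    out
  })
}

#' Family-level view of a true diet table
#'
#' @param diets Species-level diet tibble from [generate_animal_diets()].
#' @return Tibble `animal`, `family`, `prop` with proportions summing to 1.
#' @export
diet_by_family <- function(diets) {
  require_cols(diets, c("animal", "family", "prop"), "diets")
  dplyr::summarise(dplyr::group_by(diets, .data$animal, .data$family),
                   prop = sum(.data$prop), .groups = "drop")
}

#' Simulate a metabarcoding read table from true diets
#'
#' Per sample, read counts over ASVs (one per species barcode) are a single
#' multinomial draw of size `depth` with probabilities equal to the
#' species-level true diet proportions, emulating unbiased amplicon
#' sequencing of fecal DNA.
#'
#' @param diets Species-level diets from [generate_animal_diets()]; the
#'   `animal` column is used as the sample identifier.
#' @param pool Species pool (supplies barcodes).
#' @param depth Reads per sample; must be >= 1.
#' @param seed Optional integer seed.
#' @return Long tibble `sample`, `asv_id`, `reads` (zero rows dropped), with
#'   attribute `"sequences"`: named character vector asv_id -> sequence.
#' @export
generate_reads <- function(diets, pool, depth = 20000, seed = NULL) {
  if (!is.numeric(depth) || depth < 1) stop("`depth` must be >= 1")
  require_cols(diets, c("animal", "species_id", "prop"), "diets")
  asv <- tibble::tibble(
    asv_id = sprintf("ASV%04d", seq_len(nrow(pool))),
    species_id = pool$species_id,
    sequence = toupper(pool$barcode)
  )
  wide <- tidyr::pivot_wider(diets[, c("animal", "species_id", "prop")],
                             names_from = "species_id", values_from = "prop",
                             values_fill = 0)
  samples <- wide$animal
  probmat <- as.matrix(wide[, asv$species_id[asv$species_id %in% names(wide)],
                            drop = FALSE])
  # species absent from the diet table get probability zero
  full <- matrix(0, nrow(wide), nrow(asv),
                 dimnames = list(samples, asv$species_id))
  full[, colnames(probmat)] <- probmat
  with_seed_if(seed, {
    counts <- apply(full, 1, function(p) rmultinom(1, size = depth, prob = p))
    rownames(counts) <- asv$asv_id
    long <- tibble::as_tibble(as.table(counts), .name_repair = "minimal")
    names(long) <- c("asv_id", "sample", "reads")
    long$reads <- as.integer(long$reads)
    long <- long[long$reads > 0, c("sample", "asv_id", "reads")]
    long <- dplyr::arrange(long, .data$sample, .data$asv_id)
    attr(long, "sequences") <- setNames(asv$sequence, asv$asv_id)
    long
  })
}
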