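# Whole-trial simulation: ties the synthetic layers together under one seed.

default_preferences <- function() {
  # Study conditions emulated by default: animals grazing with (or as)
  # experienced ewes seek out high-CP forbs; naive lambs alone avoid them
  # and lean on the abundant grasses and Rosaceae instead.
  list(
    LA = c(forbs = 0.4, Rosaceae = 3),
    LM = c(forbs = 3),
    EM = c(forbs = 3),
    EA = c(forbs = 2.5)
  )
}

#' Simulate a complete grazing trial with known ground truth
#'
#' Generates every raw input layer of the analysis — species pool, quadrat
#' surveys, true animal diets, metabarcoding read tables, marker-dosed
#' fecal chemistry, and (optionally) accelerometer traces — under a single
#' seed, so each downstream module can be validated against the generating
#' truth. Animal diets are driven by per-strategy preference weights
#' applied to each plot/period's availability; one fecal and one diet
#' sample per animal-period.
#'
#' @param design A [trial_design()].
#' @param n_species Species pool size (default 37).
#' @param preferences Named list, strategy -> named preference weights over
#'   food items (items omitted default to 1). `NULL` means neutral
#'   selection for every strategy.
#' @param diet_concentration Dirichlet concentration of individual diets.
#' @param quadrats_per_plot,quadrat_dispersion Passed to
#'   [generate_quadrats()].
#' @param depth Sequencing depth per sample.
#' @param dose,noise_cv Passed to [generate_fecal_samples()].
#' @param collars Named vector: number of collared animals per strategy
#'   (default 6 per strategy, 24 in total). Set to 0 to skip traces.
#' @param accel_duration_h,accel_sample_rate Trace length (hours) and rate
#'   (Hz) per observation session; one session per collared animal-period.
#' @param odba_means,bout_means Passed to [generate_accel_trace()].
#' @param seed Integer seed; every layer derives its own stream from it.
#' @return List of class `grazesel_trial`: `pool`, `family_map`,
#'   `quadrats`, `samples` (sample metadata), `diets` (true species-level
#'   diets per sample), `reads`, `intake_truth`, `fecal`, `accel` (list of
#'   `accel_sim`, possibly empty), `design`.
#' @export
simulate_trial <- function(design = trial_design(),
                           n_species = 37,
                           preferences = default_preferences(),
                           diet_concentration = 80,
                           quadrats_per_plot = 10,
                           quadrat_dispersion = 150,
                           depth = 20000,
                           dose = 2.5, noise_cv = 0.05,
                           collars = c(LA = 6, LM = 6, EM = 6, EA = 6),
                           accel_duration_h = 13, accel_sample_rate = 1,
                           odba_means = c(grazing = 0.3, nongrazing = 0.02),
                           bout_means = c(grazing = 1500, nongrazing = 1000),
                           seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  pool <- generate_species_pool(n_species, seed = derive_seed(seed, "pool"))
  family_map <- tibble::tibble(species_id = pool$species_id,
                               item = pool$family)
  quadrats <- generate_quadrats(pool, design,
                                quadrats_per_plot = quadrats_per_plot,
                                dispersion = quadrat_dispersion,
                                seed = derive_seed(seed, "quadrats"))
  nutrients <- pool[, c("species_id", "cp", "ndf", "adf")]
  veg <- summarize_vegetation(quadrats, nutrients, family_map)
  avail <- availability_long(veg)

  samples <- tidyr::expand_grid(design$animals,
                                period = seq_len(design$periods))
  samples$sample <- paste0(samples$animal, "_p", samples$period)

  diets <- purrr::pmap_dfr(
    dplyr::distinct(samples, .data$strategy, .data$plot, .data$period),
    function(strategy, plot, period) {
      av <- avail[avail$plot == plot & avail$period == period, ]
      availability <- setNames(av$p, av$item)
      pref <- build_preference(preferences[[strategy]], names(availability))
      here <- samples[samples$strategy == strategy &
                        samples$plot == plot & samples$period == period, ]
      d <- generate_animal_diets(
        pool, availability, pref, animals = here$sample,
        concentration = diet_concentration,
        seed = derive_seed(seed, paste("diet", strategy, plot, period)))
      names(d)[names(d) == "animal"] <- "sample"
      d
    })

  reads <- generate_reads(
    stats::setNames(diets, c("animal", "species_id", "family", "prop")),
    pool, depth = depth, seed = derive_seed(seed, "reads"))
  names(reads)[names(reads) == "animal"] <- "sample"

  intake_truth <- generate_intake_truth(
    design$animals$animal, periods = design$periods,
    seed = derive_seed(seed, "intake"))
  fecal <- generate_fecal_samples(intake_truth, dose = dose,
                                  noise_cv = noise_cv,
                                  seed = derive_seed(seed, "fecal"))

  accel <- list()
  for (s in design$strategies) {
    k <- collars[[s]] %||% 0
    if (k <= 0) next
    ids <- utils::head(design$animals$animal[design$animals$strategy == s], k)
    for (a in ids) {
      for (pe in seq_len(design$periods)) {
        accel[[paste0(a, "_p", pe)]] <- generate_accel_trace(
          bout_means = bout_means, odba_means = odba_means,
          duration_h = accel_duration_h, sample_rate = accel_sample_rate,
          animal = a, seed = derive_seed(seed, paste("accel", a, pe)))
      }
    }
  }

  structure(
    list(pool = pool, family_map = family_map, quadrats = quadrats,
         vegetation = veg, samples = samples, diets = diets, reads = reads,
         intake_truth = intake_truth, fecal = fecal, accel = accel,
         design = design),
    class = "grazesel_trial"
  )
}

build_preference <- function(pref, items) {
  out <- setNames(rep(1, length(items)), items)
  if (!is.null(pref)) {
    unknown <- setdiff(names(pref), items)
    if (length(unknown) > 0) {
      stop("preference names not among food items: ",
           paste(unknown, collapse = ", "))
    }
    out[names(pref)] <- pref
  }
  out
}

#' @export
print.grazesel_trial <- function(x, ...) {
  cat(sprintf(
    "Simulated grazing trial: %d species, %d plots, %d periods, %d samples, %d traces\n",
    nrow(x$pool), nrow(x$design$plots), x$design$periods,
    nrow(x$samples), length(x$accel)))
  invisible(x)
}
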