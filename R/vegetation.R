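# Vegetation surveys: plot-level biomass, diversity, food-item availability
# (VRA) and community nutrient content.

#' Relative abundance of species in one community
#'
#' `p_i = n_i / N` with dry biomass used as the abundance measure `n_i`
#' (quadrat surveys weigh clipped biomass rather than count individuals;
#' supply counts in `biomass` to get a count-based version).
#'
#' @param records Quadrat records for one plot/period: tibble with
#'   `species_id` and `biomass`; multiple quadrats are pooled by summing.
#' @return Tibble `species_id`, `p` with `p` summing to 1.
#' @export
#' @examples
#' relative_abundance(tibble::tibble(species_id = c("A", "B", "C"),
#'                                   biomass = c(5, 3, 2)))
relative_abundance <- function(records) {
  require_cols(records, c("species_id", "biomass"), "quadrat records")
  if (any(records$biomass < 0)) stop("`biomass` must be non-negative")
  tot <- dplyr::summarise(dplyr::group_by(records, .data$species_id),
                          n = sum(.data$biomass), .groups = "drop")
  if (sum(tot$n) <= 0) stop("empty community: all-zero biomass")
  tibble::tibble(species_id = tot$species_id, p = tot$n / sum(tot$n))
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum(p_i * log(p_i))` over a relative-abundance vector; zero
#' entries contribute nothing (0 * log 0 := 0). Maximized at `log(S)` for a
#' uniform community.
#'
#' @param p Numeric simplex of relative abundances.
#' @return H' (dimensionless, natural log).
#' @export
#' @examples
#' shannon_index(rep(0.25, 4))  # log(4)
shannon_index <- function(p) {
  if (any(p < 0)) stop("relative abundances must be non-negative")
  assert_simplex(p, "p")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Food-item availability (VRA) from quadrat records
#'
#' The proportion of each food item (plant family, with non-focal species
#' pooled as forbs) in total above-ground biomass — the availability side of
#' the selectivity comparison.
#'
#' @param records Quadrat records with `species_id`, `biomass`.
#' @param family_map Tibble `species_id`, `item` mapping every species to a
#'   food item; unmapped species are an error naming them.
#' @param items Item universe (order of the output); defaults to
#'   [food_items()]. Items absent from the records get availability 0.
#' @return Tibble `item`, `vra`, summing to 1.
#' @export
food_item_availability <- function(records, family_map, items = food_items()) {
  require_cols(records, c("species_id", "biomass"), "quadrat records")
  require_cols(family_map, c("species_id", "item"), "family map")
  unmapped <- setdiff(unique(records$species_id), family_map$species_id)
  if (length(unmapped) > 0) {
    stop("species without a food-item mapping: ",
         paste(unmapped, collapse = ", "))
  }
  joined <- dplyr::inner_join(records, family_map, by = "species_id")
  if (sum(joined$biomass) <= 0) stop("empty community: all-zero biomass")
  agg <- dplyr::summarise(dplyr::group_by(joined, .data$item),
                          b = sum(.data$biomass), .groups = "drop")
  out <- tibble::tibble(item = items)
  out <- dplyr::left_join(out, agg, by = "item")
  out$b[is.na(out$b)] <- 0
  extra <- setdiff(agg$item, items)
  if (length(extra) > 0) {
    stop("family map uses items outside the item universe: ",
         paste(extra, collapse = ", "))
  }
  tibble::tibble(item = out$item, vra = out$b / sum(out$b))
}

#' Biomass-weighted community nutrient content
#'
#' @param records Quadrat records with `species_id`, `biomass`.
#' @param nutrients Tibble `species_id`, `cp`, `ndf`, `adf` (percent of dry
#'   matter); every species carrying biomass must be present.
#' @return One-row tibble `community_cp`, `community_ndf`, `community_adf`.
#' @export
community_nutrients <- function(records, nutrients) {
  require_cols(records, c("species_id", "biomass"), "quadrat records")
  require_cols(nutrients, c("species_id", "cp", "ndf", "adf"), "nutrient table")
  agg <- dplyr::summarise(dplyr::group_by(records, .data$species_id),
                          b = sum(.data$biomass), .groups = "drop")
  agg <- agg[agg$b > 0, ]
  miss <- setdiff(agg$species_id, nutrients$species_id)
  if (length(miss) > 0) {
    stop("missing nutrient values for species: ", paste(miss, collapse = ", "))
  }
  j <- dplyr::inner_join(agg, nutrients, by = "species_id")
  w <- j$b / sum(j$b)
  tibble::tibble(
    community_cp = sum(w * j$cp),
    community_ndf = sum(w * j$ndf),
    community_adf = sum(w * j$adf)
  )
}

#' Per-item nutrient content of the standing vegetation
#'
#' Biomass-weighted CP/NDF/ADF within each food item, per plot and period —
#' the conversion table used to express a family-level diet in nutrient
#' terms.
#'
#' @inheritParams summarize_vegetation
#' @return Tibble `plot`, `period`, `item`, `cp`, `ndf`, `adf`.
#' @export
food_item_nutrients <- function(quadrats, nutrients, family_map) {
  require_cols(quadrats, c("plot", "period", "species_id", "biomass"),
               "quadrat table")
  j <- dplyr::inner_join(quadrats, family_map, by = "species_id")
  j <- dplyr::inner_join(j, nutrients, by = "species_id")
  dplyr::summarise(
    dplyr::group_by(j, .data$plot, .data$period, .data$item),
    cp = sum(.data$biomass * .data$cp) / sum(.data$biomass),
    ndf = sum(.data$biomass * .data$ndf) / sum(.data$biomass),
    adf = sum(.data$biomass * .data$adf) / sum(.data$biomass),
    .groups = "drop"
  )
}

#' Summarize quadrat surveys per plot and period
#'
#' Pools the quadrats of each plot/period (the replicate unit is the plot)
#' and reports standing biomass, mean height, richness, Shannon diversity,
#' food-item availability and community nutrient content.
#'
#' @param quadrats Quadrat table: `plot`, `period`, `quadrat`, `species_id`,
#'   `biomass`, optionally `height` and `unit`.
#' @param nutrients Per-species nutrient table (`species_id`, `cp`, `ndf`,
#'   `adf`).
#' @param family_map Tibble `species_id`, `item`.
#' @param quadrat_area_m2 Area of one quadrat in m^2 (default 0.25, a
#'   50 x 50 cm frame) used to express biomass per m^2.
#' @return Tibble keyed by (`plot`, `period`) with `total_biomass` (g/m^2),
#'   `mean_height` (cm), `richness`, `shannon`, one `vra_<item>` column per
#'   food item, and `community_cp`/`community_ndf`/`community_adf`.
#' @export
summarize_vegetation <- function(quadrats, nutrients, family_map,
                                 quadrat_area_m2 = 0.25) {
  require_cols(quadrats, c("plot", "period", "quadrat", "species_id", "biomass"),
               "quadrat table")
  if (any(quadrats$biomass < 0)) {
    bad <- which(quadrats$biomass < 0)[1]
    stop(sprintf("negative biomass in quadrat table (row %d)", bad))
  }
  keys <- dplyr::distinct(quadrats, dplyr::across(dplyr::any_of(c("unit"))),
                          .data$plot, .data$period)
  one <- function(pl, pe) {
    rec <- quadrats[quadrats$plot == pl & quadrats$period == pe, ]
    nq <- length(unique(rec$quadrat))
    pres <- rec[rec$biomass > 0, ]
    p <- relative_abundance(rec)
    vra <- food_item_availability(rec, family_map)
    vw <- tidyr::pivot_wider(vra, names_from = "item", values_from = "vra",
                             names_prefix = "vra_")
    nutr <- community_nutrients(rec, nutrients)
    mh <- if ("height" %in% names(rec)) {
      sum(pres$biomass * pres$height) / sum(pres$biomass)
    } else NA_real_
    dplyr::bind_cols(
      tibble::tibble(
        plot = pl, period = pe,
        total_biomass = sum(rec$biomass) / (nq * quadrat_area_m2),
        mean_height = mh,
        richness = length(unique(pres$species_id)),
        shannon = shannon_index(p$p)
      ),
      vw, nutr
    )
  }
  out <- purrr::pmap_dfr(
    dplyr::distinct(quadrats, .data$plot, .data$period),
    function(plot, period) one(plot, period)
  )
  if ("unit" %in% names(quadrats)) {
    out <- dplyr::left_join(dplyr::distinct(quadrats, .data$unit, .data$plot),
                            out, by = "plot")
  }
  dplyr::arrange(out, .data$plot, .data$period)
}

#' Long availability view of a vegetation summary
#'
#' @param veg_summary Output of [summarize_vegetation()].
#' @return Tibble `plot`, `period`, `item`, `p` (availability).
#' @export
availability_long <- function(veg_summary) {
  long <- tidyr::pivot_longer(veg_summary, dplyr::starts_with("vra_"),
                              names_to = "item", names_prefix = "vra_",
                              values_to = "p")
  long[, c("plot", "period", "item", "p")]
}
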