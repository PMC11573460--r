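# Diet from metabarcoding read tables: exact-match taxonomy, relative read
# abundance (DRA), diet nutrients and bootstrap dietary richness.

#' Assign ASVs to species by exact sequence match
#'
#' An ASV is assigned if and only if its sequence is identical (100%
#' identity, case-insensitive, no gaps) to the barcode of exactly one
#' reference species. ASVs matching no reference are `"unassigned"`;
#' ASVs whose sequence occurs under more than one species are
#' `"ambiguous"` and also left unassigned.
#'
#' @param asv_seqs Named character vector (or `Biostrings::DNAStringSet`) of
#'   ASV sequences, names are ASV ids.
#' @param reference Named character vector (or `DNAStringSet`) of reference
#'   barcodes, names are species ids.
#' @return Tibble `asv_id`, `species_id` (NA when unassigned), `status`
#'   (`"assigned"`, `"unassigned"`, `"ambiguous"`).
#' @export
assign_exact <- function(asv_seqs, reference) {
  asv_seqs <- as_seq_vector(asv_seqs, "asv_seqs")
  reference <- as_seq_vector(reference, "reference")
  if (length(reference) == 0) stop("empty reference")
  ref_tbl <- tibble::tibble(species_id = names(reference),
                            seq = unname(reference))
  # sequences shared by several species are ambiguous as a whole
  n_species_per_seq <- table(ref_tbl$seq)
  hit <- match(unname(asv_seqs), ref_tbl$seq)
  species <- ref_tbl$species_id[hit]
  status <- ifelse(is.na(hit), "unassigned",
                   ifelse(n_species_per_seq[unname(asv_seqs)] > 1,
                          "ambiguous", "assigned"))
  species[status != "assigned"] <- NA_character_
  tibble::tibble(asv_id = names(asv_seqs), species_id = species,
                 status = status)
}

as_seq_vector <- function(x, what) {
  if (inherits(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  if (length(x) == 0) return(setNames(character(0), character(0)))
  if (!is.character(x) || is.null(names(x))) {
    stop(sprintf("`%s` must be a named character vector or DNAStringSet", what))
  }
  up <- toupper(x)
  bad <- grepl("[^ACGT]", up)
  if (any(bad)) {
    stop(sprintf("`%s` contains non-ACGT characters (e.g. %s)", what,
                 names(x)[bad][1]))
  }
  up
}

#' Relative read abundance (DRA) per food item
#'
#' Sums assigned reads within food items and normalizes per sample over
#' assigned reads only; the unassigned fraction is reported alongside, not
#' folded into the denominator.
#'
#' @param counts Long read table: `sample`, `asv_id`, `reads`.
#' @param taxonomy Assignment table from [assign_exact()] (`asv_id`,
#'   `species_id`); unmatched ASVs count as unassigned.
#' @param family_map Tibble `species_id`, `item`.
#' @param items Item universe; items without reads get DRA 0.
#' @return Tibble `sample`, `item`, `reads`, `dra` (simplex per sample) with
#'   per-sample `unassigned_fraction` attached as an attribute tibble.
#' @export
compute_dra <- function(counts, taxonomy, family_map, items = food_items()) {
  require_cols(counts, c("sample", "asv_id", "reads"), "read table")
  require_cols(taxonomy, c("asv_id", "species_id"), "taxonomy")
  require_cols(family_map, c("species_id", "item"), "family map")
  if (any(counts$reads < 0) || any(counts$reads != round(counts$reads))) {
    stop("`reads` must be non-negative integers")
  }
  j <- dplyr::left_join(counts, taxonomy[, c("asv_id", "species_id")],
                        by = "asv_id")
  j <- dplyr::left_join(j, family_map, by = "species_id")
  per_sample <- dplyr::summarise(
    dplyr::group_by(j, .data$sample),
    total = sum(.data$reads),
    assigned = sum(.data$reads[!is.na(.data$item)]),
    .groups = "drop"
  )
  zero <- per_sample$sample[per_sample$assigned == 0]
  if (length(zero) > 0) {
    stop("no assigned reads for sample(s): ", paste(zero, collapse = ", "))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(j[!is.na(j$item), ], .data$sample, .data$item),
    reads = sum(.data$reads), .groups = "drop"
  )
  grid <- tidyr::expand_grid(sample = unique(counts$sample), item = items)
  out <- dplyr::left_join(grid, agg, by = c("sample", "item"))
  out$reads[is.na(out$reads)] <- 0L
  out <- dplyr::left_join(out, per_sample[, c("sample", "assigned")],
                          by = "sample")
  out$dra <- out$reads / out$assigned
  out$assigned <- NULL
  per_sample$unassigned_fraction <- 1 - per_sample$assigned / per_sample$total
  attr(out, "unassigned") <-
    per_sample[, c("sample", "unassigned_fraction")]
  out
}

#' Convert a family-level diet to nutrient terms
#'
#' Weighted mean of each nutrient over the food items actually consumed,
#' weights being the diet proportions — the standard conversion of a
#' botanical diet composition to a nutritional one.
#'
#' @param dra Tibble `sample`, `item`, `dra` (per-sample simplex).
#' @param item_nutrients Tibble `item`, `cp`, `ndf`, `adf` (e.g. one
#'   plot/period slice of [food_item_nutrients()]); every item with
#'   `dra > 0` must be present.
#' @return Tibble `sample`, `diet_cp`, `diet_ndf`, `diet_adf`.
#' @export
diet_nutrients <- function(dra, item_nutrients) {
  require_cols(dra, c("sample", "item", "dra"), "dra table")
  require_cols(item_nutrients, c("item", "cp", "ndf", "adf"),
               "item nutrient table")
  used <- dra[dra$dra > 0, ]
  miss <- setdiff(unique(used$item), item_nutrients$item)
  if (length(miss) > 0) {
    stop("missing nutrient content for consumed item(s): ",
         paste(miss, collapse = ", "))
  }
  j <- dplyr::inner_join(used, item_nutrients, by = "item")
  dplyr::summarise(
    dplyr::group_by(j, .data$sample),
    diet_cp = sum(.data$dra * .data$cp) / sum(.data$dra),
    diet_ndf = sum(.data$dra * .data$ndf) / sum(.data$dra),
    diet_adf = sum(.data$dra * .data$adf) / sum(.data$dra),
    .groups = "drop"
  )
}

#' Bootstrap dietary richness at a standardized depth
#'
#' Expected number of distinct ASVs in a random subsample of `depth` reads,
#' estimated as the mean over `iterations` resamples. Default resampling is
#' without replacement (classical rarefaction; agrees with the closed-form
#' hypergeometric expectation), with-replacement available by flag.
#'
#' @param counts Integer vector of per-ASV read counts for one sample (zeros
#'   allowed and ignored).
#' @param depth Standardized depth; must not exceed the total reads when
#'   subsampling without replacement.
#' @param iterations Number of bootstrap draws (default 1000).
#' @param replace Sample with replacement instead of rarefying.
#' @param seed Optional integer seed.
#' @return Expected ASV richness at `depth` (a real number).
#' @export
#' @examples
#' bootstrap_richness(c(A = 2, B = 2), depth = 2, iterations = 2000, seed = 1)
bootstrap_richness <- function(counts, depth, iterations = 1000,
                               replace = FALSE, seed = NULL) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("sample has no reads")
  if (any(counts != round(counts))) stop("`counts` must be integers")
  if (iterations < 1) stop("`iterations` must be >= 1")
  total <- sum(counts)
  if (depth < 1) stop("`depth` must be >= 1")
  if (!replace && depth > total) {
    stop(sprintf("depth %d exceeds the sample's %d reads", depth, total))
  }
  k <- length(counts)
  if (k == 1) return(1)
  if (!replace && depth == total) return(k)
  with_seed_if(seed, {
    pool <- rep.int(seq_len(k), counts)
    draws <- vapply(seq_len(iterations), function(i) {
      length(unique(sample(pool, depth, replace = replace)))
    }, numeric(1))
    mean(draws)
  })
}

#' Per-sample diet composition, nutrients and richness
#'
#' Convenience wrapper tying the diet module together for a whole read
#' table: DRA per food item, nutrient conversion against per-item
#' vegetation nutrients, and bootstrap richness at a common depth.
#'
#' @inheritParams compute_dra
#' @param item_nutrients Tibble `sample`, joined per-sample `item`, `cp`,
#'   `ndf`, `adf` — or a single `item`-keyed table applied to all samples.
#' @param depth Standardized richness depth; `NULL` (default) uses the
#'   minimum assigned-read depth across samples.
#' @param iterations Bootstrap iterations for richness.
#' @param seed Optional integer seed for the richness bootstrap.
#' @return Tibble per sample: `sample`, `richness`, `unassigned_fraction`,
#'   `diet_cp`, `diet_ndf`, `diet_adf`, plus one `dra_<item>` column per
#'   food item.
#' @export
diet_composition <- function(counts, taxonomy, family_map, item_nutrients,
                             items = food_items(), depth = NULL,
                             iterations = 1000, seed = NULL) {
  dra <- compute_dra(counts, taxonomy, family_map, items = items)
  unassigned <- attr(dra, "unassigned")
  assigned <- dplyr::left_join(counts,
                               taxonomy[, c("asv_id", "species_id")],
                               by = "asv_id")
  assigned <- assigned[!is.na(assigned$species_id), ]
  depth_by_sample <- dplyr::summarise(
    dplyr::group_by(assigned, .data$sample),
    total = sum(.data$reads), .groups = "drop")
  if (is.null(depth)) depth <- min(depth_by_sample$total)
  rich <- purrr::imap_dfr(
    split(assigned, assigned$sample),
    function(df, s) {
      tibble::tibble(
        sample = s,
        richness = bootstrap_richness(
          df$reads, depth = depth, iterations = iterations,
          seed = if (is.null(seed)) NULL else derive_seed(seed, s))
      )
    }
  )
  nutr <- diet_nutrients(dra, item_nutrients)
  wide <- tidyr::pivot_wider(dra[, c("sample", "item", "dra")],
                             names_from = "item", values_from = "dra",
                             names_prefix = "dra_")
  out <- dplyr::left_join(rich, unassigned, by = "sample")
  out <- dplyr::left_join(out, nutr, by = "sample")
  out <- dplyr::left_join(out, wide, by = "sample")
  attr(out, "depth") <- depth
  out
}
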