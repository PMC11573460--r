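# Typed readers/writers for the pipeline's plain-text interchange formats.
# All tables are TSV with a header row; sequences travel as FASTA.

read_table_checked <- function(path, required, what, col_types = NULL) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- readr::read_tsv(path, show_col_types = FALSE, col_types = col_types,
                        progress = FALSE)
  if (nrow(df) == 0) stop(sprintf("no records in %s file: %s", what, path))
  require_cols(df, required, sprintf("%s file '%s'", what, path))
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    rlang::inform(sprintf("%s file '%s': extra column(s) preserved: %s",
                          what, path, paste(extra, collapse = ", ")))
  }
  df
}

#' Read a vegetation quadrat table
#'
#' Expects TSV columns `plot`, `period`, `quadrat`, `species_id`,
#' `biomass` (optionally `unit`, `height`); negative biomass is a
#' validation error naming the row.
#'
#' @param path File path.
#' @return Tibble of quadrat records.
#' @export
read_quadrats <- function(path) {
  df <- read_table_checked(path, c("plot", "period", "quadrat",
                                   "species_id", "biomass"), "quadrat")
  bad <- which(df$biomass < 0)
  if (length(bad) > 0) {
    stop(sprintf("negative biomass in '%s' (data row %d)", path, bad[1]))
  }
  df
}

#' Read a per-species nutrient table
#'
#' TSV columns `species_id`, `cp`, `ndf`, `adf` (percent of dry matter).
#'
#' @inheritParams read_quadrats
#' @export
read_species_nutrients <- function(path) {
  df <- read_table_checked(path, c("species_id", "cp", "ndf", "adf"),
                           "species nutrient")
  for (nu in c("cp", "ndf", "adf")) {
    if (any(df[[nu]] < 0 | df[[nu]] > 100)) {
      stop(sprintf("`%s` outside [0, 100] in '%s'", nu, path))
    }
  }
  df
}

#' Read a species-to-food-item map
#'
#' TSV columns `species_id`, `item`.
#'
#' @inheritParams read_quadrats
#' @export
read_family_map <- function(path) {
  read_table_checked(path, c("species_id", "item"), "family map")
}

#' Read a fecal chemistry table
#'
#' TSV columns `animal`, `period`, `tio2_conc`, `fcp`, `ash`.
#'
#' @inheritParams read_quadrats
#' @export
read_fecal_chemistry <- function(path) {
  read_table_checked(path, c("animal", "period", "tio2_conc", "fcp", "ash"),
                     "fecal chemistry")
}

#' Read a tri-axial accelerometer trace
#'
#' TSV columns `time`, `ax`, `ay`, `az` (optionally `animal`).
#'
#' @inheritParams read_quadrats
#' @export
read_accel_trace <- function(path) {
  read_table_checked(path, c("time", "ax", "ay", "az"), "accelerometer trace")
}

#' Read a long-format read-count table
#'
#' TSV columns `sample`, `asv_id`, `reads`.
#'
#' @inheritParams read_quadrats
#' @export
read_read_counts <- function(path) {
  df <- read_table_checked(path, c("sample", "asv_id", "reads"), "read count")
  if (any(df$reads < 0)) stop(sprintf("negative read counts in '%s'", path))
  df$reads <- as.integer(df$reads)
  df
}

#' Read sequences from a FASTA file
#'
#' Accepts wrapped or unwrapped records; sequences are normalized to
#' uppercase on read.
#'
#' @param path File path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("no records in FASTA file: ", path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a table as TSV
#'
#' @param df Data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
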