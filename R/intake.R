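# Marker-based intake chain: fecal output -> fecal organic matter ->
# digestibility from fecal crude protein -> organic-matter intake.

#' Constants of the fecal-CP digestibility regression
#'
#' Organic-matter digestibility (OMD, as a fraction) is predicted from fecal
#' crude protein (FCP, percent of fecal dry matter) by
#' `OMD = a - b * exp(-c * FCP / fcp_scale)`. The defaults are the published
#' calibration for sheep on temperate forages: asymptote `a = 0.899`,
#' range `b = 0.644`, rate `c = 0.5774`, with FCP divided by 100. Keeping
#' the constants in one object makes an alternative calibration a
#' configuration change rather than a code change.
#'
#' @param a Asymptotic digestibility (fraction), must exceed `b`.
#' @param b Range of the exponential term.
#' @param c Rate constant; positive.
#' @param fcp_scale Divisor applied to FCP before the exponent (default 100).
#' @return A list of class `omd_model`.
#' @export
#' @examples
#' m <- omd_model()
#' omd_from_fcp(15, m)
omd_model <- function(a = 0.899, b = 0.644, c = 0.5774, fcp_scale = 100) {
  if (!(a > b) || b <= 0) stop("`omd_model` requires a > b > 0")
  if (c <= 0) stop("`omd_model` requires c > 0")
  structure(list(a = a, b = b, c = c, fcp_scale = fcp_scale),
            class = "omd_model")
}

#' Fecal output from marker concentration
#'
#' Total fecal dry-matter output (g/day) from an inert external marker:
#' `FO = dose / tio2_conc`, where the animal receives `dose` grams of TiO2
#' per day and `tio2_conc` is the marker concentration in fecal dry matter
#' (g marker per g feces). Vectorized over `tio2_conc`.
#'
#' @param tio2_conc Marker concentration, g/g; must be positive.
#' @param dose Daily marker dose in grams (default 2.5).
#' @return Fecal output in g dry matter per day.
#' @export
#' @examples
#' fecal_output(0.0125)  # 200 g/day
fecal_output <- function(tio2_conc, dose = 2.5) {
  assert_positive(dose, "dose")
  if (any(!is.finite(tio2_conc)) || any(tio2_conc <= 0)) {
    stop("marker not detected: `tio2_conc` must be strictly positive")
  }
  dose / tio2_conc
}

#' Fecal organic matter from fecal output and ash
#'
#' Organic matter is the dry sample minus its incineration residue, so
#' `FOM = FO * (1 - ash / 100)` with ash as percent of fecal dry matter.
#'
#' @param fo Fecal output, g/day.
#' @param ash Ash content, percent of fecal dry matter, in `[0, 100)`.
#' @return Fecal organic matter, g/day.
#' @export
fecal_organic_matter <- function(fo, ash) {
  if (any(ash < 0) || any(ash >= 100)) {
    stop("`ash` must be in [0, 100) percent of fecal dry matter")
  }
  fo * (1 - ash / 100)
}

#' Organic-matter digestibility from fecal crude protein
#'
#' Evaluates the regression in [omd_model()]: strictly increasing in FCP,
#' bounded in `(a - b, a)` — with the default constants, from 0.255 just
#' above zero FCP to the asymptote 0.899.
#'
#' @param fcp Fecal crude protein, percent of fecal dry matter; positive.
#' @param model An [omd_model()].
#' @return OMD as a fraction.
#' @export
omd_from_fcp <- function(fcp, model = omd_model()) {
  stopifnot(inherits(model, "omd_model"))
  if (any(!is.finite(fcp)) || any(fcp <= 0)) {
    stop("`fcp` must be strictly positive")
  }
  model$a - model$b * exp(-model$c * fcp / model$fcp_scale)
}

#' Organic-matter intake from fecal organic matter and digestibility
#'
#' `OMI = FOM / (1 - OMD)`: the organic matter excreted is the indigestible
#' fraction of what was eaten.
#'
#' @param fom Fecal organic matter, g/day.
#' @param omd Digestibility as a fraction in `[0, 1)`.
#' @return Organic-matter intake, g/day.
#' @export
organic_matter_intake <- function(fom, omd) {
  if (any(omd < 0) || any(omd >= 1)) {
    stop("`omd` must be a fraction in [0, 1)")
  }
  fom / (1 - omd)
}

#' Run the full marker chain on a fecal chemistry table
#'
#' Applies [fecal_output()], [fecal_organic_matter()], [omd_from_fcp()] and
#' [organic_matter_intake()] per row of a fecal sample table.
#'
#' @param fecal Tibble with columns `animal`, `period`, `tio2_conc`, `fcp`,
#'   `ash` (see [generate_fecal_samples()] or [read_fecal_chemistry()]).
#' @param dose Daily marker dose, grams.
#' @param model An [omd_model()].
#' @param tio2_unit Either `"g_per_g"` (default) or `"mg_per_g"`; the latter
#'   is converted before Eq. use.
#' @return The input keys plus `fo`, `fom`, `omd`, `omi`.
#' @export
estimate_intake <- function(fecal, dose = 2.5, model = omd_model(),
                            tio2_unit = c("g_per_g", "mg_per_g")) {
  tio2_unit <- match.arg(tio2_unit)
  require_cols(fecal, c("animal", "period", "tio2_conc", "fcp", "ash"),
               "fecal chemistry table")
  conc <- if (tio2_unit == "mg_per_g") fecal$tio2_conc / 1000 else fecal$tio2_conc
  fo <- fecal_output(conc, dose = dose)
  fom <- fecal_organic_matter(fo, fecal$ash)
  omd <- omd_from_fcp(fecal$fcp, model)
  tibble::tibble(
    animal = fecal$animal, period = fecal$period,
    fo = fo, fom = fom, omd = omd,
    omi = organic_matter_intake(fom, omd)
  )
}
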