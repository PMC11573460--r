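# Synthetic marker-dosed fecal chemistry, consistent with the intake chain.

#' Simulate ground-truth intake physiology per animal-period
#'
#' Draws the per-animal quantities the marker chain is meant to recover:
#' daily fecal dry-matter output (lognormal), fecal ash content (uniform)
#' and organic-matter digestibility (uniform within the invertible range of
#' the digestibility regression). Fecal organic matter and organic-matter
#' intake follow deterministically.
#'
#' @param animals Character vector of animal ids.
#' @param periods Number of periods (one sample per animal-period).
#' @param fo_meanlog,fo_sdlog Lognormal parameters of fecal output (g/day).
#' @param ash_range Uniform range of fecal ash (percent of fecal DM).
#' @param omd_range Uniform range of true OMD (fraction).
#' @param seed Optional integer seed.
#' @return Tibble `animal`, `period`, `fo`, `ash`, `fom`, `omd`, `omi`.
#' @export
generate_intake_truth <- function(animals, periods = 3,
                                  fo_meanlog = log(600), fo_sdlog = 0.15,
                                  ash_range = c(12, 18),
                                  omd_range = c(0.55, 0.72),
                                  seed = NULL) {
  keys <- tidyr::expand_grid(animal = animals, period = seq_len(periods))
  with_seed_if(seed, {
    n <- nrow(keys)
    fo <- rlnorm(n, fo_meanlog, fo_sdlog)
    ash <- runif(n, ash_range[1], ash_range[2])
    omd <- runif(n, omd_range[1], omd_range[2])
    fom <- fo * (1 - ash / 100)
    tibble::tibble(keys, fo = fo, ash = ash, fom = fom, omd = omd,
                   omi = fom / (1 - omd))
  })
}

#' Simulate marker-dosed fecal chemistry from ground truth
#'
#' Builds the fecal sample table the intake module consumes, consistent with
#' the generating truth: TiO2 concentration is dose / true fecal output,
#' perturbed by multiplicative lognormal noise with coefficient of variation
#' `noise_cv` (mean-one, so `noise_cv = 0` round-trips exactly); fecal crude
#' protein is obtained by inverting the digestibility regression at the true
#' OMD; ash is set so that fecal organic matter derived downstream matches
#' the true value when the marker is noise-free.
#'
#' @param truth Tibble from [generate_intake_truth()] (columns `animal`,
#'   `period`, `fo`, `fom`, `omd`).
#' @param dose Daily marker dose in grams (default 2.5).
#' @param noise_cv Coefficient of variation of the marker concentration
#'   noise; 0 disables noise.
#' @param model Digestibility regression constants from [omd_model()].
#' @param seed Optional integer seed.
#' @return Tibble `animal`, `period`, `tio2_conc` (g marker per g fecal DM),
#'   `fcp` (percent of fecal DM), `ash` (percent of fecal DM).
#' @export
generate_fecal_samples <- function(truth, dose = 2.5, noise_cv = 0.05,
                                   model = omd_model(), seed = NULL) {
  assert_positive(dose, "dose")
  require_cols(truth, c("animal", "period", "fo", "fom", "omd"), "truth")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  fcp <- invert_omd(truth$omd, model)  # errors outside the invertible range
  with_seed_if(seed, {
    n <- nrow(truth)
    noise <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      rlnorm(n, -sdlog^2 / 2, sdlog)  # mean-one multiplicative noise
    } else rep(1, n)
    tibble::tibble(
      animal = truth$animal,
      period = truth$period,
      tio2_conc = dose / truth$fo * noise,
      fcp = fcp,
      ash = 100 * (1 - truth$fom / truth$fo)
    )
  })
}

# Invert omd = a - b exp(-c fcp / scale) for fcp; defined only on
# (a - b, a), the open range the regression can produce for positive FCP.
invert_omd <- function(omd, model = omd_model()) {
  a <- model$a; b <- model$b
  bad <- omd >= a | omd <= a - b
  if (any(bad)) {
    stop(sprintf(
      "true OMD outside the invertible range (%.3f, %.3f) of the digestibility regression: %s",
      a - b, a, paste(format(omd[bad]), collapse = ", ")), call. = FALSE)
  }
  -(model$fcp_scale / model$c) * log((a - omd) / b)
}
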