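# Synthetic tri-axial accelerometer traces with a known bout structure.

#' Simulate a tri-axial accelerometer trace with known behaviour bouts
#'
#' Behaviour alternates between grazing and non-grazing in a two-state
#' renewal (Markov) process with exponential bout lengths. Within a bout,
#' per-axis dynamic acceleration is zero-mean Gaussian noise scaled so the
#' expected per-sample ODBA equals the state's `odba_means` entry
#' (per-axis sd = m / (3 * sqrt(2/pi))). The static component is gravity
#' projected on a slowly drifting orientation, so raw axes carry a ~1 g
#' baseline that the dynamic-component filter must remove.
#'
#' The defaults mirror a daylight observation session: 13 h at 1 Hz
#' (46 800 samples), grazing ODBA well above the 0.1 g classification
#' threshold and non-grazing well below it.
#'
#' @param bout_means Named vector, mean bout length in seconds for `grazing`
#'   and `nongrazing`. A non-positive grazing mean yields a trace with no
#'   grazing at all.
#' @param odba_means Named vector of expected per-sample ODBA (g) per state.
#' @param duration_h Trace duration in hours.
#' @param sample_rate Samples per second; must be positive.
#' @param animal Identifier copied into the output.
#' @param seed Optional integer seed.
#' @return List of class `accel_sim` with elements `trace` (tibble `animal`,
#'   `time` in seconds, `ax`, `ay`, `az` in g), `states` (per-sample true
#'   behaviour) and `bouts` (tibble `start`, `end`, `state`).
#' @export
generate_accel_trace <- function(bout_means = c(grazing = 1500, nongrazing = 1000),
                                 odba_means = c(grazing = 0.3, nongrazing = 0.02),
                                 duration_h = 13, sample_rate = 1,
                                 animal = "a1", seed = NULL) {
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  for (nm in c("grazing", "nongrazing")) {
    if (!nm %in% names(bout_means) || !nm %in% names(odba_means)) {
      stop("`bout_means` and `odba_means` need 'grazing' and 'nongrazing' entries")
    }
  }
  n <- round(duration_h * 3600 * sample_rate)
  if (n < 2) stop("trace would have fewer than 2 samples")
  total_s <- duration_h * 3600

  with_seed_if(seed, {
    states <- simulate_bouts(bout_means, total_s, n)
    sd_axis <- odba_means[states] / (3 * sqrt(2 / pi))
    dx <- rnorm(n, 0, sd_axis); dy <- rnorm(n, 0, sd_axis)
    dz <- rnorm(n, 0, sd_axis)
    # slow orientation drift: random-walk pitch/roll, tiny per-sample steps
    pitch <- cumsum(rnorm(n, 0, 0.002 / sqrt(sample_rate)))
    roll <- cumsum(rnorm(n, 0, 0.002 / sqrt(sample_rate)))
    trace <- tibble::tibble(
      animal = animal,
      time = (seq_len(n) - 1) / sample_rate,
      ax = sin(pitch) + dx,
      ay = sin(roll) * cos(pitch) + dy,
      az = cos(roll) * cos(pitch) + dz
    )
    rl <- rle(states)
    ends <- cumsum(rl$lengths) / sample_rate
    bouts <- tibble::tibble(
      start = c(0, utils::head(ends, -1)),
      end = ends,
      state = rl$values
    )
    structure(list(trace = trace, states = states, bouts = bouts),
              class = "accel_sim")
  })
}

# Alternating exponential bout lengths discretized to the sample grid.
simulate_bouts <- function(bout_means, total_s, n) {
  mg <- bout_means[["grazing"]]; mn <- bout_means[["nongrazing"]]
  if (mg <= 0) return(rep("nongrazing", n))
  if (mn <= 0) return(rep("grazing", n))
  state <- if (runif(1) < mg / (mg + mn)) "grazing" else "nongrazing"
  out <- character(0)
  t <- 0
  dt <- total_s / n
  while (length(out) < n) {
    len <- rexp(1, rate = 1 / bout_means[[state]])
    k <- max(1L, round(len / dt))
    out <- c(out, rep(state, k))
    state <- if (state == "grazing") "nongrazing" else "grazing"
    t <- t + len
  }
  out[seq_len(n)]
}
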