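# Behaviour from tri-axial acceleration: dynamic component, ODBA,
# threshold classification and daily grazing time.

#' Dynamic acceleration per axis
#'
#' Separates body movement from gravity by subtracting a centred running
#' mean (the static component) from each raw axis. Edges use the truncated
#' mean over the available samples, so the output has the same length as
#' the input.
#'
#' @param trace Tibble with monotone `time` (seconds) and raw axes `ax`,
#'   `ay`, `az` in g (surge, sway, heave). Use `convert_ms2 = TRUE` for
#'   traces recorded in m/s^2.
#' @param smoothing_window Width of the running mean in seconds; must span
#'   at least 2 samples, and the trace must be at least as long as the
#'   window.
#' @param convert_ms2 Divide the axes by 9.80665 first.
#' @return The input tibble plus dynamic axes `dx`, `dy`, `dz` and `odba`.
#' @export
dynamic_component <- function(trace, smoothing_window = 2, convert_ms2 = FALSE) {
  require_cols(trace, c("time", "ax", "ay", "az"), "accelerometer trace")
  if (is.unsorted(trace$time, strictly = TRUE)) {
    stop("`time` must be strictly increasing")
  }
  rate <- 1 / stats::median(diff(trace$time))
  k <- round(smoothing_window * rate)
  if (k < 2) stop("`smoothing_window` must span at least 2 samples")
  if (nrow(trace) < k) stop("trace shorter than the smoothing window")
  g <- if (convert_ms2) 9.80665 else 1
  out <- trace
  for (axis in c("ax", "ay", "az")) {
    raw <- trace[[axis]] / g
    static <- zoo::rollapply(raw, width = k, FUN = mean,
                             align = "center", partial = TRUE)
    out[[axis]] <- raw
    out[[sub("a", "d", axis)]] <- raw - static
  }
  out$odba <- odba(out$dx, out$dy, out$dz)
  out
}

#' Overall dynamic body acceleration
#'
#' `ODBA = |dx| + |dy| + |dz|`: the sum of absolute dynamic accelerations
#' over the three orthogonal axes, in g. Invariant to axis relabeling and
#' sign flips.
#'
#' @param dx,dy,dz Dynamic acceleration per axis, g.
#' @return Per-sample ODBA, g.
#' @export
#' @examples
#' odba(0.1, -0.05, 0.05)  # 0.2
odba <- function(dx, dy, dz) {
  abs(dx) + abs(dy) + abs(dz)
}

#' Classify grazing vs non-grazing from epoch-mean ODBA
#'
#' Averages per-sample ODBA over consecutive epochs and applies the
#' activity threshold: epochs with mean ODBA strictly above `threshold` are
#' grazing, strictly below are non-grazing. An epoch mean exactly equal to
#' the threshold (a measure-zero case left open by the two strict
#' inequalities) is labelled non-grazing.
#'
#' @param trace Output of [dynamic_component()] (needs `time` and `odba`),
#'   or any tibble with those columns.
#' @param epoch Epoch length in seconds (default 60).
#' @param threshold Classification threshold in g (default 0.1).
#' @return Tibble `window_start`, `window_end` (seconds), `odba` (epoch
#'   mean), `label` (`"grazing"`/`"nongrazing"`), plus `animal` if present.
#' @export
classify_behavior <- function(trace, epoch = 60, threshold = 0.1) {
  require_cols(trace, c("time", "odba"), "ODBA series")
  assert_positive(threshold, "threshold")
  assert_positive(epoch, "epoch")
  t0 <- trace$time[1]
  dt <- if (nrow(trace) > 1) stats::median(diff(trace$time)) else epoch
  idx <- floor((trace$time - t0) / epoch)
  out <- dplyr::summarise(
    dplyr::group_by(trace, win = idx),
    window_start = t0 + .data$win[1] * epoch,
    window_end = t0 + (.data$win[1] + 1) * epoch,
    odba = mean(.data$odba),
    .groups = "drop"
  )
  # the final (possibly partial) epoch ends where the trace ends
  out$window_end <- pmin(out$window_end, max(trace$time) + dt)
  out$label <- ifelse(out$odba > threshold, "grazing", "nongrazing")
  out$win <- NULL
  if ("animal" %in% names(trace)) {
    out <- dplyr::bind_cols(tibble::tibble(animal = trace$animal[1]), out)
  }
  out
}

#' Daily grazing time from a classified behaviour series
#'
#' Sums the durations of grazing-labelled windows, clipped to an
#' observation window; windows must not overlap.
#'
#' @param series Tibble with `window_start`, `window_end`, `label`.
#' @param day_window Length-2 numeric, observation window in seconds;
#'   default spans the series.
#' @return Grazing time in hours.
#' @export
daily_grazing_time <- function(series, day_window = NULL) {
  require_cols(series, c("window_start", "window_end", "label"),
               "behaviour series")
  s <- dplyr::arrange(series, .data$window_start)
  if (any(s$window_end[-nrow(s)] > s$window_start[-1] + 1e-9)) {
    stop("overlapping windows in behaviour series")
  }
  if (is.null(day_window)) day_window <- c(min(s$window_start), max(s$window_end))
  lo <- pmax(s$window_start, day_window[1])
  hi <- pmin(s$window_end, day_window[2])
  dur <- pmax(0, hi - lo)
  sum(dur[s$label == "grazing"]) / 3600
}

#' Epoch-level accuracy of behaviour classification against known bouts
#'
#' Utility for simulation studies: compares classified epochs with the
#' majority true state in each epoch.
#'
#' @param series Classified series from [classify_behavior()].
#' @param sim An `accel_sim` from [generate_accel_trace()].
#' @return Fraction of epochs whose label matches the true majority state.
#' @export
classification_accuracy <- function(series, sim) {
  stopifnot(inherits(sim, "accel_sim"))
  t <- sim$trace$time
  truth <- vapply(seq_len(nrow(series)), function(i) {
    in_win <- t >= series$window_start[i] & t < series$window_end[i]
    st <- sim$states[in_win]
    if (length(st) == 0) return(NA_character_)
    names(sort(table(st), decreasing = TRUE))[1]
  }, character(1))
  mean(series$label == truth, na.rm = TRUE)
}
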