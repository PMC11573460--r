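# Jacobs' electivity index and tests of departure from neutral selection.

#' Jacobs' selectivity index
#'
#' `D = (r - p) / (r + p - 2 r p)` compares a food item's proportion in the
#' diet (`r`) with its relative availability in the vegetation (`p`).
#' D ranges from -1 (complete avoidance: eaten not at all though available)
#' to +1 (exclusive preference); 0 means use in proportion to availability.
#' Antisymmetric in its arguments and sign-matched to the difference
#' r - p. The degenerate cases r = p = 0 and r = p = 1 have a zero
#' denominator and
#' return `NA` (undefined, to be excluded rather than imputed).
#'
#' @param r Diet proportion(s) in `[0, 1]`.
#' @param p Availability proportion(s) in `[0, 1]`.
#' @return Jacobs' D, vectorized over `r` and `p`.
#' @export
#' @examples
#' jacobs_d(0.5, 0.2)   # 0.6, preference
#' jacobs_d(0, 0.4)     # -1, complete avoidance
jacobs_d <- function(r, p) {
  if (any(r < 0 | r > 1, na.rm = TRUE) || any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("`r` and `p` must be proportions in [0, 1]")
  }
  denom <- r + p - 2 * r * p
  out <- ifelse(abs(denom) < .Machine$double.eps, NA_real_,
                (r - p) / denom)
  out
}

#' Join diet and availability into a selectivity table
#'
#' Matches each diet sample's food-item proportions (DRA) with the
#' availability (VRA) of the same plot and period and computes Jacobs' D.
#'
#' @param dra Long diet table: `sample`, `plot`, `period`, `item`, `dra`.
#' @param availability Long availability table from [availability_long()]:
#'   `plot`, `period`, `item`, `p`.
#' @return Tibble `sample`, `plot`, `period`, `item`, `r`, `p`, `d`; rows
#'   where D is undefined carry `NA`.
#' @export
compute_selectivity <- function(dra, availability) {
  require_cols(dra, c("sample", "plot", "period", "item", "dra"),
               "diet table")
  require_cols(availability, c("plot", "period", "item", "p"),
               "availability table")
  j <- dplyr::inner_join(dra, availability,
                         by = c("plot", "period", "item"))
  if (nrow(j) == 0) stop("diet and availability tables share no plot/period/item keys")
  tibble::tibble(
    sample = j$sample, plot = j$plot, period = j$period, item = j$item,
    r = j$dra, p = j$p, d = jacobs_d(j$dra, j$p)
  )
}

#' Wilcoxon signed-rank test of selectivity against neutrality
#'
#' Tests whether a collection of per-animal Jacobs' D values for one food
#' item departs from zero. Zeros are dropped before ranking (Wilcoxon's
#' original treatment; the Pratt variant keeps them through ranking). For
#' n of 25 or fewer the null distribution of the signed-rank statistic is
#' computed exactly by convolution over sign patterns, which remains exact
#' under tied absolute values; larger samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param d Numeric vector of selectivity values (NAs dropped).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`.
#' @param exact_n Largest n for which the exact null is used (default 25).
#' @return One-row tibble: `n` (after zero handling), `statistic` (W+, sum
#'   of positive ranks), `p_value`, `direction` (sign of the median),
#'   `method`. If no informative values remain, `p_value` is `NA`.
#' @export
#' @examples
#' selectivity_test(c(0.3, 0.5, 0.1))  # all positive, exact p = 0.25
selectivity_test <- function(d, alternative = c("two.sided", "greater", "less"),
                             zero_method = c("wilcox", "pratt"),
                             exact_n = 25) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  d <- d[is.finite(d)]
  if (length(d) < 1) stop("need at least one non-missing selectivity value")
  direction <- sign(stats::median(d))
  x <- if (zero_method == "wilcox") d[d != 0] else d
  n <- length(x)
  if (n == 0 || all(x == 0)) {
    return(tibble::tibble(n = n, statistic = NA_real_, p_value = NA_real_,
                          direction = 0, method = "no information"))
  }
  r <- rank(abs(x))
  if (zero_method == "pratt") {
    keep <- x != 0
    x <- x[keep]; r <- r[keep]
  }
  w <- sum(r[x > 0])
  m <- length(x)
  if (m <= exact_n) {
    p <- signed_rank_exact_p(r, w, alternative)
    method <- "exact"
  } else {
    p <- signed_rank_normal_p(r, w, alternative)
    method <- "normal approximation"
  }
  tibble::tibble(n = n, statistic = w, p_value = p, direction = direction,
                 method = method)
}

# Exact null distribution of W+ = sum of ranks with positive sign, under
# independent equiprobable signs. Works with average (tied) ranks by
# doubling them to integers and convolving the sign-pattern polynomial.
signed_rank_exact_p <- function(ranks, w, alternative) {
  r2 <- round(2 * ranks)
  tot <- sum(r2)
  f <- numeric(tot + 1)  # f[v + 1] = #sign patterns with 2*W == v
  f[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(tot + 1 - ri)])
    f <- f + shifted
  }
  f <- f / 2^length(ranks)
  v <- round(2 * w)
  p_le <- sum(f[seq_len(v + 1)])
  p_ge <- sum(f[(v + 1):(tot + 1)])
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

signed_rank_normal_p <- function(ranks, w, alternative) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  ties <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  cc <- 0.5
  z_ge <- (w - mu - cc) / sqrt(sigma2)
  z_le <- (w - mu + cc) / sqrt(sigma2)
  switch(alternative,
         two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                    stats::pnorm(z_ge, lower.tail = FALSE))),
         greater = stats::pnorm(z_ge, lower.tail = FALSE),
         less = stats::pnorm(z_le))
}

#' Per-item selectivity tests over a selectivity table
#'
#' Applies [selectivity_test()] to each food item's per-sample D values,
#' excluding undefined entries.
#'
#' @param selectivity Output of [compute_selectivity()].
#' @param ... Passed to [selectivity_test()].
#' @return Tibble with one row per item: test results plus `median_d`.
#' @export
selectivity_tests_by_item <- function(selectivity, ...) {
  require_cols(selectivity, c("item", "d"), "selectivity table")
  purrr::imap_dfr(split(selectivity, selectivity$item), function(df, it) {
    d <- df$d[is.finite(df$d)]
    if (length(d) == 0) {
      return(tibble::tibble(item = it, n = 0, statistic = NA_real_,
                            p_value = NA_real_, direction = 0,
                            method = "no information", median_d = NA_real_))
    }
    res <- selectivity_test(d, ...)
    dplyr::bind_cols(tibble::tibble(item = it), res,
                     tibble::tibble(median_d = stats::median(d)))
  })
}
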