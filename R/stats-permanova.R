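# One-way permutational MANOVA on a dissimilarity matrix.

#' Permutational multivariate analysis of variance (one-way)
#'
#' Distance-based pseudo-F from the squared-dissimilarity decomposition:
#' the total sum of squares is the sum of all pairwise squared
#' dissimilarities divided by n, the within-group sum divides each group's
#' internal pairs by that group's size (unbalanced-safe), and
#' `F = (SS_between / (k - 1)) / (SS_within / (n - k))`. Significance comes
#' from free permutation of the group labels with the add-one estimator
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`; with
#' `permutations = "exhaustive"` every relabeling is enumerated instead
#' (feasible for n up to ~8) and p is the exact fraction of relabelings at
#' or above the observed F.
#'
#' On Euclidean distances of univariate data the pseudo-F equals the
#' classical one-way ANOVA F.
#'
#' @param dm `dist` or square symmetric dissimilarity matrix.
#' @param groups Factor (or coercible) of group labels, one per sample;
#'   at least two non-empty groups.
#' @param n_perm Number of random permutations (default 999).
#' @param permutations `"sampled"` (default) or `"exhaustive"`.
#' @param seed Optional integer seed for the permutation stream.
#' @return Object of class `grazesel_permanova`: list with `pseudo_f`,
#'   `r2`, `p`, `n_perm`, `df`, and the sums of squares.
#' @export
permanova <- function(dm, groups, n_perm = 999,
                      permutations = c("sampled", "exhaustive"),
                      seed = NULL) {
  permutations <- match.arg(permutations)
  d <- as.matrix(stats::as.dist(dm))
  groups <- factor(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("`groups` must have one label per sample")
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  if (any(tabulate(groups) == 0)) stop("a group has 0 samples")
  if (n - k < 1) stop("no residual degrees of freedom")
  D2 <- d^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  f_of <- function(g) {
    ssw <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
    }
    ssb <- ss_total - ssw
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_of(groups)
  ssw <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ssb <- ss_total - ssw

  if (permutations == "exhaustive") {
    perms <- all_permutations(n)
    f_all <- vapply(seq_len(ncol(perms)),
                    function(i) f_of(groups[perms[, i]]), numeric(1))
    p <- mean(f_all >= f_obs - 1e-12)
    n_perm <- ncol(perms)
  } else {
    f_perm <- with_seed_if(seed, {
      vapply(seq_len(n_perm), function(i) f_of(sample(groups)), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  }
  structure(
    list(pseudo_f = f_obs, r2 = ssb / ss_total, p = p, n_perm = n_perm,
         df = c(between = k - 1, within = n - k),
         ss = c(between = ssb, within = ssw, total = ss_total),
         permutations = permutations),
    class = "grazesel_permanova"
  )
}

# All n! permutations as columns; intended for small n only.
all_permutations <- function(n) {
  if (n > 9) stop("exhaustive enumeration is limited to n <= 9")
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v))
    do.call(cbind, lapply(seq_along(v), function(i) {
      rbind(v[i], rec(v[-i]))
    }))
  }
  rec(seq_len(n))
}

#' @export
print.grazesel_permanova <- function(x, ...) {
  cat(sprintf(
    "perMANOVA: pseudo-F = %.4f (df %d, %d), R2 = %.4f, p = %.4g (%s, %d permutations)\n",
    x$pseudo_f, x$df[["between"]], x$df[["within"]], x$r2, x$p,
    x$permutations, x$n_perm))
  invisible(x)
}

#' @rdname permanova
#' @param x A `grazesel_permanova` object.
#' @param ... Unused.
#' @export
tidy.grazesel_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within", "total"),
    df = c(x$df[["between"]], x$df[["within"]], sum(x$df)),
    sum_sq = unname(x$ss),
    pseudo_f = c(x$pseudo_f, NA, NA),
    r2 = c(x$r2, 1 - x$r2, 1),
    p_value = c(x$p, NA, NA)
  )
}

#' @rdname permanova
#' @export
glance.grazesel_permanova <- function(x, ...) {
  tibble::tibble(pseudo_f = x$pseudo_f, r2 = x$r2, p_value = x$p,
                 n_perm = x$n_perm)
}
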