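# Bray-Curtis dissimilarity and NMDS ordination.

#' Bray-Curtis dissimilarity between two compositions
#'
#' `BC(u, v) = sum |u - v| / sum (u + v)`, in `[0, 1]`; 0 iff the vectors
#' are identical, 1 iff their supports are disjoint. Equivalent to
#' `1 - 2 * sum(pmin(u, v)) / sum(u + v)` on non-negative input.
#'
#' @param u,v Non-negative numeric vectors of equal length, not both all
#'   zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(2, 1, 0), c(0, 1, 2))  # 4/6
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("`u` and `v` must have equal length")
  if (any(u < 0) || any(v < 0)) stop("compositions must be non-negative")
  s <- sum(u + v)
  if (s == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(u - v)) / s
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param x Sample-by-variable matrix (or data frame of numeric columns)
#'   with sample ids as row names.
#' @return A `dist` object of pairwise Bray-Curtis dissimilarities.
#' @export
bray_curtis_matrix <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("compositions must be non-negative")
  rs <- rowSums(x)
  if (any(rs == 0)) stop("all-zero row(s): ",
                         paste(which(rs == 0), collapse = ", "))
  man <- stats::dist(x, method = "manhattan")
  denom <- stats::as.dist(outer(rs, rs, "+"))
  out <- man / denom
  attr(out, "method") <- "bray-curtis"
  out
}

#' Nonmetric multidimensional scaling with random restarts
#'
#' Embeds a dissimilarity matrix in `k` dimensions by Kruskal's monotone
#' regression (via `vegan::monoMDS`), taking the best (lowest stress-1) of
#' `n_starts` fits: the first start is the metric (principal-coordinate)
#' configuration, the rest are random. The winning configuration is rotated
#' to its principal axes. Ties in stress keep the earliest start.
#'
#' @param dm A `dist` or square symmetric matrix of dissimilarities.
#' @param k Embedding dimension (default 2); needs at least `k + 2` samples.
#' @param n_starts Number of starts (default 20).
#' @param seed Optional integer seed; fixing it fixes the result.
#' @param maxit Iteration cap per fit.
#' @return Object of class `grazesel_nmds`: list with `points` (n x k
#'   matrix), `stress` (Kruskal stress-1, in `[0, 1]`), `k`, `n_starts`.
#' @export
nmds <- function(dm, k = 2, n_starts = 20, seed = NULL, maxit = 300) {
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  if (diff(range(d)) < 1e-12) {
    # all-equal dissimilarities: a regular simplex embeds exactly
    if (n < k + 1) stop("NMDS needs at least k + 1 samples")
    warning("all dissimilarities equal: degenerate configuration, stress 0")
    pts <- stats::cmdscale(d, k = k)
    if (ncol(pts) < k) pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
    return(new_nmds(pts, 0, k, n_starts, labels))
  }
  if (n < k + 2) stop("NMDS needs at least k + 2 samples")
  with_seed_if(seed, {
    best <- NULL
    init0 <- stats::cmdscale(d, k = k)
    if (ncol(init0) < k) {
      init0 <- cbind(init0, matrix(rnorm(n * (k - ncol(init0)), 0, 1e-4), n))
    }
    for (s in seq_len(max(1, n_starts))) {
      init <- if (s == 1) init0 else matrix(rnorm(n * k), n, k)
      fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                            maxit = maxit)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- best$points
    # principal-axis rotation for a reproducible orientation
    pr <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
    pts <- pr$x[, seq_len(k), drop = FALSE]
    new_nmds(pts, best$stress, k, n_starts, labels)
  })
}

new_nmds <- function(points, stress, k, n_starts, labels) {
  colnames(points) <- paste0("NMDS", seq_len(ncol(points)))
  rownames(points) <- labels
  structure(list(points = points, stress = stress, k = k,
                 n_starts = n_starts),
            class = "grazesel_nmds")
}

#' @export
print.grazesel_nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples in %d dimensions, stress = %.4f\n",
              nrow(x$points), x$k, x$stress))
  invisible(x)
}

#' @rdname nmds
#' @param x A `grazesel_nmds` object.
#' @param ... Unused.
#' @export
tidy.grazesel_nmds <- function(x, ...) {
  tibble::tibble(sample = rownames(x$points),
                 tibble::as_tibble(x$points))
}
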