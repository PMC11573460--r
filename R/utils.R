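# Internal helpers shared across modules.

#' Food items used throughout the package
#'
#' The six food items a grazing-trial diet and vegetation are partitioned
#' into: the five plant families that dominate above-ground biomass in the
#' target steppe communities, plus a pooled "forbs" item for the remaining
#' broad-leaved herbs.
#'
#' @return Character vector of the six item names, in canonical order.
#' @export
#' @examples
#' food_items()
food_items <- function() {
  c("Poaceae", "Cyperaceae", "Rosaceae", "Amaryllidaceae", "Fabaceae", "forbs")
}

# Evaluate `code` under a temporary RNG state when a seed is given,
# otherwise use the session RNG as-is.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Deterministically derive a stage seed from a global seed. Keeps results
# below .Machine$integer.max so the value is a valid R seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 65011 + 1) * 32003 + h) %% 2147483629L
}

# Validate that `x` is a probability vector (non-negative, sums to 1).
assert_simplex <- function(x, what = "weights", tol = 1e-8) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < -tol)) {
    stop(sprintf("`%s` must be a non-negative numeric vector", what),
         call. = FALSE)
  }
  if (abs(sum(x) - 1) > max(tol, 1e-6)) {
    stop(sprintf("`%s` must sum to 1 (got %.6f)", what, sum(x)),
         call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive", what), call. = FALSE)
  }
  invisible(x)
}

# Check a data frame for required columns; error names the missing ones.
require_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# One Dirichlet draw per row; alpha may be a vector (recycled) or matrix.
rdirichlet <- function(n, alpha) {
  if (is.matrix(alpha)) {
    stopifnot(nrow(alpha) == n)
    g <- matrix(rgamma(length(alpha), shape = alpha), nrow = n)
  } else {
    g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                nrow = n)
  }
  g / rowSums(g)
}
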