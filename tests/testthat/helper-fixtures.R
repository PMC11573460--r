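# Small in-code fixtures shared across tests.

# A minimal two-family pool with fixed, hand-set values.
tiny_pool <- function() {
  tibble::tibble(
    species_id = c("gr1", "gr2", "fb1"),
    family = c("Poaceae", "Poaceae", "forbs"),
    cp = c(8, 10, 16),
    ndf = c(60, 64, 40),
    adf = c(32, 34, 26),
    mean_height = c(20, 25, 10),
    barcode = c(strrep("ACGT", 10), strrep("CGTA", 10), strrep("GTAC", 10)),
    mean_rel_biomass = c(0.5, 0.3, 0.2)
  )
}

tiny_family_map <- function(pool = tiny_pool()) {
  tibble::tibble(species_id = pool$species_id, item = pool$family)
}

# All permutations of 1..n as columns (test-side enumeration).
combinat_perms <- function(n) {
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v))
    do.call(cbind, lapply(seq_along(v), function(i) rbind(v[i], rec(v[-i]))))
  }
  rec(seq_len(n))
}

# Random point on the simplex (uses the session RNG).
rdirichlet_test <- function(s) {
  x <- stats::rgamma(s, 1)
  x / sum(x)
}

# Independent pseudo-F oracle: McArdle-Anderson trace formula on the
# Gower-centred inner-product matrix (a different algebraic route from the
# package's pairwise-sum decomposition).
trace_pseudo_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  k <- nlevels(groups)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~ groups)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ss_total <- sum(diag(G))
  ss_between <- sum(diag(H %*% G %*% H))
  ss_within <- ss_total - ss_between
  (ss_between / (k - 1)) / (ss_within / (n - k))
}
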