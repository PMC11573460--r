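test_that("Bray-Curtis matches its closed forms", {
  expect_equal(bray_curtis(c(1, 2), c(1, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(2, 1, 0), c(0, 1, 2)), 4 / 6)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 1), c(1, 1)), "non-negative")
  # alternative min-based form on random non-negative vectors
  withr::with_seed(91, {
    for (i in 1:25) {
      u <- runif(6); v <- runif(6)
      expect_equal(bray_curtis(u, v),
                   1 - 2 * sum(pmin(u, v)) / sum(u + v), tolerance = 1e-12)
    }
  })
})

test_that("Bray-Curtis matrix agrees with vegan and is a proper dist", {
  withr::with_seed(92, m <- matrix(runif(40), 8))
  d <- bray_curtis_matrix(m)
  expect_true(inherits(d, "dist"))
  expect_equal(as.vector(d), as.vector(vegan::vegdist(m, "bray")),
               tolerance = 1e-12)
  expect_error(bray_curtis_matrix(rbind(m, 0)), "all-zero")
})

test_that("pseudo-F equals classical ANOVA F on univariate Euclidean data", {
  withr::with_seed(93, {
    for (i in 1:20) {
      g <- factor(rep(letters[1:3], times = sample(3:6, 3, replace = TRUE)))
      y <- rnorm(length(g), mean = as.integer(g) * 0.3)
      f_classical <- unname(summary(stats::aov(y ~ g))[[1]]$`F value`[1])
      res <- permanova(stats::dist(y), g, n_perm = 9, seed = i)
      expect_equal(res$pseudo_f, f_classical, tolerance = 1e-9)
    }
  })
})

test_that("permanova agrees with adonis2 on multivariate data", {
  withr::with_seed(94, {
    m <- matrix(runif(60), 12)
    g <- rep(c("A", "B"), each = 6)
    d <- bray_curtis_matrix(m)
    res <- permanova(d, g, n_perm = 499, seed = 7)
    ref <- vegan::adonis2(d ~ g, permutations = 999)
    expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-9)
    expect_equal(res$r2, ref$R2[1], tolerance = 1e-9)
    expect_lt(abs(res$p - ref$`Pr(>F)`[1]), 0.08)
  })
})

test_that("exhaustive permutation p matches the independent trace oracle", {
  withr::with_seed(95, {
    m <- matrix(runif(18), 6)
    g <- rep(c("A", "B"), each = 3)
    d <- bray_curtis_matrix(m)
    res <- permanova(d, g, permutations = "exhaustive")
    # brute force with an algebraically different pseudo-F route
    perms <- combinat_perms(6)
    f_all <- apply(perms, 2, function(ix) trace_pseudo_f(d, g[ix]))
    f_obs <- trace_pseudo_f(d, g)
    expect_equal(res$pseudo_f, f_obs, tolerance = 1e-9)
    expect_equal(res$p, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
  })
})

test_that("permanova degenerate and error cases behave", {
  # perfect separation: identical within groups, distinct between
  m <- rbind(matrix(1, 3, 2), matrix(5, 3, 2))
  res <- permanova(stats::dist(m), rep(c("A", "B"), each = 3), n_perm = 99,
                   seed = 1)
  expect_equal(res$r2, 1)
  expect_true(is.infinite(res$pseudo_f))
  # permutations recreating the split (or its mirror) tie at infinite F,
  # so the attainable p is ~ 2 / C(6,3) plus estimator resolution
  expect_lte(res$p, 0.25)
  expect_error(permanova(stats::dist(m), rep("A", 6)), "two groups")
  expect_error(permanova(stats::dist(m), factor(rep("A", 6),
                                                levels = c("A", "B"))),
               "two groups|0 samples")
})

test_that("NMDS recovers geometry, is seeded, and stress decreases with k", {
  withr::with_seed(96, pts <- matrix(rnorm(24), 12))
  d <- stats::dist(pts)
  fit <- nmds(d, k = 2, n_starts = 10, seed = 5)
  expect_lt(fit$stress, 0.01)
  expect_equal(fit$points, nmds(d, k = 2, n_starts = 10, seed = 5)$points)
  expect_true(all(abs(colMeans(fit$points)) < 1e-8))  # centred by rotation

  withr::with_seed(97, comp <- matrix(runif(60), 12))
  bc <- bray_curtis_matrix(comp)
  stresses <- vapply(1:3, function(k) {
    nmds(bc, k = k, n_starts = 10, seed = 6)$stress
  }, numeric(1))
  expect_true(all(diff(stresses) <= 1e-6))

  eq <- matrix(1, 3, 3) - diag(3)
  expect_warning(fit0 <- nmds(stats::as.dist(eq), k = 2), "degenerate")
  expect_equal(fit0$stress, 0)
  expect_error(nmds(stats::dist(matrix(rnorm(6), 3)), k = 2), "k \\+ 2")
})

test_that("pooled t-test matches hand computation and reports df = n1+n2-2", {
  res <- pooled_t_test(c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_equal(res$t, -2.449, tolerance = 1e-3)
  expect_equal(res$df, 6)
  nine <- pooled_t_test(rnorm(9), rnorm(9))
  expect_equal(nine$df, 16)
  same <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(pooled_t_test(c(1, 1, 1), c(1, 1, 1)), "constant")
  expect_error(pooled_t_test(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA has classical df and limiting behaviour", {
  same <- one_way_anova(rep(c(1, 2, 3), 3), rep(letters[1:3], each = 3))
  expect_equal(same$f, 0)
  expect_equal(c(same$df_between, same$df_within), c(2, 6))
  withr::with_seed(98, {
    y <- rnorm(300) + rep(c(0, 0, 3), each = 100)
    strong <- one_way_anova(y, rep(letters[1:3], each = 100))
    expect_lt(strong$p_value, 1e-10)
  })
})

test_that("richness regression reports standardized Wald effects", {
  withr::with_seed(99, {
    df <- tibble::tibble(
      mean_height = rnorm(30), total_biomass = rnorm(30),
      shannon = rnorm(30), community_cp = rnorm(30),
      community_ndf = rnorm(30), community_adf = rnorm(30))
    df$richness <- 5 + 3 * df$shannon + rnorm(30, sd = 0.01)
    fit <- richness_regression(df)
    td <- tidy(fit)
    expect_lt(td$p_value[td$term == "shannon"], 1e-10)
    expect_gt(glance(fit)$adj_r_squared, 0.999)
    expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
    # standardized predictors: the shannon effect is ~ 3 * sd(shannon)
    expect_equal(td$estimate[td$term == "shannon"], 3 * sd(df$shannon),
                 tolerance = 1e-2)
    df$dup <- df$shannon
    expect_error(richness_regression(df, predictors = c("shannon", "dup")),
                 "collinear")
    expect_error(richness_regression(df[1:5, ]), "more observations")
  })
})

test_that("null richness regressions reject at close to the nominal rate", {
  n_rep <- 500
  hits <- withr::with_seed(100, {
    vapply(seq_len(n_rep), function(i) {
      df <- tibble::tibble(richness = rnorm(25), mean_height = rnorm(25),
                           total_biomass = rnorm(25), shannon = rnorm(25))
      td <- tidy(richness_regression(
        df, predictors = c("mean_height", "total_biomass", "shannon")))
      td$p_value[td$term == "shannon"] < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(hits) - 0.05), 1.96 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("diet vs vegetation nutrient contrasts report direction and df", {
  withr::with_seed(101, {
    diet <- tibble::tibble(cp = rnorm(9, 14), ndf = rnorm(9, 45),
                           adf = rnorm(9, 30))
    veg <- tibble::tibble(cp = rnorm(9, 10), ndf = rnorm(9, 55),
                          adf = rnorm(9, 30))
  })
  res <- diet_vs_vegetation_nutrients(diet, veg)
  expect_equal(res$df, rep(16, 3))
  expect_equal(res$direction[res$nutrient == "cp"], "above")
  expect_equal(res$direction[res$nutrient == "ndf"], "below")
  expect_lt(res$p_value[res$nutrient == "cp"], 0.01)
  same <- diet_vs_vegetation_nutrients(diet, diet)
  expect_equal(same$t, rep(0, 3))
  expect_equal(same$p_value, rep(1, 3))
})
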