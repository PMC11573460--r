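# Comparative tests: pooled t, one-way ANOVA, nutrient contrasts, and
# standardized multiple regression of dietary richness.

#' Pooled (equal-variance) two-sample t-test
#'
#' Classical two-sample t with pooled variance, `df = n_x + n_y - 2`; two
#' groups of nine values therefore report df = 16. Welch's unequal-variance
#' version is available by flag.
#'
#' @param x,y Numeric vectors, each with at least two values.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
#' @examples
#' pooled_t_test(c(0, 0, 1, 1), c(1, 1, 2, 2))
pooled_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs at least 2 values")
  ht <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_x = mean(x), mean_y = mean(y))
}

#' One-way analysis of variance
#'
#' Classical between/within F with `(k - 1, N - k)` degrees of freedom.
#' With zero within-group variance and unequal means the F statistic is
#' infinite and p underflows to 0.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, one per value; each group needs >= 2 values.
#' @return One-row tibble: `f`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  tibble::tibble(f = unname(ht$statistic),
                 df_between = unname(ht$parameter[1]),
                 df_within = unname(ht$parameter[2]),
                 p_value = ht$p.value)
}

#' Contrast diet nutrients against vegetation nutrients
#'
#' For each nutrient, a two-sample pooled t-test of the diet-side values
#' against the vegetation-side values, reporting the direction of the
#' difference (whether the diet is above or below what the vegetation
#' offers).
#'
#' @param diet Tibble with one row per replicate and the columns named in
#'   `nutrients` (e.g. `diet_cp` renamed, or pass `prefix`es).
#' @param vegetation Tibble with the same nutrient columns on the
#'   vegetation side.
#' @param nutrients Character vector of shared column names to contrast.
#' @param var_equal Pool variances (default `TRUE`).
#' @return Tibble per nutrient: `nutrient`, `t`, `df`, `p_value`,
#'   `mean_diet`, `mean_vegetation`, `direction` (`"above"`, `"below"`, or
#'   `"equal"`).
#' @export
diet_vs_vegetation_nutrients <- function(diet, vegetation,
                                         nutrients = c("cp", "ndf", "adf"),
                                         var_equal = TRUE) {
  require_cols(diet, nutrients, "diet nutrient table")
  require_cols(vegetation, nutrients, "vegetation nutrient table")
  purrr::map_dfr(nutrients, function(nu) {
    res <- pooled_t_test(diet[[nu]], vegetation[[nu]], var_equal = var_equal)
    tibble::tibble(
      nutrient = nu, t = res$t, df = res$df, p_value = res$p_value,
      mean_diet = res$mean_x, mean_vegetation = res$mean_y,
      direction = if (res$mean_x > res$mean_y) "above"
                  else if (res$mean_x < res$mean_y) "below" else "equal"
    )
  })
}

#' Multiple regression of dietary richness on vegetation characteristics
#'
#' Ordinary least squares of a richness response on z-standardized
#' predictors, so the coefficients are comparable effect sizes across
#' predictors with different units. Each coefficient gets a Wald statistic
#' (estimate / SE), its two-sided p-value, and a 95% confidence interval;
#' the model's adjusted R-squared is reported via [glance()].
#'
#' @param data Data frame holding response and predictors.
#' @param response Name of the response column (default `"richness"`).
#' @param predictors Names of the predictor columns.
#' @param standardize Z-standardize the predictors (default `TRUE`).
#' @return Object of class `grazesel_regression` wrapping the `lm` fit;
#'   use [tidy()] for per-coefficient results and [glance()] for fit
#'   statistics.
#' @export
richness_regression <- function(data,
                                response = "richness",
                                predictors = c("mean_height", "total_biomass",
                                               "shannon", "community_cp",
                                               "community_ndf", "community_adf"),
                                standardize = TRUE) {
  require_cols(data, c(response, predictors), "regression data")
  n <- nrow(data)
  if (n <= length(predictors) + 1) {
    stop("need more observations than predictors plus intercept")
  }
  X <- as.matrix(data[predictors])
  if (any(!is.finite(X))) stop("non-finite predictor values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(predictors[sds == 0], collapse = ", "))
  }
  qrX <- qr(cbind(1, scale(X)))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- predictors[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (standardize) X <- scale(X)
  df <- data.frame(.response = data[[response]], X)
  names(df) <- c(".response", predictors)
  fit <- stats::lm(.response ~ ., data = df)
  structure(list(fit = fit, response = response, predictors = predictors,
                 standardized = standardize),
            class = "grazesel_regression")
}

#' @export
print.grazesel_regression <- function(x, ...) {
  cat(sprintf("Richness regression (%s predictors): adj. R2 = %.3f\n",
              if (x$standardized) "standardized" else "raw",
              summary(x$fit)$adj.r.squared))
  print(tidy(x))
  invisible(x)
}

#' @rdname richness_regression
#' @param x A `grazesel_regression` object.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @param ... Unused.
#' @export
tidy.grazesel_regression <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit, level = conf_level)
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    wald = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2])
  )
}

#' @rdname richness_regression
#' @export
glance.grazesel_regression <- function(x, ...) {
  sm <- summary(x$fit)
  f <- sm$fstatistic
  tibble::tibble(
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma,
    statistic = unname(f[1]),
    df = unname(f[2]),
    df_residual = unname(f[3]),
    p_value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    n = length(sm$residuals)
  )
}
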