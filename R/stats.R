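#' Normality and variance-homogeneity checks
#'
#' Kolmogorov-Smirnov test of each group against a normal distribution with
#' that group's mean and standard deviation, and Levene's test (classical,
#' mean-centred) of variance homogeneity across groups.
#'
#' @param data Data frame with one row per subject.
#' @param value Name of the numeric outcome column.
#' @param group Name of the grouping column (>= 2 groups, n >= 3 each).
#' @return Tibble with columns `test`, `group`, `statistic`, `p_value`.
#' @export
check_assumptions <- function(data, value, group = "group") {
  x <- data[[value]]; g <- factor(data[[group]])
  if (any(table(g) < 3)) abort("Each group needs at least 3 observations.")
  ks <- purrr::map_dfr(levels(g), function(lv) {
    xs <- x[g == lv]
    if (sd(xs) == 0) abort(paste0("Degenerate (constant) sample in group ", lv, "."))
    kt <- suppressWarnings(ks.test(xs, "pnorm", mean(xs), sd(xs)))
    tibble::tibble(test = "kolmogorov_smirnov", group = lv,
                   statistic = unname(kt$statistic), p_value = kt$p.value)
  })
  lv <- car::leveneTest(x ~ g, center = mean)
  dplyr::bind_rows(ks, tibble::tibble(
    test = "levene", group = "all",
    statistic = lv[1, "F value"], p_value = lv[1, "Pr(>F)"]))
}

#' Paired comparison of the affected and unaffected limbs
#'
#' Two-sided paired t-test between per-subject values of the plegic and
#' non-plegic limb, used to decide whether a bilateral parameter can be
#' pooled across sides.
#'
#' @param plegic,non_plegic Equal-length numeric vectors paired by subject.
#' @return A `gait_comparison` one-row tibble: `test_name`, `statistic`,
#'   `df`, `p_value`, `mean_diff`, `n`.
#' @export
paired_limb_test <- function(plegic, non_plegic) {
  if (length(plegic) != length(non_plegic)) {
    abort("`plegic` and `non_plegic` must have equal length (paired by subject).")
  }
  d <- plegic - non_plegic
  if (sd(d) < 1e-10 * max(abs(d), 1)) {
    # zero within-pair variance: the t statistic is degenerate
    res <- tibble::tibble(
      test_name = "paired_t",
      statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
      df = length(d) - 1,
      p_value = if (mean(d) == 0) 1 else 0,
      mean_diff = mean(d), n = length(d))
    warn("Zero within-pair variance; degenerate paired t-test flagged.")
    return(new_gait_comparison(res))
  }
  tt <- t.test(plegic, non_plegic, paired = TRUE)
  new_gait_comparison(tibble::tibble(
    test_name = "paired_t", statistic = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value,
    mean_diff = unname(tt$estimate), n = length(d)))
}

#' Independent two-group comparison with effect size
#'
#' Two-sided independent-samples t-test (pooled variance by default) with
#' Cohen's d computed on the pooled standard deviation, plus the
#' conventional qualitative band: small (d <= 0.2), moderate
#' (0.2 < d < 0.8), large (0.8 <= d < 1.3), very large (d >= 1.3).
#'
#' @param a,b Numeric samples for the two groups (n >= 2 each).
#' @param var_equal Assume equal variances (classical t-test); default TRUE.
#' @return A `gait_comparison` one-row tibble: `test_name`, `statistic`,
#'   `df`, `p_value`, `effect_size_d`, `d_band`, `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @export
independent_comparison <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) abort("Each sample needs n >= 2.")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) abort("Zero pooled variance; comparison undefined.")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  tt <- t.test(a, b, var.equal = var_equal)
  new_gait_comparison(tibble::tibble(
    test_name = if (var_equal) "independent_t" else "welch_t",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, effect_size_d = d, d_band = cohen_band(d),
    mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
    n_a = length(a), n_b = length(b)))
}

#' Qualitative Cohen's d band
#'
#' @param d Cohen's d (sign ignored).
#' @return `"small"`, `"moderate"`, `"large"` or `"very large"`.
#' @export
cohen_band <- function(d) {
  ad <- abs(d)
  dplyr::case_when(
    ad <= 0.2 ~ "small",
    ad < 0.8 ~ "moderate",
    ad < 1.3 ~ "large",
    TRUE ~ "very large")
}

new_gait_comparison <- function(tb) {
  class(tb) <- c("gait_comparison", class(tb))
  tb
}

#' Speed-adjusted group comparison (ANCOVA)
#'
#' Linear model `outcome ~ group + covariate + group:covariate` with effect
#' (sum-to-zero) coding for the group factor and marginal (Type-III-style)
#' F tests, so that the group main effect remains interpretable in the
#' presence of the interaction. For two groups the residual degrees of
#' freedom are `n - 4`. The same routine serves for confounder adjustment
#' (e.g. age or body mass as the covariate instead of walking speed).
#'
#' @param data Data frame with one row per subject, no missing values in the
#'   used columns.
#' @param outcome Name of the outcome column (e.g. `"eri_pct"`).
#' @param group Name of the group column (factor or character, 2 levels).
#' @param covariate Name of the continuous covariate column (e.g. `"ssws"`).
#' @return A `gait_ancova` object: tibble with one row per term (`group`,
#'   `covariate`, `interaction`): `f`, `df1`, `df2`, `p_value`; the fitted
#'   `lm` is attached as attribute `"model"`.
#' @export
ancova_adjusted <- function(data, outcome, group = "group", covariate = "ssws") {
  dd <- data.frame(y = data[[outcome]], g = factor(data[[group]]),
                   x = data[[covariate]])
  if (anyNA(dd)) abort("Missing values in outcome, group or covariate.")
  if (nlevels(dd$g) != 2) abort("`group` must have exactly two levels.")
  if (any(tapply(dd$x, dd$g, sd) == 0)) {
    abort("Covariate is constant within a group; model is collinear.")
  }
  contrasts(dd$g) <- "contr.sum"
  mod <- lm(y ~ g * x, data = dd)
  aov3 <- car::Anova(mod, type = 3)
  pick <- function(term) {
    i <- match(term, rownames(aov3))
    c(f = aov3[i, "F value"], p = aov3[i, "Pr(>F)"], df1 = aov3[i, "Df"])
  }
  df2 <- aov3["Residuals", "Df"]
  res <- tibble::tibble(
    term = c("group", "covariate", "interaction"),
    f = c(pick("g")["f"], pick("x")["f"], pick("g:x")["f"]),
    df1 = c(pick("g")["df1"], pick("x")["df1"], pick("g:x")["df1"]),
    df2 = df2,
    p_value = c(pick("g")["p"], pick("x")["p"], pick("g:x")["p"]))
  attr(res, "model") <- mod
  attr(res, "outcome") <- outcome
  attr(res, "covariate") <- covariate
  class(res) <- c("gait_ancova", class(res))
  res
}

#' Pearson correlation between two subject-level variables
#'
#' @param data Data frame with one row per subject.
#' @param x,y Names of the two numeric columns (n >= 3 complete pairs,
#'   non-constant).
#' @return One-row tibble: `pair`, `r`, `p_value`, `n`.
#' @export
correlate_pair <- function(data, x, y) {
  xv <- data[[x]]; yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("Need at least 3 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) abort("Zero variance; correlation undefined.")
  ct <- cor.test(xv, yv, method = "pearson")
  tibble::tibble(pair = paste(x, "vs", y), r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(xv))
}
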