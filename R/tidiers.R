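#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group comparison
#'
#' @param x A `gait_comparison` from [independent_comparison()] or
#'   [paired_limb_test()].
#' @param ... Unused.
#' @return A one-row tibble of test results.
#' @export
tidy.gait_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a speed-adjusted ANCOVA
#'
#' @param x A `gait_ancova` from [ancova_adjusted()].
#' @param ... Unused.
#' @return Tibble with one row per model term (`group`, `covariate`,
#'   `interaction`): `f`, `df1`, `df2`, `p_value`.
#' @export
tidy.gait_ancova <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  attr(out, "model") <- NULL
  out
}

#' One-line model summary of a speed-adjusted ANCOVA
#'
#' @param x A `gait_ancova` from [ancova_adjusted()].
#' @param ... Unused.
#' @return One-row tibble: `outcome`, `covariate`, `r_squared`,
#'   `adj_r_squared`, `sigma`, `df_residual`, `n`.
#' @export
glance.gait_ancova <- function(x, ...) {
  mod <- attr(x, "model")
  sm <- summary(mod)
  tibble::tibble(
    outcome = attr(x, "outcome"), covariate = attr(x, "covariate"),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma, df_residual = mod$df.residual,
    n = length(mod$residuals))
}

#' @export
print.gait_ancova <- function(x, ...) {
  cat(sprintf("<gait_ancova> %s ~ group * %s (type-III F tests)\n",
              attr(x, "outcome") %||% "outcome",
              attr(x, "covariate") %||% "covariate"))
  print(tidy(x))
  invisible(x)
}
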