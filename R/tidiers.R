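# broom-style tidiers for the package's fitted objects.

#' Tidy a sides-by-units ANOVA
#'
#' @param x A [sides_anova()] object.
#' @param ... Unused.
#' @return The term-level tibble (`term`, `df`, `sumsq`, `meansq`).
#' @export
tidy.sides_anova <- function(x, ...) x$table

#' @rdname tidy.sides_anova
#' @return For `glance()`: a one-row tibble with the mean squares, the
#'   directional-asymmetry F test and the measurement-error F test.
#' @export
glance.sides_anova <- function(x, ...) {
  tibble::tibble(
    n_units = x$n_units, m = x$m,
    ms_s = x$ms_s, ms_si = x$ms_si, ms_m = x$ms_m,
    f_da = x$f_da, p_da = x$p_da, f_me = x$f_me, p_me = x$p_me
  )
}

#' Tidy ANCOVA-adjusted means
#'
#' @param x An [adjusted_means()] object.
#' @param ... Unused.
#' @return The per-level tibble of adjusted and raw means.
#' @export
tidy.adjusted_means <- function(x, ...) x$means

#' @rdname tidy.adjusted_means
#' @export
glance.adjusted_means <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, transform = x$transform,
    covariate = x$covariate %||% NA_character_,
    covariate_coef = x$covariate_coef,
    residual_ms = x$residual_ms, df_residual = x$df_residual
  )
}

#' Tidy a factorial ANCOVA
#'
#' @param x A [ancova()] object.
#' @param ... Unused.
#' @return The term table including the residual row.
#' @export
tidy.phenostab_ancova <- function(x, ...) x$table

#' @rdname tidy.phenostab_ancova
#' @export
glance.phenostab_ancova <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    response = x$response, ss_type = x$ss_type, transform = x$transform,
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma, n = x$n
  )
}

#' Tidy a slope comparison
#'
#' @param x A [slope_difference_test()] object.
#' @param ... Unused.
#' @return The per-group slope tibble.
#' @export
tidy.slope_comparison <- function(x, ...) x$slopes

#' @rdname tidy.slope_comparison
#' @export
glance.slope_comparison <- function(x, ...) {
  obj <- unclass(x)
  tibble::tibble(
    x = obj$x, y = obj$y, slope_diff = obj$slope_diff,
    statistic = obj$statistic, df = obj$df, p_value = obj$p_value
  )
}
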