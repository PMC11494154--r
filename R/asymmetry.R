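#' Summarise replicate leaf measurements to one row per leaf
#'
#' Averages the `M` replicate caliper readings per side and derives, for each
#' leaf, the side means, the signed and absolute side difference and the leaf
#' size `(R + L)/2`. Leaves missing a side, or whose sides carry unequal
#' replicate counts, are excluded with a message (their count is also stored
#' in the `n_excluded` attribute).
#'
#' @param leaves Leaf table with columns `individual_id`, `leaf`, `side`
#'   (`"left"`/`"right"`), `replicate`, `width`.
#' @return A tibble of class `leaf_summary`, one row per leaf, with columns
#'   `individual_id`, `leaf`, `r_bar`, `l_bar`, `signed_diff`, `abs_diff`
#'   and `leaf_size` (all in mm).
#' @examples
#' lv <- simulate_leaf_pair(c(10, 11), asymmetry_model())
#' lv$individual_id <- "a"
#' summarize_leaves(lv)
#' @export
summarize_leaves <- function(leaves) {
  check_columns(leaves, c("individual_id", "leaf", "side", "replicate", "width"),
                "`leaves`")
  bad_side <- setdiff(unique(leaves$side), c("left", "right"))
  if (length(bad_side) > 0) {
    abort(sprintf("`side` must be \"left\"/\"right\"; found: %s.",
                  paste(bad_side, collapse = ", ")))
  }
  side_means <- leaves |>
    dplyr::group_by(.data$individual_id, .data$leaf, .data$side) |>
    dplyr::summarise(m = mean(.data$width), n_rep = dplyr::n(),
                     .groups = "drop")
  wide <- side_means |>
    tidyr::pivot_wider(names_from = "side", values_from = c("m", "n_rep"))
  for (col in c("m_left", "m_right", "n_rep_left", "n_rep_right")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  complete <- !is.na(wide$m_left) & !is.na(wide$m_right) &
    wide$n_rep_left == wide$n_rep_right
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    inform(sprintf(
      "Excluding %d incomplete leaf/leaves (missing side or unequal replicate counts).",
      n_excluded
    ))
  }
  out <- wide[complete, ] |>
    dplyr::transmute(
      .data$individual_id, .data$leaf,
      r_bar = .data$m_right, l_bar = .data$m_left,
      signed_diff = .data$m_right - .data$m_left,
      abs_diff = abs(.data$m_right - .data$m_left),
      leaf_size = (.data$m_right + .data$m_left) / 2
    )
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("leaf_summary", class(out))
  out
}

#' Fluctuating asymmetry index FA1
#'
#' Mean absolute side difference, `sum(|R - L|) / n`, in mm. Under normally
#' distributed signed differences with no measurement error this converges
#' to `0.798 * sd(R - L)` (the half-normal mean).
#'
#' @param leaves A [summarize_leaves()] table (needs column `abs_diff`).
#' @return A single numeric value (mm).
#' @export
fa1 <- function(leaves) {
  check_columns(leaves, "abs_diff", "`leaves`")
  if (nrow(leaves) == 0) abort("FA1 needs at least one leaf.")
  mean(leaves$abs_diff)
}

#' Fluctuating asymmetry index FA2
#'
#' Size-standardised mean asymmetry, `sum(|R - L| / LS) / n` (dimensionless,
#' invariant to rescaling all widths). The absolute value is the default;
#' `signed = TRUE` averages the signed ratios instead (near zero for ideal
#' fluctuating asymmetry).
#'
#' @param leaves A [summarize_leaves()] table.
#' @param signed Average signed rather than absolute ratios.
#' @return A single numeric value.
#' @export
fa2 <- function(leaves, signed = FALSE) {
  check_columns(leaves, c("abs_diff", "signed_diff", "leaf_size"), "`leaves`")
  if (nrow(leaves) == 0) abort("FA2 needs at least one leaf.")
  if (any(leaves$leaf_size <= 0)) {
    abort("FA2 requires positive leaf sizes for every leaf.")
  }
  num <- if (signed) leaves$signed_diff else leaves$abs_diff
  mean(num / leaves$leaf_size)
}

#' Sides-by-units factorial ANOVA on replicate measurements
#'
#' Fits the balanced two-way factorial (side with 2 levels crossed with
#' measured leaf as the unit, `M` replicate readings per cell) on the raw,
#' untransformed widths, by direct sums-of-squares decomposition. The
#' resulting mean squares drive the FA10 index ([fa10()]) and two
#' diagnostics: `F_da = MS_s / MS_si` tests directional asymmetry (a side
#' effect beyond leaf-to-leaf asymmetry) and `F_me = MS_si / MS_m` checks
#' that the between-sides variation exceeds measurement error.
#'
#' @param leaves Leaf table with columns `individual_id`, `leaf`, `side`,
#'   `replicate`, `width`, for a single analysis group (one individual, or a
#'   pooled species x treatment cell).
#' @return An object of class `sides_anova`: mean squares (`ms_s`, `ms_si`,
#'   `ms_m`), degrees of freedom, the replicate count `m`, unit count
#'   `n_units`, the two F statistics with p-values, and the full SS table
#'   (including the unit main effect) retrievable via [tidy()].
#' @examples
#' lv <- simulate_leaf_pair(runif(20, 9, 11), asymmetry_model(sigma_fa = 1))
#' lv$individual_id <- "a"
#' sides_anova(lv)
#' @export
sides_anova <- function(leaves) {
  check_columns(leaves, c("individual_id", "leaf", "side", "replicate", "width"),
                "`leaves`")
  unit <- paste(leaves$individual_id, leaves$leaf, sep = ".")
  counts <- table(unit, leaves$side)
  if (ncol(counts) != 2) abort("Both sides are required for the sides ANOVA.")
  m <- unique(as.vector(counts))
  if (length(m) != 1) {
    off <- rownames(counts)[apply(counts, 1, function(r) length(unique(r)) > 1 ||
                                    r[1] != as.vector(counts)[1])]
    abort(sprintf("Unbalanced replicate measurements for leaf unit(s): %s.",
                  paste(head(off, 5), collapse = ", ")))
  }
  if (m < 2) abort("At least 2 replicate measurements per side are required (M >= 2).")
  n_units <- nrow(counts)
  if (n_units < 2) abort("At least 2 leaf units are required.")

  grand <- mean(leaves$width)
  w <- leaves$width - grand # centred for numerical stability
  cm <- tapply(w, list(unit, leaves$side), mean) # n_units x 2 cell means
  side_means <- colMeans(cm)
  unit_means <- rowMeans(cm)

  ss_s <- n_units * m * sum(side_means^2)
  ss_u <- 2 * m * sum(unit_means^2)
  inter_dev <- cm - outer(unit_means, side_means, "+")
  ss_si <- m * sum(inter_dev^2)
  ss_m <- sum(w^2) - m * sum(cm^2) # within-cell (replicate) SS, balanced

  df_s <- 1L
  df_u <- n_units - 1L
  df_si <- n_units - 1L
  df_m <- 2L * n_units * (m - 1L)

  ms_s <- ss_s / df_s
  ms_u <- ss_u / df_u
  ms_si <- ss_si / df_si
  ms_m <- ss_m / df_m

  f_da <- if (ms_si > 0) ms_s / ms_si else ifelse(ms_s > 0, Inf, NaN)
  p_da <- if (is.finite(f_da)) pf(f_da, df_s, df_si, lower.tail = FALSE) else
    ifelse(is.nan(f_da), NA_real_, 0)
  f_me <- if (ms_m > 0) ms_si / ms_m else ifelse(ms_si > 0, Inf, NaN)
  p_me <- if (is.finite(f_me)) pf(f_me, df_si, df_m, lower.tail = FALSE) else
    ifelse(is.nan(f_me), NA_real_, 0)

  structure(
    list(
      table = tibble::tibble(
        term = c("side", "units", "side:units", "measurement"),
        df = c(df_s, df_u, df_si, df_m),
        sumsq = c(ss_s, ss_u, ss_si, ss_m),
        meansq = c(ms_s, ms_u, ms_si, ms_m)
      ),
      ms_s = ms_s, ms_si = ms_si, ms_m = ms_m,
      df_s = df_s, df_si = df_si, df_m = df_m,
      m = m, n_units = n_units, grand_mean = grand,
      f_da = f_da, p_da = p_da, f_me = f_me, p_me = p_me
    ),
    class = "sides_anova"
  )
}

#' @export
print.sides_anova <- function(x, ...) {
  cat(sprintf("Sides x units factorial ANOVA (%d units, M = %d)\n",
              x$n_units, x$m))
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("F_da (side / side:units) = %.4g, p = %.4g\n", x$f_da, x$p_da))
  cat(sprintf("F_me (side:units / measurement) = %.4g, p = %.4g\n",
              x$f_me, x$p_me))
  invisible(x)
}

#' Fluctuating asymmetry index FA10 (measurement-error corrected)
#'
#' Variance-component FA index from a [sides_anova()]. The side-by-unit
#' interaction variance component is `s^2 = (MS_si - MS_m) / M`; since the
#' variance of the signed difference `R - L` equals `2 * s^2`, the default
#' `"between_sides"` variant returns `0.798 * sqrt(2 * s^2)`, the
#' measurement-error-free counterpart of FA1 under normality. The
#' `"component"` variant returns `0.798 * sqrt(s^2)`, i.e. the interaction
#' component itself on the half-normal scale. A negative `s^2` estimate
#' (measurement error exceeding between-sides variation) is clamped to zero
#' and flagged.
#'
#' @param anova A [sides_anova()] result.
#' @param variant `"between_sides"` (default) or `"component"`; see Details.
#' @return One-row tibble with columns `fa10` (mm), `s2`, `negative_s2`,
#'   `n_units`, `m`, `variant`.
#' @examples
#' lv <- simulate_leaf_pair(runif(100, 9, 11),
#'                          asymmetry_model(sigma_fa = 1, sigma_me = 0.3))
#' lv$individual_id <- "a"
#' fa10(sides_anova(lv))
#' @export
fa10 <- function(anova, variant = c("between_sides", "component")) {
  stopifnot(inherits(anova, "sides_anova"))
  variant <- match.arg(variant)
  s2 <- (anova$ms_si - anova$ms_m) / anova$m
  negative <- s2 < 0
  variance <- max(s2, 0) * if (variant == "between_sides") 2 else 1
  tibble::tibble(
    fa10 = 0.798 * sqrt(variance),
    s2 = s2,
    negative_s2 = negative,
    n_units = anova$n_units,
    m = anova$m,
    variant = variant
  )
}

#' Distributional diagnostics for signed leaf asymmetry
#'
#' The assumption battery for fluctuating-asymmetry analyses: bias-corrected
#' skewness (`gamma1`) and excess kurtosis (`gamma2`) of the signed side
#' differences with normal-theory z tests (a significantly *negative*
#' `gamma2` suggests antisymmetry, i.e. a bimodal left-or-right-larger
#' pattern), a one-sample t test of `R - L` against zero for directional
#' asymmetry, and the regression of `|R - L|` on leaf size for
#' size-dependence. Standard errors for the moment tests use the exact
#' normal-theory formulas (close to `sqrt(6/n)` and `sqrt(24/n)` for large
#' `n`). With fewer than 4 leaves the moments are reported but all tests are
#' `NA`.
#'
#' @param leaves A [summarize_leaves()] table.
#' @return One-row tibble with `n`, `gamma1`, `p_gamma1`, `gamma2`,
#'   `p_gamma2`, `t_da`, `p_da`, `slope_sizedep`, `p_sizedep` and a
#'   `classification` string (`"ok"`, `"antisymmetry_suspected"` or
#'   `"directional_asymmetry_suspected"`, at the 0.05 level).
#' @export
asymmetry_diagnostics <- function(leaves) {
  check_columns(leaves, c("signed_diff", "abs_diff", "leaf_size"), "`leaves`")
  d <- leaves$signed_diff
  n <- length(d)
  if (n < 2) abort("Diagnostics need at least 2 leaves.")
  g1 <- sample_skewness(d)
  g2 <- sample_kurtosis(d)
  if (n >= 4 && sd(d) > 0) {
    p_g1 <- 2 * pnorm(-abs(g1 / se_skewness(n)))
    p_g2 <- 2 * pnorm(-abs(g2 / se_kurtosis(n)))
    tt <- t.test(d)
    t_da <- unname(tt$statistic)
    p_da <- tt$p.value
  } else {
    p_g1 <- p_g2 <- t_da <- p_da <- NA_real_
  }
  if (n >= 3 && var(leaves$leaf_size) > 0) {
    sdep <- size_dependence(leaves)
    slope <- sdep$slope
    p_slope <- sdep$p_value
  } else {
    slope <- p_slope <- NA_real_
  }
  classification <- if (!is.na(p_g2) && p_g2 < 0.05 && g2 < 0) {
    "antisymmetry_suspected"
  } else if (!is.na(p_da) && p_da < 0.05) {
    "directional_asymmetry_suspected"
  } else {
    "ok"
  }
  tibble::tibble(
    n = n, gamma1 = g1, p_gamma1 = p_g1, gamma2 = g2, p_gamma2 = p_g2,
    t_da = t_da, p_da = p_da,
    slope_sizedep = slope, p_sizedep = p_slope,
    classification = classification
  )
}

#' Size-dependence of leaf asymmetry
#'
#' Ordinary least-squares regression of the absolute side difference on leaf
#' size, with the usual t test of the slope. A significant positive slope
#' indicates that asymmetry scales with leaf size (in which case the
#' size-standardised FA2 is the more comparable index).
#'
#' @param leaves A [summarize_leaves()] table.
#' @return One-row tibble with `slope`, `intercept`, `p_value`, `r_squared`,
#'   `n`.
#' @export
size_dependence <- function(leaves) {
  check_columns(leaves, c("abs_diff", "leaf_size"), "`leaves`")
  n <- nrow(leaves)
  if (n < 3) abort("Size-dependence regression needs at least 3 leaves.")
  if (var(leaves$leaf_size) == 0) {
    abort("Leaf sizes are all equal; the size-dependence slope is undefined.")
  }
  fit <- lm(abs_diff ~ leaf_size, data = leaves)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p_value = sm$coefficients["leaf_size", "Pr(>|t|)"],
    r_squared = sm$r.squared,
    n = n
  )
}

#' Per-cell fluctuating-asymmetry table
#'
#' Computes FA1, FA2 and FA10 per individual (each plant's leaves serve as
#' the ANOVA units for its FA10) and aggregates them to mean +/- SE per
#' grouping cell, alongside a pooled-cell FA10 computed from all of the
#' cell's leaves at once. Individuals with a single complete leaf
#' contribute to FA1/FA2 but not FA10.
#'
#' @param leaves Raw leaf table.
#' @param individuals Individual table (provides the grouping columns).
#' @param by Grouping columns, default `c("species", "early", "late")`.
#' @param fa10_variant Passed to [fa10()].
#' @return A tibble of class `phenostab_fa`, one row per cell, with
#'   `n_individuals`, mean and SE columns for each index, the pooled-cell
#'   `fa10_pooled` and the count of negative variance-component estimates.
#' @export
fa_table <- function(leaves, individuals, by = c("species", "early", "late"),
                     fa10_variant = "between_sides") {
  check_columns(individuals, c("individual_id", by), "`individuals`")
  summ <- if (inherits(leaves, "leaf_summary")) leaves else summarize_leaves(leaves)
  raw <- leaves
  meta <- dplyr::distinct(individuals[, c("individual_id", by)])

  per_ind <- summ |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      n_leaves = dplyr::n(),
      fa1 = mean(.data$abs_diff),
      fa2 = mean(.data$abs_diff / .data$leaf_size),
      .groups = "drop"
    )
  # per-individual FA10: needs >= 2 leaves with replicated readings
  fa10_ind <- raw |>
    dplyr::semi_join(
      per_ind[per_ind$n_leaves >= 2, "individual_id"], by = "individual_id"
    ) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(~ fa10(sides_anova(dplyr::mutate(.x, individual_id = .y$individual_id)),
                               variant = fa10_variant)) |>
    dplyr::ungroup() |>
    dplyr::select("individual_id", "fa10", "negative_s2")

  per_ind <- per_ind |>
    dplyr::left_join(fa10_ind, by = "individual_id") |>
    dplyr::inner_join(meta, by = "individual_id")

  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  }
  cell <- per_ind |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      fa1_mean = mean(.data$fa1), fa1_se = se(.data$fa1),
      fa2_mean = mean(.data$fa2), fa2_se = se(.data$fa2),
      fa10_mean = mean(.data$fa10, na.rm = TRUE), fa10_se = se(.data$fa10),
      n_negative_s2 = sum(.data$negative_s2, na.rm = TRUE),
      .groups = "drop"
    )
  pooled <- raw |>
    dplyr::inner_join(meta, by = "individual_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ fa10(sides_anova(.x), variant = fa10_variant)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(by), fa10_pooled = "fa10")
  out <- dplyr::left_join(cell, pooled, by = by)
  class(out) <- c("phenostab_fa", class(out))
  out
}

#' Per-cell asymmetry diagnostics table
#'
#' Runs [asymmetry_diagnostics()] on the pooled leaves of each grouping
#' cell, mirroring the per-treatment assumption checks that accompany FA
#' analyses.
#'
#' @inheritParams fa_table
#' @return A tibble with one diagnostics row per cell.
#' @export
diagnostics_table <- function(leaves, individuals,
                              by = c("species", "early", "late")) {
  check_columns(individuals, c("individual_id", by), "`individuals`")
  summ <- if (inherits(leaves, "leaf_summary")) leaves else summarize_leaves(leaves)
  meta <- dplyr::distinct(individuals[, c("individual_id", by)])
  summ |>
    dplyr::inner_join(meta, by = "individual_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ asymmetry_diagnostics(.x)) |>
    dplyr::ungroup()
}
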