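#' ANCOVA-adjusted treatment means
#'
#' Fits `trait ~ factor + covariate` (no interaction) and evaluates each
#' factor level's prediction at the grand mean of the covariate -- the
#' covariate-adjusted means used for plasticity indices and LSD
#' comparisons. With `transform = "log"` (the default used by
#' [plasticity_table()]) the model is fitted on the natural-log trait. If
#' the covariate is constant (or absent) the adjusted means reduce to the
#' raw group means; a constant covariate triggers a warning and a
#' covariate-free fit.
#'
#' @param data Individual-level table.
#' @param trait Column name (string) of the response.
#' @param factor Column name (string) of the grouping factor.
#' @param covariate Column name (string) of the covariate, or `NULL`.
#' @param transform `"identity"` or `"log"` (natural log; requires positive
#'   trait values).
#' @return An object of class `adjusted_means`: tibble of `level`,
#'   `adjusted_mean`, `raw_mean`, `n`, plus the covariate coefficient,
#'   residual mean square and df, and the transform label. [tidy()] returns
#'   the per-level table, [glance()] the fit summary.
#' @examples
#' ex <- generate_experiment(design_config(seed = 1), include_leaves = FALSE)
#' one <- subset(ex$individuals, species == "S1" & early == "E_hom" &
#'                 late != "first_harvest")
#' adjusted_means(one, "total_mass", "late", "initial_size")
#' @export
adjusted_means <- function(data, trait, factor, covariate = NULL,
                           transform = c("identity", "log")) {
  transform <- match.arg(transform)
  check_columns(data, c(trait, factor, covariate), "`data`")
  data <- data[!is.na(data[[trait]]) & !is.na(data[[factor]]), , drop = FALSE]
  y <- data[[trait]]
  if (transform == "log") {
    if (any(y <= 0)) {
      abort(sprintf("log transform requires positive `%s` values.", trait))
    }
    y <- log(y)
  }
  f <- droplevels(as.factor(data[[factor]]))
  if (nlevels(f) < 2) abort("`factor` needs at least 2 levels with data.")
  if (any(table(f) < 2)) {
    warn("Some factor levels have fewer than 2 individuals; their adjusted means are unstable.")
  }

  use_cov <- !is.null(covariate)
  if (use_cov) {
    z <- data[[covariate]]
    if (any(is.na(z))) abort(sprintf("`%s` contains missing values.", covariate))
    if (var(z) == 0) {
      warn(sprintf("Covariate `%s` is constant; falling back to raw means.",
                   covariate))
      use_cov <- FALSE
    }
  }

  df_fit <- data.frame(y = y, f = f)
  if (use_cov) {
    df_fit$z <- z
    fit <- lm(y ~ f + z, data = df_fit)
    zbar <- mean(z)
    newdata <- data.frame(f = levels(f), z = zbar)
    cov_coef <- unname(coef(fit)["z"])
  } else {
    fit <- lm(y ~ f, data = df_fit)
    newdata <- data.frame(f = levels(f))
    cov_coef <- NA_real_
    zbar <- NA_real_
  }
  adj <- predict(fit, newdata = newdata)
  raw <- tapply(y, f, mean)

  structure(
    list(
      means = tibble::tibble(
        level = levels(f),
        adjusted_mean = unname(adj),
        raw_mean = as.vector(raw[levels(f)]),
        n = as.integer(table(f)[levels(f)])
      ),
      trait = trait, factor = factor,
      covariate = if (use_cov) covariate else NULL,
      covariate_coef = cov_coef,
      covariate_grand_mean = zbar,
      residual_ms = sum(resid(fit)^2) / fit$df.residual,
      df_residual = fit$df.residual,
      transform = transform,
      fit = fit
    ),
    class = "adjusted_means"
  )
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat(sprintf("Adjusted means of %s%s by %s%s\n",
              if (x$transform == "log") "log " else "", x$trait, x$factor,
              if (!is.null(x$covariate))
                sprintf(" (covariate %s at grand mean %.4g)",
                        x$covariate, x$covariate_grand_mean) else ""))
  print(as.data.frame(x$means), row.names = FALSE)
  invisible(x)
}

#' Plasticity indices from a pair of adjusted means
#'
#' `variant = "ratio"`: `pi_rel = (y2 - y1) / y1`, the signed relative
#' change from the reference environment (`y1`, typically moderate water)
#' to the alternative (`y2`); requires `y1 > 0`. `variant = "srdpi"`: the
#' simplified relative distance form `(y2 - y1) / (y2 + y1)`, bounded in
#' (-1, 1) for positive traits; requires `y1 + y2 != 0`. `pi_abs` is the
#' absolute value of `pi_rel` in either variant.
#'
#' @param y1 Adjusted mean in the reference environment (vectorised).
#' @param y2 Adjusted mean in the alternative environment.
#' @param variant `"ratio"` or `"srdpi"`.
#' @return Tibble with `y1`, `y2`, `pi_rel`, `pi_abs`, `variant`.
#' @examples
#' compute_pi(2, 3) # pi_rel 0.5
#' compute_pi(1, 3, variant = "srdpi") # 0.5
#' @export
compute_pi <- function(y1, y2, variant = c("ratio", "srdpi")) {
  variant <- match.arg(variant)
  if (length(y1) != length(y2)) abort("`y1` and `y2` must have equal length.")
  if (variant == "ratio") {
    if (any(y1 <= 0)) {
      abort("ratio variant requires y1 > 0 (reference adjusted mean).")
    }
    pi_rel <- (y2 - y1) / y1
  } else {
    if (any(y1 + y2 == 0)) {
      abort("srdpi variant requires y1 + y2 != 0.")
    }
    pi_rel <- (y2 - y1) / (y2 + y1)
  }
  tibble::tibble(y1 = y1, y2 = y2, pi_rel = pi_rel, pi_abs = abs(pi_rel),
                 variant = variant)
}

#' Plasticity table for a two-round experiment
#'
#' For every species x early-treatment x trait combination, computes the
#' covariate-adjusted mean of the trait in each late water treatment
#' ([adjusted_means()], initial size as covariate, log scale by default) and
#' derives the plasticity indices for the two contrasts: `IM` (inundation vs
#' moderate) and `DM` (drought vs moderate). With `transform = "log"` the
#' adjusted means are back-transformed (geometric adjusted means) before the
#' index is formed, so a pure multiplicative treatment effect `r` yields
#' `pi_rel = r - 1` under the ratio variant. Cells missing a late treatment
#' (or with a single survivor) skip the affected contrast with a warning.
#'
#' @param individuals Individual table (survivors of the second round).
#' @param traits Character vector of trait columns.
#' @param variant Passed to [compute_pi()].
#' @param transform Passed to [adjusted_means()].
#' @param covariate Covariate column, default `"initial_size"`.
#' @param reference,inundation,drought Late-treatment labels.
#' @return A tibble of class `phenostab_pi`: `species`, `early`, `trait`,
#'   `contrast` (`"IM"`/`"DM"`), `y1`, `y2`, `pi_rel`, `pi_abs`, `variant`.
#' @export
plasticity_table <- function(individuals,
                             traits = c("shoot_mass", "root_mass",
                                        "total_mass", "rs_ratio"),
                             variant = c("ratio", "srdpi"),
                             transform = c("log", "identity"),
                             covariate = "initial_size",
                             reference = "moderate",
                             inundation = "inundation",
                             drought = "drought") {
  variant <- match.arg(variant)
  transform <- match.arg(transform)
  check_columns(individuals, c("species", "early", "late", traits, covariate),
                "`individuals`")
  second <- individuals |>
    dplyr::filter(.data$late %in% c(reference, inundation, drought))
  if (nrow(second) == 0) abort("No second-round (late-treatment) individuals found.")

  cells <- tidyr::expand_grid(
    species = unique(second$species),
    early = unique(second$early),
    trait = traits
  )
  skipped <- 0L
  rows <- purrr::pmap(cells, function(species, early, trait) {
    sub <- second[second$species == species & second$early == early, ,
                  drop = FALSE]
    counts <- table(factor(sub$late, levels = c(reference, inundation, drought)))
    if (counts[reference] < 2) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    usable <- names(counts)[counts >= 2]
    am <- adjusted_means(sub[sub$late %in% usable, , drop = FALSE],
                         trait, "late", covariate, transform = transform)
    vals <- setNames(am$means$adjusted_mean, am$means$level)
    if (transform == "log") vals <- exp(vals)
    out <- list()
    for (ct in c("IM", "DM")) {
      alt <- if (ct == "IM") inundation else drought
      if (!alt %in% names(vals)) {
        skipped <<- skipped + 1L
        next
      }
      out[[ct]] <- dplyr::bind_cols(
        tibble::tibble(species = species, early = early, trait = trait,
                       contrast = ct),
        compute_pi(unname(vals[reference]), unname(vals[alt]),
                   variant = variant)
      )
    }
    dplyr::bind_rows(out)
  })
  if (skipped > 0) {
    warn(sprintf("Skipped %d contrast(s) with missing or undersized late-treatment cells.",
                 skipped))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phenostab_pi", class(out))
  out
}
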