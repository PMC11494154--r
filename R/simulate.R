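#' Simulate replicate width measurements for leaf pairs
#'
#' Draws, for each element of `true_size`, one leaf with a latent signed
#' side difference from an [asymmetry_model()] and `m` replicate caliper
#' readings per side. Side widths are `true_size + d/2` (right) and
#' `true_size - d/2` (left), so the leaf size `(R + L)/2` equals `true_size`
#' exactly before measurement error. Leaves whose readings or latent side
#' widths are non-positive are redrawn wholesale (rather than truncated),
#' so the distribution of `d` is not biased for realistic parameter values.
#'
#' @param true_size Positive numeric vector of latent leaf sizes (mm), one
#'   per leaf.
#' @param asym An [asymmetry_model()].
#' @param m Replicate readings per side (>= 1; the sides ANOVA needs >= 2).
#' @return A tibble with columns `leaf`, `side` (`"left"`/`"right"`),
#'   `replicate` and `width` (mm), `2 * m` rows per leaf.
#' @examples
#' simulate_leaf_pair(c(10, 12), asymmetry_model(sigma_fa = 0.5), m = 2)
#' @export
simulate_leaf_pair <- function(true_size, asym = asymmetry_model(), m = 2) {
  stopifnot(inherits(asym, "asymmetry_model"))
  if (any(!is.finite(true_size)) || any(true_size <= 0)) {
    abort("`true_size` must be positive and finite.")
  }
  check_scalar(m, "m", lower = 1, integer = TRUE)
  n <- length(true_size)

  draw <- function(size) {
    k <- length(size)
    sd_d <- asym$sigma_fa + asym$size_slope * size
    d <- rnorm(k, asym$da_offset, sd_d)
    if (asym$antisym_delta > 0) {
      d <- d + sample(c(-1, 1), k, replace = TRUE) * asym$antisym_delta
    }
    right <- size + d / 2
    left <- size - d / 2
    # readings: k x 2m matrix, right replicates then left replicates
    err <- if (asym$sigma_me > 0) {
      matrix(rnorm(k * 2 * m, 0, asym$sigma_me), nrow = k)
    } else {
      matrix(0, nrow = k, ncol = 2 * m)
    }
    w <- cbind(
      matrix(rep(right, m), nrow = k),
      matrix(rep(left, m), nrow = k)
    ) + err
    list(w = w, ok = right > 0 & left > 0 &
           matrixStats_rowMins(w) > 0)
  }

  res <- draw(true_size)
  w <- res$w
  bad <- which(!res$ok)
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > 1000) {
      abort("Could not draw positive widths; check `sigma_me`/`sigma_fa` against `true_size`.")
    }
    redo <- draw(true_size[bad])
    w[bad[redo$ok], ] <- redo$w[redo$ok, , drop = FALSE]
    bad <- bad[!redo$ok]
  }

  tibble::tibble(
    leaf = rep(seq_len(n), each = 2 * m),
    side = rep(rep(c("right", "left"), each = m), times = n),
    replicate = rep(rep(seq_len(m), times = 2), times = n),
    width = as.vector(t(w))
  )
}

# base-only row minimum (avoids a matrixStats dependency)
matrixStats_rowMins <- function(m) do.call(pmin, asplit(m, 2))

#' Generate a synthetic split-plot experiment
#'
#' Builds the individual-trait table and the leaf-measurement table for the
#' configured two-round design. All randomness flows from `seed` (taken from
#' the design by default), so identical configurations reproduce identical
#' tables. Mortality is *not* applied here; see [apply_mortality()] or the
#' one-call wrapper [simulate_experiment()].
#'
#' @param design A [design_config()].
#' @param asym An [asymmetry_model()].
#' @param traits A [trait_model()]; defaults to baselines for the design's
#'   species.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param include_leaves Generate the leaf table? Set `FALSE` for mass-trait
#'   studies that do not need leaf measurements (much faster).
#' @return A list of class `phenostab_experiment` with elements
#'   `individuals` (one row per plant: `individual_id`, `species`,
#'   `nativity`, `habitat`, `early`, `late`, `initial_size`, `shoot_mass`,
#'   `root_mass`, `total_mass`, `rs_ratio`, `alive`) and `leaves` (one row
#'   per plant x leaf x side x replicate: `individual_id`, `leaf`, `side`,
#'   `replicate`, `width`).
#' @examples
#' ex <- generate_experiment(design_config(seed = 42))
#' nrow(ex$individuals) # 800
#' @export
generate_experiment <- function(design = design_config(),
                                asym = asymmetry_model(),
                                traits = trait_model(design$species),
                                seed = design$seed,
                                include_leaves = TRUE) {
  stopifnot(inherits(design, "design_config"), inherits(asym, "asymmetry_model"),
            inherits(traits, "trait_model"))
  missing_base <- setdiff(design$species, traits$baseline$species)
  if (length(missing_base) > 0) {
    abort(sprintf("`traits$baseline` lacks species: %s.",
                  paste(missing_base, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)

  late_block <- c(
    rep(design$late, each = design$reps_late),
    rep("first_harvest", design$reps_first_harvest)
  )
  individuals <- tidyr::expand_grid(
    species = design$species,
    early = design$early,
    late = late_block
  )
  individuals <- individuals |>
    dplyr::group_by(.data$species, .data$early) |>
    dplyr::mutate(individual_id = sprintf("%s_%s_%03d", .data$species,
                                          .data$early, dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::left_join(design$species_attrs, by = "species") |>
    dplyr::select("individual_id", "species", "nativity", "habitat",
                  "early", "late")
  n <- nrow(individuals)

  # multipliers: missing cells fall back to 1
  mult <- individuals |>
    dplyr::left_join(traits$multipliers, by = c("early", "late")) |>
    dplyr::mutate(dplyr::across(c("leaf_size", "shoot_mass", "root_mass"),
                                ~ dplyr::coalesce(.x, 1)))
  base <- individuals |>
    dplyr::left_join(traits$baseline, by = "species")

  sl_is <- sdlog_for_cv(traits$initial_size_cv)
  meanlog_is <- log(traits$initial_size_mean) - sl_is^2 / 2
  initial_size <- rlnorm(n, meanlog_is, sl_is)
  z_is <- log(initial_size) - meanlog_is

  sl <- sdlog_for_cv(traits$cv_inter)
  beta <- traits$initial_size_effect
  gen_trait <- function(baseline, multiplier) {
    exp(log(baseline * multiplier) + beta * z_is +
          rnorm(n, 0, sl) - sl^2 / 2)
  }
  shoot_mass <- gen_trait(base$shoot_mass, mult$shoot_mass)
  root_mass <- gen_trait(base$root_mass, mult$root_mass)
  leaf_mean <- gen_trait(base$leaf_size, mult$leaf_size)

  individuals <- individuals |>
    dplyr::mutate(
      initial_size = initial_size,
      shoot_mass = shoot_mass,
      root_mass = root_mass,
      total_mass = shoot_mass + root_mass,
      rs_ratio = root_mass / shoot_mass,
      alive = TRUE
    )

  leaves <- NULL
  if (include_leaves) {
    lo <- design$leaves_per_individual[1]
    hi <- design$leaves_per_individual[2]
    n_leaves <- if (hi > lo) {
      lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1L
    } else {
      rep(lo, n)
    }
    sl_w <- sdlog_for_cv(traits$cv_intra)
    size <- rep(leaf_mean, n_leaves) *
      exp(rnorm(sum(n_leaves), 0, sl_w) - sl_w^2 / 2)
    leaf_idx <- sequence(n_leaves)
    pairs <- simulate_leaf_pair(size, asym, m = design$replicate_measurements)
    leaves <- tibble::tibble(
      individual_id = rep(individuals$individual_id, n_leaves)[pairs$leaf],
      leaf = leaf_idx[pairs$leaf],
      side = pairs$side,
      replicate = pairs$replicate,
      width = pairs$width
    )
  }

  structure(
    list(individuals = individuals, leaves = leaves, mortality = NULL,
         design = design, asym = asym, traits = traits, seed = seed),
    class = "phenostab_experiment"
  )
}

#' @export
print.phenostab_experiment <- function(x, ...) {
  cat("<phenostab_experiment>\n")
  cat(sprintf("  individuals: %d (%d alive)\n", nrow(x$individuals),
              sum(x$individuals$alive)))
  if (!is.null(x$leaves)) {
    cat(sprintf("  leaf measurements: %d rows (%d leaves)\n", nrow(x$leaves),
                nrow(dplyr::distinct(x$leaves, .data$individual_id, .data$leaf))))
  }
  if (!is.null(x$mortality)) {
    cat(sprintf("  mortality applied: %d deaths\n",
                sum(x$mortality$n_dead)))
  }
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Apply Bernoulli mortality to an experiment
#'
#' Removes plants that die before harvest from both tables, independently
#' per plant at the per-cell rate from the trait model, and reports the
#' realized mortality rate per species x early x late cell.
#'
#' @param individuals Individual table (as from [generate_experiment()]).
#' @param leaves Leaf table, or `NULL`.
#' @param traits A [trait_model()] (its `mortality` component is used), or a
#'   single rate in `[0, 1]`.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return A list with filtered `individuals` and `leaves`, plus `mortality`:
#'   a tibble `species`, `early`, `late`, `n`, `n_dead`, `rate_realized`.
#' @export
apply_mortality <- function(individuals, leaves = NULL, traits = trait_model(),
                            seed = NULL) {
  check_columns(individuals, c("individual_id", "species", "early", "late"),
                "`individuals`")
  if (!is.null(leaves)) {
    check_columns(leaves, "individual_id", "`leaves`")
    orphans <- setdiff(leaves$individual_id, individuals$individual_id)
    if (length(orphans) > 0) {
      abort(sprintf("Leaf rows reference unknown individual(s): %s.",
                    paste(head(orphans, 5), collapse = ", ")))
    }
  }
  rate_spec <- if (inherits(traits, "trait_model")) traits$mortality else traits
  if (is.numeric(rate_spec) && length(rate_spec) == 1) {
    check_scalar(rate_spec, "mortality", lower = 0, upper = 1)
    rates <- rep(rate_spec, nrow(individuals))
  } else {
    check_columns(rate_spec, c("early", "late", "rate"), "`mortality`")
    rates <- individuals |>
      dplyr::left_join(rate_spec, by = c("early", "late")) |>
      dplyr::pull("rate")
    rates[is.na(rates)] <- 0
  }
  if (!is.null(seed)) set.seed(seed)
  dead <- runif(nrow(individuals)) < rates

  mortality <- individuals |>
    dplyr::mutate(dead = dead) |>
    dplyr::group_by(.data$species, .data$early, .data$late) |>
    dplyr::summarise(n = dplyr::n(), n_dead = sum(.data$dead),
                     rate_realized = mean(.data$dead), .groups = "drop")

  survivors <- individuals[!dead, , drop = FALSE]
  if (!is.null(leaves)) {
    leaves <- leaves[leaves$individual_id %in% survivors$individual_id, ,
                     drop = FALSE]
  }
  list(individuals = survivors, leaves = leaves, mortality = mortality)
}

#' Generate an experiment and apply mortality in one call
#'
#' Convenience wrapper: [generate_experiment()] followed by
#' [apply_mortality()], all driven by the design's seed so the full result
#' is reproducible from the configuration alone.
#'
#' @inheritParams generate_experiment
#' @return A `phenostab_experiment` list whose tables contain survivors
#'   only, with the realized per-cell `mortality` table attached.
#' @examples
#' ex <- simulate_experiment(design_config(seed = 7))
#' @export
simulate_experiment <- function(design = design_config(),
                                asym = asymmetry_model(),
                                traits = trait_model(design$species),
                                include_leaves = TRUE) {
  ex <- generate_experiment(design, asym, traits, seed = design$seed,
                            include_leaves = include_leaves)
  filtered <- apply_mortality(ex$individuals, ex$leaves, traits, seed = NULL)
  ex$individuals <- filtered$individuals
  ex$leaves <- filtered$leaves
  ex$mortality <- filtered$mortality
  ex
}
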