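#' Configure the split-plot experimental design
#'
#' Describes the layout of a two-round water-treatment experiment: a first
#' round applying an "early experience" treatment (heterogeneous alternating
#' inundation/drought vs homogeneous moderate watering), after which a
#' subgroup per species x early cell is harvested, and a second round
#' splitting the remaining plants across late water treatments. The default
#' layout is 8 species x 2 early treatments x (3 late treatments x 10
#' replicates + 20 first-round-harvest replicates) = 800 plants.
#'
#' @param species Character vector of species labels.
#' @param early Character vector of early (first-round) treatment labels.
#' @param late Character vector of late (second-round) treatment labels.
#' @param reps_late Replicates per species x early x late cell.
#' @param reps_first_harvest Replicates per species x early cell harvested
#'   after the first round (before late treatments are applied).
#' @param leaves_per_individual Length-2 integer range; each plant's leaf
#'   count is drawn uniformly from this range.
#' @param replicate_measurements Number of successive caliper readings per
#'   leaf side (`M`). At least 2, so that measurement error is estimable.
#' @param seed Integer seed recorded in the design and used by
#'   [generate_experiment()].
#' @param species_attrs Optional tibble with columns `species`, `nativity`
#'   and `habitat` (species-level attributes used by the three-way ANCOVA).
#'   Defaults to half invasive / half native with a mix of moisture classes.
#' @return An object of class `design_config`.
#' @seealso [asymmetry_model()], [trait_model()], [generate_experiment()]
#' @examples
#' d <- design_config()
#' n_units(d) # 800
#' @export
design_config <- function(species = paste0("S", 1:8),
                          early = c("E_het", "E_hom"),
                          late = c("inundation", "moderate", "drought"),
                          reps_late = 10,
                          reps_first_harvest = 20,
                          leaves_per_individual = c(4L, 12L),
                          replicate_measurements = 2,
                          seed = 1L,
                          species_attrs = NULL) {
  if (length(species) < 1) abort("`species` must contain at least one label.")
  if (anyDuplicated(species)) abort("`species` labels must be unique.")
  if (length(early) < 1) abort("`early` must contain at least one label.")
  check_scalar(reps_late, "reps_late", lower = 0, integer = TRUE)
  check_scalar(reps_first_harvest, "reps_first_harvest", lower = 0, integer = TRUE)
  if (reps_late == 0 && reps_first_harvest == 0) {
    abort("`reps_late` and `reps_first_harvest` cannot both be zero.")
  }
  if (reps_late > 0 && length(late) < 1) {
    abort("`late` must contain at least one label when `reps_late` > 0.")
  }
  if (length(leaves_per_individual) == 1) {
    leaves_per_individual <- rep(leaves_per_individual, 2)
  }
  if (length(leaves_per_individual) != 2 ||
      any(leaves_per_individual < 1) ||
      leaves_per_individual[1] > leaves_per_individual[2]) {
    abort("`leaves_per_individual` must be an increasing range of counts >= 1.")
  }
  check_scalar(replicate_measurements, "replicate_measurements",
               lower = 2, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)

  if (is.null(species_attrs)) {
    species_attrs <- default_species_attrs(species)
  }
  check_columns(species_attrs, c("species", "nativity", "habitat"),
                "`species_attrs`")

  structure(
    list(
      species = as.character(species),
      early = as.character(early),
      late = as.character(late),
      reps_late = as.integer(reps_late),
      reps_first_harvest = as.integer(reps_first_harvest),
      leaves_per_individual = as.integer(leaves_per_individual),
      replicate_measurements = as.integer(replicate_measurements),
      seed = as.integer(seed),
      species_attrs = tibble::as_tibble(species_attrs)
    ),
    class = "design_config"
  )
}

default_species_attrs <- function(species) {
  n <- length(species)
  nativity <- rep(c("invasive", "native"), each = ceiling(n / 2))[seq_len(n)]
  # per nativity group, most species span mesic~xeric and one wetter outlier
  habitat <- rep("mesic_xeric", n)
  wet <- unique(c(
    which(nativity == "invasive")[min(4, sum(nativity == "invasive"))],
    which(nativity == "native")[min(4, sum(nativity == "native"))]
  ))
  habitat[wet[!is.na(wet)]] <- "hydric_mesic"
  tibble::tibble(species = species, nativity = nativity, habitat = habitat)
}

#' Number of experimental units implied by a design
#'
#' `|species| * |early| * (|late| * reps_late + reps_first_harvest)`, the
#' plant count before any mortality.
#'
#' @param design A [design_config()].
#' @return Integer unit count.
#' @export
n_units <- function(design) {
  stopifnot(inherits(design, "design_config"))
  length(design$species) * length(design$early) *
    (length(design$late) * design$reps_late + design$reps_first_harvest)
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  species: %d (%s%s)\n", length(x$species),
              paste(head(x$species, 4), collapse = ", "),
              if (length(x$species) > 4) ", ..." else ""))
  cat(sprintf("  early treatments: %s\n", paste(x$early, collapse = ", ")))
  cat(sprintf("  late treatments:  %s\n", paste(x$late, collapse = ", ")))
  cat(sprintf("  replicates: %d per late cell, %d first-round harvest\n",
              x$reps_late, x$reps_first_harvest))
  cat(sprintf("  leaves per plant: %d-%d, %d readings per side\n",
              x$leaves_per_individual[1], x$leaves_per_individual[2],
              x$replicate_measurements))
  cat(sprintf("  units: %d, seed: %d\n", n_units(x), x$seed))
  invisible(x)
}

#' Configure the latent leaf-asymmetry model
#'
#' Generative model for the signed side difference `d = R - L` of a leaf and
#' for replicate measurement error. The latent difference is drawn as
#' `d ~ Normal(da_offset, sd_d^2)` with `sd_d = sigma_fa + size_slope *
#' true_size`; when `antisym_delta > 0` an equal-probability `+/- delta`
#' shift is added, giving the symmetric two-point mixture that produces
#' platykurtic (antisymmetric) signed differences. Side widths are
#' `true_size +/- d/2`, so leaf size `(R + L)/2` recovers `true_size`
#' exactly. Each replicate caliper reading adds independent
#' `Normal(0, sigma_me^2)` error.
#'
#' @param sigma_fa Baseline between-sides standard deviation of `d` (mm).
#' @param da_offset Mean of `d` (mm); non-zero values induce directional
#'   asymmetry.
#' @param antisym_delta Half-separation of the two-point mixture (mm); zero
#'   disables antisymmetry.
#' @param sigma_me Standard deviation of a single replicate reading's
#'   measurement error (mm).
#' @param size_slope Increase in the standard deviation of `d` per mm of
#'   leaf size, producing size-dependent asymmetry.
#' @return An object of class `asymmetry_model`.
#' @examples
#' asymmetry_model(sigma_fa = 1, sigma_me = 0.3)
#' @export
asymmetry_model <- function(sigma_fa = 0.25,
                            da_offset = 0,
                            antisym_delta = 0,
                            sigma_me = 0.1,
                            size_slope = 0.02) {
  check_scalar(sigma_fa, "sigma_fa", lower = 0)
  check_scalar(da_offset, "da_offset")
  check_scalar(antisym_delta, "antisym_delta", lower = 0)
  check_scalar(sigma_me, "sigma_me", lower = 0)
  check_scalar(size_slope, "size_slope", lower = 0)
  structure(
    list(sigma_fa = sigma_fa, da_offset = da_offset,
         antisym_delta = antisym_delta, sigma_me = sigma_me,
         size_slope = size_slope),
    class = "asymmetry_model"
  )
}

#' @export
print.asymmetry_model <- function(x, ...) {
  cat("<asymmetry_model>\n")
  cat(sprintf("  sigma_fa: %g mm  da_offset: %g mm  antisym_delta: %g mm\n",
              x$sigma_fa, x$da_offset, x$antisym_delta))
  cat(sprintf("  sigma_me: %g mm  size_slope: %g per mm\n",
              x$sigma_me, x$size_slope))
  invisible(x)
}

#' Configure the trait-generation model
#'
#' Species baselines, dispersion and treatment effects for the individual
#' table. Mass traits and individual mean leaf size are lognormal around a
#' species baseline multiplied by the treatment multiplier for the plant's
#' cell; `cv_inter` controls the among-individual coefficient of variation,
#' `cv_intra` the within-plant leaf-size CV, and `initial_size_effect` is the
#' elasticity of traits with respect to initial plant size (longest-leaf
#' length measured before treatments). Mortality is Bernoulli per plant at a
#' per-cell rate.
#'
#' @param species Character vector of species labels (used to build default
#'   baselines).
#' @param baseline Tibble with columns `species`, `leaf_size` (mm),
#'   `shoot_mass`, `root_mass` (g): per-species baseline means.
#' @param cv_inter Among-individual coefficient of variation applied to each
#'   trait (dimensionless).
#' @param cv_intra Within-plant coefficient of variation of leaf size.
#' @param multipliers Tibble with columns `early`, `late`, `leaf_size`,
#'   `shoot_mass`, `root_mass`: multiplicative treatment effects. Use
#'   `late = "first_harvest"` rows for plants harvested after round one.
#'   Missing cells default to 1.
#' @param initial_size_effect Regression coefficient of log trait on centred
#'   log initial size.
#' @param initial_size_mean,initial_size_cv Lognormal mean (mm) and CV of
#'   initial size.
#' @param mortality Either a single death probability applied to every cell
#'   or a tibble `early`, `late`, `rate`.
#' @return An object of class `trait_model`.
#' @examples
#' trait_model(cv_inter = 0.3, mortality = 0.1)
#' @export
trait_model <- function(species = paste0("S", 1:8),
                        baseline = default_baselines(species),
                        cv_inter = 0.3,
                        cv_intra = 0.15,
                        multipliers = default_multipliers(),
                        initial_size_effect = 0.3,
                        initial_size_mean = 60,
                        initial_size_cv = 0.25,
                        mortality = 0.1) {
  check_columns(baseline, c("species", "leaf_size", "shoot_mass", "root_mass"),
                "`baseline`")
  if (any(baseline$leaf_size <= 0) || any(baseline$shoot_mass <= 0) ||
      any(baseline$root_mass <= 0)) {
    abort("`baseline` trait means must all be positive.")
  }
  check_scalar(cv_inter, "cv_inter", lower = 0)
  check_scalar(cv_intra, "cv_intra", lower = 0)
  check_columns(multipliers,
                c("early", "late", "leaf_size", "shoot_mass", "root_mass"),
                "`multipliers`")
  mult_vals <- unlist(multipliers[c("leaf_size", "shoot_mass", "root_mass")])
  if (any(mult_vals <= 0)) abort("`multipliers` must all be positive.")
  check_scalar(initial_size_effect, "initial_size_effect")
  check_scalar(initial_size_mean, "initial_size_mean", lower = 1e-12)
  check_scalar(initial_size_cv, "initial_size_cv", lower = 0)
  if (is.numeric(mortality) && length(mortality) == 1) {
    check_scalar(mortality, "mortality", lower = 0, upper = 1)
  } else {
    check_columns(mortality, c("early", "late", "rate"), "`mortality`")
    if (any(mortality$rate < 0 | mortality$rate > 1)) {
      abort("`mortality` rates must lie in [0, 1].")
    }
  }
  structure(
    list(
      baseline = tibble::as_tibble(baseline),
      cv_inter = cv_inter,
      cv_intra = cv_intra,
      multipliers = tibble::as_tibble(multipliers),
      initial_size_effect = initial_size_effect,
      initial_size_mean = initial_size_mean,
      initial_size_cv = initial_size_cv,
      mortality = mortality
    ),
    class = "trait_model"
  )
}

#' @export
print.trait_model <- function(x, ...) {
  cat("<trait_model>\n")
  cat(sprintf("  species baselines: %d rows\n", nrow(x$baseline)))
  cat(sprintf("  cv_inter: %g  cv_intra: %g  IS elasticity: %g\n",
              x$cv_inter, x$cv_intra, x$initial_size_effect))
  if (is.numeric(x$mortality)) {
    cat(sprintf("  mortality: %g (all cells)\n", x$mortality))
  } else {
    cat(sprintf("  mortality: per-cell table (%d rows)\n", nrow(x$mortality)))
  }
  invisible(x)
}

#' Default species baselines
#'
#' Leaf half-widths spanning 8-22 mm and shoot/root dry masses in the
#' 1.5-4 g / 0.7-2 g range, spread evenly across species -- typical of
#' greenhouse-grown herbaceous perennials harvested at 90-150 days.
#'
#' @param species Character vector of species labels.
#' @return Tibble with columns `species`, `leaf_size`, `shoot_mass`,
#'   `root_mass`.
#' @export
default_baselines <- function(species = paste0("S", 1:8)) {
  n <- length(species)
  even <- function(a, b) if (n == 1) (a + b) / 2 else seq(a, b, length.out = n)
  tibble::tibble(
    species = species,
    leaf_size = even(8, 22),
    shoot_mass = even(1.5, 4),
    root_mass = even(0.7, 2)
  )
}

#' Default treatment multipliers
#'
#' Moderate watering is the reference (multiplier 1). Early heterogeneous
#' experience mildly reduces leaf size and mass (x0.9); late inundation and
#' drought reduce mass (x0.75 and x0.6); first-round-harvest plants are
#' younger, so their masses are scaled to 45% of the final-harvest baseline.
#'
#' @param early,late Treatment labels; `"first_harvest"` is appended to
#'   `late` automatically.
#' @return Tibble with one row per early x late cell and multiplier columns
#'   `leaf_size`, `shoot_mass`, `root_mass`.
#' @export
default_multipliers <- function(early = c("E_het", "E_hom"),
                                late = c("inundation", "moderate", "drought")) {
  late_all <- union(late, "first_harvest")
  grid <- tidyr::expand_grid(early = early, late = late_all)
  early_f <- ifelse(grid$early == "E_het", 0.9, 1)
  late_f <- dplyr::case_match(grid$late,
    "inundation" ~ 0.75,
    "drought" ~ 0.6,
    "first_harvest" ~ 0.45,
    .default = 1
  )
  tibble::tibble(
    early = grid$early, late = grid$late,
    leaf_size = early_f,
    shoot_mass = early_f * late_f,
    root_mass = early_f * late_f
  )
}
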