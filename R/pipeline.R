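leaf_cols <- c("individual_id", "leaf", "side", "replicate", "width")
ind_cols <- c("individual_id", "species", "early", "late", "initial_size",
              "shoot_mass", "root_mass", "total_mass", "rs_ratio")

#' Load a leaf-measurement and individual-trait dataset from CSV
#'
#' Reads and validates the two tables of the pipeline's input format.
#' `rename` maps external headers onto the canonical names (named character
#' vector, `canonical = "external"`), so exports with different column
#' labels (e.g. a data-repository deposit) can be adapted without editing
#' files. Validation rejects missing columns, duplicate
#' (individual, leaf, side, replicate) keys, leaves missing a side or with
#' unequal replicate counts (the offending leaf is named), orphan leaves,
#' and non-positive widths.
#'
#' @param leaf_path CSV of leaf measurements (`individual_id`, `leaf`,
#'   `side`, `replicate`, `width` in mm).
#' @param trait_path CSV of individual traits (`individual_id`, `species`,
#'   `early`, `late`, `initial_size` in mm, `shoot_mass`, `root_mass`,
#'   `total_mass` in g, `rs_ratio`; optional `nativity`, `habitat`,
#'   `alive`).
#' @param rename Optional named character vector mapping canonical names to
#'   the file's headers.
#' @return A list with validated tibbles `individuals` and `leaves`.
#' @export
load_dataset <- function(leaf_path, trait_path, rename = NULL) {
  leaves <- readr::read_csv(leaf_path, show_col_types = FALSE)
  individuals <- readr::read_csv(trait_path, show_col_types = FALSE)
  if (!is.null(rename)) {
    for (canon in names(rename)) {
      for (tab in c("leaves", "individuals")) {
        t <- get(tab)
        if (rename[[canon]] %in% names(t)) {
          names(t)[names(t) == rename[[canon]]] <- canon
          assign(tab, t)
        }
      }
    }
  }
  check_columns(leaves, leaf_cols, "leaf table")
  check_columns(individuals, ind_cols, "individual table")
  if (!"alive" %in% names(individuals)) individuals$alive <- TRUE

  dup <- duplicated(leaves[, c("individual_id", "leaf", "side", "replicate")])
  if (any(dup)) {
    d <- leaves[dup, ][1, ]
    abort(sprintf("Duplicate measurement key: individual %s leaf %s side %s replicate %s.",
                  d$individual_id, d$leaf, d$side, d$replicate))
  }
  orphans <- setdiff(leaves$individual_id, individuals$individual_id)
  if (length(orphans) > 0) {
    abort(sprintf("Leaf rows reference unknown individual(s): %s.",
                  paste(head(orphans, 5), collapse = ", ")))
  }
  if (any(leaves$width <= 0)) abort("Leaf widths must be positive.")
  if (any(individuals$initial_size <= 0)) abort("Initial sizes must be positive.")

  per_side <- leaves |>
    dplyr::count(.data$individual_id, .data$leaf, .data$side) |>
    tidyr::pivot_wider(names_from = "side", values_from = "n")
  for (s in c("left", "right")) {
    if (!s %in% names(per_side)) per_side[[s]] <- NA_integer_
  }
  bad <- per_side[is.na(per_side$left) | is.na(per_side$right) |
                    per_side$left != per_side$right, ]
  if (nrow(bad) > 0) {
    abort(sprintf("Leaf %s of individual %s is missing a side or has unequal replicate counts.",
                  bad$leaf[1], bad$individual_id[1]))
  }
  list(individuals = individuals, leaves = leaves)
}

#' Write a synthetic experiment to disk
#'
#' Serialises the individual and leaf tables as CSV plus a YAML
#' configuration record (design, asymmetry and trait parameters, and the
#' seed) so a run can be reproduced from its output directory alone.
#'
#' @param experiment A `phenostab_experiment` (from
#'   [generate_experiment()]/[simulate_experiment()]).
#' @param dir Output directory (created if needed).
#' @param overwrite Allow replacing existing files.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(experiment, dir, overwrite = FALSE) {
  stopifnot(inherits(experiment, "phenostab_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("individuals.csv", "leaves.csv", "config.yaml"))
  if (!overwrite && any(file.exists(paths))) {
    abort("Output files exist; use `overwrite = TRUE` to replace them.")
  }
  readr::write_csv(experiment$individuals, paths[1])
  if (!is.null(experiment$leaves)) readr::write_csv(experiment$leaves, paths[2])
  cfg <- list(
    seed = experiment$seed,
    design = unclass(experiment$design)[c("species", "early", "late",
                                          "reps_late", "reps_first_harvest",
                                          "leaves_per_individual",
                                          "replicate_measurements")],
    asymmetry = unclass(experiment$asym),
    traits = list(
      cv_inter = experiment$traits$cv_inter,
      cv_intra = experiment$traits$cv_intra,
      initial_size_effect = experiment$traits$initial_size_effect,
      initial_size_mean = experiment$traits$initial_size_mean,
      initial_size_cv = experiment$traits$initial_size_cv,
      mortality = if (is.numeric(experiment$traits$mortality))
        experiment$traits$mortality else "per-cell table"
    )
  )
  yaml::write_yaml(cfg, paths[3])
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' One call from data to every result family: leaf summaries, per-cell FA
#' indices and diagnostics, intra-/inter-individual CVs, plasticity
#' indices, species-level summaries, cross-species correlation tables,
#' early-treatment slope comparisons and the three-way ANCOVA effect
#' tables. Input is either a synthetic configuration (design + asymmetry +
#' trait models; the data are generated and mortality applied) or a loaded
#' dataset from [load_dataset()]. Given the same configuration and seed the
#' bundle is fully reproducible.
#'
#' @param design,asym,traits Synthetic configuration (used when `data` is
#'   `NULL`).
#' @param data Optional list with `individuals` and `leaves` (real data).
#' @param fa10_variant,pi_variant,cv_equality_method,covariate Analysis
#'   options passed through to the respective stages.
#' @return A list of class `phenostab_bundle` with elements `data`, `fa`,
#'   `diagnostics`, `cv_intra`, `cv_inter`, `mortality`, `plasticity`,
#'   `summary`, `correlations`, `slopes`, `effects`, `meta`.
#' @examples
#' \donttest{
#' b <- run_full_analysis(design_config(seed = 11))
#' b$correlations$table3
#' }
#' @export
run_full_analysis <- function(design = design_config(),
                              asym = asymmetry_model(),
                              traits = trait_model(design$species),
                              data = NULL,
                              fa10_variant = "between_sides",
                              pi_variant = "ratio",
                              cv_equality_method = "asymptotic",
                              covariate = "mean_is") {
  if (is.null(data)) {
    ex <- simulate_experiment(design, asym, traits)
    individuals <- ex$individuals
    leaves <- ex$leaves
    mortality <- ex$mortality
    seed <- ex$seed
  } else {
    check_columns(data$individuals, ind_cols, "individual table")
    check_columns(data$leaves, leaf_cols, "leaf table")
    individuals <- data$individuals
    if (!"alive" %in% names(individuals)) individuals$alive <- TRUE
    if (!"nativity" %in% names(individuals)) individuals$nativity <- NA_character_
    if (!"habitat" %in% names(individuals)) individuals$habitat <- NA_character_
    individuals <- individuals[individuals$alive, , drop = FALSE]
    leaves <- data$leaves[data$leaves$individual_id %in%
                            individuals$individual_id, , drop = FALSE]
    mortality <- NULL
    seed <- NA_integer_
  }

  fa <- fa_table(leaves, individuals, by = c("species", "early", "late"),
                 fa10_variant = fa10_variant)
  diagnostics <- diagnostics_table(leaves, individuals,
                                   by = c("species", "early", "late"))
  cvi <- suppressMessages(cv_intra(leaves))
  cve <- purrr::map_dfr(
    c("shoot_mass", "root_mass", "total_mass", "rs_ratio"),
    ~ suppressWarnings(cv_inter(individuals, .x))
  )
  pi_tab <- suppressWarnings(plasticity_table(individuals,
                                              variant = pi_variant))
  summ <- species_summary(individuals, leaves, fa10_variant = fa10_variant)
  corr <- correlation_tables(summ, pi_tab,
                             covariate = if (covariate == "cv_inter_is")
                               "cv_inter_is" else "mean_is")
  slopes <- slope_comparisons(summ, pi_tab)
  effects <- if (!all(is.na(individuals$nativity))) {
    effects_table(summ, individuals)
  } else {
    NULL
  }

  structure(
    list(
      data = list(individuals = individuals, leaves = leaves),
      fa = fa, diagnostics = diagnostics,
      cv_intra = cvi, cv_inter = cve, mortality = mortality,
      plasticity = pi_tab, summary = summ,
      correlations = corr, slopes = slopes, effects = effects,
      meta = list(
        seed = seed,
        config_hash = rlang::hash(list(design = if (is.null(data)) design,
                                       asym = if (is.null(data)) asym,
                                       fa10_variant = fa10_variant,
                                       pi_variant = pi_variant,
                                       covariate = covariate)),
        options = list(fa10_variant = fa10_variant, pi_variant = pi_variant,
                       cv_equality_method = cv_equality_method,
                       covariate = covariate),
        package_version = as.character(utils::packageVersion("phenostab"))
      )
    ),
    class = "phenostab_bundle"
  )
}

#' @export
print.phenostab_bundle <- function(x, ...) {
  cat("<phenostab_bundle>\n")
  cat(sprintf("  individuals: %d, leaf rows: %d\n",
              nrow(x$data$individuals), nrow(x$data$leaves)))
  cat(sprintf("  fa cells: %d, plasticity rows: %d\n",
              nrow(x$fa), nrow(x$plasticity)))
  cat(sprintf("  correlation tables: %s\n",
              paste(names(x$correlations)[!vapply(x$correlations, is.null,
                                                  logical(1))],
                    collapse = ", ")))
  if (!is.null(x$meta$seed) && !is.na(x$meta$seed)) {
    cat(sprintf("  seed: %s  config: %s\n", x$meta$seed, x$meta$config_hash))
  }
  invisible(x)
}

#' Write a result bundle to disk
#'
#' One CSV per result table plus a JSON metadata file (seed, configuration
#' hash, analysis options, package version). Filenames are stable, and a
#' rerun of the same seed produces byte-identical files.
#'
#' @param bundle A [run_full_analysis()] bundle.
#' @param dir Output directory (created if needed).
#' @param overwrite Allow replacing existing files.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(bundle, dir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "phenostab_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    fa = bundle$fa,
    diagnostics = bundle$diagnostics,
    cv_intra = bundle$cv_intra,
    cv_inter = bundle$cv_inter,
    mortality = bundle$mortality,
    plasticity = bundle$plasticity,
    summary_round1 = bundle$summary$round1,
    summary_round2 = bundle$summary$round2,
    correlations_table3 = bundle$correlations$table3,
    correlations_table4 = bundle$correlations$table4,
    correlations_table5 = bundle$correlations$table5,
    slopes = bundle$slopes,
    effects = bundle$effects
  )
  tables <- tables[!vapply(tables, is.null, logical(1))]
  paths <- file.path(dir, paste0(names(tables), ".csv"))
  meta_path <- file.path(dir, "metadata.json")
  if (!overwrite && any(file.exists(c(paths, meta_path)))) {
    abort("Output files exist; use `overwrite = TRUE` to replace them.")
  }
  for (i in seq_along(tables)) {
    readr::write_csv(tables[[i]], paths[i])
  }
  jsonlite::write_json(bundle$meta, meta_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, meta_path))
}
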