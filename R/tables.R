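#' Species-level summaries for both experiment rounds
#'
#' Collapses the individual and leaf tables to the species x treatment
#' summaries that the cross-species correlation analyses operate on.
#'
#' Round 1 (per species x early treatment, from the plants harvested after
#' the first round): mean leaf size, FA1/FA2/FA10 (cell means of
#' per-individual indices), mean intra-individual CV of leaf size, the
#' inter-individual CVs of leaf size and of the mass traits, and the mean
#' and inter-individual CV of initial size.
#'
#' Round 2 (per species x early x late treatment): inter-individual CVs of
#' the mass traits and mean initial size of the survivors.
#'
#' @param individuals Individual table (survivors).
#' @param leaves Raw leaf table.
#' @param first_harvest_label Late-treatment label identifying first-round
#'   harvest plants.
#' @param fa10_variant Passed to [fa_table()].
#' @return A list of class `species_summary` with tibbles `round1` and
#'   `round2`.
#' @export
species_summary <- function(individuals, leaves,
                            first_harvest_label = "first_harvest",
                            fa10_variant = "between_sides") {
  check_columns(individuals,
                c("individual_id", "species", "early", "late", "initial_size",
                  "shoot_mass", "root_mass", "total_mass", "rs_ratio"),
                "`individuals`")
  first <- individuals[individuals$late == first_harvest_label, , drop = FALSE]
  if (nrow(first) == 0) abort("No first-round-harvest individuals found.")
  second <- individuals[individuals$late != first_harvest_label, , drop = FALSE]

  summ <- summarize_leaves(leaves)
  first_leaves <- leaves[leaves$individual_id %in% first$individual_id, ,
                         drop = FALSE]
  fa <- fa_table(first_leaves, first, by = c("species", "early"),
                 fa10_variant = fa10_variant)

  ind_ls <- summ |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(mean_ls_ind = mean(.data$leaf_size), .groups = "drop")
  cvi <- suppressMessages(cv_intra(summ))

  first_aug <- first |>
    dplyr::left_join(ind_ls, by = "individual_id") |>
    dplyr::left_join(cvi[, c("individual_id", "cv_intra")], by = "individual_id")

  cv_cell <- function(x) if (sum(!is.na(x)) >= 2) cv(x[!is.na(x)]) else NA_real_
  round1 <- first_aug |>
    dplyr::group_by(.data$species, .data$early) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ls = mean(.data$mean_ls_ind, na.rm = TRUE),
      cv_intra_ls = mean(.data$cv_intra, na.rm = TRUE),
      cv_inter_ls = cv_cell(.data$mean_ls_ind),
      cv_inter_sm = cv_cell(.data$shoot_mass),
      cv_inter_rm = cv_cell(.data$root_mass),
      cv_inter_tm = cv_cell(.data$total_mass),
      cv_inter_rs = cv_cell(.data$rs_ratio),
      mean_is = mean(.data$initial_size),
      cv_inter_is = cv_cell(.data$initial_size),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      fa[, c("species", "early", "fa1_mean", "fa2_mean", "fa10_mean",
             "fa10_pooled")],
      by = c("species", "early")
    ) |>
    dplyr::rename(fa1 = "fa1_mean", fa2 = "fa2_mean", fa10 = "fa10_mean")

  round2 <- second |>
    dplyr::group_by(.data$species, .data$early, .data$late) |>
    dplyr::summarise(
      n = dplyr::n(),
      cv_inter_sm = cv_cell(.data$shoot_mass),
      cv_inter_rm = cv_cell(.data$root_mass),
      cv_inter_tm = cv_cell(.data$total_mass),
      cv_inter_rs = cv_cell(.data$rs_ratio),
      mean_is = mean(.data$initial_size),
      cv_inter_is = cv_cell(.data$initial_size),
      .groups = "drop"
    )

  structure(list(round1 = round1, round2 = round2),
            class = "species_summary")
}

#' @export
print.species_summary <- function(x, ...) {
  cat("<species_summary>\n")
  cat(sprintf("  round1: %d species x early cells\n", nrow(x$round1)))
  cat(sprintf("  round2: %d species x early x late cells\n", nrow(x$round2)))
  invisible(x)
}

round1_vars <- c("mean_ls", "fa10", "cv_intra_ls", "cv_inter_ls", "cv_inter_tm")

# partial correlation across species within one cell, tolerant of failures
# (returns NA row rather than aborting the whole table)
pc_row <- function(df, x, y, covariates) {
  res <- tryCatch(partial_corr(df, x, y, covariates),
                  error = function(e) NULL)
  if (is.null(res)) {
    tibble::tibble(x = x, y = y,
                   covariates = paste(covariates, collapse = ","),
                   r = NA_real_, df = NA_real_, p_value = NA_real_,
                   kind = "PPCC", n = nrow(df))
  } else {
    res
  }
}

#' Cross-species correlation tables
#'
#' The three partial-correlation summaries relating the first-round
#' stability/canalization variables, the second-round inter-individual
#' variation, and plasticity, always computed *across species* (each
#' species contributes one point per cell) with initial size statistically
#' controlled:
#'
#' * `table3`: all pairwise partial correlations among the first-round
#'   variables (mean leaf size, FA10, intra- and inter-individual CV of
#'   leaf size, inter-individual CV of total mass), per early treatment.
#' * `table4`: second-round inter-individual CV of total mass (per late
#'   treatment) against each first-round variable, per early treatment;
#'   `covariate` selects mean initial size or its inter-individual CV.
#' * `table5`: relative plasticity of total mass (IM and DM contrasts)
#'   against the first-round variables and against the second-round CV of
#'   total mass in the late treatments entering each contrast.
#'
#' Significance stars mark p < 0.10 / 0.05 / 0.01; with fewer than 5
#' species-level points a `low_power` flag is set.
#'
#' @param summary A [species_summary()].
#' @param pi_table A [plasticity_table()] (needed for `table5`; `NULL`
#'   skips it).
#' @param covariate `"mean_is"` (mean initial size) or `"cv_inter_is"`,
#'   applied to `table4`/`table5`; `table3` always controls mean initial
#'   size.
#' @return A list of class `correlation_tables` with tibbles `table3`,
#'   `table4`, `table5`.
#' @export
correlation_tables <- function(summary, pi_table = NULL,
                               covariate = c("mean_is", "cv_inter_is")) {
  stopifnot(inherits(summary, "species_summary"))
  covariate <- match.arg(covariate)
  r1 <- summary$round1
  if (length(unique(r1$species)) < 2) {
    abort("Cross-species correlations need at least 2 species.")
  }
  finish <- function(tab) {
    tab$stars <- p_stars(tab$p_value)
    tab$low_power <- tab$n < 5
    tab
  }

  t3 <- purrr::map_dfr(unique(r1$early), function(e) {
    df <- r1[r1$early == e, , drop = FALSE]
    pairs <- utils::combn(round1_vars, 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      pc_row(df, pairs[1, i], pairs[2, i], "mean_is") |>
        dplyr::mutate(early = e, .before = 1)
    })
  })

  r2 <- summary$round2
  cov_r1 <- if (covariate == "mean_is") "mean_is" else "cv_inter_is"
  t4 <- purrr::map_dfr(unique(r2$early), function(e) {
    purrr::map_dfr(unique(r2$late), function(l) {
      df <- dplyr::inner_join(
        r1[r1$early == e, c("species", round1_vars, cov_r1)],
        r2[r2$early == e & r2$late == l, c("species", "cv_inter_tm")] |>
          dplyr::rename(cv_inter_tm_r2 = "cv_inter_tm"),
        by = "species"
      )
      purrr::map_dfr(round1_vars, function(v) {
        pc_row(df, v, "cv_inter_tm_r2", cov_r1) |>
          dplyr::mutate(early = e, late = l, .before = 1)
      })
    })
  })

  t5 <- NULL
  if (!is.null(pi_table)) {
    pit <- pi_table[pi_table$trait == "total_mass", , drop = FALSE]
    t5 <- purrr::map_dfr(unique(pit$early), function(e) {
      purrr::map_dfr(unique(pit$contrast), function(ct) {
        pis <- pit[pit$early == e & pit$contrast == ct,
                   c("species", "pi_rel")]
        base <- dplyr::inner_join(
          r1[r1$early == e, c("species", round1_vars, cov_r1)],
          pis, by = "species"
        )
        first_rows <- purrr::map_dfr(round1_vars, function(v) {
          pc_row(base, "pi_rel", v, cov_r1) |>
            dplyr::mutate(early = e, contrast = ct, round = "1st",
                          late = NA_character_, .before = 1)
        })
        lates <- if (ct == "IM") c("inundation", "moderate") else
          c("drought", "moderate")
        second_rows <- purrr::map_dfr(lates, function(l) {
          df <- dplyr::inner_join(
            base[, c("species", "pi_rel", cov_r1)],
            r2[r2$early == e & r2$late == l,
               c("species", "cv_inter_tm")],
            by = "species"
          )
          pc_row(df, "pi_rel", "cv_inter_tm", cov_r1) |>
            dplyr::mutate(early = e, contrast = ct, round = "2nd",
                          late = l, .before = 1)
        })
        dplyr::bind_rows(first_rows, second_rows)
      })
    })
    t5 <- finish(t5)
  }

  structure(list(table3 = finish(t3), table4 = finish(t4), table5 = t5),
            class = "correlation_tables")
}

#' @export
print.correlation_tables <- function(x, ...) {
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat(sprintf("$%s (%d correlations, %d starred at 0.05)\n", nm,
                nrow(x[[nm]]),
                sum(x[[nm]]$p_value < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}

#' Early-treatment slope comparisons for plasticity vs canalization
#'
#' For each contrast (IM, DM) and each inter-individual CV source (the
#' first-round CV of total mass, and the second-round CVs in the late
#' treatments entering the contrast), regresses relative plasticity on the
#' CV across species separately within each early treatment and tests
#' whether the two slopes differ ([slope_difference_test()]).
#'
#' @param summary A [species_summary()].
#' @param pi_table A [plasticity_table()].
#' @return Tibble with `contrast`, `cv_source`, per-early slopes and the
#'   interaction test.
#' @export
slope_comparisons <- function(summary, pi_table) {
  stopifnot(inherits(summary, "species_summary"))
  pit <- pi_table[pi_table$trait == "total_mass", , drop = FALSE]
  r1 <- summary$round1
  r2 <- summary$round2

  purrr::map_dfr(unique(pit$contrast), function(ct) {
    sources <- c("round1",
                 if (ct == "IM") c("inundation", "moderate") else
                   c("drought", "moderate"))
    purrr::map_dfr(sources, function(src) {
      cvdf <- if (src == "round1") {
        r1[, c("species", "early", "cv_inter_tm")]
      } else {
        r2[r2$late == src, c("species", "early", "cv_inter_tm")]
      }
      df <- dplyr::inner_join(
        pit[pit$contrast == ct, c("species", "early", "pi_rel")],
        cvdf, by = c("species", "early")
      )
      res <- tryCatch(
        slope_difference_test(df, "cv_inter_tm", "pi_rel", "early"),
        error = function(e) NULL
      )
      if (is.null(res)) {
        return(tibble::tibble(contrast = ct, cv_source = src,
                              statistic = NA_real_, p_value = NA_real_))
      }
      wide <- tidyr::pivot_wider(res$slopes[, c("group", "slope")],
                                 names_from = "group", values_from = "slope",
                                 names_prefix = "slope_")
      dplyr::bind_cols(
        tibble::tibble(contrast = ct, cv_source = src),
        wide,
        tibble::tibble(statistic = res$statistic, p_value = res$p_value)
      )
    })
  })
}

#' Three-way ANCOVA effect tables on species-level variables
#'
#' Tests the overall effects of early experience, habitat moisture class
#' and nativity (all crossed), with mean initial size as covariate, on each
#' species-level round-1 variable. Species attributes are taken from the
#' individual table's `nativity` and `habitat` columns.
#'
#' @param summary A [species_summary()].
#' @param individuals Individual table carrying `species`, `nativity`,
#'   `habitat`.
#' @param responses Round-1 summary columns to test.
#' @return Tibble of stacked Type III ANCOVA tables with a `response`
#'   column.
#' @export
effects_table <- function(summary, individuals,
                          responses = c("mean_ls", "fa1", "fa2", "fa10",
                                        "cv_intra_ls", "cv_inter_ls",
                                        "cv_inter_tm")) {
  stopifnot(inherits(summary, "species_summary"))
  check_columns(individuals, c("species", "nativity", "habitat"),
                "`individuals`")
  attrs <- dplyr::distinct(individuals[, c("species", "nativity", "habitat")])
  df <- dplyr::left_join(summary$round1, attrs, by = "species")
  purrr::map_dfr(responses, function(v) {
    res <- tryCatch(
      ancova(df, v, c("early", "habitat", "nativity"), "mean_is"),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    dplyr::mutate(tidy(res), response = v, .before = 1)
  })
}
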