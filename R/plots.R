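# Quick-look ggplot2 panels for the main result tables.

#' Plot per-cell fluctuating-asymmetry summaries
#'
#' Point-and-error-bar panel of a chosen FA index (mean +/- SE across
#' individuals) per species, coloured by early treatment and facetted by
#' any further grouping columns present.
#'
#' @param object A [fa_table()] result.
#' @param index One of `"fa1"`, `"fa2"`, `"fa10"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenostab_fa <- function(object, index = c("fa10", "fa1", "fa2"),
                                  ...) {
  index <- match.arg(index)
  mcol <- paste0(index, "_mean")
  scol <- paste0(index, "_se")
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$species, y = .data[[mcol]], colour = .data$early
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                   ymax = .data[[mcol]] + .data[[scol]]),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(y = paste(toupper(index), "(mean ± SE)"),
                  x = "species", colour = "early") +
    ggplot2::theme_minimal()
  if ("late" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$late))
  }
  p
}

#' Plot inter-individual CVs per cell
#'
#' Bar panel of a [cv_inter()] table: CV per species, coloured by early
#' treatment, facetted by late treatment when present.
#'
#' @param data A [cv_inter()] result.
#' @return A ggplot object.
#' @export
plot_cv_inter <- function(data) {
  check_columns(data, c("species", "cv"), "`data`")
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$species, y = .data$cv,
    fill = if ("early" %in% names(data)) .data$early else NULL
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(y = sprintf("CV_inter (%s)", data$trait[1]),
                  x = "species", fill = "early") +
    ggplot2::theme_minimal()
  if ("late" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$late))
  }
  p
}

#' Plot plasticity indices
#'
#' Bars of relative plasticity per species, facetted by contrast and trait.
#'
#' @param object A [plasticity_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenostab_pi <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$species, y = .data$pi_rel, fill = .data$early
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::facet_grid(ggplot2::vars(.data$trait),
                        ggplot2::vars(.data$contrast)) +
    ggplot2::labs(y = "relative plasticity", x = "species", fill = "early") +
    ggplot2::theme_minimal()
}

#' Plasticity vs inter-individual variation scatter
#'
#' Cross-species scatter of relative plasticity in a trait against an
#' inter-individual CV, with a separate least-squares line per early
#' treatment -- the visual companion of [slope_comparisons()].
#'
#' @param summary A [species_summary()].
#' @param pi_table A [plasticity_table()].
#' @param contrast `"IM"` or `"DM"`.
#' @param cv_source `"round1"`, or a late-treatment label for the
#'   second-round CV.
#' @return A ggplot object.
#' @export
plot_pi_cv <- function(summary, pi_table, contrast = "IM",
                       cv_source = "round1") {
  stopifnot(inherits(summary, "species_summary"))
  pit <- pi_table[pi_table$trait == "total_mass" &
                    pi_table$contrast == contrast, , drop = FALSE]
  cvdf <- if (cv_source == "round1") {
    summary$round1[, c("species", "early", "cv_inter_tm")]
  } else {
    summary$round2[summary$round2$late == cv_source,
                   c("species", "early", "cv_inter_tm")]
  }
  df <- dplyr::inner_join(pit[, c("species", "early", "pi_rel")], cvdf,
                          by = c("species", "early"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cv_inter_tm, y = .data$pi_rel,
    colour = .data$early, linetype = .data$early
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = sprintf("CV_inter in total mass (%s)", cv_source),
      y = sprintf("PI_%s (total mass)", contrast)
    ) +
    ggplot2::theme_minimal()
}
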