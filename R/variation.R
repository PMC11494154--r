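#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Scale-invariant: `cv(k * x) == cv(x)` for any `k > 0`.
#'
#' @param x Numeric vector, length >= 2, non-zero mean.
#' @return A single dimensionless value.
#' @examples
#' cv(c(2, 4)) # sqrt(2)/3
#' @export
cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("`cv()` needs at least 2 values.")
  m <- mean(x)
  if (m == 0) abort("`cv()` is undefined for zero-mean data.")
  sd(x) / m
}

#' Intra-individual coefficient of variation in leaf size
#'
#' Developmental variability of each plant: the CV of leaf size across the
#' leaves of one individual. Individuals with fewer than 2 complete leaves
#' are excluded with a message.
#'
#' @param leaves A [summarize_leaves()] table (or raw leaf table, which is
#'   summarised first).
#' @return Tibble with `individual_id`, `n_leaves`, `cv_intra`.
#' @export
cv_intra <- function(leaves) {
  summ <- if (inherits(leaves, "leaf_summary")) leaves else summarize_leaves(leaves)
  counts <- summ |>
    dplyr::count(.data$individual_id, name = "n_leaves")
  n_single <- sum(counts$n_leaves < 2)
  if (n_single > 0) {
    inform(sprintf("Excluding %d individual(s) with fewer than 2 leaves.",
                   n_single))
  }
  summ |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(n_leaves = dplyr::n(),
                     cv_intra = cv(.data$leaf_size), .groups = "drop")
}

#' Inter-individual coefficient of variation per cell
#'
#' Canalization metric: the CV of a trait across the individuals of each
#' grouping cell (species x early x late by default). Cells with fewer than
#' 2 individuals are skipped with a warning.
#'
#' @param data Individual-level table (one row per individual).
#' @param trait Column name (string) of the trait.
#' @param by Grouping columns.
#' @return Tibble with the grouping columns, `trait`, `cv` and `n`.
#' @examples
#' ex <- generate_experiment(design_config(seed = 1), include_leaves = FALSE)
#' cv_inter(ex$individuals, "total_mass")
#' @export
cv_inter <- function(data, trait, by = c("species", "early", "late")) {
  check_columns(data, c(trait, by), "`data`")
  counts <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n = sum(!is.na(.data[[trait]])), .groups = "drop")
  n_small <- sum(counts$n < 2)
  if (n_small > 0) {
    warn(sprintf("Skipping %d cell(s) with fewer than 2 individuals.", n_small))
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::filter(sum(!is.na(.data[[trait]])) >= 2) |>
    dplyr::summarise(trait = trait, cv = cv(.data[[trait]]),
                     n = sum(!is.na(.data[[trait]])), .groups = "drop")
}

#' Test equality of coefficients of variation across groups
#'
#' Compares the CVs of `k >= 2` groups of positive-valued measurements.
#' `method = "asymptotic"` (default) is the Feltz-Miller asymptotic
#' chi-square test: with `m_i = n_i - 1` and pooled CV
#' `c_p = sum(m_i c_i) / sum(m_i)`, the statistic
#' `sum(m_i (c_i - c_p)^2) / (c_p^2 (0.5 + c_p^2))` is chi-square with
#' `k - 1` df under equality. `method = "lrt"` is the normal-model
#' likelihood-ratio test with the common-CV constrained maximum likelihood
#' found numerically; for two groups the signed root
#' `sign(c_1 - c_2) * sqrt(LRT)` is also returned.
#'
#' @param data Table with one row per measurement.
#' @param value Column name (string) of the positive-valued trait.
#' @param group Column name (string) of the grouping factor.
#' @param method `"asymptotic"` or `"lrt"`.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `signed_root` (two groups, `lrt` only), `k`, `n_total`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 30),
#'                 y = c(rnorm(30, 10, 1), rnorm(30, 20, 2)))
#' cv_equality_test(d, "y", "g")
#' @export
cv_equality_test <- function(data, value, group,
                             method = c("asymptotic", "lrt")) {
  method <- match.arg(method)
  check_columns(data, c(value, group), "`data`")
  x <- data[[value]]
  g <- as.factor(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (any(x <= 0)) {
    abort("CV equality testing assumes positive-valued traits; found values <= 0.")
  }
  ns <- tapply(x, g, length)
  if (length(ns) < 2) abort("At least 2 groups are required.")
  if (any(ns < 2)) abort("Every group needs at least 2 observations.")
  k <- length(ns)
  means <- tapply(x, g, mean)
  sds <- tapply(x, g, sd)
  cvs <- sds / means

  if (method == "asymptotic") {
    m <- ns - 1
    cp <- sum(m * cvs) / sum(m)
    stat <- if (cp == 0) 0 else sum(m * (cvs - cp)^2) / (cp^2 * (0.5 + cp^2))
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
    signed <- NA_real_
  } else {
    # unrestricted normal log-likelihood (MLE variances, 1/n denominator)
    loglik_group <- function(xi, mu, sigma) {
      sum(stats::dnorm(xi, mu, sigma, log = TRUE))
    }
    sig_mle <- sqrt(tapply(x, g, function(v) mean((v - mean(v))^2)))
    l1 <- sum(mapply(function(lv, mu, s) loglik_group(x[g == lv], mu, s),
                     levels(g), means, sig_mle))
    # restricted: sigma_i = tau * mu_i; optimise over (log tau, mu_i)
    negll <- function(par) {
      tau <- exp(par[1]); mu <- par[-1]
      if (any(mu <= 0)) return(1e12)
      -sum(mapply(function(lv, m_i) loglik_group(x[g == lv], m_i, tau * m_i),
                  levels(g), mu))
    }
    cp <- sum((ns - 1) * cvs) / sum(ns - 1)
    fit <- optim(c(log(max(cp, 1e-6)), means), negll, method = "BFGS",
                 control = list(maxit = 500))
    l0 <- -fit$value
    stat <- max(0, 2 * (l1 - l0))
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
    signed <- if (k == 2) unname(sign(cvs[1] - cvs[2]) * sqrt(stat)) else NA_real_
  }
  tibble::tibble(
    method = method, statistic = unname(stat), df = k - 1,
    p_value = unname(p), signed_root = signed,
    k = k, n_total = length(x)
  )
}
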