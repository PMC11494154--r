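# Internal helpers shared across modules.

# stop() with the offending argument named, for config validation.
check_scalar <- function(x, name, lower = -Inf, integer = FALSE, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number, got %s.", name, format(x)))
  }
  if (x < lower || x > upper) {
    abort(sprintf(
      "`%s` must be in [%s, %s], got %s.",
      name, format(lower), format(upper), format(x)
    ))
  }
  invisible(x)
}

check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(data)
}

# Bias-corrected sample skewness (G1). corrected = FALSE gives the plain
# moment estimator g1 = m3 / m2^(3/2).
#' Sample skewness and excess kurtosis
#'
#' Moment-based estimators of the shape of a distribution, used by
#' [asymmetry_diagnostics()] on the signed side differences. The corrected
#' versions are the usual bias-corrected G1 and G2 statistics; the
#' uncorrected versions are the plain moment ratios (for which an
#' equal-frequency two-point sample has excess kurtosis exactly -2).
#'
#' @param x Numeric vector.
#' @param corrected Apply the small-sample bias correction? Default `TRUE`.
#' @return A single numeric value.
#' @examples
#' sample_kurtosis(rep(c(-1, 1), 50), corrected = FALSE) # exactly -2
#' @export
sample_skewness <- function(x, corrected = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  if (m2 == 0) return(0)
  g1 <- m3 / m2^1.5
  if (!corrected) return(g1)
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' @rdname sample_skewness
#' @export
sample_kurtosis <- function(x, corrected = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  if (m2 == 0) return(0)
  g2 <- m4 / m2^2 - 3
  if (!corrected) return(g2)
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

# Exact-moment standard errors of G1 / G2 under normality; the large-n
# limits are sqrt(6/n) and sqrt(24/n).
se_skewness <- function(n) {
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

se_kurtosis <- function(n) {
  2 * se_skewness(n) * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
}

# lognormal sdlog that yields a given coefficient of variation.
sdlog_for_cv <- function(cv) sqrt(log(1 + cv^2))

# Significance stars at the 0.10 / 0.05 / 0.01 tiers used throughout the
# correlation tables.
p_stars <- function(p, tiers = c(0.10, 0.05, 0.01)) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    strrep("*", sum(pi < tiers))
  }, character(1))
}
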