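#' Natural-log transform with validation
#'
#' Applied to trait values before ANCOVA-style analyses to reduce variance
#' heterogeneity. Non-positive values are an error that lists the offending
#' positions.
#'
#' @param x Positive numeric vector.
#' @return `log(x)`.
#' @export
log_transform <- function(x) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad) > 0) {
    abort(sprintf("log transform requires positive values; offending row(s): %s.",
                  paste(head(bad, 10), collapse = ", ")))
  }
  log(x)
}

#' Factorial ANCOVA with partial (Type III) term tests
#'
#' Fits a fixed-effects linear model with the supplied factors fully
#' crossed plus an optional covariate, using sum-to-zero contrasts, and
#' reports partial (Type III style) sums of squares per term -- each term
#' tested against the model containing all other terms. If empty cells make
#' an interaction inestimable, the affected highest-order interactions are
#' dropped with a warning. `type = "I"` gives sequential sums of squares
#' instead.
#'
#' @param data Table of observations.
#' @param response Response column name (string).
#' @param factors Character vector of factor column names.
#' @param covariate Optional covariate column name.
#' @param type `"III"` (default) or `"I"`.
#' @param transform `"identity"` or `"log"` applied to the response via
#'   [log_transform()].
#' @return An object of class `phenostab_ancova`; [tidy()] gives the term
#'   table (`term`, `sumsq`, `df`, `meansq`, `statistic`, `p_value`),
#'   [glance()] the fit summary.
#' @export
ancova <- function(data, response, factors, covariate = NULL,
                   type = c("III", "I"), transform = c("identity", "log")) {
  type <- match.arg(type)
  transform <- match.arg(transform)
  check_columns(data, c(response, factors, covariate), "`data`")
  df <- data[stats::complete.cases(data[, c(response, factors, covariate)]), ,
             drop = FALSE]
  y <- df[[response]]
  if (transform == "log") y <- log_transform(y)
  model_df <- data.frame(.y = y)
  for (f in factors) model_df[[f]] <- droplevels(as.factor(df[[f]]))
  if (!is.null(covariate)) model_df[[covariate]] <- df[[covariate]]

  terms_rhs <- paste(factors, collapse = " * ")
  if (!is.null(covariate)) terms_rhs <- paste(terms_rhs, "+", covariate)
  contrast_list <- setNames(
    replicate(length(factors), contr.sum, simplify = FALSE), factors
  )
  fit_formula <- function(rhs) {
    lm(as.formula(paste(".y ~", rhs)), data = model_df,
       contrasts = contrast_list)
  }
  fit <- fit_formula(terms_rhs)
  # empty cells: drop aliased interactions from the top order down
  while (anyNA(coef(fit))) {
    trm <- attr(stats::terms(fit), "term.labels")
    ord <- attr(stats::terms(fit), "order")
    drop <- trm[ord == max(ord)]
    warn(sprintf("Empty cells: dropping inestimable term(s) %s.",
                 paste(drop, collapse = ", ")))
    keep <- setdiff(trm, drop)
    if (length(keep) == 0) abort("Design is rank deficient; no terms estimable.")
    fit <- fit_formula(paste(keep, collapse = " + "))
  }

  if (type == "III") {
    tab <- car::Anova(fit, type = "III")
    tab <- as.data.frame(tab)
    tab$term <- rownames(tab)
    tab <- tab[!tab$term %in% c("(Intercept)"), ]
    res <- tab[tab$term == "Residuals", ]
    tab <- tab[tab$term != "Residuals", ]
    table <- tibble::tibble(
      term = tab$term, sumsq = tab$`Sum Sq`, df = tab$Df,
      meansq = tab$`Sum Sq` / tab$Df,
      statistic = tab$`F value`, p_value = tab$`Pr(>F)`
    )
    resid_row <- tibble::tibble(
      term = "Residuals", sumsq = res$`Sum Sq`, df = res$Df,
      meansq = res$`Sum Sq` / res$Df, statistic = NA_real_, p_value = NA_real_
    )
  } else {
    tab <- as.data.frame(anova(fit))
    tab$term <- rownames(tab)
    res <- tab[tab$term == "Residuals", ]
    tab <- tab[tab$term != "Residuals", ]
    table <- tibble::tibble(
      term = tab$term, sumsq = tab$`Sum Sq`, df = tab$Df,
      meansq = tab$`Mean Sq`, statistic = tab$`F value`,
      p_value = tab$`Pr(>F)`
    )
    resid_row <- tibble::tibble(
      term = "Residuals", sumsq = res$`Sum Sq`, df = res$Df,
      meansq = res$`Mean Sq`, statistic = NA_real_, p_value = NA_real_
    )
  }
  structure(
    list(table = dplyr::bind_rows(table, resid_row),
         response = response, factors = factors, covariate = covariate,
         ss_type = type, transform = transform, fit = fit,
         n = nrow(model_df)),
    class = "phenostab_ancova"
  )
}

#' @export
print.phenostab_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA (%s SS) of %s%s\n", x$ss_type,
              if (x$transform == "log") "log " else "", x$response))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Least Significant Difference comparisons with letter display
#'
#' All-pairs t tests on a pooled residual mean square: for groups `i`, `j`,
#' `t = (m_i - m_j) / sqrt(MSE * (1/n_i + 1/n_j))` on the residual df.
#' Pairs with `p < alpha` are declared different (a pair landing exactly at
#' `p == alpha` is *not* significant). Groups are then labelled with a
#' compact letter display (insert-and-absorb): groups sharing any letter are
#' not significantly different, with `"a"` assigned starting from the
#' smallest mean. A zero residual MS flags all unequal means
#' as different.
#'
#' @param means Named numeric vector of (adjusted) group means, or an
#'   [adjusted_means()] object (in which case `mse`, `df_error` and `n` are
#'   taken from it).
#' @param mse Pooled residual mean square.
#' @param df_error Residual degrees of freedom.
#' @param n Per-group sample sizes (scalar or vector matching `means`).
#' @param alpha Significance level, default 0.05.
#' @return A tibble `group`, `mean`, `n`, `letters`, with the pairwise
#'   p-value matrix in attribute `"pairwise_p"`.
#' @export
lsd_compare <- function(means, mse = NULL, df_error = NULL, n = NULL,
                        alpha = 0.05) {
  if (inherits(means, "adjusted_means")) {
    am <- means
    means <- setNames(am$means$adjusted_mean, am$means$level)
    mse <- am$residual_ms
    df_error <- am$df_residual
    n <- am$means$n
  }
  if (is.null(names(means))) names(means) <- seq_along(means)
  k <- length(means)
  if (k < 2) abort("LSD comparisons need at least 2 groups.")
  if (is.null(mse) || is.null(df_error) || is.null(n)) {
    abort("`mse`, `df_error` and `n` are required.")
  }
  if (df_error < 1) abort("Residual df must be at least 1.")
  n <- rep_len(n, k)

  pmat <- matrix(NA_real_, k, k, dimnames = list(names(means), names(means)))
  diff_mat <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- means[i] - means[j]
      if (mse <= 0) {
        p <- if (d == 0) 1 else 0
      } else {
        t <- d / sqrt(mse * (1 / n[i] + 1 / n[j]))
        p <- 2 * pt(-abs(t), df_error)
      }
      pmat[i, j] <- pmat[j, i] <- p
      diff_mat[i, j] <- diff_mat[j, i] <- p < alpha
    }
  }

  letters <- cld_insert_absorb(diff_mat, order(means))
  out <- tibble::tibble(
    group = names(means), mean = unname(means), n = n,
    letters = letters
  )
  attr(out, "pairwise_p") <- pmat
  attr(out, "alpha") <- alpha
  out
}

# Compact letter display by insert-and-absorb. diff_mat[i, j] TRUE when
# groups i and j differ significantly; ord gives the display order used to
# assign letters (largest mean first).
cld_insert_absorb <- function(diff_mat, ord) {
  k <- nrow(diff_mat)
  sets <- list(seq_len(k))
  absorb <- function(sets) {
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
            length(sets[[a]]) < length(sets[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    sets[keep]
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!diff_mat[i, j]) next
      repeat {
        hit <- Position(function(s) all(c(i, j) %in% s), sets)
        if (is.null(hit) || is.na(hit)) break
        sets <- append(sets[-hit], list(setdiff(sets[[hit]], i),
                                        setdiff(sets[[hit]], j)))
        sets <- absorb(sets)
      }
    }
  }
  sets <- sets[lengths(sets) > 0]
  # order letter sets by the best-ranked member, assign a, b, c, ...
  rank_of <- order(ord)
  sets <- sets[order(vapply(sets, function(s) min(rank_of[s]), numeric(1)))]
  letters_out <- character(k)
  for (s in seq_along(sets)) {
    letters_out[sets[[s]]] <- paste0(letters_out[sets[[s]]], letters[s])
  }
  letters_out
}

#' Pearson correlation with t-based test
#'
#' Product-moment correlation between two columns, with the two-sided
#' t-test p-value. Constant input is an error.
#'
#' @param data Table containing the variables.
#' @param x,y Column names (strings).
#' @return One-row tibble: `x`, `y`, `r`, `df`, `p_value`, `kind` (`"PCC"`),
#'   `n`.
#' @export
pearson_corr <- function(data, x, y) {
  check_columns(data, c(x, y), "`data`")
  keep <- complete.cases(data[, c(x, y)])
  xv <- data[[x]][keep]; yv <- data[[y]][keep]
  n <- length(xv)
  if (n < 3) abort("Pearson correlation needs at least 3 complete pairs.")
  if (var(xv) == 0 || var(yv) == 0) {
    abort("Correlation is undefined for constant input.")
  }
  ct <- cor.test(xv, yv)
  tibble::tibble(
    x = x, y = y, r = unname(ct$estimate), df = unname(ct$parameter),
    p_value = ct$p.value, kind = "PCC", n = n
  )
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlation between the residuals of `x` and `y` after each is regressed
#' on the covariates; the t test uses `df = n - 2 - k` for `k` covariates.
#' With no covariates this is exactly the plain Pearson correlation.
#' Collinear covariates, or a covariate that leaves a variable with zero
#' residual variance, are errors.
#'
#' @param data Table containing the variables.
#' @param x,y Column names (strings).
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @return One-row tibble: `x`, `y`, `covariates` (comma-collapsed), `r`,
#'   `df`, `p_value`, `kind` (`"PPCC"`, or `"PCC"` when no covariates), `n`.
#' @export
partial_corr <- function(data, x, y, covariates = character()) {
  check_columns(data, c(x, y, covariates), "`data`")
  keep <- complete.cases(data[, c(x, y, covariates)])
  df <- data[keep, , drop = FALSE]
  n <- nrow(df)
  k <- length(covariates)
  if (n < k + 3) {
    abort(sprintf("Partial correlation needs at least %d complete rows for %d covariate(s).",
                  k + 3, k))
  }
  if (k == 0) {
    out <- pearson_corr(df, x, y)
    out$covariates <- ""
    return(out[, c("x", "y", "covariates", "r", "df", "p_value", "kind", "n")])
  }
  Z <- model.matrix(as.formula(paste("~", paste(covariates, collapse = "+"))),
                    data = df)
  if (qr(Z)$rank < ncol(Z)) abort("Covariates are collinear.")
  rx <- resid(lm.fit_wrap(Z, df[[x]]))
  ry <- resid(lm.fit_wrap(Z, df[[y]]))
  if (var(rx) < .Machine$double.eps^0.75 * max(var(df[[x]]), 1) ||
      var(ry) < .Machine$double.eps^0.75 * max(var(df[[y]]), 1)) {
    abort("A variable has no residual variance after removing the covariates.")
  }
  r <- cor(rx, ry)
  dfree <- n - 2 - k
  tstat <- r * sqrt(dfree / (1 - r^2))
  tibble::tibble(
    x = x, y = y, covariates = paste(covariates, collapse = ","),
    r = r, df = dfree, p_value = 2 * pt(-abs(tstat), dfree),
    kind = "PPCC", n = n
  )
}

lm.fit_wrap <- function(X, y) stats::lm.fit(X, y)

#' Test for a difference in slopes between two groups
#'
#' Fits the pooled interaction model `y ~ x * group` and reports the
#' interaction t test (the significance of the slope difference), together
#' with the per-group slopes and their standard errors from separate
#' regressions. Requires exactly two groups, each with at least 3 points
#' and non-constant `x`.
#'
#' @param data Table containing the variables.
#' @param x,y,group Column names (strings).
#' @return An object of class `slope_comparison`; [tidy()] returns the
#'   per-group slope table, [glance()] the interaction test.
#' @export
slope_difference_test <- function(data, x, y, group) {
  check_columns(data, c(x, y, group), "`data`")
  keep <- complete.cases(data[, c(x, y, group)])
  df <- data[keep, , drop = FALSE]
  g <- droplevels(as.factor(df[[group]]))
  if (nlevels(g) != 2) abort("Exactly 2 groups are required.")
  for (lv in levels(g)) {
    sub <- df[g == lv, , drop = FALSE]
    if (nrow(sub) < 3) abort(sprintf("Group `%s` has fewer than 3 points.", lv))
    if (var(sub[[x]]) == 0) abort(sprintf("Group `%s` has constant x.", lv))
  }
  model_df <- data.frame(y = df[[y]], x = df[[x]], g = g)
  fit <- lm(y ~ x * g, data = model_df)
  sm <- summary(fit)$coefficients
  int_row <- grep("^x:g", rownames(sm))

  slopes <- purrr::map_dfr(levels(g), function(lv) {
    sub <- model_df[model_df$g == lv, ]
    sfit <- summary(lm(y ~ x, data = sub))$coefficients
    tibble::tibble(group = lv, n = nrow(sub),
                   slope = sfit["x", "Estimate"],
                   se = sfit["x", "Std. Error"])
  })
  structure(
    list(
      slopes = slopes, x = x, y = y,
      statistic = sm[int_row, "t value"],
      df = fit$df.residual,
      p_value = sm[int_row, "Pr(>|t|)"],
      slope_diff = slopes$slope[2] - slopes$slope[1],
      fit = fit
    ),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Slope difference test: %s ~ %s\n", x$y, x$x))
  print(as.data.frame(x$slopes), row.names = FALSE)
  cat(sprintf("interaction t = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
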