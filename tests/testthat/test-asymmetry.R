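test_that("leaf summaries average replicates and derive differences", {
  lv <- leaf_fixture(list(
    list(right = c(10.0, 10.2), left = c(9.8, 10.0))
  ))
  s <- summarize_leaves(lv)
  expect_equal(s$r_bar, 10.1)
  expect_equal(s$l_bar, 9.9)
  expect_equal(s$signed_diff, 0.2)
  expect_equal(s$abs_diff, 0.2)
  expect_equal(s$leaf_size, 10.0)

  same <- summarize_leaves(leaf_fixture(list(
    list(right = c(7, 7), left = c(7, 7))
  )))
  expect_equal(same$signed_diff, 0)
  expect_equal(same$leaf_size, 7)
})

test_that("a three-leaf fixture matches the hand-computed summary", {
  lv <- leaf_fixture(list(
    list(right = c(10.0, 10.2), left = c(9.8, 10.0)),
    list(right = c(8.4, 8.6), left = c(8.9, 9.1)),
    list(right = c(12, 12), left = c(12, 12))
  ))
  s <- summarize_leaves(lv)
  expect_equal(s$signed_diff, c(0.2, -0.5, 0))
  expect_equal(s$leaf_size, c(10.0, 8.75, 12))
  expect_equal(fa1(s), (0.2 + 0.5 + 0) / 3)
  expect_equal(fa2(s), (0.2 / 10 + 0.5 / 8.75 + 0) / 3)
})

test_that("incomplete leaves are excluded with a message", {
  lv <- leaf_fixture(list(
    list(right = c(10, 10.1), left = c(9.9, 10)),
    list(right = c(8, 8.1), left = numeric(0)) # missing side
  ))
  expect_message(s <- summarize_leaves(lv), "1 incomplete")
  expect_equal(nrow(s), 1)
  expect_equal(attr(s, "n_excluded"), 1)
})

test_that("fa1 and fa2 follow their defining formulas", {
  s <- summary_fixture(c(1, -1, 2), leaf_size = c(10, 10, 10))
  expect_equal(fa1(s), 4 / 3)
  expect_equal(fa1(summary_fixture(c(0, 0), c(5, 5))), 0)

  pairs <- summary_fixture(c(2, 0), leaf_size = c(2, 2)) # (R,L)=(3,1),(2,2)
  expect_equal(fa2(pairs), 0.5)
  expect_equal(fa2(summary_fixture(c(0, 0, 0), c(3, 4, 5))), 0)

  # scale invariance of FA2: doubling all widths leaves it unchanged
  s2 <- summary_fixture(c(0.4, -0.2, 0.1) * 2, leaf_size = c(8, 9, 10) * 2)
  s1 <- summary_fixture(c(0.4, -0.2, 0.1), leaf_size = c(8, 9, 10))
  expect_equal(fa2(s2), fa2(s1))

  expect_error(fa1(summary_fixture(numeric(0), numeric(0))), "at least one")
  neg <- summary_fixture(0.1, leaf_size = -1)
  expect_error(fa2(neg), "positive")
})

test_that("sides ANOVA reproduces a brute-force least-squares oracle", {
  set.seed(501)
  lv <- simulate_leaf_pair(runif(4, 8, 12),
                           asymmetry_model(sigma_fa = 1, da_offset = 0.3,
                                           sigma_me = 0.2, size_slope = 0),
                           m = 2)
  lv$individual_id <- "u"
  sa <- sides_anova(lv)
  ref <- anova(lm(width ~ side * factor(leaf), data = lv))
  expect_equal(sa$ms_s, ref["side", "Mean Sq"], tolerance = 1e-9)
  expect_equal(sa$ms_si, ref["side:factor(leaf)", "Mean Sq"], tolerance = 1e-9)
  expect_equal(sa$ms_m, ref["Residuals", "Mean Sq"], tolerance = 1e-9)
  expect_equal(sa$table$df, c(1, 3, 3, 8))
})

test_that("sums of squares decompose exactly on balanced inputs", {
  set.seed(502)
  for (i in 1:5) {
    n <- sample(3:10, 1)
    m <- sample(2:4, 1)
    lv <- simulate_leaf_pair(runif(n, 5, 15),
                             asymmetry_model(sigma_fa = 0.8, sigma_me = 0.3,
                                             size_slope = 0),
                             m = m)
    lv$individual_id <- "u"
    sa <- sides_anova(lv)
    ss_total <- sum((lv$width - mean(lv$width))^2)
    expect_equal(sum(sa$table$sumsq), ss_total, tolerance = 1e-9)
  }
})

test_that("degenerate inputs give the expected mean squares", {
  flat <- leaf_fixture(list(
    list(right = c(9, 9), left = c(9, 9)),
    list(right = c(9, 9), left = c(9, 9))
  ))
  sa <- sides_anova(flat)
  expect_equal(sa$ms_s, 0)
  expect_equal(sa$ms_si, 0)
  expect_equal(sa$ms_m, 0)

  # pure directional offset, varying sizes, no noise
  da <- leaf_fixture(list(
    list(right = c(10.5, 10.5), left = c(9.5, 9.5)),
    list(right = c(12.5, 12.5), left = c(11.5, 11.5)),
    list(right = c(8.5, 8.5), left = c(7.5, 7.5))
  ))
  sa <- sides_anova(da)
  expect_gt(sa$ms_s, 0)
  expect_equal(sa$ms_si, 0)
  expect_equal(sa$ms_m, 0)

  expect_error(sides_anova(leaf_fixture(list(
    list(right = 10, left = 9),
    list(right = 11, left = 10)
  ))), "M >= 2")
  expect_error(sides_anova(leaf_fixture(list(
    list(right = c(10, 10), left = c(9, 9)),
    list(right = c(11, 11, 11), left = c(10, 10, 10))
  ))), "Unbalanced")
})

test_that("fa10 applies the variance-component formula and flags negatives", {
  fake <- function(ms_si, ms_m, m) {
    structure(list(ms_si = ms_si, ms_m = ms_m, m = m, n_units = 10),
              class = "sides_anova")
  }
  # MS_si = MS_m: zero either way, no flag
  z <- fa10(fake(0.5, 0.5, 2))
  expect_equal(z$fa10, 0)
  expect_false(z$negative_s2)

  # direct substitution of the printed component form
  comp <- fa10(fake(2, 0, 2), variant = "component")
  expect_equal(comp$fa10, 0.798)
  expect_equal(fa10(fake(2, 0, 2))$fa10, 0.798 * sqrt(2))

  neg <- fa10(fake(0.1, 0.5, 2))
  expect_true(neg$negative_s2)
  expect_equal(neg$fa10, 0)
})

test_that("fa1 and fa10 agree without measurement error and diverge with it", {
  set.seed(503)
  asym_clean <- asymmetry_model(sigma_fa = 1, sigma_me = 0, size_slope = 0)
  lv <- simulate_leaf_pair(runif(4000, 8, 12), asym_clean, m = 2)
  lv$individual_id <- "a"
  s <- summarize_leaves(lv)
  f1 <- fa1(s)
  f10 <- fa10(sides_anova(lv))$fa10
  expect_equal(f1, 0.798, tolerance = 0.03)
  expect_equal(f10, 0.798, tolerance = 0.03)
  expect_equal(f1, f10, tolerance = 0.02)

  asym_noisy <- asymmetry_model(sigma_fa = 1, sigma_me = 0.3, size_slope = 0)
  lv <- simulate_leaf_pair(runif(4000, 8, 12), asym_noisy, m = 2)
  lv$individual_id <- "a"
  f1n <- fa1(summarize_leaves(lv))
  f10n <- fa10(sides_anova(lv))$fa10
  expect_gt(f1n, 0.81) # inflated by replicate-mean error
  expect_equal(f10n, 0.798, tolerance = 0.04) # corrected
})

test_that("moment estimators and diagnostics behave on canonical shapes", {
  two_point <- rep(c(-1, 1), 50)
  expect_equal(sample_kurtosis(two_point, corrected = FALSE), -2)
  expect_equal(sample_skewness(c(-2, -1, 0, 1, 2)), 0)

  set.seed(504)
  anti <- simulated_summary(
    200, asymmetry_model(sigma_fa = 0.1, antisym_delta = 1, sigma_me = 0,
                         size_slope = 0)
  )
  d <- asymmetry_diagnostics(anti)
  expect_lt(d$gamma2, 0)
  expect_lt(d$p_gamma2, 0.05)
  expect_equal(d$classification, "antisymmetry_suspected")

  da <- simulated_summary(
    200, asymmetry_model(sigma_fa = 0.3, da_offset = 0.5, sigma_me = 0,
                         size_slope = 0)
  )
  dd <- asymmetry_diagnostics(da)
  expect_lt(dd$p_da, 0.01)
  expect_equal(dd$classification, "directional_asymmetry_suspected")

  tiny <- summary_fixture(c(0.1, -0.2, 0.3), leaf_size = c(9, 10, 11))
  dt <- suppressWarnings(asymmetry_diagnostics(tiny))
  expect_true(is.na(dt$p_gamma2))
  expect_equal(dt$classification, "ok")
})

test_that("size-dependence regression matches the normal-equations oracle", {
  s <- summary_fixture(rep(0.1, 4) * c(8, 9, 10, 11) + 1e-6 * c(1, -1, 1, -1),
                       leaf_size = c(8, 9, 10, 11))
  fit <- size_dependence(s)
  expect_equal(fit$slope, 0.1, tolerance = 1e-4)
  expect_lt(fit$p_value, 1e-6)

  const <- summary_fixture(rep(0.25, 5), leaf_size = c(6, 7, 8, 9, 10))
  expect_equal(suppressWarnings(size_dependence(const))$slope, 0)

  set.seed(505)
  x <- runif(20, 5, 15)
  y <- abs(0.05 * x + rnorm(20, 0, 0.05))
  s <- summary_fixture(y, leaf_size = x)
  fit <- size_dependence(s)
  # closed-form OLS
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, bx, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(y) - bx * mean(x), tolerance = 1e-10)

  expect_error(size_dependence(summary_fixture(c(1, 2, 3), rep(10, 3))),
               "all equal")
})

test_that("per-cell FA tables aggregate individual indices", {
  ex <- simulate_experiment(small_design(seed = 6))
  fa <- fa_table(ex$leaves, ex$individuals, by = c("species", "early"))
  expect_s3_class(fa, "phenostab_fa")
  expect_true(all(c("fa1_mean", "fa10_mean", "fa10_pooled") %in% names(fa)))
  expect_equal(nrow(fa), 16)
  expect_true(all(fa$fa1_mean > 0))
  dg <- diagnostics_table(ex$leaves, ex$individuals, by = c("species", "early"))
  expect_equal(nrow(dg), 16)
  expect_true(all(dg$p_da >= 0 & dg$p_da <= 1, na.rm = TRUE))
})
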