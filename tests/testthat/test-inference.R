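test_that("log transform validates positivity and preserves order", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(exp(1)), 1)
  set.seed(801)
  x <- sort(runif(20, 0.1, 9))
  expect_true(all(diff(log_transform(x)) > 0))
  expect_error(log_transform(c(2, 0, 3)), "row\\(s\\): 2")
})

test_that("single-factor ANCOVA F equals the squared two-sample t", {
  set.seed(802)
  d <- tibble::tibble(g = rep(c("a", "b"), each = 12),
                      y = rnorm(24, rep(c(0, 1), each = 12)))
  a <- ancova(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tidy(a)$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(tidy(a)$p_value[1], tt$p.value, tolerance = 1e-10)
})

test_that("Type III sums of squares match a drop-one least-squares oracle", {
  set.seed(803)
  # unbalanced two-factor layout with covariate
  d <- tibble::tibble(
    f1 = sample(c("a", "b"), 40, replace = TRUE, prob = c(0.7, 0.3)),
    f2 = sample(c("u", "v"), 40, replace = TRUE),
    z = runif(40),
    y = rnorm(40) + (f1 == "a") * 0.5 + z
  )
  a <- ancova(d, "y", c("f1", "f2"), "z")
  tab <- tidy(a)

  # oracle: refit with sum contrasts; each term's SS is the RSS increase
  # from deleting its model-matrix columns while keeping all others
  X <- model.matrix(~ f1 * f2 + z, data = d,
                    contrasts.arg = list(f1 = contr.sum, f2 = contr.sum))
  asg <- attr(X, "assign")
  labels <- c("f1", "f2", "z", "f1:f2")
  full <- lm.fit(X, d$y)
  rss_full <- sum(full$residuals^2)
  for (i in seq_along(labels)) {
    Xr <- X[, asg != i, drop = FALSE]
    rss_r <- sum(lm.fit(Xr, d$y)$residuals^2)
    expect_equal(tab$sumsq[tab$term == labels[i]], rss_r - rss_full,
                 tolerance = 1e-9)
  }
  expect_equal(tab$sumsq[tab$term == "Residuals"], rss_full, tolerance = 1e-9)
})

test_that("ANCOVA term p-values are calibrated under a pure-noise response", {
  set.seed(804)
  p_cov <- vapply(1:200, function(i) {
    d <- tibble::tibble(g = rep(c("a", "b"), each = 10), z = runif(20),
                        y = rnorm(20))
    tidy(ancova(d, "y", "g", "z"))$p_value[2]
  }, numeric(1))
  expect_lt(abs(mean(p_cov < 0.05) - 0.05), 0.045)
  expect_gt(stats::ks.test(p_cov, "punif")$p.value, 0.01)
})

test_that("empty cells collapse the affected interaction with a warning", {
  d <- tibble::tibble(
    f1 = c("a", "a", "a", "a", "b", "b", "b", "b"),
    f2 = c("u", "u", "v", "v", "u", "u", "u", "u"), # no b:v cell
    y = rnorm(8)
  )
  expect_warning(a <- ancova(d, "y", c("f1", "f2")), "dropping")
  expect_false("f1:f2" %in% tidy(a)$term)
})

test_that("LSD comparisons match a direct pairwise t-test oracle", {
  means <- c(g1 = 10, g2 = 12, g3 = 15)
  res <- lsd_compare(means, mse = 4, df_error = 12, n = 5)
  pmat <- attr(res, "pairwise_p")
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    t_oracle <- abs(unname(means[pair[1]] - means[pair[2]])) / sqrt(4 * (2 / 5))
    expect_equal(pmat[pair[1], pair[2]], 2 * pt(-t_oracle, 12),
                 tolerance = 1e-12)
  }
  # g1 vs g2 ns, g1 vs g3 sig, g2 vs g3 sig at alpha = 0.05 here
  expect_equal(res$letters, c("a", "a", "b"))
})

test_that("LSD letter display handles chains and boundary p-values", {
  ident <- lsd_compare(c(a = 3, b = 3, c = 3), mse = 1, df_error = 10, n = 4)
  expect_true(all(ident$letters == "a"))

  # difference engineered to sit exactly at p = alpha: not significant
  df_err <- 10; n <- 4; mse <- 2
  t_crit <- qt(0.975, df_err)
  delta <- t_crit * sqrt(mse * (2 / n))
  res <- lsd_compare(c(a = 0, b = delta), mse = mse, df_error = df_err, n = n)
  expect_equal(attr(res, "pairwise_p")[1, 2], 0.05, tolerance = 1e-12)
  expect_true(all(res$letters == "a"))

  # overlapping chain a-b ns, b-c ns, a-c sig -> b shares both letters
  chain <- lsd_compare(c(a = 0, b = 2.2, c = 4.4), mse = 2, df_error = 10,
                       n = 4)
  expect_equal(chain$letters[chain$group == "b"], "ab")

  zero <- lsd_compare(c(a = 1, b = 2), mse = 0, df_error = 5, n = 3)
  expect_false(any(duplicated(zero$letters)))
})

test_that("Pearson correlation matches the covariance formula", {
  d <- tibble::tibble(x = 1:6, y = 2 * (1:6))
  expect_equal(pearson_corr(d, "x", "y")$r, 1)
  d$y <- -d$x
  expect_equal(pearson_corr(d, "x", "y")$r, -1)

  set.seed(805)
  d <- tibble::tibble(x = rnorm(8), y = rnorm(8))
  r <- pearson_corr(d, "x", "y")
  oracle <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) /
    sqrt(sum((d$x - mean(d$x))^2) * sum((d$y - mean(d$y))^2))
  expect_equal(r$r, oracle, tolerance = 1e-12)
  expect_equal(r$df, 6)

  expect_error(pearson_corr(tibble::tibble(x = rep(1, 5), y = rnorm(5)),
                            "x", "y"), "constant")
})

test_that("partial correlation equals both its recursive and residual forms", {
  set.seed(806)
  d <- tibble::tibble(x = rnorm(20), y = rnorm(20), z = rnorm(20),
                      w = rnorm(20), konst = rep(5, 20))

  # no covariates: exactly the plain Pearson correlation
  expect_equal(partial_corr(d, "x", "y")$r, pearson_corr(d, "x", "y")$r)
  expect_equal(partial_corr(d, "x", "y")$kind, "PCC")

  # one covariate: recursion formula
  rxy <- cor(d$x, d$y); rxz <- cor(d$x, d$z); ryz <- cor(d$y, d$z)
  oracle1 <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_corr(d, "x", "y", "z")$r, oracle1, tolerance = 1e-10)

  # two covariates: recurse once more
  pxw <- partial_corr(d, "x", "w", "z")$r
  pyw <- partial_corr(d, "y", "w", "z")$r
  oracle2 <- (oracle1 - pxw * pyw) / sqrt((1 - pxw^2) * (1 - pyw^2))
  expect_equal(partial_corr(d, "x", "y", c("z", "w"))$r, oracle2,
               tolerance = 1e-10)
  expect_equal(partial_corr(d, "x", "y", c("z", "w"))$df, 20 - 4)

  expect_error(partial_corr(d, "x", "y", "x"), "residual variance")
  d$z2 <- 2 * d$z
  expect_error(partial_corr(d, "x", "y", c("z", "z2")), "collinear")
})

test_that("slope difference test recovers per-group regressions", {
  base <- tibble::tibble(x = rep(1:6, 1), y = c(1.1, 2.2, 2.8, 4.1, 5.2, 5.9))
  ident <- dplyr::bind_rows(
    dplyr::mutate(base, g = "a"),
    dplyr::mutate(base, g = "b")
  )
  res <- slope_difference_test(ident, "x", "y", "g")
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)

  set.seed(807)
  d <- tibble::tibble(
    g = rep(c("a", "b"), each = 10),
    x = rep(1:10, 2),
    y = c(1:10 + rnorm(10, 0, 0.01), -(1:10) + rnorm(10, 0, 0.01))
  )
  res <- slope_difference_test(d, "x", "y", "g")
  expect_lt(res$p_value, 1e-10)
  for (lv in c("a", "b")) {
    sub <- d[d$g == lv, ]
    expect_equal(tidy(res)$slope[tidy(res)$group == lv],
                 unname(coef(lm(y ~ x, sub))[2]), tolerance = 1e-12)
  }
  # interaction estimate equals the slope difference of the two fits
  expect_equal(glance(res)$slope_diff,
               unname(coef(lm(y ~ x, d[d$g == "b", ]))[2] -
                        coef(lm(y ~ x, d[d$g == "a", ]))[2]),
               tolerance = 1e-12)

  bad <- tibble::tibble(g = rep(c("a", "b"), each = 3), x = c(1, 2, 3, 4, 4, 4),
                        y = rnorm(6))
  expect_error(slope_difference_test(bad, "x", "y", "g"), "constant x")
})
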