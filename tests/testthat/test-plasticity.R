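test_that("adjusted means reduce to raw means without covariate signal", {
  d <- tibble::tibble(
    g = rep(c("a", "b"), each = 5),
    y = c(rnorm(5, 10), rnorm(5, 12)),
    z = rep(3, 10) # constant covariate
  )
  expect_warning(am <- adjusted_means(d, "y", "g", "z"), "constant")
  expect_equal(am$means$adjusted_mean, am$means$raw_mean)

  # balanced groups with a covariate orthogonal to the factor
  d2 <- tibble::tibble(
    g = rep(c("a", "b"), each = 4),
    z = rep(c(1, 2, 3, 4), 2),
    y = c(10, 11, 12, 13, 20, 21, 22, 23)
  )
  am2 <- adjusted_means(d2, "y", "g", "z")
  expect_equal(am2$means$adjusted_mean, am2$means$raw_mean)
})

test_that("adjusted means equal the closed-form ANCOVA solution", {
  # known slope 2 and covariate imbalance between groups
  d <- tibble::tibble(
    g = rep(c("a", "b"), each = 4),
    z = c(1, 2, 3, 4, 5, 6, 7, 8),
    y = c(5, 7, 9, 11, 8, 10, 12, 14) + 2 * 0 # y = base_g + 2 z
  )
  am <- adjusted_means(d, "y", "g", "z")
  # oracle via explicit normal equations on the same parameterisation
  fit <- lm(y ~ g + z, data = d)
  zbar <- mean(d$z)
  oracle <- c(
    coef(fit)[1] + coef(fit)["z"] * zbar,
    coef(fit)[1] + coef(fit)["gb"] + coef(fit)["z"] * zbar
  )
  expect_equal(am$means$adjusted_mean, unname(oracle), tolerance = 1e-10)
  expect_equal(am$covariate_coef, 2, tolerance = 1e-10)
  # y = 3 + 2z in group a and y = -2 + 2z in group b, so the adjusted
  # difference is the intercept gap -5 even though raw means differ by +3
  expect_equal(diff(am$means$adjusted_mean), -5, tolerance = 1e-10)
  expect_equal(diff(am$means$raw_mean), 3, tolerance = 1e-10)
})

test_that("plasticity indices follow their defining formulas", {
  r <- compute_pi(2, 3)
  expect_equal(r$pi_rel, 0.5)
  expect_equal(r$pi_abs, 0.5)
  expect_equal(compute_pi(4, 4)$pi_rel, 0)
  expect_equal(compute_pi(1, 1, variant = "srdpi")$pi_rel, 0)
  expect_equal(compute_pi(1, 3, variant = "srdpi")$pi_rel, 0.5)
  expect_error(compute_pi(0, 1), "y1 > 0")
  expect_error(compute_pi(-1, 1, variant = "srdpi"), "y1 \\+ y2")

  # sign coherence and srdpi bounds on random positive pairs
  set.seed(701)
  y1 <- runif(50, 0.1, 5)
  y2 <- runif(50, 0.1, 5)
  ratio <- compute_pi(y1, y2)
  srdpi <- compute_pi(y1, y2, variant = "srdpi")
  expect_equal(ratio$pi_rel > 0, y2 > y1)
  expect_equal(srdpi$pi_rel > 0, y2 > y1)
  expect_true(all(abs(srdpi$pi_rel) < 1))
  expect_equal(ratio$pi_abs, abs(ratio$pi_rel))
})

test_that("plasticity tables recover multiplicative treatment effects", {
  d <- design_config(species = paste0("s", 1:4), reps_late = 40,
                     reps_first_harvest = 2, seed = 21)
  mult <- default_multipliers(d$early, d$late)
  mult$shoot_mass <- ifelse(mult$late == "inundation", 1.5, 1)
  mult$root_mass <- mult$shoot_mass
  mult$leaf_size <- 1
  tr <- trait_model(d$species, multipliers = mult, mortality = 0,
                    cv_inter = 0.3)
  ex <- generate_experiment(d, traits = tr, include_leaves = FALSE)
  pt <- plasticity_table(ex$individuals, traits = "total_mass")
  im <- pt[pt$contrast == "IM", ]
  dm <- pt[pt$contrast == "DM", ]
  expect_equal(mean(im$pi_rel), 0.5, tolerance = 0.05)
  expect_equal(mean(dm$pi_rel), 0, tolerance = 0.05)

  # all-null multipliers: plasticity vanishes within sampling error
  tr0 <- trait_model(d$species,
                     multipliers = dplyr::mutate(mult, shoot_mass = 1,
                                                 root_mass = 1),
                     mortality = 0)
  ex0 <- generate_experiment(d, traits = tr0, seed = 22,
                             include_leaves = FALSE)
  pt0 <- plasticity_table(ex0$individuals, traits = "total_mass")
  expect_equal(mean(pt0$pi_rel), 0, tolerance = 0.05)
})

test_that("contrast labels map to the late treatments symmetrically", {
  d <- design_config(species = "s1", reps_late = 15, reps_first_harvest = 2,
                     seed = 23)
  ex <- generate_experiment(d, include_leaves = FALSE)
  pt <- plasticity_table(ex$individuals, traits = "total_mass")
  swapped <- plasticity_table(ex$individuals, traits = "total_mass",
                              inundation = "drought", drought = "inundation")
  im <- pt[pt$contrast == "IM", c("species", "early", "pi_rel")]
  dm_sw <- swapped[swapped$contrast == "DM", c("species", "early", "pi_rel")]
  expect_equal(dplyr::arrange(im, species, early)$pi_rel,
               dplyr::arrange(dm_sw, species, early)$pi_rel)
})

test_that("missing late-treatment cells skip the contrast with a warning", {
  d <- design_config(species = "s1", reps_late = 8, reps_first_harvest = 2,
                     late = c("moderate", "drought"), seed = 24)
  ex <- generate_experiment(d, include_leaves = FALSE)
  expect_warning(pt <- plasticity_table(ex$individuals, traits = "total_mass"),
                 "Skipped")
  expect_true(all(pt$contrast == "DM"))
})
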