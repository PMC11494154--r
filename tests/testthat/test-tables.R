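# Build species-level summaries directly, to exercise the correlation
# machinery under a controlled generative model.
fake_summary <- function(n_sp = 8, couple = 0, noise = 1) {
  sp <- paste0("s", seq_len(n_sp))
  mk_round1 <- function(e) {
    latent <- rnorm(n_sp)
    tibble::tibble(
      species = sp, early = e, n = 20,
      mean_ls = rnorm(n_sp, 12, 2),
      cv_intra_ls = abs(rnorm(n_sp, 0.15, 0.03)),
      cv_inter_ls = abs(rnorm(n_sp, 0.2, 0.05)),
      cv_inter_tm = abs(rnorm(n_sp, 0.3, 0.05)),
      mean_is = rnorm(n_sp, 60, 10),
      cv_inter_is = abs(rnorm(n_sp, 0.25, 0.05)),
      fa1 = abs(rnorm(n_sp, 0.3, 0.05)),
      fa2 = abs(rnorm(n_sp, 0.03, 0.005)),
      fa10 = 0.3 + couple * latent + noise * 0.05 * rnorm(n_sp),
      .latent = latent
    )
  }
  r1 <- dplyr::bind_rows(mk_round1("E_het"), mk_round1("E_hom"))
  r2 <- tidyr::expand_grid(
    species = sp, early = c("E_het", "E_hom"),
    late = c("inundation", "moderate", "drought")
  ) |>
    dplyr::left_join(r1[, c("species", "early", ".latent")],
                     by = c("species", "early")) |>
    dplyr::mutate(
      n = 10,
      cv_inter_tm = 0.3 + couple * .data$.latent +
        noise * 0.05 * rnorm(dplyr::n()),
      mean_is = rnorm(dplyr::n(), 60, 10),
      cv_inter_is = abs(rnorm(dplyr::n(), 0.25, 0.05))
    ) |>
    dplyr::select(-".latent")
  r1 <- dplyr::select(r1, -".latent")
  structure(list(round1 = r1, round2 = r2), class = "species_summary")
}

fake_pi <- function(n_sp = 8) {
  tidyr::expand_grid(species = paste0("s", seq_len(n_sp)),
                     early = c("E_het", "E_hom"),
                     contrast = c("IM", "DM")) |>
    dplyr::mutate(trait = "total_mass", pi_rel = rnorm(dplyr::n(), 0, 0.2),
                  pi_abs = abs(.data$pi_rel), variant = "ratio")
}

test_that("species summaries carry both rounds with the expected shape", {
  ex <- simulate_experiment(small_design(seed = 31))
  s <- species_summary(ex$individuals, ex$leaves)
  expect_s3_class(s, "species_summary")
  expect_equal(nrow(s$round1), 16) # 8 species x 2 early
  expect_equal(nrow(s$round2), 48) # x 3 late
  expect_true(all(c("fa1", "fa10", "cv_intra_ls", "cv_inter_tm", "mean_is")
                  %in% names(s$round1)))
  expect_true(all(s$round1$cv_inter_tm > 0, na.rm = TRUE))
  # the inter-individual CV of leaf size is computed from per-individual
  # mean leaf sizes and must be present for every cell
  expect_true(all(!is.na(s$round1$cv_inter_ls)))
  expect_true(all(s$round1$cv_inter_ls > 0))
})

test_that("correlation tables have the three published shapes and stars", {
  set.seed(901)
  ct <- correlation_tables(fake_summary(), fake_pi())
  expect_equal(nrow(ct$table3), 2 * choose(5, 2))
  expect_equal(nrow(ct$table4), 2 * 3 * 5)
  expect_equal(nrow(ct$table5), 2 * 2 * (5 + 2))
  expect_true(all(ct$table3$n == 8))
  expect_true(all(ct$table3$p_value >= 0 & ct$table3$p_value <= 1,
                  na.rm = TRUE))
  # star markup lives in its own column, tiered at 0.10 / 0.05 / 0.01
  starred <- ct$table3[!is.na(ct$table3$p_value), ]
  expect_equal(starred$stars == "***", starred$p_value < 0.01)
  expect_equal(nchar(starred$stars) >= 1, starred$p_value < 0.10)

  single <- fake_summary(n_sp = 1)
  expect_error(correlation_tables(single, NULL), "at least 2 species")
})

test_that("an induced FA10 coupling surfaces as a significant correlation", {
  set.seed(902)
  hits <- vapply(1:60, function(i) {
    s <- fake_summary(couple = 0.2, noise = 0.5)
    ct <- correlation_tables(s, NULL)
    row <- ct$table4[ct$table4$x == "fa10" & ct$table4$early == "E_het" &
                       ct$table4$late == "drought", ]
    !is.na(row$r) && row$r > 0 && row$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("star rates stay near nominal under an independent generator", {
  set.seed(903)
  rates <- vapply(1:150, function(i) {
    ct <- correlation_tables(fake_summary(), NULL)
    mean(ct$table3$p_value < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(rates), 0.05, tolerance = 0.03)
})

test_that("slope comparisons cover both contrasts and their CV sources", {
  set.seed(904)
  sc <- slope_comparisons(fake_summary(), fake_pi())
  expect_equal(nrow(sc), 6)
  expect_setequal(unique(sc$contrast), c("IM", "DM"))
  expect_true("moderate" %in% sc$cv_source)
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1, na.rm = TRUE))
})

test_that("three-way effect tables test the species attributes", {
  ex <- simulate_experiment(small_design(seed = 32))
  s <- species_summary(ex$individuals, ex$leaves)
  eff <- effects_table(s, ex$individuals, responses = c("mean_ls", "fa10"))
  expect_true(all(c("early", "nativity", "habitat", "mean_is") %in% eff$term))
  expect_true(all(eff$p_value >= 0 & eff$p_value <= 1, na.rm = TRUE))
  expect_setequal(unique(eff$response), c("mean_ls", "fa10"))
})
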