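# Fixture builders shared across the suite.

# Build a raw leaf table from a list of leaves; each element is
# list(right = c(...), left = c(...)) with equal replicate counts.
leaf_fixture <- function(leaves, id = "plant1") {
  rows <- lapply(seq_along(leaves), function(i) {
    lf <- leaves[[i]]
    tibble::tibble(
      individual_id = id,
      leaf = i,
      side = rep(c("right", "left"), times = c(length(lf$right), length(lf$left))),
      replicate = c(seq_along(lf$right), seq_along(lf$left)),
      width = c(lf$right, lf$left)
    )
  })
  dplyr::bind_rows(rows)
}

# Leaf summary rows built directly (for functions that accept summaries).
summary_fixture <- function(signed_diff, leaf_size, id = "plant1") {
  out <- tibble::tibble(
    individual_id = id,
    leaf = seq_along(signed_diff),
    r_bar = leaf_size + signed_diff / 2,
    l_bar = leaf_size - signed_diff / 2,
    signed_diff = signed_diff,
    abs_diff = abs(signed_diff),
    leaf_size = leaf_size
  )
  class(out) <- c("leaf_summary", class(out))
  out
}

# Simulate n leaves with a given asymmetry model and return their summary.
simulated_summary <- function(n, asym, true_size = 10, m = 2) {
  lv <- simulate_leaf_pair(rep(true_size, n), asym, m = m)
  lv$individual_id <- "sim"
  summarize_leaves(lv)
}

# Tiny design for fast end-to-end runs: 8 species are kept so that
# cross-species correlations remain estimable.
small_design <- function(seed = 1) {
  design_config(
    reps_late = 4, reps_first_harvest = 6,
    leaves_per_individual = c(3, 5),
    seed = seed
  )
}
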