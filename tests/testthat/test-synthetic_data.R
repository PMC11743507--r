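# Generator: determinism, compositional consistency, the no-noise limit,
# effect recovery against the generative formula, and phenotype closed
# forms.

test_that("identical designs give byte-identical simulations", {
  d <- sim_design(seed = 7)
  s1 <- simulate_counts(d)
  s2 <- simulate_counts(d)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(simulate_phenotypes(d, s1$ground_truth),
                   simulate_phenotypes(d, s2$ground_truth))
  # layout: one sample per (mouse, week)
  expect_equal(nrow(s1$counts), 4 * 5 * 2)
  expect_equal(ncol(s1$counts) - 1, 66)
  expect_equal(dplyr::n_distinct(s1$metadata$mouse_id), 20)
  expect_setequal(unique(get_taxonomy(s1$counts)$phylum),
                  unique(d$phylum_assignment$phylum))
})

test_that("counts are compositionally consistent", {
  s <- simulate_counts(sim_design(seed = 11))
  m <- as.matrix(s$counts[-1])
  expect_true(all(m >= 0 & m == round(m)))
  rel <- to_relative(s$counts)
  expect_equal(unname(rowSums(as.matrix(rel[-1]))), rep(1, nrow(rel)),
               tolerance = 1e-12)
})

test_that("the no-noise limit recovers softmax(base)", {
  d <- null_design(seed = 5, n_mice = 3, theta = 1e6)
  d$library_size_log_sd <- 0
  s <- simulate_counts(d)
  rel <- as.matrix(to_relative(s$counts)[-1])
  expected <- exp(d$base_log_abundance) / sum(exp(d$base_log_abundance))
  n_reads <- exp(d$library_size_log_mean)
  for (i in seq_len(nrow(rel))) {
    expect_true(all(abs(rel[i, ] - expected) < 2 / sqrt(n_reads)))
  }
})

test_that("a +1 log-fold effect raises the key genera's mean abundance", {
  # Monte-Carlo check against the generative formula at n_mice = 50
  d <- shifted_design(seed = 23, delta = 1, n_mice = 50)
  key <- d$effect_table$genus[d$effect_table$log_fold > 0]
  s <- simulate_counts(d)
  rel <- to_relative(s$counts)
  m <- as.matrix(rel[-1])
  grp <- s$metadata$group[match(rel$sample_id, s$metadata$sample_id)]
  mean_b <- colMeans(m[grp == "B", key, drop = FALSE])
  mean_a <- colMeans(m[grp == "A", key, drop = FALSE])
  expect_gte(sum(mean_b > mean_a), ceiling(0.9 * length(key)))
})

test_that("ground truth matches the generative design", {
  d <- sim_design(seed = 3)
  gt <- design_ground_truth(d)
  sums <- gt$expected_relative_abundance |>
    dplyr::group_by(group, week) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
  # displacement is zero iff the two cells carry identical effects
  disp <- gt$true_centroid_displacement
  same <- disp[disp$group_a == "HFD+SPSS" & disp$group_b == "HFD+SPSS", ]
  # HFD+SPSS has the same pattern at both weeks by design
  expect_equal(same$displacement, 0, tolerance = 1e-12)
  both_cd <- disp[disp$group_a == "CD+SPSS" & disp$group_b == "CD+SPSS", ]
  expect_equal(both_cd$displacement, 0, tolerance = 1e-12)
  expect_gt(disp$displacement[disp$group_a == "CD+SPSS" &
                                disp$group_b == "HFD+SPSS" &
                                disp$week_a == 10 & disp$week_b == 10], 0)
  expect_setequal(gt$genera_truly_shifted, d$key_taxa)
})

test_that("phenotype deltas follow the closed-form trajectory model", {
  # zero slopes, zero coupling, zero noise: every delta is exactly 0
  d0 <- sim_design(seed = 9, bw_group_slopes = 0, fbg_group_slopes = 0,
                   bw_noise_sd = 0, fbg_noise_sd = 0, coupling = 0)
  ph <- simulate_phenotypes(d0)
  deltas <- group_delta(ph, week_ref = 4, week_end = 10)
  expect_equal(deltas$delta_bw, rep(0, 4), tolerance = 1e-12)
  expect_equal(deltas$delta_fbg, rep(0, 4), tolerance = 1e-12)

  # slope s, zero noise: group delta over 6 weeks is exactly 6 s
  d1 <- sim_design(seed = 9, bw_group_slopes = 0.7, fbg_group_slopes = -0.3,
                   bw_noise_sd = 0, fbg_noise_sd = 0, coupling = 0)
  deltas1 <- group_delta(simulate_phenotypes(d1))
  expect_equal(deltas1$delta_bw, rep(6 * 0.7, 4), tolerance = 1e-10)
  expect_equal(deltas1$delta_fbg, rep(6 * -0.3, 4), tolerance = 1e-10)

  # untreated high-fat arm stays above the diabetic threshold on average
  ph_def <- simulate_phenotypes(sim_design(seed = 2))
  hf <- group_delta(ph_def, group = "HFD+SPSS")
  expect_gt(hf$fbg_mean_ref, 9.5)
})

test_that("coupling links community shift to phenotype change", {
  # graded group shifts with kappa > 0: group-level Pearson correlation
  # between mean shift and delta FBG is positive at large n
  d <- sim_design(groups = c("g1", "g2", "g3", "g4"),
                  n_mice_per_group = 40, seed = 31, coupling = 2,
                  bw_group_slopes = 0, fbg_group_slopes = 0,
                  effect_table = NULL)
  # graded effects: each group shifts the key taxa by a different amount
  key <- d$key_taxa
  pat <- rep_len(c(1, -1), length(key))
  d$effect_table <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(group = paste0("g", i), week = 10L, genus = key,
                   log_fold = pat * (i - 1) * 0.5)
  }))
  s <- simulate_counts(d)
  ph <- simulate_phenotypes(d, s$ground_truth)
  deltas <- group_delta(ph)
  shifts <- s$ground_truth$mouse_shift |>
    dplyr::group_by(group) |>
    dplyr::summarise(shift = mean(shift), .groups = "drop")
  joined <- dplyr::inner_join(deltas, shifts, by = "group")
  expect_gt(cor(joined$shift, joined$delta_fbg), 0)
})

test_that("effect_grid scales effects and preserves ordering", {
  d <- shifted_design(seed = 1, delta = 1)
  grid <- effect_grid(d, c(0, 0.5, 1))
  expect_length(grid, 3)
  expect_equal(max(abs(grid[[1]]$effect_table$log_fold)), 0)
  expect_equal(max(abs(grid[[2]]$effect_table$log_fold)), 0.5)
  expect_equal(max(abs(grid[[3]]$effect_table$log_fold)), 1)
  disp <- vapply(grid, function(g) {
    gt <- design_ground_truth(g)
    max(gt$true_centroid_displacement$displacement)
  }, numeric(1))
  expect_true(all(diff(disp) >= 0))
  expect_error(effect_grid(d, c(1, 0.5)), class = "ms_parameter_error")
  expect_error(effect_grid(d, c(-1, 0)), class = "ms_parameter_error")
})

test_that("invalid design parameters are rejected", {
  expect_error(sim_design(theta = 0), class = "ms_parameter_error")
  expect_error(sim_design(bw_noise_sd = -1), class = "ms_parameter_error")
  expect_error(
    sim_design(effect_table = tibble::tibble(
      group = "nope", week = 4L, genus = "genus_01", log_fold = 1)),
    class = "ms_parameter_error")
})
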