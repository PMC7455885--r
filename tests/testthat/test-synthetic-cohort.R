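test_that("config validation names the offending field", {
  expect_error(cohort_config(n_cases = 0), "n_cases")
  expect_error(cohort_config(fa_sd_control = -1), "fa_sd_control")
  expect_error(cohort_config(grid_shape = c(8, 32, 32)), "grid_shape")
  expect_error(cohort_config(noise_sd = 5), "noise_sd")
  expect_error(cohort_config(scans_per_subject = 4), "scans_per_subject")
  expect_error(cohort_config(drift_per_interval = c(BAD = 1)),
               "drift_per_interval")
})

test_that("cohort has the configured size, labels and determinism", {
  cfg <- tiny_config()
  co <- generate_cohort(cfg)
  expect_length(co, 4L)
  expect_equal(sum(vapply(co, `[[`, "", "group") == "case"), 2L)
  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)  # bit-identical volumes under one seed
})

test_that("scans of one subject share one grid and increase in time", {
  co <- generate_cohort(tiny_config())
  for (subj in co) {
    times <- vapply(subj$scans, `[[`, 0, "time_years")
    expect_true(all(diff(times) > 0))
    expect_equal(times[length(times)], 0)  # index scan at t = 0
    dims <- lapply(subj$scans, function(s) dim(s$volumes$FA))
    expect_length(unique(dims), 1L)
    for (s in subj$scans)
      expect_setequal(names(s$volumes), OPG_MODALITIES)
  }
})

test_that("progression indicators exist exactly for cases", {
  co <- generate_cohort(tiny_config())
  for (subj in co) {
    has_flag <- any(subj$radiographic_flags)
    va <- subj$va_series$logmar_od
    has_va <- any(diff(va) >= 0.2)
    if (subj$group == "case") expect_true(has_flag || has_va)
    else expect_false(has_flag || has_va)
  }
})

test_that("tube mask is a digital cylinder with the requested radius", {
  # straight axial path, radius 3 mm, 1 mm spacing: every slice crossed by
  # the path is the digital disk of radius 3
  path <- cbind(10, 10, seq(4, 16))
  tm <- generate_tube_mask(c(21, 21, 21), c(1, 1, 1), path, 3, "ON_L")
  disk <- outer(0:20, 0:20, function(i, j) (i - 10)^2 + (j - 10)^2 <= 9)
  for (z in 6:14) expect_equal(tm$mask[, , z + 1], disk)
  expect_error(generate_tube_mask(c(21, 21, 21), c(1, 1, 1), path, 0.4),
               "geometry error")
  expect_error(generate_tube_mask(c(21, 21, 21), c(1, 1, 1),
                                  cbind(10, 10, c(0, 40)), 3),
               "geometry error")
})

test_that("tube voxel volume tracks the analytic cylinder volume", {
  tm <- make_cylinder_mask(radius_mm = 5, length_mm = 20)
  expect_lt(abs(compute_volume(tm) - pi * 25 * 20) / (pi * 25 * 20), 0.15)
})

test_that("streamline sets honour the decoy fraction and the seed", {
  g <- c(24L, 24L, 24L); sp <- c(1, 1, 1)
  roi_a <- opgpredict:::make_box_mask(g, sp, c(4, 4, 12), c(2, 2, 2), "ROI_A")
  roi_b <- opgpredict:::make_box_mask(g, sp, c(19, 19, 12), c(2, 2, 2), "ROI_B")
  sl0 <- generate_streamlines(roi_a, roi_b, n_lines = 10, decoy_fraction = 0,
                              seed = 3)
  expect_equal(filter_streamlines(sl0, roi_a, roi_b)$count, 10L)
  sl5 <- generate_streamlines(roi_a, roi_b, n_lines = 10,
                              decoy_fraction = 0.5, seed = 3)
  expect_equal(filter_streamlines(sl5, roi_a, roi_b)$count, 5L)
  sl5b <- generate_streamlines(roi_a, roi_b, n_lines = 10,
                               decoy_fraction = 0.5, seed = 3)
  expect_identical(sl5$lines, sl5b$lines)
  expect_error(generate_streamlines(
    opgpredict::region_mask(array(FALSE, g), "ROI_A", sp), roi_b, 5),
    "geometry error")
})

test_that("the two-level FA sampler has the configured group marginal", {
  # a fresh latent per draw makes voxel draws iid with marginal exactly
  # the configured group normal, so the KS test applies directly;
  # alpha = 0.01 with n >= 1e4 draws per group
  set.seed(101)
  noise <- 0.5
  for (g in list(c(6.23, 3.56), c(2.38, 1.79))) {
    lat <- opgpredict:::.subject_latent(stats::runif(2e4), g[1], g[2], noise)
    v <- opgpredict:::.draw_region_intensity(2e4, lat, noise)
    ks <- suppressWarnings(stats::ks.test(v, "pnorm", g[1], g[2]))
    expect_gt(ks$p.value, 0.01)
    # subject latents carry the between-subject component
    ks1 <- suppressWarnings(stats::ks.test(lat, "pnorm", g[1],
                                           sqrt(g[2]^2 - noise^2)))
    expect_gt(ks1$p.value, 0.01)
  }
})

test_that("cohort subject OR-mean FA reproduces the printed group moments", {
  cfg <- cohort_config(n_cases = 150, n_controls = 150,
                       scans_per_subject = 1, grid_shape = c(16, 16, 16),
                       seed = 5)
  co <- generate_cohort(cfg)
  or_mean <- vapply(co, function(s) {
    m <- s$masks[[1]]$OR_L$mask | s$masks[[1]]$OR_R$mask
    mean(s$scans[[1]]$volumes$FA[m])
  }, numeric(1))
  grp <- vapply(co, `[[`, "", "group")
  sdb_c <- sqrt(3.56^2 - cfg$noise_sd^2)
  sdb_0 <- sqrt(1.79^2 - cfg$noise_sd^2)
  expect_lt(abs(mean(or_mean[grp == "case"]) - 6.23), 3 * 3.56 / sqrt(150))
  expect_lt(abs(mean(or_mean[grp == "control"]) - 2.38), 3 * 1.79 / sqrt(150))
  expect_lt(abs(stats::sd(or_mean[grp == "case"]) - sdb_c) / sdb_c, 0.25)
  expect_lt(abs(stats::sd(or_mean[grp == "control"]) - sdb_0) / sdb_0, 0.25)
})

test_that("between-subject OR-FA separation matches the printed group stats", {
  # full image path at the printed means/SDs: the Welch effect size of
  # per-subject OR-mean FA should be within 10% of
  # (6.23 - 2.38) / sqrt((3.56^2 + 1.79^2) / 2) ~ 1.372
  cfg <- cohort_config(n_cases = 200, n_controls = 200,
                       scans_per_subject = 1, grid_shape = c(16, 16, 16),
                       seed = 1)
  co <- generate_cohort(cfg)
  or_mean <- vapply(co, function(s) {
    m <- s$masks[[1]]$OR_L$mask | s$masks[[1]]$OR_R$mask
    mean(s$scans[[1]]$volumes$FA[m])
  }, numeric(1))
  grp <- vapply(co, `[[`, "", "group")
  d <- (mean(or_mean[grp == "case"]) - mean(or_mean[grp == "control"])) /
    sqrt((stats::var(or_mean[grp == "case"]) +
            stats::var(or_mean[grp == "control"])) / 2)
  d_target <- (6.23 - 2.38) / sqrt((3.56^2 + 1.79^2) / 2)
  expect_lt(abs(d - d_target) / d_target, 0.10)
})

test_that("simulated feature tables carry the informative column and labels", {
  tab <- simulate_progression_features(5, 7, n_noise = 3, seed = 2)
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 12L)
  expect_equal(sum(tab$group == "case"), 5L)
  expect_equal(feature_cols(tab),
               c("OR_FA_mean", "noise_01", "noise_02", "noise_03"))
  expect_true(all(is.finite(tab$OR_FA_mean)))
  # the truncated variant stays non-negative
  tabT <- simulate_progression_features(5, 7, n_noise = 0,
                                        truncate_at_zero = TRUE, seed = 2)
  expect_true(all(tabT$OR_FA_mean >= 0))
  tab2 <- simulate_progression_features(5, 7, n_noise = 3, seed = 2)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
})
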