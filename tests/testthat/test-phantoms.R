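# Synthetic-data generators: determinism, truth consistency, realism gates.

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(generate_flow_profiles(20, 20, 5, 0.1, seed = 3),
                   generate_flow_profiles(20, 20, 5, 0.1, seed = 3))
  expect_identical(generate_well_image(2, 1, seed = 5),
                   generate_well_image(2, 1, seed = 5))
  map <- default_plate_map(1, n_sample_wells = 4)
  expect_identical(generate_screen_tables(map, seed = 9),
                   generate_screen_tables(map, seed = 9))
  expect_identical(generate_luc_trace(seed = 11, noise_cv = 0.05),
                   generate_luc_trace(seed = 11, noise_cv = 0.05))
})

test_that("empty well contains only ring and background; counts are bookkept", {
  e <- generate_well_image(0, 0, seed = 1)
  expect_true(all(e$truth$label_image == 0))
  expect_equal(nrow(e$truth$worms), 0)
  # green has the ring and flat background only
  expect_setequal(unique(as.vector(e$images$green)), c(20L, 100L, 6000L))

  g <- generate_well_image(3, 1, seed = 7)
  expect_equal(nrow(g$truth$worms), 4)
  expect_equal(sum(g$truth$worms$genotype == "heterozygote"), 1)
  expect_setequal(unique(g$truth$label_image[g$truth$label_image > 0]), 1:4)
})

test_that("green raster integrated over a truth label returns body GFP plus background", {
  g <- generate_well_image(3, 0, seed = 13, body_gfp_mean = 300,
                           body_gfp_cv = 0)
  for (k in g$truth$worms$worm) {
    m <- mean(g$images$green[g$truth$label_image == k])
    expect_lt(abs(m - (300 + 100)) / 400, 0.05)
  }
})

test_that("impossible placements raise a placement-failure error", {
  expect_error(generate_well_image(30, 0, seed = 1, dims = c(128, 128)),
               "placement failure")
})

test_that("flow-profile phantoms honour the class-defining signal shapes", {
  g <- generate_flow_profiles(5, 5, 0, noise_cv = 0, seed = 2)
  het <- g$profiles[g$truth$class == "heterozygote"]
  hom <- g$profiles[g$truth$class == "homozygote"]
  for (p in het) expect_gt(max(p$green), 10000)
  for (p in hom) {
    expect_gt(sum(p$green > 700), 120)
    expect_gt(max(p$green), 700)
    expect_lt(max(p$green), 10000)
  }
  big <- generate_flow_profiles(500, 500, 0, noise_cv = 0.1, seed = 1)
  expect_equal(as.vector(table(big$truth$class)), c(500, 500))
  expect_error(generate_flow_profiles(1, 1, 0, noise_cv = -0.1),
               "noise_cv")
})

test_that("noiseless profiles are perfectly separated by the accept rule", {
  g <- generate_flow_profiles(40, 40, 10, noise_cv = 0, seed = 6)
  cfg <- gate_config()
  for (i in seq_along(g$profiles)) {
    f <- profile_features(g$profiles[[i]], cfg$green_floor, cfg$ext_floor)
    ok <- gate_extinction(f, cfg) && classify_green(f, cfg)$accepted
    expect_identical(ok, g$truth$class[i] == "homozygote")
  }
})

test_that("screen tables plant fold changes and contaminants as specified", {
  map <- default_plate_map(1, n_sample_wells = 20)
  gen <- generate_screen_tables(map, effects = c(clone_0005 = 0.4),
                                worms_per_well = 30, noise_cv = 0.3, seed = 4)
  rec <- gen$records
  ctl <- rec$int_worm_minus_bkgd_green[rec$role == "control_neg"]
  planted <- rec$int_worm_minus_bkgd_green[rec$clone_id %in% "clone_0005"]
  expect_lt(mean(planted) / mean(ctl), 0.66)
  expect_equal(gen$truth$true_fc[gen$truth$clone_id %in% "clone_0005"], 0.4)

  # contamination: 0.2 x 40 worms -> 8 expected green-head rows per well
  gen2 <- generate_screen_tables(map, worms_per_well = 40, noise_cv = 0.3,
                                 contamination = 0.2, seed = 8)
  per_well <- tapply(gen2$records$green_head_id >= 1,
                     gen2$records$well, sum)
  se <- sqrt(40 * 0.2 * 0.8 / length(per_well))
  expect_lt(abs(mean(per_well) - 8), 4 * se)

  bad_map <- map[map$role != "control_neg", ]
  expect_error(generate_screen_tables(bad_map, seed = 1), "negative-control")
})

test_that("luciferase phantom is an exact square wave when noiseless", {
  g <- generate_luc_trace(noise_cv = 0, decay = 0, seed = 3)
  expect_setequal(unique(g$trace$lum), c(1000, 500))
  expect_equal(nrow(g$truth), 4)
  t_h <- g$trace$time_min / 60
  in_molt <- rep(FALSE, length(t_h))
  for (m in 1:4) in_molt <- in_molt |
      (t_h >= g$truth$onset_h[m] & t_h < g$truth$offset_h[m])
  expect_true(all(g$trace$lum[in_molt] < 0.75 * 1000))
  expect_true(all(g$trace$lum[!in_molt] == 1000))
  expect_error(generate_luc_trace(stage_durations_h = c(0, 8, 8, 10)),
               "durations")
})
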