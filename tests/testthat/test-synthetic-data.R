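test_that("weighing schedule covers the run with evenly spaced days", {
  d35 <- experiment_design(duration_days = 35, weighings_per_week = 3)
  expect_identical(make_schedule(d35),
                   c(0L, 2L, 4L, 7L, 9L, 11L, 14L, 16L, 18L, 21L, 23L, 25L,
                     28L, 30L, 32L, 35L))
  d7 <- experiment_design(duration_days = 7, weighings_per_week = 1)
  expect_identical(make_schedule(d7), c(0L, 7L))
  daily <- experiment_design(duration_days = 35, weighings_per_week = 7)
  expect_identical(make_schedule(daily), 0:35)
  expect_error(experiment_design(weighings_per_week = 0), "between 1 and 7")
  expect_error(experiment_design(weighings_per_week = 8), "between 1 and 7")
})

test_that("design invariants are enforced", {
  expect_error(experiment_design(layer_edges_cm = c(0, 10, 10, 40)), "increasing")
  expect_error(experiment_design(class_edges_mm = c(0, 0.5, 1.5)), "0.5 mm step")
  expect_error(experiment_design(n_blocks = 1), ">= 2")
  expect_error(experiment_design(duration_days = 0), ">= 1")
})

test_that("well-watered pots are refilled to field capacity at every weighing", {
  d <- experiment_design()
  eff <- effect_config(d, loss_noise_sd = 0)
  s <- generate_pot_series(d, "WW", eff)
  post <- s[s$post_irrigation, ]
  expect_true(all(abs(post$weight_kg - d$field_capacity_kg) < 1e-12))
  # zero loss -> constant series at field capacity
  s0 <- generate_pot_series(d, "WW", eff, daily_loss = 1e-12)
  expect_true(all(abs(s0$weight_kg - d$field_capacity_kg) < 1e-6))
})

test_that("water-deficit series decline monotonically and flatten, even with noise", {
  d <- experiment_design()
  eff0 <- effect_config(d, loss_noise_sd = 0, wd_decay = 1e-12)
  s <- generate_pot_series(d, "WD", eff0, daily_loss = 0.2)
  # constant daily loss L -> weight(t) = FC - L t
  expect_equal(s$weight_kg, d$field_capacity_kg - 0.2 * s$day, tolerance = 1e-9)
  set.seed(42)
  eff <- effect_config(d, loss_noise_sd = 0.3)
  s2 <- generate_pot_series(d, "WD", eff)
  expect_true(all(diff(s2$weight_kg) <= 0))
  expect_true(all(s2$weight_kg > 0))
  # exponential decay of the daily loss: late intervals lose less than early
  early <- s2$weight_kg[1] - s2$weight_kg[5]
  late <- s2$weight_kg[nrow(s2) - 4] - s2$weight_kg[nrow(s2)]
  expect_lt(late, early)
})

test_that("control series share the schedule and decline at the drainage rate", {
  d <- experiment_design()
  s <- generate_control_series(d, effect_config(d, drain_rate = 0.05, loss_noise_sd = 0))
  expect_identical(s$day, make_schedule(d))
  expect_true(all(s$is_control))
  expect_equal(s$weight_kg, d$field_capacity_kg - 0.05 * s$day, tolerance = 1e-9)
  s0 <- generate_control_series(d, effect_config(d, drain_rate = 0, loss_noise_sd = 0))
  expect_true(all(s0$weight_kg == d$field_capacity_kg))
})

test_that("root segments respect depth allocation and stay in range", {
  d <- experiment_design()
  eff <- effect_config(d, layer_alloc = c(1, 0, 0, 0))
  set.seed(7)
  seg <- generate_root_segments(d, "GC", "WW", eff)
  expect_true(all(seg$depth_cm >= 0 & seg$depth_cm < 10))
  expect_true(all(seg$length_mm > 0))
  expect_true(all(seg$diameter_mm > 0))
  expect_error(effect_config(d, layer_alloc = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("zero-noise generation makes WD totals exactly the reduction factor times WW", {
  d <- experiment_design()
  eff <- effect_config(d, wd_reduction = 0.5, seg_len_sdlog = 0, plant_sdlog = 0,
                       block_sdlog = 0, diam_fine_sdlog = 0, diam_thick_sdlog = 0,
                       loss_noise_sd = 0)
  set.seed(1)
  ww <- generate_root_segments(d, "GC", "WW", eff)
  wd <- generate_root_segments(d, "GC", "WD", eff)
  expect_equal(sum(wd$length_mm), 0.5 * sum(ww$length_mm), tolerance = 1e-12)
  # biomass obeys the same contract through the full generator
  ex <- generate_experiment(d, eff, seed = 3)
  p <- ex$plants
  rdw <- tapply(p$rdw_g, p$regime, mean)
  expect_equal(unname(rdw["WD"] / rdw["WW"]), 0.5, tolerance = 1e-12)
})

test_that("large-sample WD/WW root-length ratio approaches the reduction factor", {
  d <- experiment_design()
  eff <- effect_config(d, rl_ww_cm = 20000, wd_reduction = 0.5)
  set.seed(11)
  ww <- generate_root_segments(d, "GC", "WW", eff)
  wd <- generate_root_segments(d, "GC", "WD", eff)
  expect_equal(sum(wd$length_mm) / sum(ww$length_mm), 0.5, tolerance = 0.05)
})

test_that("modal root-length diameter class is 0.5-1.0 mm under defaults", {
  d <- experiment_design()
  set.seed(5)
  seg <- generate_root_segments(d, "GC", "WW", effect_config(d, rl_ww_cm = 50000))
  expect_gt(nrow(seg), 1e4 * 0.8)
  cls <- suppressWarnings(assign_diameter_class(seg$diameter_mm, d$class_edges_mm))
  rl_by_class <- tapply(seg$length_mm, cls, sum)
  expect_identical(names(which.max(rl_by_class)), "2")
})

test_that("full experiment is deterministic given the seed and sized by the design", {
  ex1 <- generate_experiment(seed = 99)
  ex2 <- generate_experiment(seed = 99)
  expect_identical(ex1$plants, ex2$plants)
  expect_identical(ex1$pot_weights, ex2$pot_weights)
  expect_identical(ex1$root_segments, ex2$root_segments)
  ex3 <- generate_experiment(seed = 100)
  expect_false(identical(ex1$plants, ex3$plants))
  expect_equal(nrow(ex1$plants), 48)
  d2 <- experiment_design(n_blocks = 2)
  expect_equal(nrow(generate_experiment(d2, paper_effects(d2), seed = 1)$plants), 32)
  # every pot shares the design schedule, starting at 0 and ending on the last day
  days <- sort(unique(ex1$pot_weights$day))
  expect_identical(as.integer(days), make_schedule(ex1$design))
})

test_that("default pattern raises root:shoot under water deficit", {
  ex <- generate_experiment(seed = 2)
  p <- ex$plants
  rs <- p$rdw_g / p$sdw_g
  expect_gt(mean(rs[p$regime == "WD"]), mean(rs[p$regime == "WW"]))
})

test_that("biomass/pot-volume QC warns only when enabled and exceeded", {
  d <- experiment_design()
  heavy <- effect_config(d, sdw_ww_g = 95)   # ~5 g/L in a 20 L pot
  light <- effect_config(d, rdw_ww_g = 1, sdw_ww_g = 20)  # ~1 g/L
  expect_warning(generate_experiment(d, heavy, seed = 1, qc = TRUE), "2 g")
  expect_silent(ex <- generate_experiment(d, heavy, seed = 1, qc = FALSE))
  expect_warning(generate_experiment(d, light, seed = 1, qc = TRUE), NA)
  # the light configuration sits inside the published 1.06-2.58 g/L band
  exl <- generate_experiment(d, light, seed = 1)
  expect_true(all(exl$plants$biomass_per_volume_g_l < 2.58))
})
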