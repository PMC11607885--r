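# Synthetic-cohort generator: degenerate cases, distributional properties,
# truth-table echoes and reproducibility.

test_that("degenerate noise: flat profile with zero noise yields constant records", {
  cfg <- tiny_config(seed = 1, n = 2, acclimation_days = 1)
  prof <- list(food = flat_profile("food", level = 0.12))
  rec <- generate_cohort(cfg, profiles = prof, effects = null_effects(),
                         behaviours = "food")
  # every 5-min record carries L * (300/3600) grams
  expect_equal(unique(round(rec$value, 12)), 0.12 / 12)
})

test_that("beta concentration: wake fractions converge to the profile mean at huge precision", {
  cfg <- tiny_config(seed = 2, n = 2, acclimation_days = 1)
  prof <- list(wake = flat_profile("wake", level = 0.4, beta_precision = 1e6))
  rec <- generate_cohort(cfg, profiles = prof, effects = null_effects(),
                         behaviours = "wake")
  expect_lt(max(abs(rec$value - 0.4)), 1e-2)
})

test_that("generated hourly wake mean matches the profile mean within Monte-Carlo error", {
  cfg <- cohort_config(n_nonpregnant = 1, n_pregnant = 1,
                       termination_schedule = list(nonpregnant = c(0, 0, 1),
                                                   pregnant = c(0, 0, 1)),
                       acclimation_days = 1, random_seed = 31)
  prof <- default_profiles()["wake"]
  prof$wake$intercept_sd <- 0  # isolate the beta draw distribution
  rec <- generate_cohort(cfg, profiles = prof, effects = null_effects(),
                         behaviours = "wake")
  f <- profile_curve(prof$wake)
  # pool draws from one repeated ZT hour across days: n >= 200 draws
  rec <- data.table::as.data.table(rec)
  sel <- rec[zt_hour >= 14 & zt_hour < 16 & mouse_id == "NP01"]
  expect_gte(nrow(sel), 200)
  mu <- mean(f(sel$zt_hour))
  se <- sd(sel$value) / sqrt(nrow(sel))
  expect_lt(abs(mean(sel$value) - mu), 3 * se)
})

test_that("default nocturnal food profile allocates 65-80% of intake to the dark phase", {
  f <- profile_curve(default_profiles()$food)
  tg <- seq(0, 24 - 0.005, by = 0.005)
  v <- f(tg)
  frac <- sum(v[tg >= 12 & tg < 24]) / sum(v)
  expect_gte(frac, 0.65)
  expect_lte(frac, 0.80)
})

test_that("generation is bit-reproducible under a fixed seed and refuses a missing seed", {
  cfg <- tiny_config(seed = 5, n = 2, acclimation_days = 1)
  r1 <- generate_cohort(cfg, behaviours = c("food", "wake"))
  r2 <- generate_cohort(cfg, behaviours = c("food", "wake"))
  expect_identical(r1, r2)
  expect_error(cohort_config(n_nonpregnant = 2, n_pregnant = 2),
               "random_seed is mandatory")
  expect_error(cohort_config(n_nonpregnant = 0, n_pregnant = 2, random_seed = 1),
               "positive")
})

test_that("termination schedule truncates pregnant records at block boundaries", {
  cfg <- cohort_config(n_nonpregnant = 3, n_pregnant = 3,
                       termination_schedule = list(nonpregnant = c(1, 1, 1),
                                                   pregnant = c(1, 1, 1)),
                       acclimation_days = 1, random_seed = 6)
  rec <- generate_cohort(cfg, behaviours = "food")
  ends <- data.table::as.data.table(rec)[, .(last = max(day)), by = mouse_id]
  expect_equal(max(ends$last), 17.5 - 1 / 288, tolerance = 1e-6)
  pg <- ends[mouse_id %like% "PG"]
  expect_setequal(round(pg$last + 1 / 288, 1), c(6.5, 12.5, 17.5))
})

test_that("truth table echoes injected peak delays and amplitude folds", {
  cfg <- tiny_config(seed = 7)
  eff <- null_effects()
  tt0 <- truth_table(cfg, effects = eff, behaviours = "food")
  expect_true(all(abs(tt0$peaks$diff_time) < 1e-9))
  expect_true(all(abs(tt0$peaks$diff_amplitude) < 1e-9))

  eff$blocks[["2"]]$peak_delay["I"] <- 1.5
  tt1 <- truth_table(cfg, effects = eff, behaviours = "food")
  expect_equal(tt1$peaks[block == 2 & window == "I", diff_time], 1.5,
               tolerance = 0.02)
  expect_true(all(abs(tt1$peaks[!(block == 2 & window == "I"), diff_time]) < 0.02))

  eff2 <- null_effects()
  eff2$blocks[["1"]]$amplitude_fold["II"] <- 2
  tt2 <- truth_table(cfg, effects = eff2, behaviours = "food")
  r <- tt2$peaks[block == 1 & window == "II",
                 amplitude_pregnant / amplitude_nonpregnant]
  expect_equal(r, 2, tolerance = 0.01)
})

test_that("profile validation enforces wake range and peak-window membership", {
  expect_error(behaviour_profile(
    "wake", data.frame(zt = c(0, 12), level = c(0.5, 1.2)),
    data.frame(window = "II", time = 13.5, amplitude = 0.8)),
    "wake levels")
  expect_error(behaviour_profile(
    "food", data.frame(zt = c(0, 12), level = c(0.1, 0.2)),
    data.frame(window = "II", time = 16, amplitude = 0.3)),
    "inside its window")
})

test_that("records round-trip through CSV and config through YAML", {
  cfg <- tiny_config(seed = 8, n = 2, acclimation_days = 1)
  rec <- generate_cohort(cfg, behaviours = "food")
  tmp <- tempfile(fileext = ".csv")
  write_records(rec, tmp)
  back <- read_records(tmp)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$value, rec$value, tolerance = 1e-12)
  tmpc <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, tmpc)
  expect_equal(yaml::read_yaml(tmpc)$random_seed, 8)
})
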