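# Preprocessing: food-event exclusion, sleep scoring, aggregation and study
# block assignment.

mk_records <- function(day, value, behaviour = "food", mouse = "M1",
                       group = "nonpregnant") {
  data.table::data.table(mouse_id = mouse, group = group, day = day,
                         zt_hour = (day %% 1) * 24, behaviour = behaviour,
                         value = value)
}

test_that("food events below 0.002 g are excluded, boundary kept (strict <)", {
  rec <- mk_records(day = 1 + (0:2) / 288, value = c(0.001, 0.002, 0.005))
  kept <- filter_food_events(rec)
  expect_equal(kept$value, c(0.002, 0.005))

  # all at/above the limit -> identity
  rec2 <- mk_records(day = 1 + (0:2) / 288, value = c(0.002, 0.01, 0.3))
  expect_equal(filter_food_events(rec2)$value, rec2$value)

  # all below -> empty food stream
  rec3 <- mk_records(day = 1 + (0:2) / 288, value = rep(0.0019, 3))
  expect_equal(nrow(filter_food_events(rec3)), 0)

  # other behaviours untouched; negative values rejected with a warning
  rec4 <- rbind(mk_records(1, 0.001),
                mk_records(1, 0.0005, behaviour = "activity"))
  out <- filter_food_events(rec4)
  expect_equal(out$behaviour, "activity")
  expect_warning(filter_food_events(mk_records(1, -0.01)), "negative")
})

test_that("sleep scoring counts only stillness runs of >= 40 s", {
  # one full-block stillness run
  expect_equal(score_sleep(rep(TRUE, 300))$asleep_fraction, 1.0)
  # a 39 s run does not qualify
  s <- rep(FALSE, 300); s[10:48] <- TRUE
  expect_equal(score_sleep(s)$asleep_fraction, 0.0)
  # a 40 s run contributes exactly 40/300
  s <- rep(FALSE, 300); s[10:49] <- TRUE
  expect_equal(score_sleep(s)$asleep_fraction, 40 / 300)
  # wake + sleep fractions always sum to 1 exactly
  set.seed(1)
  s <- runif(900) < 0.6
  sc <- score_sleep(s)
  expect_identical(sc$asleep_fraction + sc$awake_fraction, rep(1, 3))
})

test_that("a qualifying run split across block boundaries counts in both blocks", {
  # 60 s run straddling the first block boundary: 280..339
  s <- rep(FALSE, 600); s[281:340] <- TRUE
  sc <- score_sleep(s)
  expect_equal(sc$asleep_fraction, c(20 / 300, 40 / 300))
  # two 25 s fragments that would each fail alone still qualify as one run
  s2 <- rep(FALSE, 600); s2[276:325] <- TRUE
  sc2 <- score_sleep(s2)
  expect_equal(sc2$asleep_fraction, c(25 / 300, 25 / 300))
})

test_that("hourly aggregation sums intake blocks and averages wake fractions", {
  day <- 1 + (0:11) / 288
  rec <- mk_records(day, rep(0.02, 12))
  h <- aggregate_records(rec)
  expect_equal(h$value, 0.24)
  expect_equal(h$zt_hour, 0L)

  recw <- mk_records(day, rep(0.5, 12), behaviour = "wake")
  expect_equal(aggregate_records(recw)$value, 0.5)
})

test_that("a missing block makes the hour missing for continuous signals, not rescaled", {
  day <- 1 + (0:11) / 288
  rec <- mk_records(day[-5], rep(2, 11), behaviour = "activity")
  h <- aggregate_records(rec)
  expect_true(is.na(h$value))
  # but an absent intake block is an observed zero inside the span
  recf <- mk_records(day[-5], rep(0.02, 11), behaviour = "food")
  expect_equal(aggregate_records(recf)$value, 0.22)
})

test_that("duplicate records within a block raise an error", {
  rec <- mk_records(c(1, 1), c(0.1, 0.1))
  expect_error(aggregate_records(rec), "duplicate")
})

test_that("aggregation conserves daily food totals and is idempotent on hourly input", {
  cfg <- tiny_config(seed = 9, n = 2, acclimation_days = 1)
  rec <- filter_food_events(generate_cohort(cfg, behaviours = "food"))
  h <- aggregate_records(rec)
  rec <- data.table::as.data.table(rec)
  raw_day <- rec[day >= 1 & day < 2 & mouse_id == "NP01", sum(value)]
  agg_day <- h[day >= 1 & day < 2 & mouse_id == "NP01", sum(value)]
  expect_equal(agg_day, raw_day, tolerance = 1e-9)

  h2 <- aggregate_records(h, interval_s = 3600)
  expect_equal(h2$value, h$value)
  expect_equal(h2$zt_hour, h$zt_hour)
})

test_that("study blocks follow the half-open convention with boundary days in the later block", {
  expect_equal(assign_block(c(0.5, 6.5, 12.5, 17.5)), c(1L, 2L, 3L, 3L))
  # brute-force enumeration over all half-days of the study
  days <- seq(0.5, 17.5, by = 0.5)
  expected <- ifelse(days < 6.5, 1L, ifelse(days < 12.5, 2L, 3L))
  expect_equal(assign_block(days), expected)
  expect_message(b <- assign_block(c(0.2, 18)), "outside")
  expect_true(all(is.na(b)))
})

test_that("reading records enforces required columns and honours a rename map", {
  tmp <- tempfile(fileext = ".csv")
  rec <- mk_records(1 + (0:2) / 288, c(0.1, 0.2, 0.3))
  data.table::setnames(rec, "value", "Food_g")
  data.table::fwrite(rec, tmp)
  expect_error(read_records(tmp), "missing required columns")
  out <- read_records(tmp, column_map = c(value = "Food_g"))
  expect_true("value" %in% names(out))
})
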