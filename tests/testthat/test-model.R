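# Spline basis, sampler bookkeeping, back-transformation, acclimation
# profiles and the Bayesian behaviour model.

test_that("the circadian spline basis has 13 evenly spaced knots and linear tails", {
  k <- circadian_knots()
  expect_length(k, 13)
  expect_equal(range(k), c(8.5, 28.5))
  expect_equal(unique(round(diff(k), 10)), 20 / 12, tolerance = 1e-9)
  # natural tails: second differences vanish beyond the boundary knots
  tt <- seq(4, 8.4, by = 0.1)
  B <- circadian_basis(tt)
  d2 <- diff(B, differences = 2)
  expect_lt(max(abs(d2)), 1e-8)
  expect_equal(ncol(B), 12)
})

test_that("sampler presets imply the documented retained draw counts", {
  expect_equal(sampler_settings("full")$n_draws, 3750)
  expect_equal(sampler_settings("reduced")$n_draws, 500)
  expect_error(sampler_settings("full", burnin = 10000), "burnin")
})

test_that("sqrt back-transformation is the exact mean of a squared normal", {
  expect_equal(back_transform_sqrt(0.5, 0), 0.25)
  expect_equal(back_transform_sqrt(0, 0.04), 0.04)
  expect_error(back_transform_sqrt(0.5, -0.1), "negative variance")
  # Monte-Carlo oracle at one pair
  set.seed(10)
  y <- rnorm(1e5, 0.4, 0.1)
  mc <- mean(y^2)
  se <- sd(y^2) / sqrt(length(y))
  expect_lt(abs(back_transform_sqrt(0.4, 0.01) - mc), 3 * se)
})

test_that("acclimation profiles return the common curve for identical noise-free mice", {
  curve_np <- function(t) 0.15 + 0.05 * sin((t - 6) * pi / 12)
  h <- synthetic_hourly(3, 17, curve_np, noise_sd = 0, intercept_sd = 0, seed = 3)
  prof <- suppressWarnings(fit_acclimation(h, "food"))
  wide <- data.table::dcast(prof, zt_hour ~ mouse_id, value.var = "accl")
  spread <- apply(as.matrix(wide[, -1]), 1, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-3)
  # and the profile tracks sqrt(curve) at each hour
  expect_equal(prof[prof$mouse_id == "N01", ]$accl,
               sqrt(curve_np(hour_centre(0:23))), tolerance = 0.01)
})

test_that("acclimation profiles recover a constant per-mouse sqrt-scale offset", {
  curve_np <- function(t) 0.15 + 0.05 * sin((t - 6) * pi / 12)
  h <- synthetic_hourly(4, 17, curve_np, noise_sd = 0.02, intercept_sd = 0.1,
                        seed = 4, accl_days = 4)
  # inject a known offset for one mouse on the sqrt scale
  h2 <- data.table::copy(h)
  h2[mouse_id == "N01", value := (sqrt(value) + 0.3)^2]
  p1 <- fit_acclimation(h, "food")
  p2 <- fit_acclimation(h2, "food")
  off <- merge(p1, p2, by = c("mouse_id", "zt_hour"))
  gain <- off[mouse_id == "N01", mean(accl.y - accl.x)]
  expect_equal(gain, 0.3, tolerance = 0.05)
})

test_that("a constant 0.5 wake stream yields a logit profile near zero", {
  curve_np <- function(t) rep(0.25, length(t))  # unused placeholder
  h <- synthetic_hourly(2, 17, curve_np, noise_sd = 0, intercept_sd = 0,
                        seed = 5, behaviour = "wake")
  h[, value := 0.5]
  prof <- suppressWarnings(fit_acclimation(h, "wake"))
  expect_lt(max(abs(prof$accl)), 1e-4)
})

test_that("mice absent from acclimation get the group curve with a warning", {
  curve_np <- function(t) 0.15 + 0.05 * sin((t - 6) * pi / 12)
  h <- synthetic_hourly(3, 17, curve_np, noise_sd = 0.02, seed = 6)
  h_no <- h[!(mouse_id == "N01" & phase == "acclimation")]
  expect_warning(prof <- fit_acclimation(h_no, "food"), "absent")
  expect_true(all(0:23 %in% prof[prof$mouse_id == "N01", ]$zt_hour))
})

test_that("null data: group-difference CrI covers zero at most grid points", {
  curve_np <- function(t) 0.12 + 0.08 * exp(-((t - 14) / 2)^2)
  h <- synthetic_hourly(4, 17, curve_np, seed = 7)
  accl <- fit_acclimation(h, "food")
  fit <- fit_behaviour_model(h, accl, model_spec("food", sampler_settings("reduced")),
                             seed = 7)
  expect_equal(nrow(fit$beta), 500)
  pc <- posterior_curves(fit, force = TRUE)
  covered <- 0L
  ngrid <- length(pc$grid)
  for (b in 1:3) {
    D <- pc$cells[[paste0("pregnant.", b)]] - pc$cells[[paste0("nonpregnant.", b)]]
    lo <- apply(D, 2, quantile, 0.025)
    hi <- apply(D, 2, quantile, 0.975)
    covered <- covered + sum(lo <= 0 & hi >= 0)
  }
  expect_gte(covered / (3 * ngrid), 0.9)
})

test_that("posterior curves cover the true curve pointwise at >= 90% of the grid", {
  curve_np <- function(t) 0.12 + 0.08 * exp(-((t - 14) / 2)^2)
  h <- synthetic_hourly(4, 17, curve_np, seed = 8)
  accl <- fit_acclimation(h, "food")
  fit <- fit_behaviour_model(h, accl, model_spec("food", sampler_settings("reduced")),
                             seed = 8)
  pc <- posterior_curves(fit, force = TRUE)
  truth <- curve_np(pc$grid) + mean(fit$sigma2)  # response-scale mean
  hits <- 0L
  for (b in 1:3) {
    M <- pc$cells[[paste0("nonpregnant.", b)]]
    lo <- apply(M, 2, quantile, 0.025)
    hi <- apply(M, 2, quantile, 0.975)
    hits <- hits + sum(lo <= truth & truth <= hi)
  }
  expect_gte(hits / (3 * length(pc$grid)), 0.9)
})

test_that("wake fits keep every posterior fitted value strictly inside (0, 1)", {
  set.seed(9)
  mice <- data.frame(mouse_id = sprintf("W%02d", 1:6),
                     group = rep(c("nonpregnant", "pregnant"), each = 3))
  grid <- expand.grid(mouse_id = mice$mouse_id,
                      day = seq(-0.5, 14.5 - 1 / 24, by = 1 / 24))
  h <- data.table::as.data.table(merge(grid, mice, by = "mouse_id"))
  h[, zt_hour := as.integer(floor(day * 24 + 1e-9) %% 24)]
  h[, phase := ifelse(day < 0.5, "acclimation", "study")]
  h[, block := suppressMessages(assign_block(day))]
  mu <- plogis(-0.5 + 1.5 * sin((unwrap_zt(h$zt_hour + 0.5) - 8) * pi / 12))
  h[, value := rbeta(.N, mu * 60, (1 - mu) * 60)]
  h[, behaviour := "wake"]
  accl <- fit_acclimation(h, "wake")
  fit <- fit_behaviour_model(
    h, accl, model_spec("wake", sampler_settings("reduced", iter = 600, burnin = 300)),
    seed = 9)
  pc <- posterior_curves(fit, force = TRUE)
  rng <- range(unlist(lapply(pc$cells, range)))
  expect_gt(rng[1], 0)
  expect_lt(rng[2], 1)
})

test_that("curve reports summarise draws and refuse empty draw sets", {
  grid <- zt_grid()
  const <- matrix(0.3, nrow = 50, ncol = length(grid))
  pc <- structure(list(grid = grid, behaviour = "food", family = "gaussian_sqrt",
                       cells = list(nonpregnant.1 = const)),
                  class = "posterior_curves")
  rep_tab <- curves_to_report(pc)
  expect_true(all(rep_tab$mean == 0.3))
  expect_true(all(rep_tab$hi - rep_tab$lo == 0))

  set.seed(11)
  norm <- matrix(rnorm(4000 * 3, mean = 2, sd = 0.5), nrow = 4000)
  pc2 <- structure(list(grid = c(10, 10.05, 10.1), behaviour = "food",
                        family = "gaussian_sqrt",
                        cells = list(nonpregnant.1 = norm)),
                   class = "posterior_curves")
  r2 <- curves_to_report(pc2)
  expect_equal(r2$lo, rep(2 - 1.96 * 0.5, 3), tolerance = 0.05)
  expect_equal(r2$hi, rep(2 + 1.96 * 0.5, 3), tolerance = 0.05)

  pc$cells$nonpregnant.1 <- const[0, , drop = FALSE]
  expect_error(curves_to_report(pc), "empty draw set")
})

test_that("non-converged fits refuse peak analysis unless forced", {
  fake <- structure(list(behaviour = "food", family = "gaussian_sqrt",
                         beta = matrix(0, 10, 2), sigma2 = rep(1, 10),
                         coef_names = c("a", "b"),
                         xlevels = list(group = "nonpregnant", block = "1"),
                         rhat = c(2, 1), converged = FALSE),
                    class = "circa_fit")
  expect_error(posterior_curves(fake), "non-converged")
})
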