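# Shared fixture builders: small synthetic cohorts kept deliberately tiny so
# the default test run stays fast.

tiny_config <- function(seed, n = 4, days_all = TRUE, acclimation_days = 3) {
  sched <- if (days_all) c(0, 0, n) else c(n, 0, 0)
  cohort_config(n_nonpregnant = n, n_pregnant = n,
                termination_schedule = list(nonpregnant = sched, pregnant = sched),
                acclimation_days = acclimation_days, random_seed = seed)
}

# A flat, noise-free profile: constant level, no peaks (degenerate cases).
flat_profile <- function(behaviour = "food", level = 0.1, noise_sd = 0,
                         intercept_sd = 0, beta_precision = 50) {
  behaviour_profile(
    behaviour,
    baseline = data.frame(zt = c(0, 6, 12, 18), level = level),
    peaks = data.frame(window = character(), time = numeric(),
                       amplitude = numeric()),
    noise_sd = noise_sd, intercept_sd = intercept_sd,
    beta_precision = beta_precision)
}

# Hourly series built directly (bypassing the generator) for model tests:
# sqrt-scale Gaussian data from a known smooth curve.
synthetic_hourly <- function(n_per_group, days, curve_np, curve_pg = curve_np,
                             noise_sd = 0.05, intercept_sd = 0.05, seed = 1,
                             behaviour = "food", accl_days = 2) {
  set.seed(seed)
  mice <- data.frame(
    mouse_id = c(sprintf("N%02d", seq_len(n_per_group)),
                 sprintf("P%02d", seq_len(n_per_group))),
    group = rep(c("nonpregnant", "pregnant"), each = n_per_group))
  mice$icpt <- rnorm(nrow(mice), 0, intercept_sd)
  grid <- expand.grid(mouse_id = mice$mouse_id,
                      day = seq(0.5 - accl_days, 17.5 - 1 / 24, by = 1 / 24))
  h <- merge(grid, mice, by = "mouse_id")
  h <- data.table::as.data.table(h)
  h[, zt_hour := as.integer(floor(day * 24 + 1e-9) %% 24)]
  h[, phase := ifelse(day < 0.5, "acclimation", "study")]
  h[, block := suppressMessages(assign_block(day))]
  tt <- unwrap_zt(h$zt_hour + 0.5)
  mu <- ifelse(h$group == "nonpregnant", curve_np(tt), curve_pg(tt))
  h[, value := pmax(sqrt(mu) + icpt + rnorm(.N, 0, noise_sd), 0)^2]
  h[, behaviour := behaviour]
  h[, icpt := NULL]
  h[]
}
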