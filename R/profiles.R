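# Behaviour profiles: smooth 24 h mean curves with localised peaks, plus the
# pregnancy-effect specification that perturbs them per study block.

#' Define a behaviour profile for the synthetic cohort
#'
#' A profile is a smooth periodic baseline over the 24 h cycle plus localised
#' peaks. The baseline is a periodic cubic-spline interpolant through the
#' control points (deliberately a different basis from the natural-spline model
#' fitted downstream); each peak is blended in through a compact raised-cosine
#' weight so the curve attains exactly `amplitude` at `time` with a local
#' maximum there, whatever the local baseline slope.
#'
#' @param behaviour One of `"food"`, `"water"`, `"activity"`, `"wake"`.
#' @param baseline data.frame with columns `zt` (hours in `[0, 24)`) and
#'   `level` (behaviour units: g/h, m/h, or wake fraction in (0,1)).
#' @param peaks data.frame with columns `window` (`"I"`-`"V"`), `time`
#'   (calendar ZT hours) and `amplitude` (absolute curve height at the peak).
#' @param noise_sd Residual SD on the square-root hourly scale (intake and
#'   activity behaviours; ignored for wake).
#' @param intercept_sd SD of the per-mouse random intercept, on the sqrt scale
#'   (intake/activity) or logit scale (wake).
#' @param beta_precision Precision of the beta distribution for wake fractions
#'   (larger = less variable); ignored for other behaviours.
#' @param bump_halfwidth Half-width (h) of the raised-cosine peak bumps;
#'   scalar or one value per peak.
#' @return An object of class `behaviour_profile`.
#' @export
behaviour_profile <- function(behaviour, baseline, peaks,
                              noise_sd = 0, intercept_sd = 0,
                              beta_precision = 50, bump_halfwidth = 2) {
  behaviour <- match.arg(behaviour, BEHAVIOURS)
  stop_if_not(all(c("zt", "level") %in% names(baseline)),
              "baseline needs columns zt, level")
  stop_if_not(all(c("window", "time", "amplitude") %in% names(peaks)),
              "peaks needs columns window, time, amplitude")
  stop_if_not(all(baseline$level >= 0), "baseline levels must be >= 0")
  if (behaviour == "wake") {
    stop_if_not(all(baseline$level > 0 & baseline$level < 1) &&
                  all(peaks$amplitude > 0 & peaks$amplitude < 1),
                "wake levels must lie in (0, 1)")
  }
  win <- time_windows()
  tu <- unwrap_zt(peaks$time %% 24)
  m <- match(peaks$window, win$window)
  stop_if_not(!anyNA(m) && all(tu >= win$lo[m] & tu < win$hi[m]),
              "each peak time must lie inside its window")
  stop_if_not(length(bump_halfwidth) %in% c(1L, nrow(peaks)),
              "bump_halfwidth must be scalar or one value per peak")
  bump_halfwidth <- rep_len(bump_halfwidth, max(nrow(peaks), 1L))
  structure(list(behaviour = behaviour,
                 baseline = baseline[order(baseline$zt), , drop = FALSE],
                 peaks = peaks, noise_sd = noise_sd,
                 intercept_sd = intercept_sd,
                 beta_precision = beta_precision,
                 bump_halfwidth = bump_halfwidth),
            class = "behaviour_profile")
}

# Raised-cosine bump with support |u| < 1, bump(0) = 1, bump'(0) = 0.
rc_bump <- function(u) ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)

# Circular hour distance in (-12, 12].
circ_dist <- function(t, t0) ((t - t0 + 12) %% 24) - 12

# Smooth dark-phase mask: ~1 inside ZT12-ZT24, ~0 in the light phase, with
# half-hour raised-cosine edges so scaled curves stay smooth.
dark_mask <- function(t) {
  edge <- function(x) ifelse(x <= -0.5, 0, ifelse(x >= 0.5, 1, (sin(pi * x) + 1) / 2))
  # distance from the dark-phase midpoint (ZT18); edges centred on ZT12/ZT24
  edge(6 - abs(circ_dist(t, 18)))
}

#' Mean behaviour curve implied by a profile (with optional pregnancy effects)
#'
#' Returns the noiseless population mean curve as a vectorised function of
#' calendar ZT hours (any real; evaluated periodically). For the pregnant group
#' within a study block, window-specific peak delays and amplitude folds are
#' applied to the behaviours named in the effect specification, and dark-phase
#' activity/wake scaling is applied multiplicatively through a smooth mask.
#'
#' @param profile A [behaviour_profile()].
#' @param effects A [pregnancy_effects()] specification, or `NULL` for none.
#' @param group `"nonpregnant"` or `"pregnant"`.
#' @param block Study block 1-3 (required when effects are applied).
#' @return `function(t)` giving the mean level at ZT hour `t`.
#' @export
profile_curve <- function(profile, effects = NULL, group = "nonpregnant",
                          block = 1L) {
  group <- match.arg(group, GROUPS)
  pk <- profile$peaks
  scale_dark <- 1
  if (group == "pregnant" && !is.null(effects)) {
    be <- effects$blocks[[as.character(block)]]
    stop_if_not(!is.null(be), "effects must cover the requested block")
    if (profile$behaviour %in% effects$affected) {
      pk$time <- pk$time + be$peak_delay[pk$window]
      pk$amplitude <- pk$amplitude * be$amplitude_fold[pk$window]
    }
    if (profile$behaviour == "activity") scale_dark <- be$activity_scale_dark
    if (profile$behaviour == "wake") scale_dark <- be$wake_scale_dark
  }
  base <- profile$baseline
  x <- c(base$zt, base$zt[1] + 24)
  y <- c(base$level, base$level[1])
  bf <- stats::splinefun(x, y, method = "periodic")
  x0 <- base$zt[1]
  h <- profile$bump_halfwidth
  function(t) {
    v <- bf(x0 + (t - x0) %% 24)
    # blend each peak in as v + s*(A - v): the derivative at the peak time is
    # exactly zero whatever the baseline slope, so the curve attains a local
    # maximum of height A exactly at the (possibly delayed) peak time
    for (i in seq_len(nrow(pk))) {
      s <- rc_bump(circ_dist(t, pk$time[i]) / h[i])
      v <- v + s * (pk$amplitude[i] - v)
    }
    v <- v * (1 - (1 - scale_dark) * dark_mask(t))
    if (profile$behaviour == "wake") v <- pmin(pmax(v, 1e-3), 1 - 1e-3)
    pmax(v, 0)
  }
}

#' Default behaviour profiles of a non-pregnant female mouse
#'
#' Nocturnally biased 24 h profiles for food intake (g/h), water intake (g/h),
#' cage activity (m/h) and wakefulness (fraction awake), with local peaks in
#' the five ZT windows (late light phase ~ZT9, early dark ~ZT13.5, mid dark
#' ~ZT16.5-17.3, late dark ~ZT22 and early light ~ZT1.6-2). Food and water
#' peaks share times, reflecting the tight coupling of drinking to eating.
#' The noiseless food curve allocates roughly 70% of daily intake to the dark
#' phase.
#'
#' @return Named list of [behaviour_profile()] objects
#'   (`food`, `water`, `activity`, `wake`).
#' @export
default_profiles <- function() {
  food_times <- c(I = 9.2, II = 13.5, III = 16.5, IV = 22.0, V = 2.0)
  bp <- function(zt, level) data.frame(zt = zt, level = level)
  pk <- function(times, amps) data.frame(window = names(times), time = unname(times),
                                         amplitude = unname(amps))
  # baseline shapes: sharp fall after lights-on, low early-light level, a
  # broad light-phase trough ("siesta") through ~ZT11, a sharp rise at dark
  # onset and sustained dark-phase levels -- wide enough features that the
  # 13-knot circadian basis can represent the local peaks riding on them
  zts <- c(0.5, 3.5, 5.5, 7.5, 9.5, 11.6, 12.6, 13.3, 14.5, 16, 18, 20, 22, 23.4)
  list(
    food = behaviour_profile(
      "food",
      bp(zts, c(0.046, 0.038, 0.032, 0.042, 0.048, 0.05, 0.10, 0.17, 0.14,
                0.16, 0.12, 0.12, 0.125, 0.085)),
      pk(food_times, c(I = 0.083, II = 0.212, III = 0.238, IV = 0.167, V = 0.092)),
      noise_sd = 0.05, intercept_sd = 0.04, bump_halfwidth = 1.5),
    water = behaviour_profile(
      "water",
      bp(zts, c(0.036, 0.028, 0.025, 0.032, 0.038, 0.04, 0.085, 0.15, 0.12,
                0.14, 0.11, 0.11, 0.11, 0.07)),
      pk(food_times, c(I = 0.071, II = 0.256, III = 0.262, IV = 0.267, V = 0.124)),
      noise_sd = 0.05, intercept_sd = 0.04, bump_halfwidth = 1.5),
    activity = behaviour_profile(
      "activity",
      bp(zts, c(2.6, 2.1, 1.5, 2, 2.2, 2.5, 9, 20, 12, 13, 9, 9, 10, 5.5)),
      pk(c(I = 8.7, II = 13.5, III = 17.3, IV = 22.3, V = 1.6),
         c(I = 3.95, II = 26.4, III = 24.5, IV = 20.7, V = 6.59)),
      noise_sd = 0.5, intercept_sd = 0.3, bump_halfwidth = 1.5),
    wake = behaviour_profile(
      "wake",
      bp(zts, c(0.27, 0.23, 0.18, 0.21, 0.22, 0.25, 0.52, 0.75, 0.62,
                0.64, 0.56, 0.56, 0.60, 0.40)),
      pk(c(I = 8.7, II = 13.7, III = 17.3, IV = 22.4, V = 1.6),
         c(I = 0.268, II = 0.847, III = 0.838, IV = 0.781, V = 0.365)),
      intercept_sd = 0.3, beta_precision = 30, bump_halfwidth = 1.5)
  )
}

#' Food profile for parameter-recovery experiments
#'
#' A deliberately clean food-intake profile for injected-effect recovery
#' studies: one broad late-light feeding elevation (window I, peaking at
#' ZT9.4, half-width 3.6 h -- wide enough that the 13-knot circadian basis
#' represents it, and
#' a delayed copy, with little attenuation), a gentle dark-onset rise to a
#' flat dark-phase plateau and a late-dark peak. Unlike [default_profiles()]
#' it omits the early-dark and mid-dark peaks so the window-I bout and its
#' delayed counterpart are never confounded with neighbouring features;
#' recovered peak-time and amplitude differences can then be compared
#' directly against the generator's truth table.
#'
#' @return A [behaviour_profile()] for food intake.
#' @export
recovery_food_profile <- function() {
  behaviour_profile(
    "food",
    baseline = data.frame(
      zt = c(0.5, 3.5, 5.5, 7.5, 9.5, 11.5, 12.5, 13.5, 15, 17, 19, 21, 22.5, 23.4),
      level = c(0.05, 0.04, 0.035, 0.04, 0.042, 0.045, 0.07, 0.12, 0.15,
                0.15, 0.14, 0.14, 0.12, 0.08)),
    peaks = data.frame(window = c("I", "IV"), time = c(9.4, 22),
                       amplitude = c(0.10, 0.167)),
    noise_sd = 0.05, intercept_sd = 0.04, bump_halfwidth = c(3.6, 1.5))
}

#' Pregnancy-effect specification
#'
#' Per study block (1: days 0.5-6.5, 2: 6.5-12.5, 3: 12.5-17.5): window-wise
#' peak-time delays (h) and amplitude fold-changes applied to the affected
#' behaviours (food and water by default), multiplicative dark-phase scaling
#' of activity and wakefulness, and a per-study-day delay (h) of dark-phase
#' activity onset. Positive delays and folds > 1 encode later/larger
#' behaviour in the pregnant group.
#'
#' @param blocks Named list (`"1"`, `"2"`, `"3"`), each a list with elements
#'   `amplitude_fold` and `peak_delay` (named numeric vectors over windows
#'   I-V), `activity_scale_dark` and `wake_scale_dark` (scalars in (0, 1]).
#' @param onset_delay Numeric vector of onset delays (h) for study days
#'   1..17; must be non-negative and non-decreasing.
#' @param affected Behaviours to which `amplitude_fold`/`peak_delay` apply.
#' @return An object of class `pregnancy_effects`.
#' @export
pregnancy_effects <- function(blocks = NULL, onset_delay = NULL,
                              affected = c("food", "water")) {
  wv <- function(...) {
    v <- c(...)
    stopifnot(identical(names(v), c("I", "II", "III", "IV", "V")))
    v
  }
  if (is.null(blocks)) {
    blocks <- list(
      `1` = list(amplitude_fold = wv(I = 0.9, II = 1.3, III = 0.9, IV = 1.25, V = 0.85),
                 peak_delay = wv(I = 0, II = 0.4, III = 0.5, IV = 0.1, V = 0.4),
                 activity_scale_dark = 0.45, wake_scale_dark = 0.85),
      `2` = list(amplitude_fold = wv(I = 2.0, II = 1.4, III = 1.0, IV = 1.1, V = 1.1),
                 peak_delay = wv(I = 1.6, II = 0, III = 0.3, IV = 0.1, V = 1.0),
                 activity_scale_dark = 0.50, wake_scale_dark = 0.78),
      `3` = list(amplitude_fold = wv(I = 3.1, II = 1.7, III = 1.0, IV = 0.76, V = 1.17),
                 peak_delay = wv(I = 1.6, II = 0.3, III = 0.8, IV = 0.3, V = 1.4),
                 activity_scale_dark = 0.35, wake_scale_dark = 0.73)
    )
  }
  if (is.null(onset_delay)) {
    onset_delay <- 1.8 + (6.0 - 1.8) * (seq_len(17) - 1) / 16
  }
  stop_if_not(all(onset_delay >= 0), "onset_delay must be non-negative")
  stop_if_not(!is.unsorted(onset_delay), "onset_delay must be non-decreasing")
  for (b in blocks) {
    stop_if_not(all(is.finite(b$peak_delay)), "peak_delay must be finite")
    stop_if_not(b$activity_scale_dark > 0 && b$activity_scale_dark <= 1,
                "activity_scale_dark must lie in (0, 1]")
  }
  structure(list(blocks = blocks, onset_delay = onset_delay,
                 affected = affected),
            class = "pregnancy_effects")
}

#' Null pregnancy effects (no group difference)
#'
#' All folds 1, delays 0, dark-phase scales 1 and onset delays 0: the pregnant
#' group is generated from the same profiles as the non-pregnant group. Used
#' for null-calibration experiments.
#'
#' @return A [pregnancy_effects()] object encoding no effect.
#' @export
null_effects <- function() {
  wv <- c(I = 1, II = 1, III = 1, IV = 1, V = 1)
  zv <- c(I = 0, II = 0, III = 0, IV = 0, V = 0)
  b <- list(amplitude_fold = wv, peak_delay = zv,
            activity_scale_dark = 1, wake_scale_dark = 1)
  pregnancy_effects(blocks = list(`1` = b, `2` = b, `3` = b),
                    onset_delay = rep(0, 17))
}
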