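# Synthetic-cohort generation: raw per-interval cage records for a virtual
# cohort with known circadian structure and pregnancy effects.

#' Cohort configuration
#'
#' Describes the virtual study: group sizes, the termination schedule at study
#' days 6.5/12.5/17.5 (thirds of mouse pregnancy), the acclimation length, and
#' the recording interval. Time is counted in decimal study days with integer
#' boundaries at lights-on (ZT0); the study spans days 0.5-17.5 (first
#' lights-off to last termination) and acclimation the preceding
#' `acclimation_days` full days.
#'
#' @param n_nonpregnant,n_pregnant Group sizes.
#' @param termination_schedule Named list with elements `nonpregnant` and
#'   `pregnant`, each a length-3 vector of counts removed at days 6.5, 12.5
#'   and 17.5; must sum to the group size.
#' @param acclimation_days Days of acclimation before study day 0.5.
#' @param study_days Length of the study in days (last termination at
#'   `study_days + 0.5`).
#' @param sampling_interval Recording interval in seconds; must divide 3600.
#' @param random_seed Integer seed; mandatory (reproducibility contract).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_nonpregnant = 12, n_pregnant = 31,
                          termination_schedule = NULL,
                          acclimation_days = 7, study_days = 17,
                          sampling_interval = 300, random_seed = NULL) {
  stop_if_not(is.numeric(n_nonpregnant) && n_nonpregnant > 0 &&
                is.numeric(n_pregnant) && n_pregnant > 0,
              "group sizes must be positive")
  stop_if_not(3600 %% sampling_interval == 0,
              "sampling_interval must divide 3600")
  stop_if_not(!is.null(random_seed) && is.finite(random_seed),
              "random_seed is mandatory: synthetic cohorts must be reproducible")
  if (is.null(termination_schedule)) {
    termination_schedule <- list(
      nonpregnant = default_split(n_nonpregnant, c(4, 2, 6) / 12),
      pregnant = default_split(n_pregnant, c(10, 10, 11) / 31)
    )
  }
  for (g in GROUPS) {
    n <- if (g == "nonpregnant") n_nonpregnant else n_pregnant
    stop_if_not(length(termination_schedule[[g]]) == 3 &&
                  sum(termination_schedule[[g]]) == n,
                sprintf("termination counts for %s must sum to group size", g))
  }
  structure(list(n_nonpregnant = n_nonpregnant, n_pregnant = n_pregnant,
                 termination_schedule = termination_schedule,
                 acclimation_days = acclimation_days, study_days = study_days,
                 sampling_interval = sampling_interval,
                 random_seed = as.integer(random_seed)),
            class = "cohort_config")
}

# Split n across the three termination days roughly in the given proportions.
default_split <- function(n, prop) {
  k <- floor(n * prop)
  k[3] <- n - k[1] - k[2]
  k
}

#' Generate raw cage records for a synthetic cohort
#'
#' Produces one record per mouse x recording interval x behaviour over the
#' acclimation and study periods. Intake and activity are generated on the
#' square-root scale: for each mouse-hour, the recorded hourly total is
#' `(sqrt(curve) + intercept + noise)^2` (negative sqrt-scale draws truncated
#' at zero), distributed evenly over the hour's intervals; the per-mouse
#' intercept is drawn once. Wake fractions are drawn per 5-min block from a
#' beta distribution whose mean is the profile curve shifted by a logit-scale
#' mouse intercept. Pregnancy effects apply from study day 0.5 onward
#' (acclimation precedes mating); the pregnant dark-phase activity rhythm is
#' additionally shifted later by the scheduled per-day onset delay, so the
#' post-lights-off rise (and the detected activity onset) moves by exactly
#' that delay. Mice terminated at 6.5/12.5/17.5 emit no further records.
#'
#' @param config A [cohort_config()] (seed mandatory).
#' @param profiles Named list of [behaviour_profile()]s; default
#'   [default_profiles()].
#' @param effects A [pregnancy_effects()] specification; default the
#'   study-like effects, use [null_effects()] for none.
#' @param behaviours Which behaviours to generate (subset of profile names).
#' @return data.table of raw records with columns
#'   `mouse_id, group, day, zt_hour, behaviour, value` (`day` decimal study
#'   days, negative during acclimation; `zt_hour` decimal ZT of the interval
#'   start; `value` units per interval: g, m, or wake fraction).
#' @export
generate_cohort <- function(config, profiles = default_profiles(),
                            effects = pregnancy_effects(),
                            behaviours = names(profiles)) {
  stop_if_not(inherits(config, "cohort_config"), "config must be a cohort_config")
  behaviours <- match.arg(behaviours, BEHAVIOURS, several.ok = TRUE)
  set.seed(config$random_seed)
  mice <- cohort_mice(config)
  dt_day <- config$sampling_interval / 86400
  dt_h <- config$sampling_interval / 3600
  t0 <- 0.5 - config$acclimation_days

  # pre-build mean curves: baseline (acclimation / non-pregnant) and the
  # pregnant per-block curves, per behaviour
  curves <- lapply(behaviours, function(b) {
    list(base = profile_curve(profiles[[b]]),
         preg = lapply(1:3, function(k)
           profile_curve(profiles[[b]], effects, "pregnant", k)))
  })
  names(curves) <- behaviours

  out <- vector("list", nrow(mice) * length(behaviours))
  ix <- 0L
  for (m in seq_len(nrow(mice))) {
    tm <- seq(t0, mice$term_day[m] - dt_day / 2, by = dt_day)
    zt <- (tm %% 1) * 24
    hour_id <- floor(tm * 24 + 1e-9)
    blk <- findInterval(tm, c(0.5, 6.5, 12.5))  # 0 = acclimation
    pregnant <- mice$group[m] == "pregnant"
    for (b in behaviours) {
      pr <- profiles[[b]]
      mu <- curves[[b]]$base(zt)
      if (pregnant) {
        for (k in 1:3) {
          sel <- blk == k
          if (any(sel)) mu[sel] <- curves[[b]]$preg[[k]](zt[sel])
        }
        if (b == "activity") {
          mu <- delay_onset(mu, tm, zt, blk, effects, curves[[b]]$preg)
        }
      }
      if (b == "wake") {
        icpt <- stats::rnorm(1, 0, pr$intercept_sd)
        muw <- stats::plogis(stats::qlogis(mu) + icpt)
        phi <- pr$beta_precision
        val <- stats::rbeta(length(muw), muw * phi, (1 - muw) * phi)
      } else {
        icpt <- stats::rnorm(1, 0, pr$intercept_sd)
        uh <- match(hour_id, unique(hour_id))
        eps <- stats::rnorm(max(uh), 0, pr$noise_sd)[uh]
        s <- pmax(sqrt(mu) + icpt + eps, 0)
        val <- dt_h * s^2
      }
      ix <- ix + 1L
      out[[ix]] <- data.table::data.table(
        mouse_id = mice$mouse_id[m], group = mice$group[m],
        day = tm, zt_hour = zt, behaviour = b, value = val)
    }
  }
  rec <- data.table::rbindlist(out)
  data.table::setkey(rec, mouse_id, behaviour, day)
  rec[]
}

# Mouse roster with termination days.
cohort_mice <- function(config) {
  term_days <- c(6.5, 12.5, 17.5)
  rows <- list()
  for (g in GROUPS) {
    n <- if (g == "nonpregnant") config$n_nonpregnant else config$n_pregnant
    term <- rep(term_days, times = config$termination_schedule[[g]])
    pfx <- if (g == "nonpregnant") "NP" else "PG"
    rows[[g]] <- data.frame(
      mouse_id = sprintf("%s%02d", pfx, seq_len(n)),
      group = g, term_day = pmin(term, config$study_days + 0.5),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# For pregnant mice, delay the dark-phase activity rhythm: on study day d the
# night-time mean follows the curve evaluated at zt - delay_d, so the whole
# rise after lights-off (and hence the detected activity onset) shifts later
# by exactly the scheduled delay.
delay_onset <- function(mu, tm, zt, blk, effects, preg_curves) {
  day_lab <- ceiling(tm)  # night [d - 0.5, d) belongs to study day d
  frac <- tm %% 1
  nd <- length(effects$onset_delay)
  delay <- ifelse(day_lab >= 1 & day_lab <= nd & tm >= 0.5,
                  effects$onset_delay[pmin(pmax(day_lab, 1), nd)], 0)
  shift <- frac >= 0.5 & delay > 0 & blk > 0
  if (any(shift)) {
    for (k in 1:3) {
      sel <- shift & blk == k
      if (any(sel)) mu[sel] <- preg_curves[[k]](zt[sel] - delay[sel])
    }
  }
  mu
}

#' True peak and onset parameters implied by a generator configuration
#'
#' Computes, from the noiseless mean curves, the true peak presence, times and
#' amplitudes per behaviour x group x study block x ZT window (interior local
#' maxima on a 0.005 h grid of the unwrapped ZT6-ZT30 axis, largest-amplitude
#' rule), their pregnant-minus-non-pregnant differences, and the true
#' dark-phase activity-onset delays per study day. Used as ground truth in
#' parameter-recovery experiments.
#'
#' @inheritParams generate_cohort
#' @return List with `peaks` (data.table: behaviour, block, window, per-group
#'   presence/time/amplitude, `diff_time`, `diff_amplitude`) and `onset`
#'   (data.frame: day, `delay` in hours).
#' @export
truth_table <- function(config, profiles = default_profiles(),
                        effects = pregnancy_effects(),
                        behaviours = names(profiles)) {
  grid <- seq(ZT_AXIS_MIN, ZT_AXIS_MAX, by = 0.005)
  win <- time_windows()
  rows <- list()
  for (b in behaviours) {
    for (blk in 1:3) {
      fN <- profile_curve(profiles[[b]])
      fP <- profile_curve(profiles[[b]], effects, "pregnant", blk)
      vN <- fN(grid); vP <- fP(grid)
      for (w in seq_len(nrow(win))) {
        pN <- scan_window_peak(vN, grid, win$lo[w], win$hi[w])
        pP <- scan_window_peak(vP, grid, win$lo[w], win$hi[w])
        rows[[length(rows) + 1L]] <- data.table::data.table(
          behaviour = b, block = blk, window = win$window[w],
          present_nonpregnant = pN$present, present_pregnant = pP$present,
          time_nonpregnant = pN$time, time_pregnant = pP$time,
          amplitude_nonpregnant = pN$amplitude, amplitude_pregnant = pP$amplitude,
          diff_time = pP$time - pN$time,
          diff_amplitude = pP$amplitude - pN$amplitude)
      }
    }
  }
  nd <- length(effects$onset_delay)
  list(peaks = data.table::rbindlist(rows),
       onset = data.frame(day = seq_len(nd), delay = effects$onset_delay))
}

# Largest interior local maximum of v within [lo, hi); ties -> earliest.
scan_window_peak <- function(v, grid, lo, hi) {
  n <- length(v)
  i <- 2:(n - 1)
  is_max <- v[i] > v[i - 1] & v[i] > v[i + 1] & grid[i] >= lo & grid[i] < hi
  idx <- i[is_max]
  if (!length(idx)) return(list(present = FALSE, time = NA_real_, amplitude = NA_real_))
  best <- idx[which.max(v[idx])]
  list(present = TRUE, time = grid[best], amplitude = v[best])
}

#' Write raw records, a truth table and a configuration to disk
#'
#' Records and truth tables are written as CSV, the configuration as YAML.
#'
#' @param records data.table from [generate_cohort()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  data.table::fwrite(records, path)
  invisible(path)
}

#' @rdname write_records
#' @param config A [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
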