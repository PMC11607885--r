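# Dark-phase activity-onset detection and group comparison.

#' Per-mouse activity threshold from the acclimation period
#'
#' The threshold is the arithmetic mean of a mouse's 5-min activity values
#' over all dark-phase (ZT12-ZT24) blocks of the acclimation period.
#'
#' @param fivemin 5-min activity blocks from [five_min_blocks()] (behaviour
#'   `"activity"`), covering the acclimation period (`day < 0.5`).
#' @return data.frame with `mouse_id` and `threshold` (m per 5 min).
#' @export
acclimation_threshold <- function(fivemin) {
  fm <- data.table::as.data.table(fivemin)
  fm <- fm[behaviour == "activity" & day < 0.5 &
             zt_start >= DARK_START & zt_start < DARK_END]
  stop_if_not(nrow(fm) > 0, "no acclimation dark-phase activity blocks")
  out <- fm[, .(threshold = mean(value)), by = mouse_id]
  as.data.frame(out)
}

#' Detect dark-phase activity onset for one night
#'
#' Onset is the start time (hours after lights-off) of the first run of at
#' least three consecutive 5-min blocks whose activity strictly exceeds the
#' threshold. Gaps in the block sequence break runs (a missing block cannot
#' count as above-threshold). If no qualifying run starts within the dark
#' phase, onset is censored at 12 h.
#'
#' @param time_h Block start times in hours after lights-off (multiples of
#'   1/12 h), in increasing order.
#' @param value Activity per 5-min block (m), same length as `time_h`.
#' @param threshold Threshold (m per 5 min).
#' @return list with `onset` (h, in `[0, 12]`) and `censored` (logical;
#'   `onset == 12` iff censored).
#' @export
detect_onset <- function(time_h, value, threshold) {
  stop_if_not(length(time_h) == length(value), "time/value length mismatch")
  if (length(time_h) >= 3) {
    slot <- round(time_h * 12)
    above <- value > threshold
    contig <- c(diff(slot) == 1L, FALSE)
    ok <- above &
      c(above[-1], FALSE) & contig &
      c(above[-(1:2)], FALSE, FALSE) & c(contig[-1], FALSE)
    hit <- which(ok & time_h < 12)
    if (length(hit)) {
      return(list(onset = time_h[hit[1]], censored = FALSE))
    }
  }
  list(onset = 12, censored = TRUE)
}

#' Per-mouse, per-night activity-onset times
#'
#' Applies [detect_onset()] to every night (dark phase) in the data, using
#' each mouse's own acclimation threshold (or an explicit numeric override).
#' Nights are labelled by study day: night `[d - 0.5, d)` is day `d`, so
#' acclimation nights carry labels `<= 0` and study nights 1..17.
#'
#' @param records Raw activity records (or all behaviours; activity is
#'   selected), at 5-min or finer resolution.
#' @param thresholds data.frame from [acclimation_threshold()], or a single
#'   number applied to every mouse.
#' @param interval_s Recording interval of `records` in seconds.
#' @return data.table: `mouse_id, group, day, phase, onset, censored`.
#' @export
onset_results <- function(records, thresholds = NULL, interval_s = 300) {
  fm <- five_min_blocks(
    data.table::as.data.table(records)[behaviour == "activity"], interval_s)
  if (is.null(thresholds)) thresholds <- acclimation_threshold(fm)
  if (is.numeric(thresholds) && length(thresholds) == 1) {
    thresholds <- data.frame(mouse_id = unique(fm$mouse_id),
                             threshold = thresholds)
  }
  dark <- fm[zt_start >= DARK_START & zt_start < DARK_END & complete]
  dark[, night := ceiling(day)]
  dark[, after_off := zt_start - DARK_START]
  dark <- merge(dark, data.table::as.data.table(thresholds), by = "mouse_id")
  res <- dark[order(after_off),
              c(detect_onset(after_off, value, threshold[1])),
              by = .(mouse_id, group, night)]
  data.table::setnames(res, "night", "day")
  res[, phase := ifelse(day < 1, "acclimation", "study")]
  data.table::setkey(res, mouse_id, day)
  res[]
}

#' Share of acclimation nights with prompt activity onset
#'
#' Returns the fraction of acclimation mouse-nights whose onset falls within
#' `within_h` hours of lights-off, and the share of mice achieving that on at
#' least one acclimation night.
#'
#' @param onsets Onset results from [onset_results()].
#' @param within_h Window after lights-off (h), default 2.
#' @return list with `fraction_nights` and `fraction_mice`.
#' @export
validate_acclimation <- function(onsets, within_h = 2) {
  on <- data.table::as.data.table(onsets)
  acc <- if ("phase" %in% names(on)) on[phase == "acclimation"] else on
  if (nrow(acc) == 0) return(list(fraction_nights = NA_real_, fraction_mice = NA_real_))
  hit <- acc$onset <= within_h
  by_mouse <- tapply(hit, acc$mouse_id, any)
  list(fraction_nights = mean(hit), fraction_mice = mean(by_mouse))
}

#' Mixed-model comparison of activity-onset times between groups
#'
#' Fits a linear mixed model with pregnancy status (between-animal), study day
#' (categorical, within-animal) and their interaction as fixed effects and a
#' random intercept per mouse. Censored onsets enter as their recorded 12 h
#' value. Reports the interaction test (Satterthwaite F) and per-day
#' pregnant-minus-non-pregnant differences with two-sided Wald p-values (no
#' multiplicity correction). On balanced complete data the estimates equal
#' ordinary two-way repeated-measures results.
#'
#' @param onsets Onset results from [onset_results()]; only study nights
#'   (`day >= 1`) are modelled.
#' @return list with `model` (the lmerTest fit), `interaction`
#'   (data.frame: F, df, p), `per_day` (data.frame: day, estimate, SE, df,
#'   p.value) and `singular` (logical).
#' @export
onset_group_model <- function(onsets) {
  on <- data.table::as.data.table(onsets)[day >= 1]
  stop_if_not(length(unique(on$group)) == 2, "need both groups")
  stop_if_not(all(table(unique(on[, .(mouse_id, group)])$group) >= 2),
              "need >= 2 mice per group")
  d <- data.frame(onset = on$onset,
                  group = factor(on$group, levels = GROUPS),
                  day = factor(on$day),
                  mouse = factor(on$mouse_id))
  fit <- lmerTest::lmer(onset ~ group * day + (1 | mouse), data = d)
  singular <- lme4::isSingular(fit)
  if (singular) message("onset model: singular random-effect fit (reported, not dropped)")
  an <- stats::anova(fit, type = 3)
  ia <- an[rownames(an) == "group:day", , drop = FALSE]
  interaction <- data.frame(F = ia[["F value"]], df1 = ia[["NumDF"]],
                            df2 = ia[["DenDF"]], p = ia[["Pr(>F)"]])
  emm <- emmeans::emmeans(fit, ~ group | day,
                          lmer.df = "satterthwaite",
                          lmerTest.limit = 1e5)
  ctr <- summary(emmeans::contrast(emm, method = "revpairwise"), adjust = "none")
  per_day <- data.frame(day = as.numeric(as.character(ctr$day)),
                        estimate = ctr$estimate, SE = ctr$SE, df = ctr$df,
                        p.value = ctr$p.value)
  list(model = fit, interaction = interaction, per_day = per_day,
       singular = singular)
}
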