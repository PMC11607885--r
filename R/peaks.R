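# Posterior peak detection within ZT windows and Table-style summaries.

#' Detect a local-maximum peak of one curve within a ZT window
#'
#' A peak is present iff some grid point strictly greater than both of its
#' neighbours lies inside the half-open window; boundary maxima (monotone
#' stretches ending at a window edge) never count. Among multiple local
#' maxima the largest amplitude wins, ties going to the earliest time.
#'
#' @param values Curve values on the grid.
#' @param grid Grid times (h, unwrapped axis); must cover the window plus at
#'   least one grid point on each side.
#' @param window Length-2 numeric `c(lo, hi)` or a window id `"I"`-`"V"`.
#' @return list with `present`, `time` and `amplitude` (`NA` when absent).
#' @export
detect_peak <- function(values, grid, window) {
  if (is.character(window)) {
    w <- time_windows()
    window <- unlist(w[w$window == window, c("lo", "hi")])
  }
  stop_if_not(length(window) == 2 && window[1] < window[2], "bad window")
  stop_if_not(min(grid) < window[1] && max(grid) >= window[2],
              "grid must cover the window plus one point each side")
  scan_window_peak(values, grid, window[1], window[2])
}

# Vectorised over posterior draws: for a draws x grid matrix, the chosen peak
# per draw within [lo, hi). Local-maximum test uses the full grid so window
# edges have true neighbours.
peaks_by_draw <- function(M, grid, lo, hi) {
  n <- ncol(M)
  inner <- 2:(n - 1)
  locmax <- M[, inner, drop = FALSE] > M[, inner - 1, drop = FALSE] &
    M[, inner, drop = FALSE] > M[, inner + 1, drop = FALSE]
  inwin <- grid[inner] >= lo & grid[inner] < hi
  cand <- sweep(locmax, 2, inwin, `&`)
  vals <- M[, inner, drop = FALSE]
  vals[!cand] <- -Inf
  present <- rowSums(cand) > 0
  best <- max.col(vals, ties.method = "first")
  time <- grid[inner][best]
  amp <- vals[cbind(seq_len(nrow(M)), best)]
  time[!present] <- NA_real_
  amp[!present] <- NA_real_
  data.table::data.table(draw = seq_len(nrow(M)), present = present,
                         time = time, amplitude = amp)
}

#' Per-draw peaks of posterior curves in all ZT windows
#'
#' Applies the local-maximum rule to every posterior draw of every
#' group x block curve within each of the five ZT windows.
#'
#' @param pc A [posterior_curves()] object.
#' @return data.table: `behaviour, group, block, window, draw, present, time,
#'   amplitude`.
#' @export
draw_peaks <- function(pc) {
  stop_if_not(inherits(pc, "posterior_curves"), "need a posterior_curves object")
  win <- time_windows()
  out <- list()
  for (nm in names(pc$cells)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    for (w in seq_len(nrow(win))) {
      dp <- peaks_by_draw(pc$cells[[nm]], pc$grid, win$lo[w], win$hi[w])
      dp[, `:=`(behaviour = pc$behaviour, group = parts[1],
                block = as.integer(parts[2]), window = win$window[w])]
      out[[length(out) + 1L]] <- dp
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("behaviour", "group", "block", "window",
                                 "draw", "present", "time", "amplitude"))
  res[]
}

#' Credible-interval significance rule
#'
#' An effect is significant iff its credible interval excludes zero:
#' both endpoints strictly share a sign (a closed endpoint at zero counts as
#' crossing).
#'
#' @param lo,hi Interval endpoints.
#' @return Logical vector.
#' @export
cri_significant <- function(lo, hi) {
  stop_if_not(!any(is.nan(lo) | is.nan(hi)), "NaN interval endpoint")
  lo > 0 | hi < 0
}

#' Summarise per-draw peaks into a Table-style comparison
#'
#' For each window x block: presence percentage per group over all draws;
#' posterior mean and 2.5/97.5% quantiles of peak time and amplitude over
#' draws with a detected peak; and the pregnant-minus-non-pregnant time and
#' amplitude differences computed per draw over draws in which BOTH groups
#' show a peak, with the credible-interval significance rule. Differences are
#' reported as undefined (with a note) when fewer than `min_joint` of draws
#' have joint presence.
#'
#' @param dp data.table from [draw_peaks()].
#' @param min_joint Minimum joint-presence fraction for reporting differences.
#' @return data.table with one row per behaviour x window x block.
#' @export
summarise_peaks <- function(dp, min_joint = 0.01) {
  dp <- data.table::as.data.table(dp)
  q <- function(x, p) if (length(x)) unname(stats::quantile(x, p)) else NA_real_
  mn <- function(x) if (length(x)) mean(x) else NA_real_
  out <- dp[, {
    N <- .SD[group == "nonpregnant"][order(draw)]
    P <- .SD[group == "pregnant"][order(draw)]
    joint <- N$present & P$present
    dt_ <- P$time[joint] - N$time[joint]
    da_ <- P$amplitude[joint] - N$amplitude[joint]
    low_joint <- mean(joint) < min_joint
    list(
      presence_nonpregnant = 100 * mean(N$present),
      presence_pregnant = 100 * mean(P$present),
      time_nonpregnant = mn(N$time[N$present]),
      time_np_lo = q(N$time[N$present], 0.025),
      time_np_hi = q(N$time[N$present], 0.975),
      time_pregnant = mn(P$time[P$present]),
      time_pg_lo = q(P$time[P$present], 0.025),
      time_pg_hi = q(P$time[P$present], 0.975),
      amp_nonpregnant = mn(N$amplitude[N$present]),
      amp_np_lo = q(N$amplitude[N$present], 0.025),
      amp_np_hi = q(N$amplitude[N$present], 0.975),
      amp_pregnant = mn(P$amplitude[P$present]),
      amp_pg_lo = q(P$amplitude[P$present], 0.025),
      amp_pg_hi = q(P$amplitude[P$present], 0.975),
      joint_presence = mean(joint),
      diff_time = if (low_joint) NA_real_ else mn(dt_),
      diff_time_lo = if (low_joint) NA_real_ else q(dt_, 0.025),
      diff_time_hi = if (low_joint) NA_real_ else q(dt_, 0.975),
      diff_amp = if (low_joint) NA_real_ else mn(da_),
      diff_amp_lo = if (low_joint) NA_real_ else q(da_, 0.025),
      diff_amp_hi = if (low_joint) NA_real_ else q(da_, 0.975),
      note = if (low_joint) "difference undefined: <1% joint-presence draws"
             else NA_character_
    )
  }, by = .(behaviour, window, block)]
  out[, sig_time := ifelse(is.na(diff_time_lo), NA,
                           cri_significant(diff_time_lo, diff_time_hi))]
  out[, sig_amp := ifelse(is.na(diff_amp_lo), NA,
                          cri_significant(diff_amp_lo, diff_amp_hi))]
  out[]
}
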