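# Shared constants and small helpers.

# Unwrapped circadian axis: hours since lights-on, running ZT6 -> ZT30 so the
# dark phase (ZT12-ZT24) sits in the interior.  Calendar hours ZT0-ZT6 of day d
# are mapped to ZT24-ZT30 of day d-1.
ZT_AXIS_MIN <- 6
ZT_AXIS_MAX <- 30
ZT_GRID_STEP <- 0.05

DARK_START <- 12
DARK_END <- 24

BEHAVIOURS <- c("food", "water", "activity", "wake")
GROUPS <- c("nonpregnant", "pregnant")

#' Five Zeitgeber-time windows of interest
#'
#' Windows on the unwrapped ZT6-ZT30 axis within which local behavioural peaks
#' are assessed: I late light phase, II early dark, III mid dark, IV late dark,
#' V early light phase of the following cycle (ZT24-ZT28 = ZT0-ZT4).
#'
#' @return A data.frame with columns `window` (I-V), `lo` and `hi` (hours,
#'   half-open `[lo, hi)`).
#' @export
time_windows <- function() {
  data.frame(
    window = c("I", "II", "III", "IV", "V"),
    lo = c(8, 12, 15, 18, 24),
    hi = c(12, 15, 18, 24, 28),
    stringsAsFactors = FALSE
  )
}

# Map calendar ZT in [0, 24) to the unwrapped axis [6, 30).
unwrap_zt <- function(zt) ifelse(zt < ZT_AXIS_MIN, zt + 24, zt)

# Inverse: unwrapped hour back to calendar ZT in [0, 24).
wrap_zt <- function(t) t %% 24

zt_grid <- function(step = ZT_GRID_STEP) seq(ZT_AXIS_MIN, ZT_AXIS_MAX, by = step)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
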