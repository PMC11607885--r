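# Ingest and preprocess raw cage records into the hourly per-mouse series the
# circadian models consume.

#' Read raw cage records from CSV
#'
#' Reads the dialect written by [write_records()]
#' (`mouse_id,group,day,zt_hour,behaviour,value`). A column-rename mapping can
#' be supplied (directly or as a YAML file) for exports whose macro column
#' names differ, e.g. Promethion-style extracts.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector (or YAML file path
#'   holding one) mapping standard names to the file's column names.
#' @return data.table of raw records.
#' @export
read_records <- function(path, column_map = NULL) {
  rec <- data.table::fread(path)
  if (!is.null(column_map)) {
    if (is.character(column_map) && length(column_map) == 1 &&
        file.exists(column_map)) {
      column_map <- unlist(yaml::read_yaml(column_map))
    }
    data.table::setnames(rec, unname(column_map), names(column_map),
                         skip_absent = TRUE)
  }
  need <- c("mouse_id", "group", "day", "zt_hour", "behaviour", "value")
  missing <- setdiff(need, names(rec))
  stop_if_not(length(missing) == 0,
              paste0("ingest: missing required columns: ",
                     paste(missing, collapse = ", ")))
  rec
}

#' Exclude negligible food-intake events
#'
#' Removes food records below the detection limit (default 0.002 g,
#' strictly `<`, so boundary events are kept). Other behaviours are untouched.
#' Negative values are rejected (dropped) with a warning.
#'
#' @param records Raw records.
#' @param min_intake Exclusion limit in grams.
#' @return Filtered records.
#' @export
filter_food_events <- function(records, min_intake = 0.002) {
  records <- data.table::as.data.table(records)
  neg <- records$value < 0
  if (any(neg)) {
    warning(sprintf("rejecting %d record(s) with negative values", sum(neg)))
    records <- records[!neg]
  }
  records[behaviour != "food" | value >= min_intake]
}

#' Score sleep from a 1 Hz stillness signal
#'
#' Sleep is stillness lasting at least `min_run` seconds (default 40 s).
#' Seconds belonging to qualifying stillness runs count as sleep; the
#' asleep fraction per 5-min block is sleep seconds / 300. Runs are qualified
#' on their full length before being split across block boundaries, so a long
#' run spanning blocks contributes to both.
#'
#' @param still Logical (or 0/1) vector at 1 s resolution, `TRUE` = still.
#' @param min_run Minimum qualifying run length in seconds.
#' @param block_s Block length in seconds.
#' @return data.frame with `block` (0-based index), `asleep_fraction` and
#'   `awake_fraction` (summing to 1 exactly).
#' @export
score_sleep <- function(still, min_run = 40, block_s = 300) {
  still <- as.logical(still)
  stop_if_not(!anyNA(still), "stillness signal must not contain NA")
  r <- rle(still)
  sleep <- rep(r$values & r$lengths >= min_run, r$lengths)
  block <- (seq_along(still) - 1L) %/% block_s
  frac <- tapply(sleep, block, mean)
  data.frame(block = as.integer(names(frac)),
             asleep_fraction = as.numeric(frac),
             awake_fraction = 1 - as.numeric(frac))
}

#' Assign study days to study blocks
#'
#' Blocks correspond to thirds of mouse pregnancy: 1 = days 0.5-6.5,
#' 2 = 6.5-12.5, 3 = 12.5-17.5. Intervals are half-open `[lo, hi)` with the
#' final boundary closed, so boundary days (terminations) belong to the later
#' block. Days outside 0.5-17.5 are excluded (`NA`) with a message.
#'
#' @param day Numeric vector of decimal study days.
#' @return Integer vector of blocks (1-3), `NA` outside the study range.
#' @export
assign_block <- function(day) {
  blk <- findInterval(day, c(0.5, 6.5, 12.5))
  blk[day < 0.5 | day > 17.5] <- NA_integer_
  if (anyNA(blk)) {
    message(sprintf("assign_block: %d day value(s) outside 0.5-17.5 excluded",
                    sum(is.na(blk))))
  }
  as.integer(blk)
}

# Sum/average raw records into 5-min blocks. Intake/activity values are
# per-interval amounts and are summed; wake fractions are averaged.
# Food and water are event streams: a block without events within a mouse's
# observed span is an observed zero, so intake blocks are zero-filled.
# Activity and wake are continuous signals, so an absent block there is
# genuinely missing (complete = FALSE propagates to the hourly series).
five_min_blocks <- function(records, interval_s = 300) {
  stop_if_not(interval_s <= 300, "raw input must be at interval <= 300 s")
  rec <- data.table::as.data.table(records)
  per_block <- as.integer(round(300 / interval_s))
  rec[, slot := floor(day * 288 + 1e-7)]
  agg <- rec[, {
    if (.N > per_block) stop("duplicate records within a 5-min block", call. = FALSE)
    list(value = if (behaviour[1] == "wake") mean(value) else sum(value),
         n_rec = .N)
  }, by = .(mouse_id, group, behaviour, slot)]
  agg[, complete := n_rec == per_block]
  intake <- agg$behaviour %in% c("food", "water")
  if (any(intake)) {
    filled <- agg[intake][, {
      full <- seq(min(slot), max(slot))
      i <- match(full, slot)
      list(slot = full,
           value = ifelse(is.na(i), 0, value[i]),
           n_rec = per_block, complete = TRUE)
    }, by = .(mouse_id, group, behaviour)]
    agg <- rbind(agg[!intake], filled, use.names = TRUE)
  }
  agg[, day := slot / 288]
  agg[, zt_start := (slot %% 288) / 12]
  agg[]
}

#' Aggregate raw records into five-minute blocks and hourly series
#'
#' Raw records at any interval up to 300 s are first combined into 5-min
#' blocks (sums for intake/activity, fractions for wake), then into hourly
#' values: intake/activity hourly values are the sum of the twelve 5-min
#' sums (units per hour), wake the mean fraction. For the continuous signals
#' (activity, wake) hours missing any of their twelve blocks are flagged
#' missing (`NA`) rather than rescaled, to avoid biasing amplitudes; for the
#' event streams (food, water) a block without events inside a mouse's
#' observed span is an observed zero and is filled as such. Already-hourly
#' input (interval 3600 s) passes through unchanged, making aggregation
#' idempotent.
#'
#' @param records Raw records (columns `mouse_id, group, day, zt_hour,
#'   behaviour, value`).
#' @param interval_s Recording interval of the input in seconds.
#' @return data.table hourly series: `mouse_id, group, phase, day` (decimal
#'   day at hour start), `zt_hour` (integer 0-23), `block` (study block or
#'   `NA` in acclimation), `behaviour`, `value` (g/h, m/h or wake fraction).
#' @export
aggregate_records <- function(records, interval_s = 300) {
  rec <- data.table::as.data.table(records)
  if (interval_s == 3600) {
    hourly <- rec[, .(mouse_id, group, behaviour,
                      hour = floor(day * 24 + 1e-7), value)]
    if (anyDuplicated(hourly[, .(mouse_id, behaviour, hour)]) > 0)
      stop("duplicate hourly records", call. = FALSE)
  } else {
    fm <- five_min_blocks(rec, interval_s)
    fm[, hour := slot %/% 12]
    hourly <- fm[, {
      ok <- .N == 12L && all(complete)
      v <- if (!ok) NA_real_
           else if (behaviour[1] == "wake") mean(value) else sum(value)
      list(value = v)
    }, by = .(mouse_id, group, behaviour, hour)]
  }
  hourly[, day := hour / 24]
  hourly[, zt_hour := as.integer(hour %% 24)]
  hourly[, phase := ifelse(day < 0.5, "acclimation", "study")]
  suppressMessages(hourly[, block := assign_block(day)])
  data.table::setcolorder(hourly, c("mouse_id", "group", "phase", "day",
                                    "zt_hour", "block", "behaviour", "value"))
  hourly[, hour := NULL]
  data.table::setkey(hourly, mouse_id, behaviour, day)
  hourly[]
}
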