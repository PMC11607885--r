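# Independent brute-force oracles shared by the unit and acceptance suites.
# Deliberately written as direct scans, independent of the package's
# implementations.

# Check every candidate start index of a three-consecutive-blocks run.
brute_onset <- function(time_h, value, threshold) {
  slot <- round(time_h * 12)
  n <- length(value)
  for (i in seq_len(n)) {
    if (time_h[i] >= 12) next
    if (i + 2 > n) next
    if (all(value[i:(i + 2)] > threshold) &&
        slot[i + 1] == slot[i] + 1 && slot[i + 2] == slot[i] + 2) {
      return(list(onset = time_h[i], censored = FALSE))
    }
  }
  list(onset = 12, censored = TRUE)
}

# Exhaustive scan of all grid points for the largest interior local maximum.
brute_peak <- function(values, grid, lo, hi) {
  best <- NULL
  for (i in seq_along(grid)) {
    if (i == 1 || i == length(grid)) next
    if (grid[i] < lo || grid[i] >= hi) next
    if (values[i] > values[i - 1] && values[i] > values[i + 1]) {
      if (is.null(best) || values[i] > best$amplitude) {
        best <- list(present = TRUE, time = grid[i], amplitude = values[i])
      }
    }
  }
  if (is.null(best)) list(present = FALSE, time = NA_real_, amplitude = NA_real_)
  else best
}

# Smooth random curve on the unwrapped axis (random Fourier series).
random_curve <- function(grid, seed) {
  set.seed(seed)
  k <- 1:5
  a <- rnorm(5, 0, 1 / k); b <- rnorm(5, 0, 1 / k)
  drop(cos(outer(grid, k) * pi / 12) %*% a + sin(outer(grid, k) * pi / 12) %*% b)
}
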