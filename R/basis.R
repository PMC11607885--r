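# Natural cubic spline basis over the unwrapped circadian axis.

#' Knot positions of the circadian spline basis
#'
#' Thirteen knots evenly spaced from ZT8.5 to ZT28.5 (= ZT4.5 of the next
#' cycle), spacing 20/12 h, on the unwrapped ZT6-ZT30 axis. The two extreme
#' positions serve as the boundary knots of the natural spline; the curve is
#' linear beyond them.
#'
#' @return Numeric vector of 13 knot positions (hours).
#' @export
circadian_knots <- function() seq(8.5, 28.5, length.out = 13)

#' Evaluate the circadian natural-spline basis
#'
#' Natural cubic spline basis (continuous value, first and second derivative
#' at interior knots; linear tails beyond the boundary knots) evaluated at
#' unwrapped ZT hours.
#'
#' @param t Unwrapped ZT hours (ZT6-ZT30 axis).
#' @return Basis matrix (one column per degree of freedom, 12 columns).
#' @export
circadian_basis <- function(t) {
  k <- circadian_knots()
  splines::ns(t, knots = k[-c(1, length(k))],
              Boundary.knots = k[c(1, length(k))])
}

# Unwrapped hour for an integer ZT hour: hour centre, hours 0-5 mapped to the
# following cycle so every observation lies on the ZT6-ZT30 axis.
hour_centre <- function(zt_hour) unwrap_zt(zt_hour + 0.5)
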