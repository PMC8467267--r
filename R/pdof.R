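#' Principal direction of force (PDOF)
#'
#' Crash investigators express the principal direction of force on a vehicle
#' either as a clock face (12 o'clock = frontal) or in degrees of a circle.
#' `pdof()` builds the canonical representation used throughout the package:
#' degrees in \[0, 360), measured clockwise with 0 at 12 o'clock (frontal).
#'
#' @param degrees numeric vector of directions in degrees; values are reduced
#'   modulo 360 only when `normalize = TRUE`, otherwise must already lie in
#'   \[0, 360).
#' @param normalize reduce arbitrary finite angles into \[0, 360)?
#' @return a numeric vector of class `pdof`.
#' @examples
#' pdof(315)                  # the 10:30 direction
#' clock_to_degrees(10, 30)   # same thing, from clock notation
#' @export
pdof <- function(degrees, normalize = FALSE) {
  if (!is.numeric(degrees) || anyNA(degrees) || any(!is.finite(degrees)))
    stop_domain("PDOF degrees must be finite numeric values")
  if (normalize) degrees <- degrees %% 360
  if (any(degrees < 0 | degrees >= 360))
    stop_domain("PDOF degrees must lie in [0, 360)")
  structure(as.numeric(degrees), class = "pdof")
}

#' @export
print.pdof <- function(x, ...) {
  cat(sprintf("PDOF: %s deg (%s)\n", format(unclass(x)),
              vapply(unclass(x), function(d) degrees_to_clock(d), "")))
  invisible(x)
}

#' Convert a clock-face direction to PDOF degrees
#'
#' A position of h o'clock and m minutes maps to
#' `(h mod 12) * 30 + m * 0.5` degrees, so 12:00 is 0 (frontal), 3:00 is 90
#' (right side), 9:00 is 270 (left side).
#'
#' @param hours integer 1-12.
#' @param minutes integer 0-59.
#' @return a `pdof` value.
#' @examples
#' clock_to_degrees(12, 0)  # 0
#' clock_to_degrees(9, 0)   # 270
#' @export
clock_to_degrees <- function(hours, minutes = 0) {
  if (!is.numeric(hours) || anyNA(hours) || any(hours != round(hours)) ||
      any(hours < 1 | hours > 12))
    stop_domain("clock hours must be integers in 1..12")
  if (!is.numeric(minutes) || anyNA(minutes) || any(minutes != round(minutes)) ||
      any(minutes < 0 | minutes > 59))
    stop_domain("clock minutes must be integers in 0..59")
  pdof((hours %% 12) * 30 + minutes * 0.5)
}

#' Convert PDOF degrees back to clock notation
#'
#' Inverse of [clock_to_degrees()] to the nearest minute (0.5 degree).
#'
#' @param degrees numeric direction in \[0, 360).
#' @return a character string `"h:mm"`.
#' @export
degrees_to_clock <- function(degrees) {
  degrees <- unclass(pdof(degrees))
  total_min <- round(degrees / 0.5)       # one clock minute = 0.5 degree
  h <- (total_min %/% 60) %% 12
  m <- total_min %% 60
  h[h == 0] <- 12
  sprintf("%d:%02d", h, m)
}

#' Coerce clock strings or degrees to PDOF
#'
#' Accepts a `pdof`, a numeric vector of degrees, or clock strings such as
#' `"10:30"` (minutes optional: `"9"` means 9:00).
#'
#' @param x value to coerce.
#' @return a `pdof` vector.
#' @export
as_pdof <- function(x) {
  if (inherits(x, "pdof")) return(x)
  if (is.numeric(x)) return(pdof(x))
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)
    deg <- vapply(parts, function(p) {
      h <- suppressWarnings(as.integer(p[[1]]))
      m <- if (length(p) > 1) suppressWarnings(as.integer(p[[2]])) else 0L
      if (is.na(h) || is.na(m)) stop_domain(sprintf(
        "cannot parse clock position '%s'", paste(p, collapse = ":")))
      unclass(clock_to_degrees(h, m))
    }, numeric(1))
    return(pdof(deg))
  }
  stop_domain("cannot coerce to PDOF: supply degrees or 'h:mm' clock text")
}

#' Test whether a PDOF lies in a clockwise clock arc
#'
#' The window runs clockwise from `start_clock` to `end_clock` and is closed
#' (both endpoints included); arcs that cross 12 o'clock (0 degrees) are
#' handled. This is the test used to match a cohort window such as
#' "9 to 11 o'clock" left-frontal damage.
#'
#' @param p PDOF (degrees, `pdof`, or clock text).
#' @param start_clock,end_clock arc endpoints (clock text, degrees, or `pdof`).
#' @return logical vector, `TRUE` where `p` lies in the closed arc.
#' @examples
#' pdof_in_window(300, "9:00", "11:00")   # TRUE: 270..330 contains 300
#' pdof_in_window(0, "11:00", "1:00")     # TRUE: wrap-around arc
#' @export
pdof_in_window <- function(p, start_clock, end_clock) {
  p <- unclass(as_pdof(p))
  a <- unclass(as_pdof(start_clock))
  b <- unclass(as_pdof(end_clock))
  if (length(a) != 1L || length(b) != 1L)
    stop_domain("window endpoints must be single positions")
  if (a <= b) p >= a & p <= b else p >= a | p <= b
}
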