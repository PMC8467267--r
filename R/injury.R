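#' Parse a 7-digit crash injury code
#'
#' Crash injury databases code each medically observed injury as a 7-digit
#' identifier whose final digit is the Abbreviated Injury Scale (AIS) severity:
#' 1 minor, 2 moderate, 3 serious, 4 severe, 5 critical, 6 maximum, 7 unknown
#' severity. The leading six digits (anatomical location / lesion) are carried
#' opaquely and preserved byte-for-byte.
#'
#' @param code a single 7-character digit string.
#' @return an object of class `injury_record` with fields `raw_code`,
#'   `body_region_part` (leading 6 digits), `ais_severity` (integer 1-7) and
#'   `unknown_severity` (`TRUE` when severity is 7).
#' @examples
#' parse_injury_code("1506023")$ais_severity  # 3 (serious)
#' @export
parse_injury_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code))
    stop_malformed("injury code must be a single character string")
  if (nchar(code) != 7L || !grepl("^[0-9]{7}$", code))
    stop_malformed(sprintf(
      "malformed injury code '%s': expected exactly 7 digit characters", code))
  sev <- as.integer(substr(code, 7L, 7L))
  if (!sev %in% 1:7)
    stop_severity(sprintf(
      "invalid AIS severity digit %d in code '%s': must be 1-7", sev, code))
  structure(list(
    raw_code         = code,
    body_region_part = substr(code, 1L, 6L),
    ais_severity     = sev,
    unknown_severity = sev == 7L
  ), class = "injury_record")
}

#' @export
format.injury_record <- function(x, ...) x$raw_code

#' @export
print.injury_record <- function(x, ...) {
  lab <- c("minor", "moderate", "serious", "severe", "critical", "maximum",
           "unknown severity")[x$ais_severity]
  cat(sprintf("Injury %s: AIS %d (%s)\n", x$raw_code, x$ais_severity, lab))
  invisible(x)
}

#' Maximum known AIS severity over a set of injuries
#'
#' Returns the maximum AIS severity among codes with a known severity (1-6).
#' Severity 7 means "unknown" and is not a magnitude, so it never counts
#' toward the maximum. An empty list, or a list whose codes are all unknown,
#' yields 0; the all-unknown case is flagged in the `"all_unknown"` attribute.
#'
#' @param injuries a list of `injury_record` objects (or 7-digit code strings,
#'   which are parsed).
#' @return integer 0-6, with attribute `all_unknown`.
#' @export
max_ais <- function(injuries) {
  if (length(injuries) == 0L)
    return(structure(0L, all_unknown = FALSE))
  sev <- vapply(injuries, function(x) {
    if (is.character(x)) x <- parse_injury_code(x)
    if (!inherits(x, "injury_record"))
      stop_malformed("max_ais expects injury records or 7-digit code strings")
    x$ais_severity
  }, integer(1))
  known <- sev[sev <= 6L]
  if (length(known) == 0L) return(structure(0L, all_unknown = TRUE))
  structure(max(known), all_unknown = FALSE)
}

#' Parse a semicolon-delimited injury-code cell
#'
#' The interchange CSV stores an occupant's injuries as a single
#' semicolon-delimited cell, possibly empty.
#'
#' @param cell character scalar like `"1506023;4202042"` (empty or `NA` means
#'   no recorded injuries).
#' @return list of `injury_record`.
#' @export
parse_injury_codes <- function(cell) {
  if (length(cell) != 1L) stop_malformed("one cell at a time")
  if (is.na(cell) || !nzchar(trimws(cell))) return(list())
  lapply(strsplit(trimws(cell), ";", fixed = TRUE)[[1L]], parse_injury_code)
}

#' Serialize injury records to the interchange cell format
#'
#' @param injuries list of `injury_record`.
#' @return character scalar, codes joined by `";"` (empty string for none).
#' @export
serialize_injury_codes <- function(injuries) {
  if (length(injuries) == 0L) return("")
  paste(vapply(injuries, format, ""), collapse = ";")
}
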