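# Occupant-level interchange format.
#
# One row per occupant-in-crash. Canonical column order below is also the CSV
# header of the interchange format; booleans travel as 0/1, injuries as a
# semicolon-delimited cell of 7-digit codes.

RECORD_COLUMNS <- c(
  "record_id", "year", "delta_v_mph", "pdof_deg", "belt_used",
  "airbag_deployed", "rollover", "ejected", "role", "body_type",
  "model_year", "died_30day", "injury_codes", "weight", "stratum", "psu"
)

TRIVALENT_LEVELS <- c("used", "not_used", "unknown")
AIRBAG_LEVELS    <- c("deployed", "not_deployed", "unknown")
ROLE_LEVELS      <- c("driver", "front_passenger", "rear_passenger")

MISSING_TOKENS <- c("", "na", "unknown")  # matched case-insensitively on read

#' Construct a validated crash-occupant record table
#'
#' Wraps a data frame in the `crash_records` class after checking the
#' interchange schema: positive sampling weights, non-negative delta V where
#' present, valid categorical levels, and a consistent stratum/PSU nesting
#' (each PSU belongs to exactly one stratum).
#'
#' @param df data frame with the interchange columns (see Details of
#'   [read_records()]).
#' @return `df` with class `crash_records`.
#' @export
crash_records <- function(df) {
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop_schema(paste0("missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")))
  df <- df[, RECORD_COLUMNS, drop = FALSE]
  if (nrow(df) > 0L) {
    if (anyNA(df$weight) || any(df$weight <= 0))
      stop_schema("weight must be a positive real for every record")
    if (any(!is.na(df$delta_v_mph) & df$delta_v_mph < 0))
      stop_schema("delta_v_mph must be non-negative where present")
    if (!all(df$belt_used %in% TRIVALENT_LEVELS))
      stop_schema("belt_used must be one of used/not_used/unknown")
    if (!all(df$airbag_deployed %in% AIRBAG_LEVELS))
      stop_schema("airbag_deployed must be one of deployed/not_deployed/unknown")
    if (!all(df$role %in% ROLE_LEVELS))
      stop_schema("role must be driver/front_passenger/rear_passenger")
    psu_strata <- unique(df[, c("stratum", "psu")])
    if (anyDuplicated(psu_strata$psu))
      stop_schema("each PSU label must belong to exactly one stratum")
  }
  class(df) <- c("crash_records", "data.frame")
  df
}

#' @export
print.crash_records <- function(x, ...) {
  cat(sprintf("<crash_records: %d occupants, %d strata, %d PSUs, total weight %.1f>\n",
              nrow(x), length(unique(x$stratum)), length(unique(x$psu)),
              sum(x$weight)))
  NextMethod()
}

# Map a raw character column to a canonical trivalent level set.
map_trivalent <- function(x, levels) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x %in% MISSING_TOKENS] <- "unknown"
  # accept common 0/1/yes/no encodings for the binary part
  x[x %in% c("1", "yes", "true", "y", "belted")]       <- levels[1L]
  x[x %in% c("0", "no", "false", "n", "unbelted")]     <- levels[2L]
  x
}

parse_bool <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes", "y")]  <- TRUE
  out[x %in% c("0", "false", "no", "n")]  <- FALSE
  out
}

parse_num <- function(x) {
  x <- trimws(as.character(x))
  x[tolower(x) %in% MISSING_TOKENS] <- NA
  suppressWarnings(as.numeric(x))
}

#' Read crash-occupant records from the interchange CSV
#'
#' Reads the tabular interchange format (see `RECORD_COLUMNS` in the package
#' source): one row per occupant with exposure (`delta_v_mph`, `pdof_deg`,
#' `belt_used`), covariates, the 30-day death outcome, and the survey design
#' labels (`weight`, `stratum`, `psu`). Empty cells, `NA` and `unknown`
#' (case-insensitive) are treated as missing/unknown. Malformed rows are not
#' silently dropped: they are collected into a reject report attached as the
#' `"rejects"` attribute, and the reader refuses to proceed when more than
#' `max_reject_fraction` of rows reject.
#'
#' @param path path to a CSV (or TSV, see `sep`).
#' @param sep field separator, `","` by default.
#' @param column_map optional named character vector mapping interchange names
#'   to the names used in the source file, e.g. `c(delta_v_mph = "dv")`.
#' @param speed_unit unit of the delta V column, `"mph"` (canonical) or
#'   `"km_h"` (converted on read).
#' @param max_reject_fraction refuse with an error when the rejected-row
#'   fraction exceeds this (default 0.1).
#' @return a `crash_records` data frame; attribute `"rejects"` holds a data
#'   frame of `(row, reason)` for rejected rows.
#' @export
read_records <- function(path, sep = ",", column_map = NULL,
                         speed_unit = c("mph", "km_h"),
                         max_reject_fraction = 0.1) {
  speed_unit <- match.arg(speed_unit)
  if (!file.exists(path)) stop_schema(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canonical
    }
  }
  missing_cols <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing_cols) > 0L)
    stop_schema(paste0("missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")))

  n <- nrow(raw)
  df <- data.frame(
    record_id       = as.character(raw$record_id),
    year            = parse_num(raw$year),
    delta_v_mph     = parse_num(raw$delta_v_mph),
    pdof_deg        = parse_num(raw$pdof_deg),
    belt_used       = map_trivalent(raw$belt_used, c("used", "not_used")),
    airbag_deployed = map_trivalent(raw$airbag_deployed,
                                    c("deployed", "not_deployed")),
    rollover        = parse_bool(raw$rollover),
    ejected         = parse_bool(raw$ejected),
    role            = tolower(trimws(raw$role)),
    body_type       = tolower(trimws(raw$body_type)),
    model_year      = parse_num(raw$model_year),
    died_30day      = parse_bool(raw$died_30day),
    injury_codes    = as.character(raw$injury_codes),
    weight          = parse_num(raw$weight),
    stratum         = as.character(raw$stratum),
    psu             = as.character(raw$psu),
    stringsAsFactors = FALSE
  )
  if (speed_unit == "km_h") df$delta_v_mph <- mph(df$delta_v_mph)

  reason <- rep(NA_character_, n)
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(df$weight) | df$weight <= 0, "weight missing or not positive")
  reason <- bad(!is.na(df$delta_v_mph) & df$delta_v_mph < 0, "negative delta V")
  reason <- bad(!df$belt_used %in% TRIVALENT_LEVELS, "unparsable belt_used")
  reason <- bad(!df$airbag_deployed %in% AIRBAG_LEVELS, "unparsable airbag_deployed")
  reason <- bad(!df$role %in% ROLE_LEVELS, "unparsable role")
  reason <- bad(is.na(df$rollover), "unparsable rollover flag")
  reason <- bad(is.na(df$died_30day), "unparsable died_30day outcome")
  reason <- bad(is.na(df$year), "unparsable year")
  inj_ok <- vapply(df$injury_codes, function(cell)
    !inherits(try(parse_injury_codes(cell), silent = TRUE), "try-error"),
    logical(1), USE.NAMES = FALSE)
  reason <- bad(!inj_ok, "malformed injury code")

  rejects <- data.frame(row = which(!is.na(reason)),
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  if (n > 0L && nrow(rejects) / n > max_reject_fraction)
    stop_schema(sprintf(
      "%d of %d rows rejected (%.1f%%), above the %.0f%% limit; first reason: %s",
      nrow(rejects), n, 100 * nrow(rejects) / n, 100 * max_reject_fraction,
      rejects$reason[1L]))

  keep <- df[is.na(reason), , drop = FALSE]
  rownames(keep) <- NULL
  out <- crash_records(keep)
  attr(out, "rejects") <- rejects
  out
}

#' Write crash-occupant records to the interchange CSV
#'
#' Inverse of [read_records()]: `read_records(write_records(x, p))` reproduces
#' `x` field-for-field. Booleans are written as 0/1; missing values as empty
#' cells.
#'
#' @param records a `crash_records` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- crash_records(as.data.frame(records))
  out <- as.data.frame(records)
  for (col in c("rollover", "ejected", "died_30day"))
    out[[col]] <- as.integer(out[[col]])
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n",
                   na = "")
  invisible(path)
}

#' Speed unit conversions
#'
#' Convert between miles per hour (the package's canonical unit for delta V)
#' and kilometres per hour using the exact factor 1.609344.
#'
#' @param x speed value(s).
#' @return converted value(s).
#' @examples
#' km_h(55.8)  # 89.8
#' mph(89)     # 55.3
#' @export
km_h <- function(x) x * 1.609344

#' @rdname km_h
#' @export
mph <- function(x) x / 1.609344
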