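#' Cohort inclusion/exclusion specification
#'
#' Declares the case-matched analysis cohort: occupant role, single frontal
#' collision with PDOF inside a clockwise clock arc, rollovers excluded, belt
#' and airbag status known, and an inclusive year range. Defaults reproduce a
#' driver-side frontal cohort: drivers, PDOF 9 to 11 o'clock, no rollovers,
#' belt and airbag knownness required, years 2001-2015.
#'
#' @param role_required occupant role kept in the cohort.
#' @param pdof_window length-2 clockwise arc (clock text or degrees), closed
#'   at both endpoints.
#' @param require_belt_known,require_airbag_known drop records whose belt /
#'   airbag status is unknown?
#' @param exclude_rollover drop rollover crashes?
#' @param years inclusive integer range of case years.
#' @param outcome_definition `"death_30day"` or `"max_ais_ge_k"`.
#' @param ais_threshold AIS cut point when `outcome_definition` is
#'   `"max_ais_ge_k"` (3 = serious, the conventional mortality-relevant cut).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(role_required = "driver",
                        pdof_window = c("9:00", "11:00"),
                        require_belt_known = TRUE,
                        require_airbag_known = TRUE,
                        exclude_rollover = TRUE,
                        years = 2001:2015,
                        outcome_definition = c("death_30day", "max_ais_ge_k"),
                        ais_threshold = 3L) {
  outcome_definition <- match.arg(outcome_definition)
  if (length(years) == 0L) stop_domain("year range must be nonempty")
  if (!role_required %in% ROLE_LEVELS)
    stop_domain("role_required must be a valid occupant role")
  pdof_window <- vapply(pdof_window, function(p) unclass(as_pdof(p)), 0)
  if (length(pdof_window) != 2L)
    stop_domain("pdof_window must give the two arc endpoints")
  structure(list(role_required = role_required,
                 pdof_window = unname(pdof_window),
                 require_belt_known = require_belt_known,
                 require_airbag_known = require_airbag_known,
                 exclude_rollover = exclude_rollover,
                 years = years,
                 outcome_definition = outcome_definition,
                 ais_threshold = as.integer(ais_threshold)),
            class = "cohort_spec")
}

# Fixed exclusion order; each record is charged to the FIRST rule it fails.
cohort_rules <- function(spec) {
  rules <- list(
    role = function(df) df$role == spec$role_required,
    frontal_pdof = function(df)
      !is.na(df$pdof_deg) &
        pdof_in_window(df$pdof_deg, spec$pdof_window[1L], spec$pdof_window[2L])
  )
  if (spec$exclude_rollover)
    rules$rollover <- function(df) !df$rollover
  if (spec$require_belt_known)
    rules$belt_known <- function(df) df$belt_used != "unknown"
  if (spec$require_airbag_known)
    rules$airbag_known <- function(df) df$airbag_deployed != "unknown"
  rules$year_range <- function(df) df$year %in% spec$years
  rules
}

#' Build the analysis cohort and its exclusion ledger
#'
#' Applies the cohort rules in a fixed declared order (role, frontal PDOF
#' window, rollover exclusion, belt knownness, airbag knownness, year range);
#' each record removed is counted against exactly the first rule it fails, so
#' the ledger conserves counts: `n_input = n_output + sum(removed)`. The
#' operation is idempotent. Records with missing delta V are retained here —
#' delta V knownness is a model-fitting concern, handled (and separately
#' ledgered) by [fit_weighted_logistic()].
#'
#' @param records a `crash_records` table.
#' @param spec a [cohort_spec()].
#' @return list with `cohort` (`crash_records`) and `ledger` (class
#'   `filter_ledger`: `n_input`, `exclusions` data frame, `n_output`).
#' @export
apply_cohort_spec <- function(records, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- crash_records(as.data.frame(records))
  rules <- cohort_rules(spec)
  alive <- rep(TRUE, nrow(records))
  removed <- integer(length(rules))
  names(removed) <- names(rules)
  for (rule in names(rules)) {
    pass <- rules[[rule]](records)
    fail_now <- alive & !pass
    removed[[rule]] <- sum(fail_now)
    alive <- alive & pass
  }
  cohort <- records[alive, , drop = FALSE]
  rownames(cohort) <- NULL
  ledger <- structure(list(
    n_input = nrow(records),
    exclusions = data.frame(rule = names(removed), removed = unname(removed),
                            stringsAsFactors = FALSE),
    n_output = nrow(cohort)
  ), class = "filter_ledger")
  stopifnot(ledger$n_input == ledger$n_output + sum(ledger$exclusions$removed))
  list(cohort = crash_records(cohort), ledger = ledger)
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat(sprintf("Cohort filter ledger: %d in -> %d out\n", x$n_input, x$n_output))
  for (i in seq_len(nrow(x$exclusions)))
    cat(sprintf("  - %-14s removed %d\n",
                x$exclusions$rule[i], x$exclusions$removed[i]))
  invisible(x)
}

#' Weighted occupant totals by belt use and airbag deployment
#'
#' Sums the national-inflation weights within belt x airbag cells — the
#' weighted totals a survey analysis reports (e.g. "a weighted total of N
#' belted and M unbelted drivers").
#'
#' @param cohort a `crash_records` table.
#' @return list with `belted`, `unbelted` weighted totals and `by_airbag`, a
#'   data frame of weighted totals per belt x airbag cell.
#' @export
cohort_weighted_counts <- function(cohort) {
  if (nrow(cohort) == 0L) {
    return(list(belted = 0, unbelted = 0,
                by_airbag = data.frame(belt_used = character(0),
                                       airbag_deployed = character(0),
                                       weighted_n = numeric(0))))
  }
  cells <- stats::aggregate(weight ~ belt_used + airbag_deployed,
                            data = as.data.frame(cohort), FUN = sum)
  names(cells)[names(cells) == "weight"] <- "weighted_n"
  list(
    belted   = sum(cohort$weight[cohort$belt_used == "used"]),
    unbelted = sum(cohort$weight[cohort$belt_used == "not_used"]),
    by_airbag = cells[order(cells$belt_used, cells$airbag_deployed), ,
                      drop = FALSE]
  )
}
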