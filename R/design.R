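#' Survey design labels for a weighted crash sample
#'
#' Describes the stratified cluster structure used for design-based variance
#' estimation: strata containing primary sampling units (PSUs), analysed under
#' the with-replacement approximation (no finite population correction), which
#' is the standard treatment for national crash-sample data. Strata with a
#' single PSU cannot contribute a between-PSU variance and are flagged as
#' variance-degenerate.
#'
#' @param strata character vector of stratum labels, one per record (or a
#'   `crash_records` table, from which `stratum`/`psu` are taken).
#' @param psu character vector of PSU labels, parallel to `strata`.
#' @return an object of class `survey_design` with elements `strata`
#'   (stratum labels), `psus_by_stratum` (named list), and
#'   `single_psu_strata`.
#' @export
survey_design <- function(strata, psu = NULL) {
  if (inherits(strata, "crash_records") || is.data.frame(strata)) {
    psu <- strata$psu
    strata <- strata$stratum
  }
  if (is.null(psu) || length(psu) != length(strata))
    stop_domain("strata and psu labels must be parallel vectors")
  map <- unique(data.frame(stratum = strata, psu = psu,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(map$psu))
    stop_schema("each PSU label must belong to exactly one stratum")
  psus_by_stratum <- split(map$psu, map$stratum)
  n_psu <- vapply(psus_by_stratum, length, integer(1))
  structure(list(
    strata           = names(psus_by_stratum),
    psus_by_stratum  = psus_by_stratum,
    single_psu_strata = names(psus_by_stratum)[n_psu == 1L],
    fpc              = NULL
  ), class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("<survey_design: %d strata, %d PSUs%s>\n",
              length(x$strata),
              sum(vapply(x$psus_by_stratum, length, integer(1))),
              if (length(x$single_psu_strata) > 0L)
                sprintf(", %d single-PSU (variance-degenerate)",
                        length(x$single_psu_strata)) else ""))
  invisible(x)
}
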