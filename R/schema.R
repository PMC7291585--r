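#' Structural check of a serialized agreement report
#'
#' A lightweight validator for the JSON produced by [report_to_json()],
#' mirroring the shipped schema (`inst/schema/report-schema.json`): required
#' top-level fields, required LoA fields, and admissible ranges for the
#' bounded indices.  Returns invisibly `TRUE` or throws a data error listing
#' the violations.
#'
#' @param json a JSON string or parsed list.
#' @export
check_report_json <- function(json) {
  x <- if (is.character(json)) jsonlite::fromJSON(json) else json
  bad <- character(0)
  need <- c("indices", "verdicts", "settings", "provenance")
  miss <- setdiff(need, names(x))
  if (length(miss)) bad <- c(bad, paste("missing field(s):",
                                        paste(miss, collapse = ", ")))
  idx <- x$indices
  in_range <- function(v, lo, hi) is.null(v) || is.na(v) ||
    (is.numeric(v) && v >= lo && v <= hi)
  if (!is.null(idx)) {
    if (!in_range(idx$ccc, -1, 1)) bad <- c(bad, "ccc outside [-1, 1]")
    if (!in_range(idx$cp, 0, 1)) bad <- c(bad, "cp outside [0, 1]")
    if (!in_range(idx$cia, 0, 1)) bad <- c(bad, "cia outside [0, 1]")
    if (!is.null(idx$msd) && idx$msd < 0) bad <- c(bad, "negative msd")
    if (!is.null(idx$tdi) && idx$tdi < 0) bad <- c(bad, "negative tdi")
    loa <- idx$loa
    if (!is.null(loa)) {
      lmiss <- setdiff(c("bias", "lower", "upper", "source"), names(loa))
      if (length(lmiss)) bad <- c(bad, paste("loa missing:",
                                             paste(lmiss, collapse = ", ")))
      if (length(lmiss) == 0 &&
          !(loa$lower <= loa$bias && loa$bias <= loa$upper)) {
        bad <- c(bad, "loa not ordered lower <= bias <= upper")
      }
    }
  }
  st <- x$settings
  if (!is.null(st)) {
    smiss <- setdiff(c("cad_delta", "tdi_p", "cp_threshold", "cia_threshold",
                       "loa_multiplier"), names(st))
    if (length(smiss)) bad <- c(bad, paste("settings missing:",
                                           paste(smiss, collapse = ", ")))
  }
  if (length(bad)) ag_data_error(paste("invalid report JSON:",
                                       paste(bad, collapse = "; ")))
  invisible(TRUE)
}
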