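#' Construct a validated measurement table
#'
#' A measurement table holds long-format readings from a two-device method
#' comparison study: one row per reading, keyed by subject, device, activity
#' (or any other condition label) and a replicate index.  Replicates within a
#' (subject, device, activity) cell are treated as exchangeable; the replicate
#' index stands in for measurement time when pairing readings across devices.
#'
#' @param data data.frame with columns `subject`, `device`, `activity`,
#'   `value` and optionally `replicate`.  Identifier columns are treated as
#'   opaque strings (numeric-looking ids are not coerced).
#' @param reference_device label of the reference ("gold standard") device;
#'   must be one of the two levels of `device`.
#' @param synthesize_replicates if `TRUE` (default) and `replicate` is absent,
#'   replicate indices 1, 2, ... are assigned in row order within each
#'   (subject, device, activity) cell.
#' @return An object of class `measurement_table`: the validated data.frame
#'   with attributes `reference_device`, `test_device` and `validation`
#'   (a summary of counts per subject/device/activity).
#' @export
measurement_table <- function(data, reference_device,
                              synthesize_replicates = TRUE) {
  needed <- c("subject", "device", "activity", "value")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0L) {
    ag_config_error(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("subject", "device", "activity")) {
    if (anyNA(data[[col]])) {
      ag_data_error(paste0("missing values in key column '", col, "'"))
    }
    data[[col]] <- as.character(data[[col]])
  }
  if (!is.numeric(data$value)) {
    bad <- suppressWarnings(as.numeric(data$value))
    if (anyNA(bad)) {
      ag_data_error(paste0(
        "non-numeric measurement value in row(s): ",
        paste(utils::head(which(is.na(bad)), 5L), collapse = ", ")
      ))
    }
    data$value <- bad
  }
  if (any(!is.finite(data$value))) {
    ag_data_error(paste0(
      "non-finite measurement value in row(s): ",
      paste(utils::head(which(!is.finite(data$value)), 5L), collapse = ", ")
    ))
  }

  devices <- sort(unique(data$device))
  if (length(devices) != 2L) {
    ag_data_error(paste0(
      "device column must have exactly 2 levels, found ",
      length(devices), " (", paste(devices, collapse = ", "), ")"
    ))
  }
  if (!reference_device %in% devices) {
    ag_config_error(paste0(
      "reference device '", reference_device, "' not found among device ",
      "levels (", paste(devices, collapse = ", "), ")"
    ))
  }
  test_device <- setdiff(devices, reference_device)

  if (!"replicate" %in% names(data)) {
    if (!synthesize_replicates) {
      ag_config_error("replicate column absent and synthesis disabled")
    }
    key <- interaction(data$subject, data$device, data$activity, drop = TRUE)
    data$replicate <- stats::ave(seq_len(nrow(data)), key,
                                 FUN = seq_along)
  }
  data$replicate <- as.integer(data$replicate)
  if (anyNA(data$replicate) || any(data$replicate < 1L)) {
    ag_data_error("replicate indices must be integers >= 1")
  }

  key <- paste(data$subject, data$device, data$activity, data$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    ag_data_error(paste0(
      "duplicate (subject, device, activity, replicate) keys, e.g. row ",
      which(duplicated(key))[1L]
    ))
  }
  if (length(unique(data$subject)) < 2L) {
    ag_data_error("need at least 2 distinct subjects")
  }

  data <- data[, c("subject", "device", "activity", "replicate", "value")]
  validation <- list(
    n_records = nrow(data),
    n_subjects = length(unique(data$subject)),
    n_activities = length(unique(data$activity)),
    records_per_device = table(data$device),
    records_per_subject = table(data$subject),
    records_per_activity = table(data$activity)
  )
  structure(data,
            reference_device = reference_device,
            test_device = test_device,
            validation = validation,
            class = c("measurement_table", "data.frame"))
}

#' Read a long-format measurement CSV
#'
#' @param path path to a delimited text file with a header row.
#' @param reference_device label of the reference device.
#' @param mapping named list mapping the canonical column names `subject`,
#'   `device`, `activity`, `value` and optionally `replicate` (alias `time`)
#'   to the column names in the file.  Defaults to identity.
#' @param delim field delimiter, default ",".
#' @param devices optional character vector of length 2: subset the device
#'   column to these two levels before validation.
#' @return A [measurement_table()].
#' @export
read_measurements <- function(path, reference_device,
                              mapping = list(), delim = ",",
                              devices = NULL) {
  if (!file.exists(path)) {
    ag_config_error(paste0("input file does not exist: ", path))
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  canon <- c("subject", "device", "activity", "value", "replicate")
  out <- list()
  for (col in canon) {
    src <- mapping[[col]] %||% (if (col == "replicate") mapping[["time"]] else NULL) %||% col
    if (src %in% names(raw)) {
      out[[col]] <- raw[[src]]
    } else if (!col %in% c("replicate")) {
      ag_config_error(paste0(
        "column '", src, "' (mapped to '", col, "') not found in ", path
      ))
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (!is.null(devices)) {
    if (length(devices) != 2L) {
      ag_config_error("'devices' subset must have exactly 2 labels")
    }
    out <- out[out$device %in% devices, , drop = FALSE]
  }
  if (nrow(out) == 0L) ag_data_error("no rows after reading/subsetting")
  measurement_table(out, reference_device = reference_device)
}

#' @export
print.measurement_table <- function(x, ...) {
  v <- attr(x, "validation")
  cat("Measurement table: ", v$n_records, " readings, ",
      v$n_subjects, " subjects, ", v$n_activities, " activities\n", sep = "")
  cat("  reference device: ", attr(x, "reference_device"),
      " | test device: ", attr(x, "test_device"), "\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ... (", nrow(x) - 4L, " more rows)\n", sep = "")
  invisible(x)
}

#' Time-matched paired differences between the two devices
#'
#' Forms one row per complete (subject, activity, replicate) pair present on
#' both devices, with `diff = test - reference` (or the reverse) and
#' `avg = (test + reference)/2` (the Bland-Altman abscissa).  Readings with no
#' counterpart on the other device are dropped and counted.
#'
#' @param table a [measurement_table()].
#' @param orientation `"test_minus_reference"` (default) or
#'   `"reference_minus_test"`.
#' @return Object of class `paired_differences`: data.frame with columns
#'   `subject`, `activity`, `replicate`, `diff`, `avg`, plus attributes
#'   `n_dropped` (unpaired readings) and `orientation`.
#' @export
pair_differences <- function(table,
                             orientation = c("test_minus_reference",
                                             "reference_minus_test")) {
  stopifnot(inherits(table, "measurement_table"))
  orientation <- match.arg(orientation)
  ref <- attr(table, "reference_device")
  tst <- attr(table, "test_device")
  df <- as.data.frame(table)
  r <- df[df$device == ref, c("subject", "activity", "replicate", "value")]
  t_ <- df[df$device == tst, c("subject", "activity", "replicate", "value")]
  m <- merge(r, t_, by = c("subject", "activity", "replicate"),
             suffixes = c("_ref", "_test"))
  n_dropped <- (nrow(r) - nrow(m)) + (nrow(t_) - nrow(m))
  if (nrow(m) == 0L) {
    ag_data_error("no complete device pairs in the data")
  }
  sgn <- if (orientation == "test_minus_reference") 1 else -1
  out <- data.frame(
    subject = m$subject,
    activity = m$activity,
    replicate = m$replicate,
    diff = sgn * (m$value_test - m$value_ref),
    avg = (m$value_test + m$value_ref) / 2,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$subject, out$activity, out$replicate), ]
  rownames(out) <- NULL
  structure(out,
            n_dropped = n_dropped,
            orientation = orientation,
            class = c("paired_differences", "data.frame"))
}

#' @export
print.paired_differences <- function(x, ...) {
  cat("Paired differences: ", nrow(x), " pairs (",
      attr(x, "n_dropped"), " unpaired readings dropped), orientation ",
      attr(x, "orientation"), "\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Construct a paired-differences table directly
#'
#' Convenience constructor for workflows where the paired differences are
#' already available (e.g. the synthetic differences generator).
#'
#' @param subject,activity,replicate,diff vectors of equal length; `avg`
#'   optional (NA when the underlying paired readings are unknown).
#' @param avg optional pair averages.
#' @export
paired_differences <- function(subject, activity, replicate, diff,
                               avg = NA_real_) {
  if (any(!is.finite(diff))) ag_data_error("non-finite differences")
  out <- data.frame(subject = as.character(subject),
                    activity = as.character(activity),
                    replicate = as.integer(replicate),
                    diff = as.numeric(diff),
                    avg = as.numeric(avg),
                    stringsAsFactors = FALSE)
  structure(out, n_dropped = 0L, orientation = "test_minus_reference",
            class = c("paired_differences", "data.frame"))
}
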