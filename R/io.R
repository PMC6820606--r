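## Event-record (NONMEM dialect) readers/writers and validation.
##
## Column semantics: ID patient id; TIME days since first dose; AMT dose in
## mg (dose rows); RATE infusion rate in mg/day; DV observed concentration
## in ug/mL; EVID 1 = dose, 0 = observation; MDV 1 = missing DV (DV ignored
## downstream).  Covariate columns are carried through unchanged.  CSV
## dialect: comma-separated, header row, UTF-8, '.' decimal.

EVENT_COLUMNS <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV")

#' Validate an event-record dataset
#'
#' @param data data.frame of event records.
#' @return list with `data` (validated, row order preserved) and
#'   `violations` (data.frame row, column, message — empty when clean).
#'   Structural violations (missing columns, non-monotone TIME within ID)
#'   are errors; soft violations are reported.
#' @export
validate_event_records <- function(data) {
  missing <- setdiff(EVENT_COLUMNS, names(data))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  for (i in unique(data$ID)) {
    tt <- data$TIME[data$ID == i]
    if (is.unsorted(tt)) {
      stop("non-monotone TIME within ID ", i)
    }
  }
  v <- list()
  bad_evid <- !data$EVID %in% c(0, 1)
  if (any(bad_evid)) {
    v[[length(v) + 1]] <- data.frame(
      row = which(bad_evid), column = "EVID",
      message = "EVID must be 0 (observation) or 1 (dose)")
  }
  dose_rows <- data$EVID == 1
  first_dose <- tapply(data$TIME[dose_rows], data$ID[dose_rows], min)
  fd <- first_dose[as.character(data$ID)]
  pre_dose <- data$EVID == 0 & data$MDV == 0 & (is.na(fd) | data$TIME < fd)
  if (any(pre_dose & data$DV != 0)) {
    stop("observation with nonzero DV before first dose (ID ",
         paste(unique(data$ID[pre_dose & data$DV != 0]), collapse = ", "),
         ")")
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(row = integer(0), column = character(0),
               message = character(0))
  list(data = data, violations = violations)
}

#' Read an event-record CSV
#'
#' @param path CSV file path.
#' @return Validated event-record data.frame (violation report attached as
#'   attribute `"violations"`).
#' @export
read_event_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  res <- validate_event_records(data)
  structure(res$data, violations = res$violations)
}

#' Write an event-record CSV
#'
#' @param data event-record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_records <- function(data, path) {
  validate_event_records(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
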