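#' Write survey records to CSV
#'
#' One row per record; schema columns (`record_id`, `protocol`, `x`, `y`,
#' `day`, `time`, `duration_hours`, `distance_km`, `n_observers`,
#' `complete`, `era`, `outcome`) followed by the raw covariate columns.
#'
#' @param records records data frame.
#' @param path output CSV path.
#' @export
write_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read survey records from CSV, with per-row validation
#'
#' Checks the documented column schema and per-protocol encoding: outcomes
#' must be 0/1 for single-visit and checklist records and 0..5 for
#' five-interval records; checklist rows must carry duration, distance and
#' observer counts. Malformed rows are reported with their row numbers.
#'
#' @param path CSV path.
#' @param protocol optionally require a single protocol.
#' @return validated records data frame.
#' @export
read_records <- function(path, protocol = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- RECORD_COLS
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_param("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.null(protocol) && any(df$protocol != protocol))
    stop_param("records are not all protocol `", protocol, "`")
  bad <- character(0)
  fi <- df$protocol == "five_interval"
  bad_outcome <- is.na(df$outcome) |
    (!fi & !df$outcome %in% c(0, 1)) | (fi & !df$outcome %in% 0:5)
  if (any(bad_outcome))
    bad <- c(bad, paste0("out-of-range outcome in row(s): ",
                         paste(which(bad_outcome), collapse = ", ")))
  cl <- df$protocol == "checklist"
  bad_effort <- cl & (is.na(df$duration_hours) | is.na(df$distance_km) |
                        is.na(df$n_observers))
  if (any(bad_effort))
    bad <- c(bad, paste0("checklist row(s) missing effort fields: ",
                         paste(which(bad_effort), collapse = ", ")))
  bad_era <- !df$era %in% c("current", "historic")
  if (any(bad_era))
    bad <- c(bad, paste0("invalid era in row(s): ",
                         paste(which(bad_era), collapse = ", ")))
  if (length(bad)) stop_param(paste(bad, collapse = "; "))
  df
}

#' Write a dataset bundle to a directory
#'
#' One CSV per dataset plus a `truth.json` sidecar recording the generating
#' parameters and master seed (when the bundle carries them).
#'
#' @param bundle a dataset bundle.
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in c("single_visit", "five_interval", "checklist", "historic")) {
    if (!is.null(bundle[[key]]))
      write_records(bundle[[key]], file.path(dir, paste0(key, ".csv")))
  }
  if (!is.null(bundle$truth)) {
    truth <- bundle$truth
    truth$center <- as.numeric(truth$center)
    truth$scale <- as.numeric(truth$scale)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a dataset bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return bundle list (`truth` restored from the JSON sidecar when
#'   present; the landscape/process closures are not serialized).
#' @export
read_bundle <- function(dir) {
  out <- list()
  for (key in c("single_visit", "five_interval", "checklist", "historic")) {
    f <- file.path(dir, paste0(key, ".csv"))
    if (file.exists(f)) out[[key]] <- read_records(f)
  }
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) out$truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  out
}
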