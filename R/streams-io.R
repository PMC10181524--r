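#' Read and write sensor streams
#'
#' Streams are serialized as a directory of delimited text files, one per
#' channel, with ISO-8601 UTC timestamps and a value column, plus a small
#' JSON sidecar holding the patient id and the time origin. The round trip
#' is lossless for integer-second timestamps and for values at full
#' double precision.
#'
#' @param streams a `sensor_streams` object.
#' @param path directory to write into (created if missing).
#' @param origin POSIXct instant corresponding to stream time 0 (end of
#'   surgery).
#' @return `write_streams` returns `path` invisibly; `read_streams` returns
#'   a `sensor_streams` object.
#' @export
write_streams <- function(streams, path,
                          origin = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(streams, "sensor_streams"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(streams)) {
    df <- streams[[ch]]
    out <- data.frame(
      timestamp = strftime(origin + df$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      value = if (is.numeric(df$value)) sprintf("%.17g", df$value) else df$value,
      stringsAsFactors = FALSE
    )
    utils::write.csv(out, file.path(path, paste0(ch, ".csv")), row.names = FALSE,
                     quote = FALSE)
  }
  jsonlite::write_json(
    list(patient_id = attr(streams, "patient_id"),
         age = attr(streams, "age"),
         origin = strftime(origin, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         channels = names(streams)),
    file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_streams
#' @export
read_streams <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop(sprintf("parse error: %s is not a stream directory (no meta.json)", path),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  origin <- as.POSIXct(meta$origin, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  streams <- lapply(meta$channels, function(ch) {
    f <- file.path(path, paste0(ch, ".csv"))
    df <- tryCatch(
      utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) stop(sprintf("parse error in %s: %s", f, conditionMessage(e)),
                               call. = FALSE))
    if (!identical(names(df), c("timestamp", "value"))) {
      stop(sprintf("parse error in %s: expected columns timestamp,value", f),
           call. = FALSE)
    }
    if (nrow(df) == 0L) {
      return(data.frame(t = numeric(0), value = numeric(0)))
    }
    ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    if (anyNA(ts)) {
      stop(sprintf("parse error in %s: bad timestamp at record %d", f,
                   which(is.na(ts))[1]), call. = FALSE)
    }
    value <- if (ch == "chest_posture") df$value else suppressWarnings(as.numeric(df$value))
    if (ch != "chest_posture" && anyNA(value)) {
      stop(sprintf("parse error in %s: bad value at record %d", f,
                   which(is.na(value))[1]), call. = FALSE)
    }
    data.frame(t = as.numeric(ts) - as.numeric(origin), value = value,
               stringsAsFactors = FALSE)
  })
  names(streams) <- meta$channels
  structure(streams, class = "sensor_streams",
            patient_id = meta$patient_id, age = meta$age)
}

#' Read and write a cohort as JSON
#'
#' @param cohort list of patient records.
#' @param path file path for the JSON document.
#' @export
write_cohort <- function(cohort, path) {
  jsonlite::write_json(cohort, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    p$age <- as.numeric(p$age)
    p$los <- as.integer(p$los)
    p$readmission_day <- if (is.null(p$readmission_day)) NA_integer_ else
      as.integer(p$readmission_day)
    p$complications <- lapply(p$complications, function(ev) {
      list(day = as.integer(ev$day), cd_grade = as.integer(ev$cd_grade),
           location = ev$location)
    })
    p
  })
}
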