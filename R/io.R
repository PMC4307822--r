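#' Write a cohort to disk
#'
#' Two lossless on-disk forms are supported: a single JSON document, or a CSV
#' bundle (a directory holding `subjects.csv`, `visits.csv`, `sessions.csv`,
#' `events.csv` joined by ids, plus `protocol.csv` carrying the canonical
#' activity order). Both are UTF-8 with `.` as decimal separator; timestamps
#' are written with millisecond precision. Writing the same cohort twice
#' produces byte-identical files.
#'
#' @param cohort A `vrdot_cohort`.
#' @param path Output file (JSON) or directory (CSV bundle).
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [load_cohort()]
#' @export
write_cohort <- function(cohort, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "vrdot_cohort"))
  if (format == "json") {
    doc <- list(
      provenance = cohort$provenance,
      protocol = list(scenario_id = cohort$protocol$scenario_id,
                      activities = cohort$protocol$activities),
      subjects = cohort$subjects,
      visits = cohort$visits,
      sessions = cohort$sessions,
      events = cohort$events
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = FALSE)
  } else {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop(sprintf("cannot create directory '%s'", path),
                    call. = FALSE)
    }
    wr <- function(df, name) {
      utils::write.csv(df, file.path(path, name), row.names = FALSE,
                       fileEncoding = "UTF-8", quote = TRUE, na = "")
    }
    wr(cohort$subjects, "subjects.csv")
    wr(cohort$visits, "visits.csv")
    wr(cohort$sessions, "sessions.csv")
    wr(cohort$events, "events.csv")
    proto <- data.frame(
      scenario_id = cohort$protocol$scenario_id,
      position = seq_along(cohort$protocol$activities),
      activity_id = cohort$protocol$activities,
      stringsAsFactors = FALSE
    )
    wr(proto, "protocol.csv")
    writeLines(cohort$provenance, file.path(path, "provenance.txt"))
  }
  invisible(path)
}

#' Load a cohort from disk
#'
#' Reads either serialized form written by [write_cohort()] and re-validates
#' every invariant, so any file that loads is a fully valid cohort;
#' `load_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param path JSON file or CSV-bundle directory.
#' @param format `"json"` or `"csv"`.
#' @return A `vrdot_cohort`.
#' @export
load_cohort <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    if (!file.exists(path)) {
      stop(sprintf("file '%s' does not exist", path), call. = FALSE)
    }
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    for (part in c("protocol", "subjects", "visits", "sessions", "events")) {
      if (is.null(doc[[part]])) {
        stop(sprintf("cohort JSON is missing the '%s' element", part),
             call. = FALSE)
      }
    }
    protocol <- protocol_spec(doc$protocol$activities,
                              doc$protocol$scenario_id)
    vrdot_cohort(
      subjects = fill_empty(doc$subjects, subject_cols),
      visits = fill_empty(doc$visits, visit_cols),
      sessions = fill_empty(doc$sessions, session_cols),
      events = fill_empty(doc$events, event_cols),
      protocol = protocol,
      provenance = doc$provenance %||% ""
    )
  } else {
    rd <- function(name) {
      f <- file.path(path, name)
      if (!file.exists(f)) {
        stop(sprintf("CSV bundle is missing '%s'", name), call. = FALSE)
      }
      utils::read.csv(f, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    }
    proto <- rd("protocol.csv")
    proto <- proto[order(proto$position), ]
    prov_file <- file.path(path, "provenance.txt")
    prov <- if (file.exists(prov_file)) {
      paste(readLines(prov_file, warn = FALSE), collapse = "\n")
    } else ""
    vrdot_cohort(
      subjects = fill_empty(rd("subjects.csv"), subject_cols),
      visits = fill_empty(rd("visits.csv"), visit_cols),
      sessions = fill_empty(rd("sessions.csv"), session_cols),
      events = fill_empty(rd("events.csv"), event_cols),
      protocol = protocol_spec(proto$activity_id, proto$scenario_id[1]),
      provenance = prov
    )
  }
}

# a zero-row table can come back from JSON as an empty list: rebuild schema
fill_empty <- function(df, cols) {
  if (is.null(df) || (is.data.frame(df) && nrow(df) == 0L) ||
      (!is.data.frame(df) && length(df) == 0L)) {
    out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                         cols))
    return(out)
  }
  as.data.frame(df, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
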