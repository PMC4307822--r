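#' Construct a table of activity events
#'
#' Events are the raw material of scoring: each row is one performance of an
#' activity with its time interval, the number of attempts made within that
#' performance, and whether it was completed. Repeating an activity is
#' represented as multiple rows sharing an `activity_id`.
#'
#' @param activity_id Character vector of activity identifiers.
#' @param start_s,end_s Numeric vectors, seconds from session start
#'   (millisecond precision); `end_s >= start_s >= 0`.
#' @param attempts Integer vector, attempts within each performance (>= 1).
#' @param completed Logical vector; whether the performance completed the
#'   activity.
#' @return A data.frame with one row per event.
#' @export
activity_events <- function(activity_id, start_s, end_s,
                            attempts = 1L, completed = TRUE) {
  n <- length(activity_id)
  ev <- data.frame(
    activity_id = as.character(activity_id),
    start_s = round(as.numeric(start_s), 3),
    end_s = round(as.numeric(end_s), 3),
    attempts = as.integer(rep_len(attempts, n)),
    completed = as.logical(rep_len(completed, n)),
    stringsAsFactors = FALSE
  )
  bad <- which(ev$end_s < ev$start_s)
  if (length(bad)) {
    stop(sprintf("event %d ('%s'): end_s < start_s", bad[1],
                 ev$activity_id[bad[1]]), call. = FALSE)
  }
  if (any(ev$start_s < 0)) stop("event start_s must be >= 0", call. = FALSE)
  if (any(is.na(ev$attempts)) || any(ev$attempts < 1L)) {
    stop("event attempts must be integers >= 1", call. = FALSE)
  }
  ev
}

empty_events <- function() {
  data.frame(
    activity_id = character(), start_s = numeric(), end_s = numeric(),
    attempts = integer(), completed = logical(), stringsAsFactors = FALSE
  )
}

#' Construct a session log
#'
#' One subject-visit's timed event sequence in one evacuation scenario.
#'
#' @param subject_id Subject identifier (scalar character).
#' @param visit_year Visit index, 1..3.
#' @param events Event table as built by [activity_events()] (may have zero
#'   rows).
#' @param total_duration_s Total session duration in seconds (> 0); every
#'   event must lie within `[0, total_duration_s]`.
#' @param scenario_id Scenario number in 1..6.
#' @return An object of class `vrdot_session`.
#' @export
session_log <- function(subject_id, visit_year, events, total_duration_s,
                        scenario_id = 1L) {
  visit_year <- as.integer(visit_year)
  if (!visit_year %in% 1:3) {
    stop("visit_year must be 1, 2 or 3", call. = FALSE)
  }
  total_duration_s <- as.numeric(total_duration_s)
  if (!is.finite(total_duration_s) || total_duration_s <= 0) {
    stop("total_duration_s must be > 0", call. = FALSE)
  }
  if (nrow(events) && any(events$end_s > total_duration_s + 1e-9)) {
    stop(sprintf("subject '%s' visit %d: event extends beyond total_duration_s",
                 subject_id, visit_year), call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      visit_year = visit_year,
      scenario_id = as.integer(scenario_id),
      events = events,
      total_duration_s = total_duration_s
    ),
    class = "vrdot_session"
  )
}

#' @export
print.vrdot_session <- function(x, ...) {
  cat(sprintf("<vrdot_session> subject %s, visit %d, scenario %d: %d events over %.1f s\n",
              x$subject_id, x$visit_year, x$scenario_id, nrow(x$events),
              x$total_duration_s))
  invisible(x)
}

#' Check a session against its protocol
#'
#' Returns violations rather than raising, so callers can triage. Each row
#' names the violated rule, a severity (`"error"` for structural problems
#' that make scoring undefined, `"warning"` for irregularities scoring can
#' absorb, such as same-activity overlap, which the efficacy ratio unions),
#' and a human-readable detail.
#'
#' @param session A `vrdot_session`.
#' @param protocol A `vrdot_protocol`.
#' @return A data.frame with columns `rule`, `severity`, `detail`; zero rows
#'   for a fully conformant session.
#' @export
validate_session <- function(session, protocol) {
  stopifnot(inherits(session, "vrdot_session"),
            inherits(protocol, "vrdot_protocol"))
  v <- list()
  add <- function(rule, severity, detail) {
    v[[length(v) + 1L]] <<- data.frame(
      rule = rule, severity = severity, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  ev <- session$events
  unknown <- setdiff(unique(ev$activity_id), protocol$activities)
  for (a in unknown) {
    add("unknown activity", "error",
        sprintf("activity_id '%s' is not in the protocol", a))
  }
  bad_t <- which(ev$end_s < ev$start_s)
  for (i in bad_t) {
    add("negative duration", "error",
        sprintf("event %d ('%s'): end_s < start_s", i, ev$activity_id[i]))
  }
  out <- which(ev$start_s < 0 | ev$end_s > session$total_duration_s + 1e-9)
  for (i in out) {
    add("event outside session", "error",
        sprintf("event %d ('%s') outside [0, total_duration_s]", i,
                ev$activity_id[i]))
  }
  if (any(ev$attempts < 1L)) {
    add("attempts", "error", "event attempts must be >= 1")
  }
  # same-activity overlap: scoring unions these intervals, but flag them
  for (a in intersect(unique(ev$activity_id), protocol$activities)) {
    idx <- which(ev$activity_id == a)
    if (length(idx) < 2L) next
    o <- order(ev$start_s[idx])
    s <- ev$start_s[idx][o]
    e <- ev$end_s[idx][o]
    if (any(s[-1] < e[-length(e)] - 1e-9)) {
      add("overlapping events", "warning",
          sprintf("activity '%s' has overlapping intervals", a))
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), severity = character(),
               detail = character(), stringsAsFactors = FALSE)
}

# stop on structural (error-severity) violations; warnings are tolerated
assert_session_valid <- function(session, protocol) {
  v <- validate_session(session, protocol)
  err <- v[v$severity == "error", , drop = FALSE]
  if (nrow(err)) {
    stop(sprintf("invalid session (subject '%s', visit %d): %s",
                 session$subject_id, session$visit_year,
                 paste(err$detail, collapse = "; ")), call. = FALSE)
  }
  invisible(TRUE)
}
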