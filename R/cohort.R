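#' @name cohort
#' @title Cohort container and schema
#'
#' @description
#' A cohort is stored relationally as four tables joined on
#' `subject_id` (+ `visit_year`), plus the evacuation protocol:
#'
#' * `subjects`: `subject_id`, `group` (control/aMCI/mildAD), `age`, `sex`
#'   (`"M"`/`"F"`), `education` (years), `knee_heel_cm`,
#'   `converted_to_ad` (logical, aMCI only, else `NA`), `dropout` (logical;
#'   dropouts have baseline data only).
#' * `visits`: one row per completed subject-visit with the scale scores
#'   (`mmse`, `bristol_adl`, `blessed_adl`, `gds`, `ravlt_delayed`, `faq`,
#'   `tmt_a_s`, `tmt_b_s`, `digit_symbol`) and raw psychomotor measures
#'   (`walk_time_s`, `walk_steps`, `taps_dominant_15s`,
#'   `taps_nondominant_15s`, `grip_kg`).
#' * `sessions`: `subject_id`, `visit_year`, `scenario_id`,
#'   `total_duration_s`.
#' * `events`: `subject_id`, `visit_year`, `event_idx`, `activity_id`,
#'   `start_s`, `end_s`, `attempts`, `completed`.
#'
#' Timestamps are seconds from session start with millisecond precision.
NULL

subject_cols <- c("subject_id", "group", "age", "sex", "education",
                  "knee_heel_cm", "converted_to_ad", "dropout")
scale_cols <- c("mmse", "bristol_adl", "blessed_adl", "gds", "ravlt_delayed",
                "faq", "tmt_a_s", "tmt_b_s", "digit_symbol")
psychomotor_cols <- c("walk_time_s", "walk_steps", "taps_dominant_15s",
                      "taps_nondominant_15s", "grip_kg")
visit_cols <- c("subject_id", "visit_year", scale_cols, psychomotor_cols)
session_cols <- c("subject_id", "visit_year", "scenario_id",
                  "total_duration_s")
event_cols <- c("subject_id", "visit_year", "event_idx", "activity_id",
                "start_s", "end_s", "attempts", "completed")

cohort_groups <- c("control", "aMCI", "mildAD")

# enforce column order, types and row order so that equal cohorts are
# identical objects (and writes are byte-stable)
canonicalize_cohort_tables <- function(subjects, visits, sessions, events) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing required column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    df[cols]
  }
  subjects <- need(as.data.frame(subjects), subject_cols, "subjects")
  visits <- need(as.data.frame(visits), visit_cols, "visits")
  sessions <- need(as.data.frame(sessions), session_cols, "sessions")
  events <- need(as.data.frame(events), event_cols, "events")

  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$group <- as.character(subjects$group)
  subjects$sex <- as.character(subjects$sex)
  for (col in c("age", "education", "knee_heel_cm")) {
    subjects[[col]] <- as.numeric(subjects[[col]])
  }
  subjects$converted_to_ad <- as.logical(subjects$converted_to_ad)
  subjects$dropout <- as.logical(subjects$dropout)

  visits$subject_id <- as.character(visits$subject_id)
  visits$visit_year <- as.integer(visits$visit_year)
  visits$walk_steps <- as.integer(visits$walk_steps)
  visits$taps_dominant_15s <- as.integer(visits$taps_dominant_15s)
  visits$taps_nondominant_15s <- as.integer(visits$taps_nondominant_15s)
  for (col in setdiff(visit_cols, c("subject_id", "visit_year", "walk_steps",
                                    "taps_dominant_15s",
                                    "taps_nondominant_15s"))) {
    visits[[col]] <- as.numeric(visits[[col]])
  }

  sessions$subject_id <- as.character(sessions$subject_id)
  sessions$visit_year <- as.integer(sessions$visit_year)
  sessions$scenario_id <- as.integer(sessions$scenario_id)
  sessions$total_duration_s <- round(as.numeric(sessions$total_duration_s), 3)

  events$subject_id <- as.character(events$subject_id)
  events$visit_year <- as.integer(events$visit_year)
  events$event_idx <- as.integer(events$event_idx)
  events$activity_id <- as.character(events$activity_id)
  events$start_s <- round(as.numeric(events$start_s), 3)
  events$end_s <- round(as.numeric(events$end_s), 3)
  events$attempts <- as.integer(events$attempts)
  events$completed <- as.logical(events$completed)

  ord <- function(df, keys) {
    df <- df[do.call(order, df[keys]), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  list(
    subjects = ord(subjects, "subject_id"),
    visits = ord(visits, c("subject_id", "visit_year")),
    sessions = ord(sessions, c("subject_id", "visit_year")),
    events = ord(events, c("subject_id", "visit_year", "event_idx"))
  )
}

#' Assemble and validate a cohort dataset
#'
#' @param subjects,visits,sessions,events Data frames following the schema
#'   described in [cohort].
#' @param protocol A [protocol_spec()].
#' @param provenance Free-text origin of the data (file source, or the
#'   simulation seed and configuration).
#' @return An object of class `vrdot_cohort`.
#' @export
vrdot_cohort <- function(subjects, visits, sessions, events,
                         protocol = default_protocol(), provenance = "") {
  tabs <- canonicalize_cohort_tables(subjects, visits, sessions, events)
  x <- structure(
    c(tabs, list(protocol = protocol, provenance = as.character(provenance))),
    class = "vrdot_cohort"
  )
  validate_cohort(x)
  x
}

#' Validate a cohort's invariants
#'
#' Checks id uniqueness and referential integrity across the four tables,
#' instrument bounds (MMSE in 0..30, walk_steps >= 1), and every session's
#' event-level invariants. Errors name the offending subject and field.
#'
#' @param cohort A `vrdot_cohort`.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$subjects
  if (anyDuplicated(s$subject_id)) {
    stop("subject_ids must be unique", call. = FALSE)
  }
  bad_group <- setdiff(unique(s$group), cohort_groups)
  if (length(bad_group)) {
    stop(sprintf("unknown group label(s): %s (field 'group')",
                 paste(bad_group, collapse = ", ")), call. = FALSE)
  }
  v <- cohort$visits
  orphan <- setdiff(v$subject_id, s$subject_id)
  if (length(orphan)) {
    stop(sprintf("visits reference unknown subject_id '%s'", orphan[1]),
         call. = FALSE)
  }
  if (anyDuplicated(v[c("subject_id", "visit_year")])) {
    stop("duplicate subject_id/visit_year rows in visits", call. = FALSE)
  }
  bad <- which(!is.na(v$mmse) & (v$mmse < 0 | v$mmse > 30))
  if (length(bad)) {
    stop(sprintf("subject '%s': MMSE in [0,30] violated (value %.1f)",
                 v$subject_id[bad[1]], v$mmse[bad[1]]), call. = FALSE)
  }
  bad <- which(!is.na(v$walk_steps) & v$walk_steps < 1L)
  if (length(bad)) {
    stop(sprintf("subject '%s': walk_steps >= 1 violated",
                 v$subject_id[bad[1]]), call. = FALSE)
  }
  if (any(!v$visit_year %in% 1:3)) {
    stop("visit_year must be in 1..3", call. = FALSE)
  }
  se <- cohort$sessions
  orphan <- setdiff(se$subject_id, s$subject_id)
  if (length(orphan)) {
    stop(sprintf("sessions reference unknown subject_id '%s'", orphan[1]),
         call. = FALSE)
  }
  if (any(se$total_duration_s <= 0)) {
    i <- which(se$total_duration_s <= 0)[1]
    stop(sprintf("subject '%s' visit %d: total_duration_s must be > 0",
                 se$subject_id[i], se$visit_year[i]), call. = FALSE)
  }
  # event-level invariants, checked per session
  for (i in seq_len(nrow(se))) {
    sess <- get_session(cohort, se$subject_id[i], se$visit_year[i])
    ev <- sess$events
    if (nrow(ev) == 0L) next
    if (any(ev$end_s < ev$start_s)) {
      j <- which(ev$end_s < ev$start_s)[1]
      stop(sprintf("subject '%s' visit %d event %d ('%s'): end_s < start_s",
                   sess$subject_id, sess$visit_year, j, ev$activity_id[j]),
           call. = FALSE)
    }
    if (any(ev$start_s < 0) || any(ev$end_s > sess$total_duration_s + 1e-9)) {
      stop(sprintf("subject '%s' visit %d: event outside [0, total_duration_s]",
                   sess$subject_id, sess$visit_year), call. = FALSE)
    }
    if (any(ev$attempts < 1L)) {
      stop(sprintf("subject '%s' visit %d: attempts >= 1 violated",
                   sess$subject_id, sess$visit_year), call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Extract one session from a cohort
#'
#' @param cohort A `vrdot_cohort`.
#' @param subject_id,visit_year Keys of the session.
#' @return A `vrdot_session`, or an error if absent.
#' @export
get_session <- function(cohort, subject_id, visit_year) {
  se <- cohort$sessions
  i <- which(se$subject_id == subject_id & se$visit_year == visit_year)
  if (length(i) != 1L) {
    stop(sprintf("no session for subject '%s' visit %d", subject_id,
                 as.integer(visit_year)), call. = FALSE)
  }
  ev <- cohort$events
  ev <- ev[ev$subject_id == subject_id & ev$visit_year == visit_year, ,
           drop = FALSE]
  ev <- ev[order(ev$event_idx), c("activity_id", "start_s", "end_s",
                                  "attempts", "completed")]
  rownames(ev) <- NULL
  session_log(subject_id, visit_year, ev, se$total_duration_s[i],
              scenario_id = se$scenario_id[i])
}

#' @export
print.vrdot_cohort <- function(x, ...) {
  tab <- table(factor(x$subjects$group, levels = cohort_groups))
  cat(sprintf("<vrdot_cohort> %d subjects (%s), %d visits, %d sessions, %d events\n",
              nrow(x$subjects),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$visits), nrow(x$sessions), nrow(x$events)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
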