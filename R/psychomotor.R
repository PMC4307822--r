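#' Psychomotor metrics
#'
#' Helpers that turn the raw psychomotor measurements (a timed 4.6-m walk,
#' the step count over the same course, 15-s midair finger tapping, grip
#' strength) into the derived metrics used by the analysis.
#'
#' @param distance_m Course length in metres (default 4.6).
#' @param time_s Walk time in seconds (> 0).
#' @name psychomotor
NULL

#' @rdname psychomotor
#' @return `gait_speed()`: speed in m/s.
#' @export
gait_speed <- function(time_s, distance_m = 4.6) {
  if (any(!is.na(time_s) & time_s <= 0)) {
    stop("walk time must be > 0 seconds", call. = FALSE)
  }
  distance_m / time_s
}

#' @rdname psychomotor
#' @param steps Number of steps taken over the course (>= 1).
#' @return `stride_length()`: stride length in metres (distance / steps).
#' @export
stride_length <- function(steps, distance_m = 4.6) {
  if (any(!is.na(steps) & steps < 1)) {
    stop("steps must be >= 1", call. = FALSE)
  }
  distance_m / steps
}

#' @rdname psychomotor
#' @param value Gait speed or stride length to normalise.
#' @param knee_heel_cm Knee-heel (lower leg) length in cm (> 0).
#' @return `knee_heel_adjust()`: the value rescaled to a 50-cm knee-heel
#'   length, `value * 50 / knee_heel_cm`. Identity at 50 cm;
#'   scale-equivariant.
#' @export
knee_heel_adjust <- function(value, knee_heel_cm) {
  if (any(!is.na(knee_heel_cm) & knee_heel_cm <= 0)) {
    stop("knee_heel_cm must be > 0", call. = FALSE)
  }
  value * (50 / knee_heel_cm)
}

#' @rdname psychomotor
#' @param n_taps Tap count (>= 0).
#' @param duration_s Tapping interval in seconds (default 15, > 0).
#' @return `tapping_rate()`: taps per second.
#' @export
tapping_rate <- function(n_taps, duration_s = 15) {
  if (any(!is.na(duration_s) & duration_s <= 0)) {
    stop("tapping duration must be > 0 seconds", call. = FALSE)
  }
  if (any(!is.na(n_taps) & n_taps < 0)) {
    stop("n_taps must be >= 0", call. = FALSE)
  }
  n_taps / duration_s
}

#' @rdname psychomotor
#' @param ... Up to three raw grip measurements (kg), vectors recycled
#'   row-wise.
#' @return `grip_best()`: the best (maximum) of the attempts.
#' @export
grip_best <- function(...) {
  do.call(pmax, c(list(...), na.rm = TRUE))
}

#' Derived psychomotor metrics per subject-visit
#'
#' Computes gait speed, stride length (both optionally normalised to a 50-cm
#' knee-heel length) and dominant/non-dominant tapping rates for every visit
#' in a cohort. The knee-heel normalisation is controlled by `knee_heel`:
#' `"apply"` always rescales, `"skip"` never does, and `"auto"` rescales a
#' metric only when the knee-heel covariate reaches 10% significance in a
#' linear regression of the raw metric on knee-heel length across baseline
#' visits.
#'
#' @param cohort A `vrdot_cohort`.
#' @param knee_heel One of `"apply"`, `"auto"`, `"skip"`.
#' @return A data.frame (`subject_id`, `visit_year`, `gait_speed_ms`,
#'   `stride_m`, `tap_rate_dom`, `tap_rate_nondom`, `grip_kg`) with an
#'   attribute `knee_heel_applied` naming the metrics that were rescaled.
#' @export
psychomotor_features <- function(cohort,
                                 knee_heel = c("apply", "auto", "skip")) {
  knee_heel <- match.arg(knee_heel)
  v <- cohort$visits
  s <- cohort$subjects
  kh <- s$knee_heel_cm[match(v$subject_id, s$subject_id)]
  out <- data.frame(
    subject_id = v$subject_id,
    visit_year = v$visit_year,
    gait_speed_ms = gait_speed(v$walk_time_s),
    stride_m = stride_length(v$walk_steps),
    tap_rate_dom = tapping_rate(v$taps_dominant_15s),
    tap_rate_nondom = tapping_rate(v$taps_nondominant_15s),
    grip_kg = v$grip_kg,
    stringsAsFactors = FALSE
  )
  adjust <- c(gait_speed_ms = FALSE, stride_m = FALSE)
  for (m in names(adjust)) {
    adjust[[m]] <- switch(knee_heel,
      apply = TRUE,
      skip = FALSE,
      auto = {
        base <- out$visit_year == 1L & !is.na(out[[m]]) & !is.na(kh)
        if (sum(base) < 3L) FALSE else {
          fit <- stats::lm(out[[m]][base] ~ kh[base])
          p <- summary(fit)$coefficients
          nrow(p) >= 2L && p[2, 4] < 0.10
        }
      }
    )
    if (adjust[[m]]) out[[m]] <- knee_heel_adjust(out[[m]], kh)
  }
  attr(out, "knee_heel_applied") <- names(adjust)[adjust]
  out
}
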