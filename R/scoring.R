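#' Error-penalty weights of the functional index
#'
#' The index penalises four error processes observed in a session: omissions
#' (k1), repetitions (k2), order errors (k3), and extra attempts before a
#' first completion (k4). Weights are dimensionless and non-negative. The
#' defaults are the reference set used throughout the package's worked
#' examples and simulation studies; in applied use they should come from
#' [calibrate()] on a pilot sample.
#'
#' @param k1,k2,k3,k4 Non-negative penalty weights for omissions,
#'   repetitions, order errors, extra attempts.
#' @return An object of class `vrdot_params` (named numeric vector).
#' @export
score_params <- function(k1 = 0.3, k2 = 0.2, k3 = 0.4, k4 = 0.1) {
  k <- c(k1 = as.numeric(k1), k2 = as.numeric(k2),
         k3 = as.numeric(k3), k4 = as.numeric(k4))
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("penalty weights k1..k4 must be finite and >= 0", call. = FALSE)
  }
  structure(k, class = "vrdot_params")
}

#' @export
print.vrdot_params <- function(x, ...) {
  cat(sprintf("<vrdot_params> k1=%.3g (omission) k2=%.3g (repetition) k3=%.3g (order) k4=%.3g (attempts)\n",
              x[["k1"]], x[["k2"]], x[["k3"]], x[["k4"]]))
  invisible(x)
}

error_counts <- function(omissions, repetitions, order_errors,
                         extra_attempts) {
  x <- c(omissions = as.integer(omissions),
         repetitions = as.integer(repetitions),
         order_errors = as.integer(order_errors),
         extra_attempts = as.integer(extra_attempts))
  if (any(is.na(x)) || any(x < 0L)) {
    stop("error counts must be non-negative integers", call. = FALSE)
  }
  structure(x, class = "vrdot_error_counts")
}

#' @export
print.vrdot_error_counts <- function(x, ...) {
  cat(sprintf("<vrdot_error_counts> O=%d R=%d W=%d A=%d\n",
              x[["omissions"]], x[["repetitions"]], x[["order_errors"]],
              x[["extra_attempts"]]))
  invisible(x)
}

# length of the longest strictly increasing subsequence (O(n^2) DP; protocol
# lengths are small)
lis_length <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && best[j] + 1L > best[i]) best[i] <- best[j] + 1L
    }
  }
  max(best)
}

# first completion (earliest completion instant) per activity; returns the
# event rows in completion order
first_completions <- function(events) {
  done <- events[events$completed, , drop = FALSE]
  if (nrow(done) == 0L) return(done)
  o <- order(done$end_s, done$start_s, seq_len(nrow(done)))
  done <- done[o, , drop = FALSE]
  done[!duplicated(done$activity_id), , drop = FALSE]
}

#' Extract the four error counts from a session
#'
#' Against the protocol's canonical activity list, this derives:
#' * omissions `O` — protocol activities with no completed event;
#' * repetitions `R` — completed performances beyond the first, summed over
#'   activities;
#' * order errors `W` — the order-restoration deficit of the
#'   first-completion sequence: the number of completed activities minus the
#'   length of its longest increasing subsequence when mapped to protocol
#'   positions. Equivalently, the minimum number of activities that would
#'   have to be dropped for the remainder to be in protocol order; zero iff
#'   first completions occur in protocol order;
#' * extra attempts `A` — attempts beyond the first on each activity's first
#'   completion (retries inside repeated performances are already counted by
#'   `R`).
#'
#' @param session A `vrdot_session`; must be structurally valid against the
#'   protocol (see [validate_session()]).
#' @param protocol A `vrdot_protocol`.
#' @return A `vrdot_error_counts` (named integer vector `omissions`,
#'   `repetitions`, `order_errors`, `extra_attempts`).
#' @export
#' @examples
#' p <- protocol_spec(c("A", "B", "C", "D", "E"))
#' ev <- activity_events(c("A", "C", "B", "C"),
#'                       start_s = c(0, 10, 20, 30),
#'                       end_s = c(5, 15, 25, 35),
#'                       attempts = c(1, 2, 1, 1))
#' s <- session_log("s1", 1, ev, 60)
#' count_errors(s, p)  # D, E omitted is O=2 unless D completed later
count_errors <- function(session, protocol) {
  assert_session_valid(session, protocol)
  acts <- protocol$activities
  ev <- session$events
  done <- ev[ev$completed, , drop = FALSE]
  completions <- table(factor(done$activity_id, levels = acts))
  O <- sum(completions == 0L)
  R <- sum(pmax(as.integer(completions) - 1L, 0L))
  fc <- first_completions(ev)
  idx <- match(fc$activity_id, acts)
  W <- length(idx) - lis_length(idx)
  A <- sum(pmax(fc$attempts - 1L, 0L))
  error_counts(O, R, W, A)
}

#' Efficacy ratio of a session
#'
#' The fraction of total session time spent performing protocol activities:
#' the summed duration of events whose `activity_id` belongs to the
#' protocol, divided by `total_duration_s`. Overlapping intervals of the
#' same activity are unioned before summing, and the result is clamped to
#' `[0, 1]`.
#'
#' @inheritParams count_errors
#' @return A proportion in `[0, 1]`.
#' @export
efficacy_ratio <- function(session, protocol) {
  stopifnot(inherits(session, "vrdot_session"),
            inherits(protocol, "vrdot_protocol"))
  if (session$total_duration_s <= 0) {
    stop("total_duration_s must be > 0", call. = FALSE)
  }
  ev <- session$events
  ev <- ev[ev$activity_id %in% protocol$activities, , drop = FALSE]
  if (nrow(ev) == 0L) return(0)
  tot <- 0
  for (a in unique(ev$activity_id)) {
    idx <- ev$activity_id == a
    tot <- tot + interval_union_length(ev$start_s[idx], ev$end_s[idx])
  }
  min(max(tot / session$total_duration_s, 0), 1)
}

interval_union_length <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  total <- 0
  cur_s <- start[1]
  cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]
      cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Functional impairment index of a session
#'
#' The efficacy ratio adjusted by the four error penalties through the
#' rational form
#' \deqn{FI = 100 \cdot R_{eff} / (1 + k_1 O + k_2 R + k_3 W + k_4 A).}
#' The index lives on a 0--100 scale, reduces to `100 * reff` when no errors
#' occurred (or all weights are zero), and is non-increasing in every error
#' count. Higher FI means better everyday function.
#'
#' @inheritParams count_errors
#' @param params Penalty weights from [score_params()] or [calibrate()].
#' @return An object of class `vrdot_score` with elements `reff`, `fi`, and
#'   `counts`.
#' @export
functional_index <- function(session, protocol, params = score_params()) {
  if (!inherits(params, "vrdot_params")) params <- do.call(score_params,
                                                           as.list(params))
  counts <- count_errors(session, protocol)
  reff <- efficacy_ratio(session, protocol)
  penalty <- 1 + sum(as.numeric(params) * as.numeric(counts))
  structure(
    list(reff = reff, fi = 100 * reff / penalty, counts = counts),
    class = "vrdot_score"
  )
}

#' @export
print.vrdot_score <- function(x, ...) {
  cat(sprintf("<vrdot_score> REff=%.3f FI=%.2f (O=%d R=%d W=%d A=%d)\n",
              x$reff, x$fi, x$counts[["omissions"]],
              x$counts[["repetitions"]], x$counts[["order_errors"]],
              x$counts[["extra_attempts"]]))
  invisible(x)
}

#' Score every session in a cohort
#'
#' @param cohort A `vrdot_cohort`.
#' @param params Penalty weights (see [score_params()]).
#' @return A data.frame with one row per subject-visit that has a session:
#'   `subject_id`, `visit_year`, `reff`, `fi`, `omissions`, `repetitions`,
#'   `order_errors`, `extra_attempts`.
#' @export
score_cohort <- function(cohort, params = score_params()) {
  stopifnot(inherits(cohort, "vrdot_cohort"))
  se <- cohort$sessions
  rows <- vector("list", nrow(se))
  for (i in seq_len(nrow(se))) {
    sc <- tryCatch(
      functional_index(get_session(cohort, se$subject_id[i],
                                   se$visit_year[i]),
                       cohort$protocol, params),
      error = function(e) {
        stop(sprintf("scoring failed for subject '%s' visit %d: %s",
                     se$subject_id[i], se$visit_year[i],
                     conditionMessage(e)), call. = FALSE)
      }
    )
    rows[[i]] <- data.frame(
      subject_id = se$subject_id[i], visit_year = se$visit_year[i],
      reff = sc$reff, fi = sc$fi,
      omissions = sc$counts[["omissions"]],
      repetitions = sc$counts[["repetitions"]],
      order_errors = sc$counts[["order_errors"]],
      extra_attempts = sc$counts[["extra_attempts"]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), visit_year = integer(),
                      reff = numeric(), fi = numeric(),
                      omissions = integer(), repetitions = integer(),
                      order_errors = integer(), extra_attempts = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
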