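#' Evacuation protocol specification
#'
#' A protocol is the canonical, ordered list of activities that make up one
#' evacuation scenario. Scoring compares the order and completeness of a
#' session's events against this list.
#'
#' @param activities Character vector of unique activity identifiers, in
#'   canonical completion order. Must be non-empty.
#' @param scenario_id Integer scenario number in 1..6 (scenarios are graded
#'   from easy to difficult).
#'
#' @return An object of class `vrdot_protocol` with elements `scenario_id`
#'   and `activities`.
#' @seealso [default_protocol()]
#' @export
#' @examples
#' protocol_spec(c("raise_alarm", "avoid_smoke", "exit"), scenario_id = 2)
protocol_spec <- function(activities, scenario_id = 1L) {
  if (!is.character(activities) || length(activities) == 0L) {
    stop("`activities` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(activities)) {
    stop("protocol activity_ids must be unique", call. = FALSE)
  }
  scenario_id <- as.integer(scenario_id)
  if (length(scenario_id) != 1L || is.na(scenario_id) ||
      scenario_id < 1L || scenario_id > 6L) {
    stop("`scenario_id` must be a single integer in 1..6", call. = FALSE)
  }
  structure(
    list(scenario_id = scenario_id, activities = activities),
    class = "vrdot_protocol"
  )
}

#' Default eight-activity evacuation protocol
#'
#' The instrument's concrete activity list is configurable; this default is a
#' plausible eight-step fire-evacuation routine (assess the situation, alert,
#' gather, and exit safely), not a claim about any specific deployment.
#'
#' @param scenario_id Integer scenario number in 1..6.
#' @return A `vrdot_protocol`.
#' @export
default_protocol <- function(scenario_id = 1L) {
  protocol_spec(
    c(
      "assess_fire", "raise_alarm", "alert_neighbors", "gather_essentials",
      "check_door_heat", "avoid_smoke", "descend_stairs", "reach_assembly"
    ),
    scenario_id = scenario_id
  )
}

#' @export
print.vrdot_protocol <- function(x, ...) {
  cat("<vrdot_protocol> scenario", x$scenario_id, "with",
      length(x$activities), "activities:\n")
  cat(" ", paste(seq_along(x$activities), x$activities, sep = ". ",
                 collapse = ", "), "\n")
  invisible(x)
}
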