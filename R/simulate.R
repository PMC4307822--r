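#' Synthetic cohort configuration
#'
#' The generator emulates a three-group annual-visit study: healthy
#' controls, amnestic MCI, and mild Alzheimer-type dementia, with
#' group-anchored scale and psychomotor distributions, group-dependent
#' session error processes, per-subject linear decline, and conversion
#' outcomes for the aMCI group. `default_config()` carries the reference
#' anchors (group sizes 72/65/68 completers; e.g. MMSE 29.1 (1.0) /
#' 26.1 (1.8) / 23.4 (2.0); combined gait speed 0.96 / 0.91 / 0.86 m/s;
#' 11.6% dropout after baseline). Scales are drawn from normals truncated
#' at instrument bounds; several anchors sit close enough to a bound that
#' untruncated draws would be invalid.
#'
#' Error-event rates, efficacy-ratio levels and annual slopes are not
#' published as distributions; the defaults encode the qualitative
#' structure the analysis assumes (control < aMCI < mildAD error rates,
#' declining trajectories, conversion driven by the efficacy-ratio slope)
#' at magnitudes a geriatric cohort would plausibly show. See the package
#' vignette for the reasoning behind each choice.
#'
#' @param groups Named list of per-group settings (see `group_config()`
#'   inside `default_config()` for the shape).
#' @param n_visits Number of annual visits (fixed design: 3).
#' @param dropout Probability of dropping out after baseline; dropouts
#'   contribute baseline data only and are flagged, so a config with
#'   completer targets (72, 65, 68) emits 232 subjects of whom 205
#'   complete.
#' @return A list of class `vrdot_sim_config`.
#' @export
default_config <- function(groups = NULL, n_visits = 3L, dropout = 0.116) {
  if (is.null(groups)) {
    # per-scale anchors: mean, sd, lower bound, upper bound
    sc <- function(mean, sd, lo, hi) c(mean = mean, sd = sd, lo = lo, hi = hi)
    groups <- list(
      control = list(
        n = 72L, p_male = 0.38,
        age = sc(72.63, 5.06, 60, 95),
        education = sc(16.1, 2.9, 6, 22),
        knee_heel_cm = sc(50, 4, 38, 62),
        scales = list(
          mmse = sc(29.1, 1.0, 0, 30),
          ravlt_delayed = sc(7.4, 3.7, 0, 15),
          gds = sc(4.59, 4.1, 0, 30),
          faq = sc(0.1, 0.6, 0, 30),
          tmt_a_s = sc(36.3, 13.0, 10, 300),
          tmt_b_s = sc(89.3, 44.3, 20, 400),
          digit_symbol = sc(45.8, 10.2, 0, 93),
          bristol_adl = sc(4.46, 0.5, 0, 60),
          blessed_adl = sc(1.85, 0.27, 0, 17)
        ),
        gait_speed = sc(0.96, 0.23, 0.3, 2.0),
        stride_m = sc(0.62, 0.07, 0.3, 1.0),
        taps_dom = sc(3.87, 0.80, 1.0, 7.0),
        taps_nondom = sc(3.63, 0.64, 1.0, 7.0),
        grip_kg = sc(29, 8, 5, 60),
        reff = sc(0.85, 0.05, 0.05, 0.98),
        error_lambda = c(O = 0.15, R = 0.20, W = 0.20, A = 0.30),
        error_growth = 0.05,
        session_duration = c(meanlog = log(300), sdlog = 0.20),
        reff_slope = c(mean = -0.005, sd = 0.010),
        slopes = list(
          mmse = c(-0.05, 0.15), ravlt_delayed = c(-0.10, 0.20),
          gds = c(0.05, 0.30), faq = c(0.05, 0.20),
          tmt_a_s = c(0.5, 1.0), tmt_b_s = c(1.0, 2.0),
          digit_symbol = c(-0.3, 0.5), bristol_adl = c(0.05, 0.10),
          blessed_adl = c(0.02, 0.05), gait_speed = c(-0.005, 0.010),
          stride_m = c(-0.002, 0.005), taps_dom = c(-0.02, 0.03),
          taps_nondom = c(-0.02, 0.03), grip_kg = c(-0.3, 0.3)
        )
      ),
      aMCI = list(
        n = 65L, p_male = 0.43,
        age = sc(72.78, 6.21, 60, 95),
        education = sc(15.7, 3.0, 6, 22),
        knee_heel_cm = sc(50, 4, 38, 62),
        scales = list(
          mmse = sc(26.1, 1.8, 0, 30),
          ravlt_delayed = sc(2.9, 3.3, 0, 15),
          gds = sc(5.49, 5.76, 0, 30),
          faq = sc(3.8, 4.4, 0, 30),
          tmt_a_s = sc(44.2, 21.7, 10, 300),
          tmt_b_s = sc(130.8, 73.2, 20, 400),
          digit_symbol = sc(37.0, 11.1, 0, 93),
          bristol_adl = sc(5.59, 0.9, 0, 60),
          blessed_adl = sc(2.38, 0.56, 0, 17)
        ),
        gait_speed = sc(0.91, 0.24, 0.3, 2.0),
        stride_m = sc(0.60, 0.07, 0.3, 1.0),
        taps_dom = sc(3.77, 0.81, 1.0, 7.0),
        taps_nondom = sc(3.61, 0.71, 1.0, 7.0),
        grip_kg = sc(28, 8, 5, 60),
        reff = sc(0.65, 0.07, 0.05, 0.98),
        error_lambda = c(O = 0.9, R = 1.0, W = 1.0, A = 1.2),
        error_growth = 0.25,
        session_duration = c(meanlog = log(420), sdlog = 0.20),
        reff_slope = c(mean = -0.050, sd = 0.020),
        slopes = list(
          mmse = c(-0.8, 0.5), ravlt_delayed = c(-0.6, 0.4),
          gds = c(0.2, 0.5), faq = c(1.5, 0.8),
          tmt_a_s = c(4.0, 2.0), tmt_b_s = c(8.0, 4.0),
          digit_symbol = c(-2.0, 1.0), bristol_adl = c(0.8, 0.4),
          blessed_adl = c(0.3, 0.2), gait_speed = c(-0.030, 0.015),
          stride_m = c(-0.010, 0.006), taps_dom = c(-0.08, 0.05),
          taps_nondom = c(-0.08, 0.05), grip_kg = c(-0.6, 0.4)
        ),
        conversion = c(intercept = -7.0, beta = -120)
      ),
      mildAD = list(
        n = 68L, p_male = 0.46,
        age = sc(72.58, 6.21, 60, 95),
        education = sc(14.6, 3.2, 6, 22),
        knee_heel_cm = sc(50, 4, 38, 62),
        scales = list(
          mmse = sc(23.4, 2.0, 0, 30),
          ravlt_delayed = sc(0.7, 1.6, 0, 15),
          gds = sc(5.29, 4.45, 0, 30),
          faq = sc(12.7, 6.7, 0, 30),
          tmt_a_s = sc(64.8, 34.5, 10, 300),
          tmt_b_s = sc(200.5, 86.6, 20, 400),
          digit_symbol = sc(27.6, 12.5, 0, 93),
          bristol_adl = sc(10.59, 0.9, 0, 60),
          blessed_adl = sc(4.38, 0.56, 0, 17)
        ),
        gait_speed = sc(0.86, 0.20, 0.3, 2.0),
        stride_m = sc(0.56, 0.07, 0.3, 1.0),
        taps_dom = sc(3.74, 0.80, 1.0, 7.0),
        taps_nondom = sc(3.58, 0.70, 1.0, 7.0),
        grip_kg = sc(26, 8, 5, 60),
        reff = sc(0.45, 0.08, 0.05, 0.98),
        error_lambda = c(O = 2.0, R = 2.2, W = 2.2, A = 2.5),
        error_growth = 0.35,
        session_duration = c(meanlog = log(540), sdlog = 0.20),
        reff_slope = c(mean = -0.080, sd = 0.025),
        slopes = list(
          mmse = c(-1.6, 0.7), ravlt_delayed = c(-0.3, 0.3),
          gds = c(0.3, 0.6), faq = c(2.5, 1.0),
          tmt_a_s = c(8.0, 4.0), tmt_b_s = c(15.0, 6.0),
          digit_symbol = c(-3.5, 1.5), bristol_adl = c(1.5, 0.6),
          blessed_adl = c(0.6, 0.25), gait_speed = c(-0.050, 0.020),
          stride_m = c(-0.015, 0.008), taps_dom = c(-0.12, 0.06),
          taps_nondom = c(-0.12, 0.06), grip_kg = c(-0.9, 0.5)
        )
      )
    )
  }
  if (!setequal(names(groups), cohort_groups)) {
    stop("groups must be named exactly control, aMCI, mildAD", call. = FALSE)
  }
  for (g in names(groups)) {
    if (groups[[g]]$n < 0L) stop("group sizes must be >= 0", call. = FALSE)
    if (any(groups[[g]]$error_lambda < 0)) {
      stop("error rates must be >= 0", call. = FALSE)
    }
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                        call. = FALSE)
  structure(
    list(groups = groups, n_visits = as.integer(n_visits), dropout = dropout),
    class = "vrdot_sim_config"
  )
}

rbind_or_empty <- function(rows, cols) {
  if (length(rows)) do.call(rbind, rows) else fill_empty(NULL, cols)
}

# truncated-normal draws by inverse-CDF so the RNG stream length is fixed
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

draw_scale <- function(n, anchor) {
  rtrunc_norm(n, anchor[["mean"]], anchor[["sd"]], anchor[["lo"]],
              anchor[["hi"]])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Construct a session realizing drawn error counts
#'
#' Builds an event sequence whose [count_errors()] output equals the given
#' `(O, R, W, A)` exactly and whose [efficacy_ratio()] equals `reff` up to
#' millisecond rounding: the generator is constructed to be the scorer's
#' inverse, which is what makes the scorer testable. Omitted activities
#' produce no events; order errors are realized as disjoint adjacent
#' transpositions of the performed order (each transposition lowers the
#' longest-increasing-subsequence length by exactly one); repetitions are
#' appended after all first completions; extra attempts are spread over
#' first completions. Infeasible draws (more order errors than the
#' performed-activity count supports) are capped at the feasible maximum.
#'
#' @param protocol A `vrdot_protocol`.
#' @param omissions,repetitions,order_errors,extra_attempts Target counts.
#' @param reff Target efficacy ratio in (0, 1).
#' @param total_duration_s Session duration in seconds.
#' @param subject_id,visit_year,scenario_id Session identity.
#' @return A `vrdot_session`. Consumes random numbers from the current RNG
#'   stream.
#' @export
generate_session <- function(protocol, omissions, repetitions, order_errors,
                             extra_attempts, reff, total_duration_s,
                             subject_id = "sim", visit_year = 1L,
                             scenario_id = 1L) {
  n_act <- length(protocol$activities)
  O <- min(as.integer(omissions), n_act)
  m <- n_act - O
  W <- if (m >= 2L) min(as.integer(order_errors), m %/% 2L) else 0L
  R <- if (m >= 1L) as.integer(repetitions) else 0L
  A <- if (m >= 1L) as.integer(extra_attempts) else 0L

  performed_idx <- sort(sample.int(n_act, m))
  if (W > 0L) {
    # W pairwise-disjoint adjacent transposition positions in 1..m-1
    slots <- sort(sample.int(m - W, W)) + seq_len(W) - 1L
    for (p in slots) {
      performed_idx[c(p, p + 1L)] <- performed_idx[c(p + 1L, p)]
    }
  }
  first_ids <- protocol$activities[performed_idx]
  extra <- if (m > 0L && A > 0L) {
    stats::rmultinom(1, A, rep(1, m))[, 1]
  } else integer(m)
  rep_ids <- if (m > 0L && R > 0L) {
    protocol$activities[performed_idx[sample.int(m, R, replace = TRUE)]]
  } else character()

  ids <- c(first_ids, rep_ids)
  n_ev <- length(ids)
  if (n_ev == 0L) {
    return(session_log(subject_id, visit_year, empty_events(),
                       round(total_duration_s, 3),
                       scenario_id = scenario_id))
  }
  reff <- clamp(reff, 0.02, 0.98)
  active_total <- reff * total_duration_s
  idle_total <- total_duration_s - active_total
  dur <- active_total * as.numeric(stats::rmultinom(1, 1000, rep(1, n_ev)) +
                                     1) /
    (1000 + n_ev)
  gaps <- idle_total * as.numeric(stats::rmultinom(1, 1000,
                                                   rep(1, n_ev + 1L)) + 1) /
    (1000 + n_ev + 1L)
  start <- cumsum(gaps[seq_len(n_ev)]) + c(0, cumsum(dur))[seq_len(n_ev)]
  end <- start + dur
  ev <- activity_events(
    ids, start, end,
    attempts = c(1L + extra, rep(1L, length(rep_ids))),
    completed = TRUE
  )
  # millisecond rounding must keep events ordered and inside the session
  ev$end_s <- pmin(ev$end_s, round(total_duration_s, 3))
  session_log(subject_id, visit_year, ev, round(total_duration_s, 3),
              scenario_id = scenario_id)
}

#' Generate a synthetic cohort
#'
#' Draws the full relational dataset: demographics and baseline scales from
#' the configured truncated normals, per-subject annual slopes, yearly
#' visit values following each subject's linear trend (re-truncated at
#' instrument bounds), one session per completed visit built by
#' [generate_session()] from Poisson error draws whose rates grow with
#' visit year, and conversion labels for the aMCI group from a logistic
#' model in the subject's realized efficacy-ratio slope. Dropout counts are
#' deterministic (`round(n * p / (1 - p))` extra subjects per group), so
#' the default configuration always yields 232 subjects of whom 205
#' complete all three visits.
#'
#' @param config A [default_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `vrdot_cohort`.
#' @export
generate_cohort <- function(config = default_config(), seed = 1L) {
  stopifnot(inherits(config, "vrdot_sim_config"))
  protocol <- default_protocol()
  withr::with_seed(as.integer(seed), {
    subj_rows <- list()
    visit_rows <- list()
    sess_rows <- list()
    event_rows <- list()
    counter <- 0L
    for (g in cohort_groups) {
      gc <- config$groups[[g]]
      n_complete <- gc$n
      n_drop <- round(n_complete * config$dropout / (1 - config$dropout))
      n_tot <- n_complete + n_drop
      if (n_tot == 0L) next
      drop_flags <- rep(FALSE, n_tot)
      if (n_drop > 0L) drop_flags[sample.int(n_tot, n_drop)] <- TRUE
      for (i in seq_len(n_tot)) {
        counter <- counter + 1L
        sid <- sprintf("S%03d", counter)
        sex <- if (stats::runif(1) < gc$p_male) "M" else "F"
        age <- round(draw_scale(1, gc$age), 1)
        edu <- round(draw_scale(1, gc$education), 1)
        kh <- round(draw_scale(1, gc$knee_heel_cm), 1)
        base_scales <- lapply(gc$scales, function(a) draw_scale(1, a))
        slopes <- lapply(gc$slopes, function(ms) stats::rnorm(1, ms[1], ms[2]))
        base_gait <- draw_scale(1, gc$gait_speed)
        base_stride <- draw_scale(1, gc$stride_m)
        base_tap_d <- draw_scale(1, gc$taps_dom)
        base_tap_n <- draw_scale(1, gc$taps_nondom)
        base_grip <- draw_scale(1, gc$grip_kg)
        base_reff <- draw_scale(1, gc$reff)
        reff_slope <- stats::rnorm(1, gc$reff_slope[["mean"]],
                                   gc$reff_slope[["sd"]])
        n_vis <- if (drop_flags[i]) 1L else config$n_visits
        for (yr in seq_len(n_vis)) {
          t <- yr - 1L
          val <- function(name) {
            a <- gc$scales[[name]]
            noise <- stats::rnorm(1, 0, 0.3 * a[["sd"]])
            clamp(base_scales[[name]] + slopes[[name]] * t + noise,
                  a[["lo"]], a[["hi"]])
          }
          gait <- clamp(base_gait + slopes$gait_speed * t +
                          stats::rnorm(1, 0, 0.02), 0.3, 2.0)
          stride <- clamp(base_stride + slopes$stride_m * t +
                            stats::rnorm(1, 0, 0.01), 0.3, 1.0)
          tap_d <- clamp(base_tap_d + slopes$taps_dom * t +
                           stats::rnorm(1, 0, 0.05), 1.0, 7.0)
          tap_n <- clamp(base_tap_n + slopes$taps_nondom * t +
                           stats::rnorm(1, 0, 0.05), 1.0, 7.0)
          grip <- clamp(base_grip + slopes$grip_kg * t +
                          stats::rnorm(1, 0, 0.5), 5, 60)
          visit_rows[[length(visit_rows) + 1L]] <- data.frame(
            subject_id = sid, visit_year = yr,
            mmse = round(val("mmse")),
            bristol_adl = round(val("bristol_adl"), 1),
            blessed_adl = round(val("blessed_adl"), 1),
            gds = round(val("gds")),
            ravlt_delayed = round(val("ravlt_delayed")),
            faq = round(val("faq")),
            tmt_a_s = round(val("tmt_a_s"), 1),
            tmt_b_s = round(val("tmt_b_s"), 1),
            digit_symbol = round(val("digit_symbol")),
            walk_time_s = round(4.6 / gait, 1),
            walk_steps = max(1L, as.integer(round(4.6 / stride))),
            taps_dominant_15s = as.integer(round(tap_d * 15)),
            taps_nondominant_15s = as.integer(round(tap_n * 15)),
            grip_kg = round(grip, 1),
            stringsAsFactors = FALSE
          )
          lam <- gc$error_lambda * (1 + gc$error_growth * t)
          counts <- stats::rpois(4, lam)
          counts <- pmin(counts, c(length(protocol$activities), 10L, 4L, 12L))
          reff_yr <- clamp(base_reff + reff_slope * t +
                             stats::rnorm(1, 0, 0.01), 0.05, 0.98)
          dur <- stats::rlnorm(1, gc$session_duration[["meanlog"]],
                               gc$session_duration[["sdlog"]])
          scen <- sample.int(6L, 1L)
          sess <- generate_session(protocol, counts[1], counts[2], counts[3],
                                   counts[4], reff_yr, dur,
                                   subject_id = sid, visit_year = yr,
                                   scenario_id = scen)
          sess_rows[[length(sess_rows) + 1L]] <- data.frame(
            subject_id = sid, visit_year = yr, scenario_id = scen,
            total_duration_s = sess$total_duration_s,
            stringsAsFactors = FALSE
          )
          if (nrow(sess$events)) {
            event_rows[[length(event_rows) + 1L]] <- cbind(
              data.frame(subject_id = sid, visit_year = yr,
                         event_idx = seq_len(nrow(sess$events)),
                         stringsAsFactors = FALSE),
              sess$events
            )
          }
        }
        converted <- NA
        if (g == "aMCI" && !drop_flags[i]) {
          cv <- gc$conversion
          p_conv <- stats::plogis(cv[["intercept"]] + cv[["beta"]] *
                                    reff_slope)
          converted <- stats::runif(1) < p_conv
        }
        subj_rows[[length(subj_rows) + 1L]] <- data.frame(
          subject_id = sid, group = g, age = age, sex = sex,
          education = edu, knee_heel_cm = kh,
          converted_to_ad = converted, dropout = drop_flags[i],
          stringsAsFactors = FALSE
        )
      }
    }
    vrdot_cohort(
      subjects = rbind_or_empty(subj_rows, subject_cols),
      visits = rbind_or_empty(visit_rows, visit_cols),
      sessions = rbind_or_empty(sess_rows, session_cols),
      events = rbind_or_empty(event_rows, event_cols),
      protocol = protocol,
      provenance = sprintf("synthetic: default_config, seed=%d",
                           as.integer(seed))
    )
  })
}

#' Generate a calibration pilot
#'
#' A single-visit cohort with the pilot group sizes 25/26/24 (mean ages
#' 73.7, 74.2 and 76.7 years) whose MMSE and Bristol ADL scores are tied
#' monotonically, up to configurable noise, to the functional index
#' computed with a known weight set `true_k`. Error counts are drawn
#' independently per error type (subject-level Poisson rates uniform over a
#' wide range, unlinked across types) and the efficacy ratio is spread
#' widely and independently of the counts; both choices are what make the
#' weight set identifiable from rank correlations rather than only up to a
#' common rescaling. This pilot is a synthetic calibration testbed, not an
#' emulation of a clinical sample.
#'
#' @param true_k The generating weight set ([score_params()]).
#' @param seed Integer seed.
#' @param n Named group sizes (control/aMCI/mildAD).
#' @param scale_noise_sd Standard deviation of the noise added to the
#'   scale values that are tied to the functional index.
#' @return A single-visit `vrdot_cohort`.
#' @export
make_pilot <- function(true_k = score_params(), seed = 1L,
                       n = c(control = 25L, aMCI = 26L, mildAD = 24L),
                       scale_noise_sd = 0.25) {
  if (!inherits(true_k, "vrdot_params")) true_k <- do.call(score_params,
                                                           as.list(true_k))
  protocol <- default_protocol()
  ages <- list(control = c(73.7, 4.0), aMCI = c(74.2, 2.0),
               mildAD = c(76.7, 3.0))
  withr::with_seed(as.integer(seed), {
    subj_rows <- list()
    visit_rows <- list()
    sess_rows <- list()
    event_rows <- list()
    counter <- 0L
    for (g in cohort_groups) {
      for (i in seq_len(n[[g]])) {
        counter <- counter + 1L
        sid <- sprintf("P%03d", counter)
        lam <- stats::runif(4, 0, c(2.5, 3.0, 2.0, 4.0))
        counts <- pmin(stats::rpois(4, lam), c(6L, 8L, 4L, 10L))
        reff <- stats::runif(1, 0.25, 0.95)
        dur <- stats::rlnorm(1, log(360), 0.25)
        sess <- generate_session(protocol, counts[1], counts[2], counts[3],
                                 counts[4], reff, dur, subject_id = sid,
                                 visit_year = 1L, scenario_id = 1L)
        fi <- functional_index(sess, protocol, true_k)$fi
        mmse <- clamp(17 + 13 * fi / 100 +
                        stats::rnorm(1, 0, scale_noise_sd), 0, 30)
        bristol <- clamp(20 - 16 * fi / 100 +
                           stats::rnorm(1, 0, scale_noise_sd), 0, 60)
        blessed <- clamp(8 - 6 * fi / 100 +
                           stats::rnorm(1, 0, scale_noise_sd), 0, 17)
        subj_rows[[length(subj_rows) + 1L]] <- data.frame(
          subject_id = sid, group = g,
          age = round(stats::rnorm(1, ages[[g]][1], ages[[g]][2]), 1),
          sex = if (stats::runif(1) < 0.45) "M" else "F",
          education = round(stats::rnorm(1, 15, 3), 1),
          knee_heel_cm = round(rtrunc_norm(1, 50, 4, 38, 62), 1),
          converted_to_ad = NA, dropout = FALSE,
          stringsAsFactors = FALSE
        )
        visit_rows[[length(visit_rows) + 1L]] <- data.frame(
          subject_id = sid, visit_year = 1L,
          mmse = mmse, bristol_adl = bristol, blessed_adl = blessed,
          gds = round(stats::runif(1, 0, 10)),
          ravlt_delayed = round(stats::runif(1, 0, 12)),
          faq = round(stats::runif(1, 0, 20)),
          tmt_a_s = round(stats::runif(1, 25, 90), 1),
          tmt_b_s = round(stats::runif(1, 60, 250), 1),
          digit_symbol = round(stats::runif(1, 20, 55)),
          walk_time_s = round(stats::runif(1, 3.5, 8), 1),
          walk_steps = sample(6:12, 1),
          taps_dominant_15s = sample(40:70, 1),
          taps_nondominant_15s = sample(40:70, 1),
          grip_kg = round(stats::runif(1, 15, 45), 1),
          stringsAsFactors = FALSE
        )
        sess_rows[[length(sess_rows) + 1L]] <- data.frame(
          subject_id = sid, visit_year = 1L, scenario_id = 1L,
          total_duration_s = sess$total_duration_s, stringsAsFactors = FALSE
        )
        if (nrow(sess$events)) {
          event_rows[[length(event_rows) + 1L]] <- cbind(
            data.frame(subject_id = sid, visit_year = 1L,
                       event_idx = seq_len(nrow(sess$events)),
                       stringsAsFactors = FALSE),
            sess$events
          )
        }
      }
    }
    vrdot_cohort(
      subjects = do.call(rbind, subj_rows),
      visits = do.call(rbind, visit_rows),
      sessions = do.call(rbind, sess_rows),
      events = do.call(rbind, event_rows),
      protocol = protocol,
      provenance = sprintf("synthetic pilot: true_k=(%s), seed=%d",
                           paste(format(as.numeric(true_k)), collapse = ", "),
                           as.integer(seed))
    )
  })
}
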