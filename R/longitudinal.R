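#' Per-subject linear trajectory over yearly visits
#'
#' Ordinary least-squares line through a subject's (visit year, value)
#' points; the slope is the subject's annual rate of change. The intercept
#' is reported on the raw visit-year scale (value extrapolated to year 0).
#'
#' @param visit_year Numeric vector of visit years (at least two distinct).
#' @param value Measure values at those visits.
#' @param subject_id,measure Optional labels carried through to the fit.
#' @return An object of class `vrdot_trajectory`: `subject_id`, `measure`,
#'   `intercept`, `slope` (units/year), `n_visits`, `residual_sd` (`NA`
#'   with fewer than 3 visits), and `sxx` (the design spread used for
#'   precision weighting when pooling).
#' @export
fit_subject_trajectory <- function(visit_year, value, subject_id = NA_character_,
                                   measure = NA_character_) {
  keep <- !is.na(visit_year) & !is.na(value)
  x <- as.numeric(visit_year[keep])
  y <- as.numeric(value[keep])
  n <- length(x)
  if (n < 2L) {
    stop("at least 2 visits are required for a defined slope", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("visit years are identical: slope is undefined (degenerate design)",
         call. = FALSE)
  }
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  rss <- sum((y - intercept - slope * x)^2)
  residual_sd <- if (n > 2L) sqrt(rss / (n - 2L)) else NA_real_
  structure(
    list(subject_id = subject_id, measure = measure, intercept = intercept,
         slope = slope, n_visits = n, residual_sd = residual_sd, sxx = sxx),
    class = "vrdot_trajectory"
  )
}

#' @export
print.vrdot_trajectory <- function(x, ...) {
  cat(sprintf("<vrdot_trajectory> %s%sslope %.4g/year, intercept %.4g (n=%d)\n",
              if (is.na(x$subject_id)) "" else paste0(x$subject_id, " "),
              if (is.na(x$measure)) "" else paste0("[", x$measure, "] "),
              x$slope, x$intercept, x$n_visits))
  invisible(x)
}

#' Pool per-subject slopes into population rates of change
#'
#' A transparent two-stage analogue of a random intercept-and-slope model:
#' subject slopes come from per-subject OLS ([fit_subject_trajectory()]),
#' and the population (and per-group) mean annual rate of change is the mean
#' of those slopes with its standard error. Subject slopes are additionally
#' shrunk toward their group mean with empirical-Bayes weights
#' `w = tau^2 / (tau^2 + v_i)`, where `v_i = residual_sd^2 / sxx` is the
#' sampling variance of a subject's OLS slope and `tau^2` is a
#' method-of-moments estimate of the between-subject slope variance.
#' Shrinkage never moves a slope past its group mean; subjects with exact
#' (zero-residual) fits are not shrunk.
#'
#' @param fits List of `vrdot_trajectory` objects.
#' @param groups Optional named character vector mapping `subject_id` to
#'   group; when omitted all subjects form one group.
#' @return An object of class `vrdot_pooled`: `measure`, `mean_slope`, `se`,
#'   `n`, `group_means` (named vector), `tau2`, and a data.frame `subjects`
#'   with raw and shrunken slopes.
#' @export
pool_slopes <- function(fits, groups = NULL) {
  if (length(fits) == 0L) stop("no trajectory fits supplied", call. = FALSE)
  slope <- vapply(fits, function(f) f$slope, numeric(1))
  id <- vapply(fits, function(f) f$subject_id, character(1))
  v <- vapply(fits, function(f) {
    if (is.na(f$residual_sd)) NA_real_ else f$residual_sd^2 / f$sxx
  }, numeric(1))
  grp <- if (is.null(groups)) rep("all", length(slope)) else {
    as.character(groups[id])
  }
  if (anyNA(grp)) grp[is.na(grp)] <- "all"
  v[is.na(v)] <- if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
  n <- length(slope)
  mean_slope <- mean(slope)
  se <- if (n >= 2L) stats::sd(slope) / sqrt(n) else NA_real_
  group_means <- tapply(slope, grp, mean)
  tau2 <- max(stats::var(slope) - mean(v), 0)
  if (n < 2L || is.na(tau2)) tau2 <- 0
  w <- ifelse(tau2 + v <= 0, 1, tau2 / (tau2 + v))
  shrunk <- w * slope + (1 - w) * group_means[grp]
  measure <- unique(vapply(fits, function(f) f$measure, character(1)))
  structure(
    list(
      measure = if (length(measure) == 1L) measure else NA_character_,
      mean_slope = mean_slope, se = se, n = n,
      group_means = group_means, tau2 = tau2,
      subjects = data.frame(subject_id = id, group = grp, slope = slope,
                            slope_var = v, shrunken_slope = as.numeric(shrunk),
                            stringsAsFactors = FALSE)
    ),
    class = "vrdot_pooled"
  )
}

#' @export
print.vrdot_pooled <- function(x, ...) {
  cat(sprintf("<vrdot_pooled>%s mean slope %.4g/year (SE %.3g, n=%d)\n",
              if (is.na(x$measure)) "" else paste0(" [", x$measure, "]"),
              x$mean_slope, x$se, x$n))
  for (g in names(x$group_means)) {
    cat(sprintf("  %s: %.4g\n", g, x$group_means[[g]]))
  }
  invisible(x)
}

#' Baseline and annual-slope features for every measure
#'
#' Builds the predictor table for the screening and conversion analyses:
#' for each subject and each requested measure, the year-1 (baseline) value
#' and the annual slope over available visits. Subjects with a single visit
#' keep their baseline and get a missing slope. Scored session measures
#' (`fi`, `reff`) and derived psychomotor metrics are computed on the fly;
#' every other measure name must be a column of the cohort's visits table.
#'
#' @param cohort A `vrdot_cohort`.
#' @param measures Character vector of measure names. Defaults to the
#'   session scores, the scale columns, and the derived psychomotor
#'   metrics.
#' @param params Penalty weights used when scoring `fi`/`reff`.
#' @param knee_heel Passed to [psychomotor_features()].
#' @param shrink If `TRUE`, also report slopes shrunk toward their group
#'   mean (see [pool_slopes()]); raw per-subject OLS slopes are always the
#'   `slope` column.
#' @return A long data.frame: `subject_id`, `group`, `measure`, `baseline`,
#'   `slope` (and `shrunken_slope` when `shrink = TRUE`).
#' @export
rate_of_change_features <- function(cohort, measures = NULL,
                                    params = score_params(),
                                    knee_heel = "apply", shrink = FALSE) {
  stopifnot(inherits(cohort, "vrdot_cohort"))
  psy <- psychomotor_features(cohort, knee_heel = knee_heel)
  values <- merge(cohort$visits[c("subject_id", "visit_year", scale_cols)],
                  psy, by = c("subject_id", "visit_year"), all.x = TRUE)
  if (nrow(cohort$sessions)) {
    values <- merge(values, score_cohort(cohort, params),
                    by = c("subject_id", "visit_year"), all.x = TRUE)
  } else {
    values$reff <- NA_real_
    values$fi <- NA_real_
  }
  if (is.null(measures)) {
    measures <- c("fi", "reff", scale_cols,
                  "gait_speed_ms", "stride_m", "tap_rate_dom",
                  "tap_rate_nondom", "grip_kg")
  }
  missing_m <- setdiff(measures, names(values))
  if (length(missing_m)) {
    stop(sprintf("unknown measure(s): %s", paste(missing_m, collapse = ", ")),
         call. = FALSE)
  }
  s <- cohort$subjects
  grp <- stats::setNames(s$group, s$subject_id)
  out <- list()
  for (m in measures) {
    fits <- list()
    rows <- list()
    for (sid in s$subject_id) {
      sub <- values[values$subject_id == sid & !is.na(values[[m]]), ,
                    drop = FALSE]
      base <- sub[[m]][sub$visit_year == 1L]
      baseline <- if (length(base)) base[1] else NA_real_
      slope <- NA_real_
      if (nrow(sub) >= 2L && length(unique(sub$visit_year)) >= 2L) {
        fit <- fit_subject_trajectory(sub$visit_year, sub[[m]],
                                      subject_id = sid, measure = m)
        slope <- fit$slope
        fits[[length(fits) + 1L]] <- fit
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = grp[[sid]], measure = m,
        baseline = baseline, slope = slope, stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    if (shrink) {
      tab$shrunken_slope <- NA_real_
      if (length(fits) >= 2L) {
        pooled <- pool_slopes(fits, groups = grp)
        j <- match(pooled$subjects$subject_id, tab$subject_id)
        tab$shrunken_slope[j] <- pooled$subjects$shrunken_slope
      }
    }
    out[[m]] <- tab
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Widen a feature table for regression
#'
#' @param features Long table from [rate_of_change_features()].
#' @param what Which statistic(s) to spread into columns.
#' @return A wide data.frame keyed by `subject_id` and `group`, with columns
#'   `<measure>_baseline` and/or `<measure>_slope`.
#' @export
features_matrix <- function(features, what = c("baseline", "slope")) {
  what <- match.arg(what, several.ok = TRUE)
  ids <- unique(features[c("subject_id", "group")])
  out <- ids
  for (m in unique(features$measure)) {
    sub <- features[features$measure == m, , drop = FALSE]
    j <- match(out$subject_id, sub$subject_id)
    for (w in what) {
      out[[paste0(m, "_", w)]] <- sub[[w]][j]
    }
  }
  rownames(out) <- NULL
  out
}
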