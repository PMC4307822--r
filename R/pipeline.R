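#' Pipeline configuration
#'
#' One object drives the full analysis: data source (a cohort file or the
#' simulator), the weight-set source (explicit parameters or calibration on
#' a generated pilot), the ROC group pairs, the conversion outcome, and the
#' seed recorded in every output.
#'
#' @param input `"simulate"`, or a path to a cohort JSON/CSV bundle.
#' @param input_format `"json"` or `"csv"` when `input` is a path.
#' @param sim_config Simulation configuration used when
#'   `input = "simulate"`.
#' @param params Either a `vrdot_params`, or `"calibrate"` to fit the
#'   weights on a generated pilot first.
#' @param calib_config Calibration settings used when
#'   `params = "calibrate"`.
#' @param roc_measures Named character vector mapping measure name to score
#'   direction (`"higher"`/`"lower"` = which side indicates the *more
#'   impaired* group).
#' @param group_pairs List of `c(reference, positive)` group pairs for the
#'   ROC battery; the positive label is the more impaired group.
#' @param outcome Subjects column holding the conversion outcome.
#' @param force_in Covariate feature names exempt from stepwise removal.
#' @param knee_heel Knee-heel normalisation mode (see
#'   [psychomotor_features()]).
#' @param seed Integer seed for simulation, calibration and bootstrap.
#' @param n_boot Bootstrap replicates for AUC confidence intervals.
#' @return A list of class `vrdot_pipeline_config`.
#' @export
pipeline_config <- function(input = "simulate",
                            input_format = "json",
                            sim_config = default_config(),
                            params = score_params(),
                            calib_config = calibration_config(),
                            roc_measures = c(mmse = "lower",
                                             bristol_adl = "higher",
                                             blessed_adl = "higher",
                                             ravlt_delayed = "lower",
                                             fi = "lower"),
                            group_pairs = list(c("control", "aMCI"),
                                               c("aMCI", "mildAD")),
                            outcome = "converted_to_ad",
                            force_in = character(),
                            knee_heel = "apply",
                            seed = 1L,
                            n_boot = 500L) {
  structure(
    list(input = input, input_format = input_format, sim_config = sim_config,
         params = params, calib_config = calib_config,
         roc_measures = roc_measures, group_pairs = group_pairs,
         outcome = outcome, force_in = force_in, knee_heel = knee_heel,
         seed = as.integer(seed), n_boot = as.integer(n_boot)),
    class = "vrdot_pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain the cohort (simulate or load), resolve the
#' penalty weights (given or calibrated on a generated pilot), score all
#' sessions, derive psychomotor metrics, compute baseline + annual-slope
#' features, run the correlation matrix (partial Spearman controlling for
#' age, sex and education), the ROC battery with bootstrap CIs and Youden
#' cutoffs per group pair and measure, and the conversion models (one
#' univariate logistic per candidate slope predictor, ranked by odds-ratio
#' magnitude, plus a backward-stepwise joint model). Any stage failure
#' aborts with the stage name. With a fixed seed the report is fully
#' deterministic.
#'
#' @param config A [pipeline_config()].
#' @param out_dir If non-`NULL`, artifacts are written there: `scores.csv`,
#'   `features.csv`, `params.json`, `roc_<pair>.json`, `fit.json`,
#'   `report.json`.
#' @return An object of class `vrdot_report` (a list; see details in the
#'   vignette).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "vrdot_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("input", {
    if (identical(config$input, "simulate")) {
      generate_cohort(config$sim_config, seed = config$seed)
    } else {
      load_cohort(config$input, config$input_format)
    }
  })

  params <- stage("params", {
    if (identical(config$params, "calibrate")) {
      pilot <- make_pilot(seed = config$seed)
      calibrate(pilot, config$calib_config)$final
    } else if (inherits(config$params, "vrdot_params")) {
      config$params
    } else {
      do.call(score_params, as.list(config$params))
    }
  })

  scores <- stage("score", score_cohort(cohort, params))
  features <- stage("features", {
    rate_of_change_features(cohort, params = params,
                            knee_heel = config$knee_heel)
  })

  correlations <- stage("correlations", {
    base <- merge(scores[scores$visit_year == 1L,
                         c("subject_id", "fi")],
                  cohort$visits[cohort$visits$visit_year == 1L,
                                c("subject_id", "mmse", "bristol_adl")],
                  by = "subject_id")
    base <- merge(base, cohort$subjects[, c("subject_id", "age", "sex",
                                            "education")],
                  by = "subject_id")
    covs <- cbind(age = base$age, sex = as.numeric(base$sex == "M"),
                  education = base$education)
    pairs <- list(c("fi", "mmse"), c("fi", "bristol_adl"),
                  c("mmse", "bristol_adl"))
    do.call(rbind, lapply(pairs, function(p) {
      r <- partial_spearman(base[[p[1]]], base[[p[2]]], covs)
      data.frame(test1 = p[1], test2 = p[2], rho = r$rho,
                 p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
    }))
  })

  baseline_measures <- stage("roc-data", {
    f <- features[features$measure %in% names(config$roc_measures), ,
                  drop = FALSE]
    stats::reshape(f[c("subject_id", "group", "measure", "baseline")],
                   direction = "wide", idvar = c("subject_id", "group"),
                   timevar = "measure", v.names = "baseline")
  })
  names(baseline_measures) <- sub("^baseline\\.", "", names(baseline_measures))

  roc_results <- stage("roc", {
    out <- list()
    for (pair in config$group_pairs) {
      ref <- pair[1]
      pos <- pair[2]
      sub <- baseline_measures[baseline_measures$group %in% pair, ,
                               drop = FALSE]
      for (m in names(config$roc_measures)) {
        roc <- roc_curve(sub[[m]], sub$group, positive = pos,
                         direction = config$roc_measures[[m]])
        roc <- auc_ci(roc, n_boot = config$n_boot, seed = config$seed)
        cut <- optimal_cutoff(roc)
        out[[paste(m, ref, pos, sep = ".")]] <- list(
          measure = m, reference = ref, positive = pos, roc = roc,
          cutoff = cut
        )
      }
    }
    out
  })

  auc_table <- do.call(rbind, lapply(roc_results, function(r) {
    data.frame(
      measure = r$measure, pair = paste(r$reference, r$positive, sep = " vs "),
      auc = r$roc$auc, ci_low = r$roc$ci_low, ci_high = r$roc$ci_high,
      cutoff = r$cutoff$cutoff, sensitivity = r$cutoff$sensitivity,
      specificity = r$cutoff$specificity, stringsAsFactors = FALSE
    )
  }))
  rownames(auc_table) <- NULL

  conversion <- stage("prediction", {
    if (!config$outcome %in% names(cohort$subjects)) {
      stop(sprintf("outcome column '%s' not found in subjects",
                   config$outcome))
    }
    wide <- features_matrix(features, what = "slope")
    amci <- merge(wide[wide$group == "aMCI", , drop = FALSE],
                  cohort$subjects[, c("subject_id", config$outcome, "age",
                                      "sex", "education")],
                  by = "subject_id")
    y <- amci[[config$outcome]]
    keep <- !is.na(y)
    amci <- amci[keep, , drop = FALSE]
    y <- as.numeric(y[keep])
    if (length(unique(y)) < 2L) {
      stop("conversion outcome has a single class; cannot model conversion")
    }
    predictors <- c(reff = "reff_slope", bristol_adl = "bristol_adl_slope",
                    blessed_adl = "blessed_adl_slope")
    uni <- lapply(predictors, function(col) {
      # slopes standardized so odds ratios are per 1 SD of annual change
      z <- scale(amci[[col]])[, 1]
      fit_logistic(matrix(z, ncol = 1,
                          dimnames = list(NULL, col)), y)
    })
    or_mag <- vapply(uni, function(f) abs(log(f$odds_ratios$odds_ratio[2])),
                     numeric(1))
    ranking <- data.frame(
      predictor = unname(predictors),
      odds_ratio = vapply(uni, function(f) f$odds_ratios$odds_ratio[2],
                          numeric(1)),
      or_low = vapply(uni, function(f) f$odds_ratios$or_low[2], numeric(1)),
      or_high = vapply(uni, function(f) f$odds_ratios$or_high[2], numeric(1)),
      p_value = vapply(uni, function(f) f$odds_ratios$p_value[2], numeric(1)),
      nagelkerke_r2 = vapply(uni, function(f) f$nagelkerke_r2, numeric(1)),
      pct_correct = vapply(uni, function(f) f$pct_correct, numeric(1)),
      stringsAsFactors = FALSE
    )
    ranking <- ranking[order(-or_mag), ]
    rownames(ranking) <- NULL
    x_all <- as.matrix(
      data.frame(lapply(amci[unname(predictors)],
                        function(v) scale(v)[, 1]),
                 check.names = FALSE)
    )
    colnames(x_all) <- unname(predictors)
    if (length(config$force_in)) {
      extra <- amci[intersect(config$force_in,
                              c("age", "education"))]
      if ("sex" %in% config$force_in) extra$sex <- as.numeric(amci$sex == "M")
      x_all <- cbind(x_all, as.matrix(extra))
    }
    step <- backward_stepwise(x_all, y, p_keep = 0.10,
                              force_in = config$force_in)
    list(univariate = uni, ranking = ranking, stepwise = step)
  })

  group_fi <- stage("summary", {
    base <- merge(scores[scores$visit_year == 1L, ],
                  cohort$subjects[, c("subject_id", "group")],
                  by = "subject_id")
    agg <- stats::aggregate(base[c("fi", "reff")], by = list(group = base$group),
                            FUN = mean)
    agg[match(cohort_groups, agg$group), ]
  })

  report <- structure(
    list(
      seed = config$seed,
      params = params,
      group_fi = group_fi,
      correlations = correlations,
      auc_table = auc_table,
      roc = roc_results,
      conversion = conversion,
      scores = scores,
      features = features,
      config = config
    ),
    class = "vrdot_report"
  )

  if (!is.null(out_dir)) {
    stage("write", write_report(report, out_dir))
  }
  report
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(unclass(report$params)),
                       file.path(out_dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  for (nm in names(report$roc)) {
    r <- report$roc[[nm]]
    jsonlite::write_json(
      list(measure = r$measure, reference = r$reference,
           positive = r$positive, thresholds = r$roc$thresholds,
           sens = r$roc$sens, spec = r$roc$spec, auc = r$roc$auc,
           ci_low = r$roc$ci_low, ci_high = r$roc$ci_high,
           cutoff = r$cutoff$cutoff, sensitivity = r$cutoff$sensitivity,
           specificity = r$cutoff$specificity),
      file.path(out_dir, paste0("roc_", nm, ".json")), auto_unbox = TRUE,
      digits = NA, na = "null"
    )
  }
  jsonlite::write_json(
    list(ranking = report$conversion$ranking,
         stepwise_retained = report$conversion$stepwise$retained),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    na = "null"
  )
  jsonlite::write_json(
    list(seed = report$seed,
         params = as.list(unclass(report$params)),
         group_fi = report$group_fi,
         correlations = report$correlations,
         auc_table = report$auc_table,
         conversion_ranking = report$conversion$ranking),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null"
  )
  invisible(out_dir)
}

#' @export
print.vrdot_report <- function(x, ...) {
  cat("<vrdot_report> seed", x$seed, "\n\nGroup mean baseline scores:\n")
  print(x$group_fi, digits = 3, row.names = FALSE)
  cat("\nPartial Spearman correlations (age, sex, education controlled):\n")
  print(x$correlations, digits = 2, row.names = FALSE)
  cat("\nAUC table:\n")
  print(x$auc_table, digits = 3, row.names = FALSE)
  cat("\nConversion predictors (aMCI), ranked by |log OR|:\n")
  print(x$conversion$ranking, digits = 3, row.names = FALSE)
  invisible(x)
}
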