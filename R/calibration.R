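#' Calibration configuration
#'
#' The penalty weights (k1..k4) are calibrated on a pilot sample in two
#' steps: every candidate weight set on a grid is scored, candidates whose
#' functional index is strongly and positively Spearman-correlated with
#' MMSE *and* strongly and negatively correlated with an IADL scale are
#' accepted, and the final set is the componentwise mean of the accepted
#' candidates. "Strong" is a convention, not a universal constant, so both
#' thresholds are configuration; the defaults use |rho| >= 0.6, the usual
#' reading of a strong Spearman correlation.
#'
#' @param grid_min,grid_max,grid_step Grid bounds and step shared by all
#'   four weights (defaults 0, 1, 0.05).
#' @param rho_mmse_min Minimum Spearman rho of FI with MMSE for acceptance.
#' @param rho_iadl_max Maximum (most positive allowed) rho of FI with the
#'   IADL scale; acceptance requires `rho_iadl <= rho_iadl_max`.
#' @param iadl_scale Visits column playing the IADL score
#'   (`"bristol_adl"` by default, `"blessed_adl"` selectable).
#' @return A list of class `vrdot_calib_config`.
#' @export
calibration_config <- function(grid_min = 0, grid_max = 1, grid_step = 0.05,
                               rho_mmse_min = 0.6, rho_iadl_max = -0.6,
                               iadl_scale = c("bristol_adl", "blessed_adl")) {
  iadl_scale <- match.arg(iadl_scale)
  if (grid_min > grid_max) stop("grid_min must be <= grid_max", call. = FALSE)
  if (grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)
  if (abs(rho_mmse_min) > 1.5 || abs(rho_iadl_max) > 1.5) {
    stop("rho thresholds should be correlation-scale values", call. = FALSE)
  }
  structure(
    list(grid_min = grid_min, grid_max = grid_max, grid_step = grid_step,
         rho_mmse_min = rho_mmse_min, rho_iadl_max = rho_iadl_max,
         iadl_scale = iadl_scale),
    class = "vrdot_calib_config"
  )
}

# baseline (visit 1) efficacy ratio, error-count matrix, and target scales
# for a pilot cohort; computed once and reused across the whole grid
pilot_baseline <- function(pilot, config) {
  scored <- score_cohort(pilot)  # k irrelevant here; we keep reff + counts
  scored <- scored[scored$visit_year == 1L, , drop = FALSE]
  v <- pilot$visits[pilot$visits$visit_year == 1L, , drop = FALSE]
  m <- merge(scored, v[, c("subject_id", "mmse", config$iadl_scale)],
             by = "subject_id")
  m <- m[stats::complete.cases(m[c("reff", "mmse", config$iadl_scale)]), ,
         drop = FALSE]
  if (nrow(m) < 3L) {
    stop("calibration needs at least 3 pilot subjects with baseline MMSE, IADL and a session",
         call. = FALSE)
  }
  list(
    reff = m$reff,
    counts = as.matrix(m[c("omissions", "repetitions", "order_errors",
                           "extra_attempts")]),
    mmse = m$mmse,
    iadl = m[[config$iadl_scale]]
  )
}

#' Correlation diagnostics for one candidate weight set
#'
#' Scores the pilot's baseline sessions with `params` and returns the
#' Spearman correlations of the resulting functional index with MMSE and
#' with the configured IADL scale.
#'
#' @param params A [score_params()] candidate.
#' @param pilot A single-visit (or baseline-bearing) `vrdot_cohort`.
#' @param config A [calibration_config()].
#' @return Named numeric vector `c(rho_mmse, rho_iadl)`.
#' @export
evaluate_candidate <- function(params, pilot, config = calibration_config()) {
  if (!inherits(params, "vrdot_params")) params <- do.call(score_params,
                                                           as.list(params))
  base <- pilot_baseline(pilot, config)
  fi <- 100 * base$reff / (1 + drop(base$counts %*% as.numeric(params)))
  if (stats::sd(fi) == 0) {
    stop("correlation undefined: candidate produces a constant functional index",
         call. = FALSE)
  }
  c(rho_mmse = spearman_rho(fi, base$mmse)$rho,
    rho_iadl = spearman_rho(fi, base$iadl)$rho)
}

#' Calibrate the penalty weights on a pilot sample
#'
#' Evaluates every candidate `(k1, k2, k3, k4)` on the configured grid
#' (vectorised over candidates, in chunks), accepts those meeting both
#' correlation thresholds, and returns their componentwise mean as the
#' final weight set.
#'
#' @inheritParams evaluate_candidate
#' @param verbose Print progress for large grids.
#' @return An object of class `vrdot_calibration`: `final`
#'   (a `vrdot_params`), `accepted` (data.frame of accepted candidates),
#'   `diagnostics` (all candidates with their two rhos and acceptance
#'   flag), `config`.
#' @export
calibrate <- function(pilot, config = calibration_config(), verbose = FALSE) {
  base <- pilot_baseline(pilot, config)
  ks <- seq(config$grid_min, config$grid_max, by = config$grid_step)
  grid <- as.matrix(expand.grid(k1 = ks, k2 = ks, k3 = ks, k4 = ks,
                                KEEP.OUT.ATTRS = FALSE))
  n_cand <- nrow(grid)
  rank_mmse <- rank(base$mmse)
  rank_iadl <- rank(base$iadl)
  rho_mmse <- numeric(n_cand)
  rho_iadl <- numeric(n_cand)
  chunk <- 20000L
  for (from in seq(1L, n_cand, by = chunk)) {
    to <- min(from + chunk - 1L, n_cand)
    kchunk <- grid[from:to, , drop = FALSE]
    denom <- 1 + base$counts %*% t(kchunk)          # n_subj x n_chunk
    fimat <- (100 * base$reff) / denom
    fr <- apply(fimat, 2, rank)
    rho_mmse[from:to] <- suppressWarnings(drop(stats::cor(fr, rank_mmse)))
    rho_iadl[from:to] <- suppressWarnings(drop(stats::cor(fr, rank_iadl)))
    if (verbose) message(sprintf("calibration grid: %d / %d", to, n_cand))
  }
  ok <- !is.na(rho_mmse) & !is.na(rho_iadl) &
    rho_mmse >= config$rho_mmse_min & rho_iadl <= config$rho_iadl_max
  diagnostics <- data.frame(grid, rho_mmse = rho_mmse, rho_iadl = rho_iadl,
                            accepted = ok)
  if (!any(ok)) {
    fit_score <- (rho_mmse - rho_iadl) / 2
    best <- which.max(fit_score)
    stop(sprintf(
      paste0("calibration failed: no candidate met rho_mmse >= %.3g and ",
             "rho_iadl <= %.3g; best candidate k=(%.3g, %.3g, %.3g, %.3g) ",
             "had rho_mmse=%.3f, rho_iadl=%.3f"),
      config$rho_mmse_min, config$rho_iadl_max,
      grid[best, 1], grid[best, 2], grid[best, 3], grid[best, 4],
      rho_mmse[best], rho_iadl[best]), call. = FALSE)
  }
  accepted <- diagnostics[ok, , drop = FALSE]
  final <- do.call(score_params, as.list(colMeans(accepted[, 1:4])))
  structure(
    list(final = final, accepted = accepted, diagnostics = diagnostics,
         config = config),
    class = "vrdot_calibration"
  )
}

#' @export
print.vrdot_calibration <- function(x, ...) {
  cat(sprintf("<vrdot_calibration> %d of %d candidates accepted\n",
              nrow(x$accepted), nrow(x$diagnostics)))
  cat("  final: ")
  print(x$final)
  invisible(x)
}
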