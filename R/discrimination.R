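#' Spearman rank correlation
#'
#' Product-moment correlation of mid-ranks (ties receive average ranks),
#' with a two-sided p-value from the t approximation on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values are
#'   dropped; at least 3 complete pairs are required.
#' @return An object of class `vrdot_cor`: `rho`, `p_value`, `n`,
#'   `covariates` (empty for the plain coefficient).
#' @export
spearman_rho <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: input vector is constant", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  structure(
    list(rho = rho, p_value = rho_p_value(rho, n, 0L), n = n,
         covariates = character()),
    class = "vrdot_cor"
  )
}

rho_p_value <- function(rho, n, n_cov) {
  df <- n - 2L - n_cov
  if (df < 1L) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and every covariate, regresses the ranked `x`
#' and `y` on the ranked covariates by OLS, and correlates the residuals.
#' This is the rank analogue of a partial correlation and is what a
#' "controlling for age, gender and education" correlation matrix uses.
#'
#' @inheritParams spearman_rho
#' @param covariates Numeric matrix or data.frame of adjustment variables.
#' @return A `vrdot_cor` with the covariate names recorded.
#' @export
partial_spearman <- function(x, y, covariates) {
  covariates <- as.matrix(covariates)
  keep <- stats::complete.cases(x, y, covariates)
  x <- x[keep]
  y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(covariates)
  if (n <= k + 2L) {
    stop("need n > number of covariates + 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: input vector is constant", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rc <- apply(covariates, 2, rank)
  design <- cbind(1, rc)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    # drop redundant (constant/collinear after ranking) covariate columns
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    if (ncol(design) < 1L) {
      stop("degenerate design: covariates are collinear", call. = FALSE)
    }
  }
  res_x <- stats::lm.fit(design, rx)$residuals
  res_y <- stats::lm.fit(design, ry)$residuals
  # a variable fully explained by the covariates has nothing left to
  # correlate: the partial coefficient is 0, not numerical noise
  tol <- 1e-8 * stats::sd(rx)
  rho <- if (stats::sd(res_x) < tol || stats::sd(res_y) < tol) 0 else
    stats::cor(res_x, res_y)
  structure(
    list(rho = rho, p_value = rho_p_value(rho, n, k), n = n,
         covariates = colnames(covariates) %||% paste0("c", seq_len(k))),
    class = "vrdot_cor"
  )
}

#' @export
print.vrdot_cor <- function(x, ...) {
  adj <- if (length(x$covariates)) {
    sprintf(" | %s", paste(x$covariates, collapse = ", "))
  } else ""
  cat(sprintf("<vrdot_cor> rho=%.3f (p=%.3g, n=%d)%s\n", x$rho, x$p_value,
              x$n, adj))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Empirical ROC over every distinct score value. `direction` states, per
#' measure, whether high or low scores indicate the positive class (it is
#' never inferred from the data). With `direction = "higher"`, a case is
#' called positive when `score >= threshold`; with `"lower"`, when
#' `score <= threshold`. The AUC is the Mann--Whitney probability that a
#' random positive outscores a random negative, with ties credited 1/2.
#'
#' @param scores Numeric scores.
#' @param labels Class labels (any type); `positive` selects the positive
#'   class.
#' @param positive The label treated as positive (defaults to the larger of
#'   two sorted unique labels' second element, so pass it explicitly).
#' @param direction `"higher"` or `"lower"`: which score direction indicates
#'   the positive class.
#' @return An object of class `vrdot_roc`: `thresholds` (sorted distinct
#'   score values), `sens`, `spec`, `auc`, `ci_low`/`ci_high` (`NA` until
#'   [auc_ci()] fills them), `positive_label`, `direction`, plus the input
#'   `scores` and logical `is_pos` for resampling.
#' @export
roc_curve <- function(scores, labels, positive,
                      direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (missing(positive)) positive <- sort(unique(labels))[length(unique(labels))]
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  oriented <- if (direction == "lower") -scores else scores
  thr_or <- sort(unique(oriented))
  sens <- vapply(thr_or, function(t) mean(oriented[is_pos] >= t), numeric(1))
  spec <- vapply(thr_or, function(t) mean(oriented[!is_pos] < t), numeric(1))
  r <- rank(oriented)  # mid-ranks give the tie-corrected Mann-Whitney AUC
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- if (direction == "lower") -thr_or else thr_or
  structure(
    list(thresholds = thresholds, sens = sens, spec = spec, auc = auc,
         ci_low = NA_real_, ci_high = NA_real_,
         positive_label = positive, direction = direction,
         scores = scores, is_pos = is_pos),
    class = "vrdot_roc"
  )
}

#' @export
print.vrdot_roc <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (95%% CI %.3f-%.3f)",
                                             x$ci_low, x$ci_high)
  cat(sprintf("<vrdot_roc> AUC=%.3f%s, positive='%s' (%s scores), %d thresholds\n",
              x$auc, ci, x$positive_label, x$direction, length(x$thresholds)))
  invisible(x)
}

#' Bootstrap confidence interval for an AUC
#'
#' Percentile interval from a stratified bootstrap: positives and negatives
#' are resampled within class, preserving class sizes, and the AUC is
#' recomputed on each replicate. Reproducible under a fixed `seed`.
#'
#' @param roc A `vrdot_roc` (carries its scores and labels).
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return The `vrdot_roc` with `ci_low`/`ci_high` filled in.
#' @export
auc_ci <- function(roc, n_boot = 2000L, seed = 1L, conf = 0.95) {
  stopifnot(inherits(roc, "vrdot_roc"))
  pos <- roc$scores[roc$is_pos]
  neg <- roc$scores[!roc$is_pos]
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("each class needs at least 2 members for a bootstrap CI",
         call. = FALSE)
  }
  sgn <- if (roc$direction == "lower") -1 else 1
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      p <- sample(pos, replace = TRUE)
      n <- sample(neg, replace = TRUE)
      pair_auc(sgn * p, sgn * n)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  q <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  roc$ci_low <- q[1]
  roc$ci_high <- q[2]
  roc
}

# Mann-Whitney AUC from oriented positive/negative scores via mid-ranks
pair_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(neg))
}

#' Youden-optimal cutoff
#'
#' Scans every ROC threshold for the maximum of Youden's
#' `J = sensitivity + specificity - 1`; ties are broken toward the higher
#' specificity (and then the more conservative threshold). The reported
#' cutoff is placed midway between the selected threshold and the adjacent
#' distinct score on its negative side, and the four operating
#' characteristics are recomputed from the sample at that cutoff.
#'
#' @param roc A `vrdot_roc`.
#' @param criterion Cutoff criterion; only `"youden"` is implemented.
#' @return A `vrdot_cutoff` report (see [confusion_metrics()]) with the
#'   achieved `youden_j` attached.
#' @export
optimal_cutoff <- function(roc, criterion = "youden") {
  criterion <- match.arg(criterion, "youden")
  j <- roc$sens + roc$spec - 1
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) {
    best <- best[order(roc$spec[best],
                       if (roc$direction == "higher") roc$thresholds[best]
                       else -roc$thresholds[best])]
    best <- best[length(best)]
  }
  thr <- roc$thresholds[best]
  # midpoint toward the adjacent distinct value on the negative side
  sorted <- sort(unique(roc$scores))
  i <- match(thr, sorted)
  cutoff <- if (roc$direction == "higher") {
    if (i > 1L) (sorted[i - 1L] + thr) / 2 else thr
  } else {
    if (i < length(sorted)) (sorted[i + 1L] + thr) / 2 else thr
  }
  labels <- ifelse(roc$is_pos, "positive", "negative")
  rep <- confusion_metrics(roc$scores, labels, cutoff, positive = "positive",
                           direction = roc$direction)
  rep$youden_j <- j[best]
  rep
}

#' Confusion-matrix metrics at a cutoff
#'
#' Sensitivity, specificity, positive and negative predictive values from
#' the 2x2 table at a given cutoff. With `direction = "higher"` a score
#' `>= cutoff` is called positive; with `"lower"`, `<= cutoff`. An empty
#' predicted-positive (or -negative) margin yields an `NA` predictive value
#' rather than an error.
#'
#' @inheritParams roc_curve
#' @param cutoff Decision threshold in score units.
#' @return An object of class `vrdot_cutoff`: `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `n_pos`, `n_neg`.
#' @export
confusion_metrics <- function(scores, labels, cutoff, positive,
                              direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  called <- if (direction == "higher") scores >= cutoff else scores <= cutoff
  tp <- sum(called & is_pos)
  fn <- sum(!called & is_pos)
  fp <- sum(called & !is_pos)
  tn <- sum(!called & !is_pos)
  structure(
    list(
      cutoff = cutoff,
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      ppv = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
      npv = if (tn + fn == 0L) NA_real_ else tn / (tn + fn),
      n_pos = sum(is_pos), n_neg = sum(!is_pos)
    ),
    class = "vrdot_cutoff"
  )
}

#' @export
print.vrdot_cutoff <- function(x, ...) {
  cat(sprintf("<vrdot_cutoff> cutoff=%.4g: sens=%.3f spec=%.3f ppv=%s npv=%s\n",
              x$cutoff, x$sensitivity, x$specificity,
              formatC(x$ppv, digits = 3, format = "f"),
              formatC(x$npv, digits = 3, format = "f")))
  invisible(x)
}
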