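#' Logistic regression for conversion modelling
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]), with Wald standard errors, odds ratios with
#' 95% confidence intervals (`exp(b +/- 1.96 SE)`), log-likelihoods of the
#' fitted and null models, Nagelkerke pseudo-R2, and in-sample
#' classification accuracy at probability 0.5.
#'
#' Perfect or quasi-perfect separation does not error: the fit is returned
#' with `separation = TRUE` so callers can switch to the Firth
#' bias-reduction penalty (`firth = TRUE`), which keeps estimates finite
#' under separation.
#'
#' @param x Predictor matrix or data.frame (no intercept column; one is
#'   added). Column names become coefficient names.
#' @param y Binary outcome: logical, or 0/1 numeric; both classes must be
#'   present.
#' @param firth If `TRUE`, fit by Firth-penalised likelihood instead of
#'   plain maximum likelihood.
#' @return An object of class `vrdot_logit` with elements `coefficients`,
#'   `se`, `odds_ratios` (data.frame with CI), `log_likelihood`,
#'   `null_log_likelihood`, `nagelkerke_r2`, `pct_correct`, `n`,
#'   `separation`, `firth`, `fitted`, and the model matrix `x`.
#' @export
fit_logistic <- function(x, y, firth = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  keep <- stats::complete.cases(x, y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L) {
    stop("y must be binary with both classes present", call. = FALSE)
  }
  if (n <= ncol(x) + 1L) {
    stop("need n > number of predictors + 1", call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, x)
  if (qr(design)$rank < ncol(design)) {
    stop("degenerate design: predictor matrix is rank deficient",
         call. = FALSE)
  }
  if (firth) {
    fit <- firth_logistic(design, y)
    beta <- fit$beta
    se <- fit$se
    p <- fit$p
    ll <- sum(y * log(p) + (1 - y) * log(1 - p))
    converged <- fit$converged
  } else {
    gfit <- suppressWarnings(
      stats::glm.fit(design, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100))
    )
    beta <- gfit$coefficients
    p <- gfit$fitted.values
    w <- p * (1 - p)
    info <- crossprod(design * w, design)
    se <- sqrt(diag(solve(info)))
    ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
    converged <- gfit$converged
  }
  names(se) <- names(beta)
  separation <- !firth &&
    (any(abs(beta[-1]) > 15) || all(abs(y - p) < 1e-6) || !converged)
  pbar <- mean(y)
  ll0 <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  or <- data.frame(
    term = names(beta),
    estimate = beta,
    se = se,
    odds_ratio = exp(beta),
    or_low = exp(beta - 1.96 * se),
    or_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- structure(
    list(
      coefficients = beta, se = se, odds_ratios = or,
      log_likelihood = ll, null_log_likelihood = ll0,
      nagelkerke_r2 = NA_real_,
      pct_correct = 100 * mean((p >= 0.5) == (y == 1)),
      n = n, separation = separation, firth = firth,
      fitted = p, x = x, y = y
    ),
    class = "vrdot_logit"
  )
  out$nagelkerke_r2 <- nagelkerke_r2(out)
  out
}

# Firth bias-reduced logistic regression: Newton iterations on the
# penalised score U*(b) = X'(y - p + h (1/2 - p)), h the hat diagonals
firth_logistic <- function(design, y, max_iter = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(design))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(design %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(design * w, design)
    inv <- solve(info)
    h <- rowSums((design %*% inv) * design) * w
    score <- crossprod(design, y - p + h * (0.5 - p))
    step <- drop(inv %*% score)
    # dampen huge steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(design %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  se <- sqrt(diag(solve(crossprod(design * w, design))))
  list(beta = stats::setNames(beta, colnames(design)), se = se, p = p,
       converged = converged)
}

#' Nagelkerke pseudo-R2
#'
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`, the Cox--Snell ratio rescaled to
#' a 0--1 range, computed from the log-likelihoods stored in a fit.
#'
#' @param fit A `vrdot_logit`.
#' @return A proportion in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  if (is.null(fit$log_likelihood) || is.null(fit$null_log_likelihood)) {
    stop("fit must carry fitted and null log-likelihoods", call. = FALSE)
  }
  n <- fit$n
  cox_snell <- 1 - exp((2 / n) * (fit$null_log_likelihood -
                                    fit$log_likelihood))
  max_r2 <- 1 - exp((2 / n) * fit$null_log_likelihood)
  min(max(cox_snell / max_r2, 0), 1)
}

#' Classify with a fitted logistic model
#'
#' @param fit A `vrdot_logit`.
#' @param x New predictor matrix with the fit's columns; defaults to the
#'   training matrix.
#' @param y Outcomes to grade against; defaults to the training outcomes.
#' @param threshold Probability threshold; predicted positive when the
#'   fitted probability is `>= threshold`.
#' @return A list: `labels` (logical predictions), `prob`, `pct_correct`
#'   in 0--100 (`NA` when `y` is unavailable).
#' @export
classify <- function(fit, x = NULL, y = NULL, threshold = 0.5) {
  stopifnot(inherits(fit, "vrdot_logit"))
  if (is.null(x)) {
    prob <- fit$fitted
    if (is.null(y)) y <- fit$y
  } else {
    x <- as.matrix(x)
    design <- cbind(1, x[, names(fit$coefficients)[-1], drop = FALSE])
    prob <- stats::plogis(drop(design %*% fit$coefficients))
  }
  labels <- prob >= threshold
  pct <- if (is.null(y)) NA_real_ else 100 * mean(labels == (y == 1))
  list(labels = labels, prob = prob, pct_correct = pct)
}

#' Backward stepwise elimination by Wald p-value
#'
#' Starting from the full model, repeatedly removes the predictor with the
#' largest Wald p-value at or above `p_keep`, refitting after each removal,
#' until every remaining free predictor has `p < p_keep`. Predictors named
#' in `force_in` (covariates such as age and sex) are exempt from removal.
#' Ties on the maximum p-value are broken toward the later column, so the
#' procedure is deterministic for a given column order.
#'
#' @inheritParams fit_logistic
#' @param p_keep Retention threshold on the Wald p-value (default 0.10).
#' @param force_in Character vector of predictor names never removed.
#' @return A list: `retained` (character vector), `fit` (the final
#'   `vrdot_logit`), `dropped` (in removal order).
#' @export
backward_stepwise <- function(x, y, p_keep = 0.10, force_in = character(),
                              firth = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  current <- colnames(x)
  dropped <- character()
  repeat {
    fit <- fit_logistic(x[, current, drop = FALSE], y, firth = firth)
    free <- setdiff(current, force_in)
    if (!length(free)) break
    pv <- fit$odds_ratios$p_value[match(free, fit$odds_ratios$term)]
    worst <- max(pv)
    if (worst < p_keep) break
    cand <- free[pv >= worst - 1e-15]
    drop_name <- cand[length(cand)]  # later column wins ties
    current <- setdiff(current, drop_name)
    dropped <- c(dropped, drop_name)
    if (!length(current)) {
      fit <- intercept_only_fit(y)
      break
    }
  }
  list(retained = current, fit = fit, dropped = dropped)
}

# closed-form intercept-only logistic fit: fitted probability equals the
# sample prevalence
intercept_only_fit <- function(y) {
  y <- as.numeric(y)
  y <- y[!is.na(y)]
  n <- length(y)
  pbar <- mean(y)
  beta <- stats::setNames(stats::qlogis(pbar), "(Intercept)")
  se <- stats::setNames(sqrt(1 / (n * pbar * (1 - pbar))), "(Intercept)")
  ll <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  out <- structure(
    list(
      coefficients = beta, se = se,
      odds_ratios = data.frame(
        term = "(Intercept)", estimate = beta, se = se,
        odds_ratio = exp(beta), or_low = exp(beta - 1.96 * se),
        or_high = exp(beta + 1.96 * se),
        p_value = 2 * stats::pnorm(-abs(beta / se)),
        row.names = NULL, stringsAsFactors = FALSE
      ),
      log_likelihood = ll, null_log_likelihood = ll,
      nagelkerke_r2 = 0, pct_correct = 100 * mean((pbar >= 0.5) == (y == 1)),
      n = n, separation = FALSE, firth = FALSE,
      fitted = rep(pbar, n), x = NULL, y = y
    ),
    class = "vrdot_logit"
  )
  out
}

#' @export
print.vrdot_logit <- function(x, ...) {
  cat(sprintf("<vrdot_logit> n=%d, logLik=%.2f, Nagelkerke R2=%.3f, %.0f%% correctly classified%s%s\n",
              x$n, x$log_likelihood, x$nagelkerke_r2, x$pct_correct,
              if (x$firth) " [Firth]" else "",
              if (x$separation) " [separation flagged]" else ""))
  print(x$odds_ratios, digits = 3)
  invisible(x)
}
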