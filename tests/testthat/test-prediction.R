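test_that("single binary predictor: OR equals the 2x2 cross-product ratio", {
  # table: exposed (10 events, 5 non), unexposed (4 events, 20 non)
  x <- matrix(c(rep(1, 15), rep(0, 24)), ncol = 1,
              dimnames = list(NULL, "exposed"))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 4), rep(0, 20))
  fit <- fit_logistic(x, y)
  expect_equal(fit$odds_ratios$odds_ratio[2], (10 * 20) / (5 * 4),
               tolerance = 1e-6)
  # glm oracle
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("intercept-only behaviour: prevalence fit, zero Nagelkerke", {
  y <- c(rep(1, 3), rep(0, 7))
  fit <- intercept_only <- vrdot:::intercept_only_fit(y)
  expect_equal(unique(fit$fitted), 0.3)
  expect_equal(fit$nagelkerke_r2, 0)
  expect_equal(fit$pct_correct, 70)
})

test_that("Nagelkerke R2 matches a direct likelihood computation and is scale-invariant", {
  set.seed(13)
  n <- 200
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "z"))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x[, 1]))
  fit <- fit_logistic(x, y)
  # independent likelihood evaluation at the fitted coefficients
  p <- plogis(fit$coefficients[1] + fit$coefficients[2] * x[, 1])
  ll1 <- sum(dbinom(y, 1, p, log = TRUE))
  pbar <- mean(y)
  ll0 <- sum(dbinom(y, 1, pbar, log = TRUE))
  expected <- (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
  expect_equal(fit$nagelkerke_r2, expected, tolerance = 1e-8)

  rescaled <- fit_logistic(x * 100, y)
  expect_equal(rescaled$nagelkerke_r2, fit$nagelkerke_r2, tolerance = 1e-6)
})

test_that("coefficient recovery at n = 500", {
  set.seed(13)
  n <- 500
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "z"))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x[, 1]))
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$coefficients[1] - (-1)), 2 * fit$se[1])
  expect_lt(abs(fit$coefficients[2] - 0.8), 2 * fit$se[2])
})

test_that("deviance never increases when a predictor is added", {
  set.seed(23)
  for (i in 1:10) {
    n <- 80
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.5 * x1))
    f1 <- fit_logistic(cbind(a = x1), y)
    f2 <- fit_logistic(cbind(a = x1, b = x2), y)
    expect_gte(f2$log_likelihood, f1$log_likelihood - 1e-6)
  }
})

test_that("classification thresholds behave at the extremes", {
  set.seed(33)
  x <- cbind(z = rnorm(60))
  y <- rbinom(60, 1, plogis(2 * x[, 1]))
  fit <- fit_logistic(x, y)
  all_neg <- classify(fit, threshold = 1.0000001)
  expect_false(any(all_neg$labels))
  expect_equal(classify(fit)$pct_correct, fit$pct_correct)
})

test_that("perfect separation is flagged, and the Firth penalty tames it", {
  x <- cbind(z = c(1:5, 11:15))
  y <- c(rep(0, 5), rep(1, 5))
  plain <- fit_logistic(x, y)
  expect_true(plain$separation)
  firth <- fit_logistic(x, y, firth = TRUE)
  expect_false(firth$separation)
  expect_true(is.finite(firth$coefficients[2]))
  expect_lt(abs(firth$coefficients[2]), 15)
  expect_equal(classify(firth)$pct_correct, 100)
})

test_that("backward stepwise retains signal, drops noise, and respects force_in", {
  set.seed(17)
  n <- 400
  strong <- rnorm(n)
  noise <- matrix(rnorm(n * 3), ncol = 3,
                  dimnames = list(NULL, paste0("noise", 1:3)))
  y <- rbinom(n, 1, plogis(1.5 * strong))
  x <- cbind(strong = strong, noise)
  step <- backward_stepwise(x, y, p_keep = 0.10)
  expect_true("strong" %in% step$retained)

  # across replicates, noise predictors are almost always eliminated
  removed <- replicate(30, {
    s2 <- rnorm(n)
    y2 <- rbinom(n, 1, plogis(1.5 * s2))
    x2 <- cbind(strong = s2, matrix(rnorm(n * 3), ncol = 3,
                                    dimnames = list(NULL,
                                                    paste0("noise", 1:3))))
    st <- backward_stepwise(x2, y2)
    !any(grepl("noise", st$retained))
  })
  expect_gt(mean(removed), 0.6)

  forced <- backward_stepwise(x, y, force_in = "noise1")
  expect_true("noise1" %in% forced$retained)

  # a lone strong predictor is retained unchanged
  solo <- backward_stepwise(cbind(strong = strong), y)
  expect_identical(solo$retained, "strong")

  # all-noise model collapses toward the intercept
  set.seed(18)
  yn <- rbinom(200, 1, 0.4)
  xn <- matrix(rnorm(200 * 3), ncol = 3,
               dimnames = list(NULL, paste0("n", 1:3)))
  stn <- backward_stepwise(xn, yn)
  expect_lte(length(stn$retained), 1L)
})

test_that("degenerate designs and bad outcomes error clearly", {
  x <- cbind(a = 1:10, b = 2 * (1:10))
  y <- rep(c(0, 1), 5)
  expect_error(fit_logistic(x, y), "rank deficient")
  expect_error(fit_logistic(cbind(a = 1:10), rep(1, 10)), "both classes")
  expect_error(fit_logistic(cbind(a = 1:3, b = c(1, 5, 2)), c(0, 1, 0)), "n >")
})
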