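test_that("spearman_rho handles monotone, tied and hand-computed cases", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(1:3, c(30, 20, 10))$rho, -1)
  # ranks of y = (1,1,2,3) are (1.5,1.5,3,4): rho = 4.5/sqrt(22.5)
  r <- spearman_rho(1:4, c(1, 1, 2, 3))
  expect_equal(r$rho, 4.5 / sqrt(22.5), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("spearman_rho agrees with cor.test on random data", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(25)
    y <- x + rnorm(25, 0, 2)
    ours <- spearman_rho(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("partial_spearman removes covariate-driven association", {
  set.seed(3)
  # zero-variance covariate: equals the plain coefficient
  x <- rnorm(30)
  y <- x + rnorm(30)
  z0 <- rep(1, 30)
  expect_equal(partial_spearman(x, y, cbind(z = z0))$rho,
               spearman_rho(x, y)$rho, tolerance = 1e-10)

  # y an exact monotone function of the covariate: partial rho ~ 0
  z <- rnorm(100)
  y2 <- 2 * z + 1
  x2 <- rnorm(100)
  expect_equal(partial_spearman(x2, y2, cbind(z = z))$rho, 0)

  # an independent covariate barely changes the coefficient
  n <- 200
  x3 <- rnorm(n)
  y3 <- x3 + rnorm(n)
  w <- rnorm(n)
  plain <- spearman_rho(x3, y3)$rho
  partial <- partial_spearman(x3, y3, cbind(w = w))$rho
  expect_lt(abs(plain - partial), 0.1)
})

test_that("AUC equals the exhaustive pairwise probability", {
  roc <- roc_curve(c(3, 5, 1, 4), c("p", "p", "n", "n"), positive = "p")
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$auc, oracle_auc(c(3, 5), c(1, 4)))

  sep <- roc_curve(c(10, 11, 1, 2), c("p", "p", "n", "n"), positive = "p")
  expect_equal(sep$auc, 1)

  set.seed(15)
  for (i in 1:100) {
    n1 <- sample(3:15, 1)
    n0 <- sample(3:15, 1)
    pos <- sample(1:10, n1, replace = TRUE)  # ties across classes likely
    neg <- sample(1:10, n0, replace = TRUE)
    roc <- roc_curve(c(pos, neg), rep(c("p", "n"), c(n1, n0)),
                     positive = "p")
    expect_equal(roc$auc, oracle_auc(pos, neg))
  }
})

test_that("AUC agrees with pROC and respects direction antisymmetry", {
  skip_if_not_installed("pROC")
  set.seed(25)
  for (i in 1:10) {
    scores <- rnorm(40)
    labels <- rep(c("a", "b"), each = 20)
    ours <- roc_curve(scores, labels, positive = "b")$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                levels = c("a", "b"),
                                                direction = "<")))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
    flipped <- roc_curve(-scores, labels, positive = "b")$auc
    expect_equal(ours + flipped, 1)
    low <- roc_curve(scores, labels, positive = "b",
                     direction = "lower")$auc
    expect_equal(low, flipped)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(35)
  scores <- rnorm(50)
  labels <- sample(c("x", "y"), 50, replace = TRUE, prob = c(0.4, 0.6))
  base <- roc_curve(scores, labels, positive = "y")$auc
  expect_equal(roc_curve(exp(scores), labels, positive = "y")$auc, base)
  expect_equal(roc_curve(qlogis(plogis(scores)), labels,
                         positive = "y")$auc, base)
})

test_that("bootstrap CI is seeded, covers the AUC, and pins separations", {
  set.seed(45)
  scores <- c(rnorm(30, 1.5), rnorm(30))
  labels <- rep(c("p", "n"), each = 30)
  roc <- roc_curve(scores, labels, positive = "p")
  a <- auc_ci(roc, n_boot = 200, seed = 5)
  b <- auc_ci(roc, n_boot = 200, seed = 5)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  expect_lte(a$ci_low, roc$auc)
  expect_gte(a$ci_high, roc$auc)

  sep <- roc_curve(c(rnorm(20, 10), rnorm(20)), rep(c("p", "n"), each = 20),
                   positive = "p")
  sep <- auc_ci(sep, n_boot = 100, seed = 1)
  expect_equal(c(sep$ci_low, sep$ci_high), c(1, 1))

  # equal distributions: the CI covers 0.5
  eq <- roc_curve(rnorm(100), rep(c("p", "n"), 50), positive = "p")
  eq <- auc_ci(eq, n_boot = 400, seed = 5)
  expect_lte(eq$ci_low, 0.5)
  expect_gte(eq$ci_high, 0.5)
})

test_that("Youden cutoff maximizes J with ties broken toward specificity", {
  roc <- roc_curve(c(3, 5, 1, 4), c("p", "p", "n", "n"), positive = "p")
  cut <- optimal_cutoff(roc)
  expect_equal(cut$cutoff, 4.5)
  expect_equal(cut$sensitivity, 0.5)
  expect_equal(cut$specificity, 1.0)
  expect_equal(cut$youden_j, 0.5)

  sep <- roc_curve(c(10, 11, 1, 2), c("p", "p", "n", "n"), positive = "p")
  expect_equal(optimal_cutoff(sep)$youden_j, 1)

  flat <- roc_curve(rep(4, 6), rep(c("p", "n"), 3), positive = "p")
  expect_equal(optimal_cutoff(flat)$youden_j, 0)

  # no other threshold beats the selected J (exhaustive scan)
  set.seed(55)
  scores <- sample(1:8, 30, replace = TRUE)
  labels <- sample(c("p", "n"), 30, replace = TRUE)
  roc <- roc_curve(scores, labels, positive = "p")
  best <- optimal_cutoff(roc)$youden_j
  expect_equal(best, max(roc$sens + roc$spec - 1))
})

test_that("confusion metrics reproduce the 2x2 table quartet", {
  # TP=10 FN=0 FP=2 TN=8
  scores <- c(rep(1, 10), rep(1, 2), rep(0, 8))
  labels <- c(rep("p", 10), rep("n", 10))
  cm <- confusion_metrics(scores, labels, cutoff = 0.5, positive = "p")
  expect_equal(cm$sensitivity, 1.0)
  expect_equal(cm$specificity, 0.8)
  expect_equal(cm$ppv, 10 / 12)
  expect_equal(cm$npv, 1.0)

  lo <- confusion_metrics(c(1, 2, 3, 4), c("p", "p", "n", "n"),
                          cutoff = 0, positive = "p")
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  hi <- confusion_metrics(c(1, 2, 3, 4), c("p", "p", "n", "n"),
                          cutoff = 99, positive = "p")
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
  expect_true(is.na(hi$ppv))
})
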