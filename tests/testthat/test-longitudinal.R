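test_that("per-subject OLS matches exact lines and the lm oracle", {
  f <- fit_subject_trajectory(c(1, 2, 3), c(10, 12, 14))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 8)

  flat <- fit_subject_trajectory(c(1, 3), c(5, 5))
  expect_equal(flat$slope, 0)

  # non-collinear points: frozen against lm(c(1,4,5) ~ c(1,2,3))
  f3 <- fit_subject_trajectory(c(1, 2, 3), c(1, 4, 5))
  expect_equal(f3$slope, 2)
  expect_equal(f3$intercept, -2 / 3)
  ora <- unname(coef(lm(y ~ x, data.frame(x = c(1, 2, 3), y = c(1, 4, 5)))))
  expect_equal(c(f3$intercept, f3$slope), ora)

  expect_error(fit_subject_trajectory(1, 10), "at least 2")
  expect_error(fit_subject_trajectory(c(2, 2), c(1, 3)), "degenerate")
})

test_that("slope estimation is affine-equivariant", {
  set.seed(21)
  for (i in 1:20) {
    x <- 1:3
    y <- rnorm(3)
    f <- fit_subject_trajectory(x, y)
    shifted <- fit_subject_trajectory(x, y + 7)
    expect_equal(shifted$slope, f$slope)
    expect_equal(shifted$intercept, f$intercept + 7)
    scaled <- fit_subject_trajectory(x, 3 * y)
    expect_equal(scaled$slope, 3 * f$slope)
  }
})

test_that("pooling averages slopes and shrinkage stays inside the group mean", {
  mk <- function(sid, slope, noise = 0) {
    fit_subject_trajectory(1:3, slope * (1:3) + c(-noise, noise, -noise),
                           subject_id = sid)
  }
  same <- pool_slopes(list(mk("a", 2), mk("b", 2), mk("c", 2)))
  expect_equal(same$mean_slope, 2)
  expect_equal(same$subjects$shrunken_slope, rep(2, 3))

  two <- pool_slopes(list(mk("a", 1), mk("b", 3)))
  expect_equal(two$mean_slope, 2)

  set.seed(31)
  fits <- lapply(1:30, function(i) {
    fit_subject_trajectory(1:3, rnorm(1, 0, 1) * (1:3) + rnorm(3, 0, 0.8),
                           subject_id = paste0("s", i))
  })
  pooled <- pool_slopes(fits)
  raw <- pooled$subjects$slope
  shrunk <- pooled$subjects$shrunken_slope
  gm <- pooled$group_means[["all"]]
  # shrunken slope lies between the raw slope and the group mean
  expect_true(all(shrunk >= pmin(raw, gm) - 1e-12 &
                    shrunk <= pmax(raw, gm) + 1e-12))
  expect_gt(pooled$se, 0)
  expect_error(pool_slopes(list()), "no trajectory")
})

test_that("pooled mean slope recovers the generating rate of change", {
  set.seed(11)
  n <- 60
  true_mean <- -0.8
  est <- replicate(50, {
    slopes <- rnorm(n, true_mean, 0.3)
    intercepts <- rnorm(n, 20, 2)
    fits <- lapply(seq_len(n), function(i) {
      y <- intercepts[i] + slopes[i] * (0:2) + rnorm(3, 0, 0.5)
      fit_subject_trajectory(1:3, y, subject_id = paste0("s", i))
    })
    pool_slopes(fits)$mean_slope
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - true_mean), 3 * mc_se + 0.01)
})

test_that("rate_of_change_features emits baseline + slope with dropout handling", {
  co <- tiny_cohort()
  # force one dropout: subject keeps only visit 1
  sid <- co$subjects$subject_id[1]
  co$visits <- co$visits[!(co$visits$subject_id == sid &
                             co$visits$visit_year > 1), ]
  co$sessions <- co$sessions[!(co$sessions$subject_id == sid &
                                 co$sessions$visit_year > 1), ]
  co$events <- co$events[!(co$events$subject_id == sid &
                             co$events$visit_year > 1), ]
  feats <- rate_of_change_features(co, measures = c("reff", "mmse"))
  expect_setequal(unique(feats$measure), c("reff", "mmse"))
  expect_identical(nrow(feats), nrow(co$subjects) * 2L)

  drop_row <- feats[feats$subject_id == sid & feats$measure == "reff", ]
  expect_false(is.na(drop_row$baseline))
  expect_true(is.na(drop_row$slope))

  # slope equals the exact line through the per-visit values
  other <- co$subjects$subject_id[2]
  sc <- score_cohort(co)
  sub <- sc[sc$subject_id == other, ]
  expected <- fit_subject_trajectory(sub$visit_year, sub$reff)$slope
  expect_equal(feats$slope[feats$subject_id == other &
                             feats$measure == "reff"], expected)

  wide <- features_matrix(feats)
  expect_true(all(c("reff_baseline", "reff_slope", "mmse_baseline",
                    "mmse_slope") %in% names(wide)))
  expect_identical(nrow(wide), nrow(co$subjects))
})
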