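test_that("default configuration carries the anchored group structure", {
  cfg <- default_config()
  expect_equal(vapply(cfg$groups, function(g) g$n, integer(1)),
               c(control = 72L, aMCI = 65L, mildAD = 68L))
  expect_equal(unname(cfg$groups$control$scales$mmse[c("mean", "sd")]),
               c(29.1, 1.0))
  expect_equal(unname(cfg$groups$mildAD$scales$bristol_adl[c("mean", "sd")]),
               c(10.59, 0.9))
  expect_equal(cfg$dropout, 0.116)
  # error rates ordered control < aMCI < mildAD, every error type
  lam <- sapply(cfg$groups, function(g) g$error_lambda)
  expect_true(all(lam[, "control"] < lam[, "aMCI"]))
  expect_true(all(lam[, "aMCI"] < lam[, "mildAD"]))
})

test_that("generated cohorts have the published sizes and are seed-deterministic", {
  co <- generate_cohort(seed = 1)
  expect_identical(nrow(co$subjects), 232L)
  expect_identical(sum(!co$subjects$dropout), 205L)
  expect_equal(
    as.vector(table(factor(co$subjects$group[!co$subjects$dropout],
                           levels = c("control", "aMCI", "mildAD")))),
    c(72L, 65L, 68L))
  # dropouts contribute baseline only
  drops <- co$subjects$subject_id[co$subjects$dropout]
  expect_true(all(co$visits$visit_year[co$visits$subject_id %in% drops] == 1L))

  co2 <- generate_cohort(seed = 1)
  expect_equal(co$subjects, co2$subjects)
  expect_equal(co$events, co2$events)
  co3 <- generate_cohort(seed = 2)
  expect_false(identical(co$events, co3$events))
})

test_that("generated sessions score back to their drawn error counts", {
  p <- default_protocol()
  set.seed(77)
  for (i in 1:300) {
    counts <- c(sample(0:3, 1), sample(0:4, 1), sample(0:3, 1),
                sample(0:5, 1))
    s <- generate_session(p, counts[1], counts[2], counts[3], counts[4],
                          reff = runif(1, 0.1, 0.9),
                          total_duration_s = runif(1, 120, 600))
    m <- length(p$activities) - counts[1]
    expected_w <- if (m >= 2) min(counts[3], m %/% 2) else 0
    got <- as.integer(count_errors(s, p))
    expect_identical(got, c(counts[1], if (m >= 1) counts[2] else 0L,
                            as.integer(expected_w),
                            if (m >= 1) counts[4] else 0L))
  }
})

test_that("generated sessions hit their target efficacy ratio", {
  p <- default_protocol()
  set.seed(78)
  for (i in 1:50) {
    r <- runif(1, 0.1, 0.9)
    s <- generate_session(p, 1, 1, 1, 2, reff = r,
                          total_duration_s = runif(1, 200, 500))
    expect_equal(efficacy_ratio(s, p), r, tolerance = 1e-3)
  }
})

test_that("sample moments match the configured anchors", {
  co <- generate_cohort(seed = 1)
  base <- merge(co$visits[co$visits$visit_year == 1, ],
                co$subjects[, c("subject_id", "group")], by = "subject_id")
  ctrl <- base[base$group == "control", ]
  # truncation at 30 pulls the control MMSE mean slightly below 29.1;
  # integer rounding adds at most half a point of further slack
  expect_lt(abs(mean(ctrl$mmse) - 29.1), 4 * 1.0 / sqrt(nrow(ctrl)) + 0.35)
  ad <- base[base$group == "mildAD", ]
  expect_lt(abs(mean(ad$bristol_adl) - 10.59), 4 * 0.9 / sqrt(nrow(ad)) + 0.1)
  expect_lt(abs(mean(ad$mmse) - 23.4), 4 * 2.0 / sqrt(nrow(ad)) + 0.55)
})

test_that("control sessions are more efficient than mild AD sessions", {
  co <- generate_cohort(seed = 1)
  sc <- merge(score_cohort(co), co$subjects[, c("subject_id", "group")],
              by = "subject_id")
  base <- sc[sc$visit_year == 1, ]
  expect_gt(mean(base$reff[base$group == "control"]),
            mean(base$reff[base$group == "mildAD"]))
})

test_that("pilot cohorts have the pilot sizes, one visit, and the intended correlation structure", {
  pi <- make_pilot(seed = 3)
  expect_equal(
    as.vector(table(factor(pi$subjects$group,
                           levels = c("control", "aMCI", "mildAD")))),
    c(25L, 26L, 24L))
  expect_true(all(pi$visits$visit_year == 1L))
  expect_lt(abs(mean(pi$subjects$age[pi$subjects$group == "control"]) - 73.7),
            4 * 4.0 / sqrt(25))
  expect_equal(make_pilot(seed = 3)$events, pi$events)

  # conversion labels drawn for completer aMCI subjects only
  co <- generate_cohort(seed = 1)
  amci <- co$subjects[co$subjects$group == "aMCI" & !co$subjects$dropout, ]
  expect_true(all(!is.na(amci$converted_to_ad)))
  expect_true(all(is.na(co$subjects$converted_to_ad[co$subjects$group ==
                                                      "control"])))
  expect_gt(mean(amci$converted_to_ad), 0.05)
  expect_lt(mean(amci$converted_to_ad), 0.8)
})
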