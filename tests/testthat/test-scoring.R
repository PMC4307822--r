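make_session <- function(ids, attempts = NULL, completed = NULL,
                         total = 100) {
  n <- length(ids)
  if (is.null(attempts)) attempts <- rep(1L, n)
  if (is.null(completed)) completed <- rep(TRUE, n)
  start <- seq(0, by = 10, length.out = n)
  session_log("s", 1, activity_events(ids, start, start + 8, attempts,
                                      completed), total)
}

test_that("count_errors reproduces the hand-enumerated example", {
  p <- protocol_spec(c("A", "B", "C", "D", "E"))
  # completions in order A(1), C(2 attempts), B(1), C again(1), D(1); E never
  s <- make_session(c("A", "C", "B", "C", "D"),
                    attempts = c(1L, 2L, 1L, 1L, 1L))
  counts <- count_errors(s, p)
  # first-completion protocol indices [1,3,2,4]: LIS 3 by enumeration
  expect_identical(oracle_lis(c(1L, 3L, 2L, 4L)), 3L)
  expect_identical(as.integer(counts),
                   c(1L, 1L, 1L, 1L))
})

test_that("count_errors identity and degenerate cases", {
  p <- protocol_spec(c("A", "B", "C", "D", "E"))
  perfect <- make_session(c("A", "B", "C", "D", "E"))
  expect_identical(as.integer(count_errors(perfect, p)), rep(0L, 4))

  empty <- session_log("s", 1, activity_events(character(0), numeric(0),
                                               numeric(0), integer(0),
                                               logical(0)), 50)
  expect_identical(as.integer(count_errors(empty, p)),
                   c(5L, 0L, 0L, 0L))
})

test_that("count_errors matches the brute-force oracle on random sessions", {
  set.seed(101)
  p <- default_protocol()
  for (i in 1:200) {
    s <- random_session(p)
    expect_identical(as.integer(count_errors(s, p)),
                     as.integer(oracle_count_errors(s, p)))
  }
})

test_that("order errors vanish exactly when first completions are in protocol order", {
  set.seed(202)
  p <- protocol_spec(LETTERS[1:6])
  for (i in 1:200) {
    s <- random_session(p, max_events = 10L)
    counts <- count_errors(s, p)
    fc <- s$events[s$events$completed, , drop = FALSE]
    fc <- fc[order(fc$end_s, fc$start_s), , drop = FALSE]
    fc <- fc[!duplicated(fc$activity_id), , drop = FALSE]
    idx <- match(fc$activity_id, p$activities)
    in_order <- all(diff(idx) > 0)
    expect_identical(counts[["order_errors"]] == 0L, in_order)
  }
})

test_that("error counts are invariant to event reordering that keeps completion times", {
  set.seed(303)
  p <- default_protocol()
  for (i in 1:50) {
    s <- random_session(p)
    counts <- count_errors(s, p)
    perm <- s
    perm$events <- perm$events[sample(nrow(perm$events)), , drop = FALSE]
    rownames(perm$events) <- NULL
    expect_identical(as.integer(count_errors(perm, p)), as.integer(counts))
  }
})

test_that("efficacy ratio is activity time over total time with overlap union", {
  p <- protocol_spec(c("a", "b"))
  s <- session_log("s", 1, activity_events(c("a", "b"), c(0, 200),
                                           c(100, 250)), 300)
  expect_equal(efficacy_ratio(s, p), 0.5)

  none <- session_log("s", 1, activity_events(character(0), numeric(0),
                                              numeric(0), integer(0),
                                              logical(0)), 300)
  expect_equal(efficacy_ratio(none, p), 0)

  tiled <- session_log("s", 1, activity_events(c("a", "b"), c(0, 150),
                                               c(150, 300)), 300)
  expect_equal(efficacy_ratio(tiled, p), 1)

  # overlapping same-activity intervals are unioned, not double counted
  over <- session_log("s", 1, activity_events(c("a", "a"), c(0, 50),
                                              c(100, 150)), 300)
  expect_equal(efficacy_ratio(over, p), 0.5)
})

test_that("functional index follows the rational penalty form", {
  p <- protocol_spec(c("A", "B", "C", "D", "E"))
  # counts (1,1,1,1) with k=(0.1,0.1,0.2,0.05): FI = 100*reff/1.45
  s <- make_session(c("A", "C", "B", "C", "D"),
                    attempts = c(1L, 2L, 1L, 1L, 1L), total = 80)
  k <- score_params(0.1, 0.1, 0.2, 0.05)
  sc <- functional_index(s, p, k)
  expect_equal(sc$reff, 0.5)  # 5 events x 8 s of an 80 s session
  expect_equal(sc$fi, 34.48276, tolerance = 1e-4)

  # zero weights: penalty vanishes
  sc0 <- functional_index(s, p, score_params(0, 0, 0, 0))
  expect_equal(sc0$fi, 100 * sc0$reff)

  # zero errors: FI = 100 * reff for any k
  perfect <- make_session(c("A", "B", "C", "D", "E"))
  scp <- functional_index(perfect, p, score_params(0.9, 0.9, 0.9, 0.9))
  expect_equal(scp$fi, 100 * scp$reff)
})

test_that("FI is monotone: non-increasing in each error count, increasing in REff", {
  k <- score_params(0.3, 0.2, 0.4, 0.1)
  fi <- function(reff, x) 100 * reff / (1 + sum(as.numeric(k) * x))
  set.seed(404)
  for (i in 1:100) {
    x <- rpois(4, 2)
    reff <- runif(1)
    base <- fi(reff, x)
    for (j in 1:4) {
      bump <- x
      bump[j] <- bump[j] + 1
      expect_lte(fi(reff, bump), base)
    }
    expect_gte(fi(min(reff + 0.05, 1), x), base)
  }
})

test_that("score_cohort rows agree with single-session scoring", {
  co <- tiny_cohort()
  tab <- score_cohort(co)
  expect_identical(nrow(tab), nrow(co$sessions))
  i <- 5L
  single <- functional_index(get_session(co, tab$subject_id[i],
                                         tab$visit_year[i]),
                             co$protocol)
  expect_equal(tab$fi[i], single$fi)
  expect_equal(tab$reff[i], single$reff)
})

test_that("scoring refuses structurally invalid sessions with context", {
  p <- protocol_spec(c("a", "b"))
  s <- session_log("s9", 2, activity_events("X", 0, 5), 50)
  expect_error(count_errors(s, p), "s9")
  expect_error(count_errors(s, p), "not in the protocol")
})
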