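# Brute-force oracles, deliberately independent of the package's
# implementation paths: subsequence enumeration for the LIS, all-pairs
# comparison for the AUC, and a loop-based error recount.

# longest increasing subsequence by enumerating all 2^n subsequences
oracle_lis <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    v <- x[idx]
    if (all(diff(v) > 0)) best <- length(idx)
  }
  best
}

# independent error recount from first principles
oracle_count_errors <- function(session, protocol) {
  ev <- session$events
  acts <- protocol$activities
  done <- ev[ev$completed, , drop = FALSE]
  O <- 0L
  R <- 0L
  for (a in acts) {
    k <- sum(done$activity_id == a)
    if (k == 0L) O <- O + 1L
    if (k > 1L) R <- R + (k - 1L)
  }
  # first completion per activity, ordered by completion instant
  firsts <- list()
  for (a in acts) {
    rows <- done[done$activity_id == a, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rows[order(rows$end_s, rows$start_s), , drop = FALSE]
    firsts[[a]] <- rows[1, ]
  }
  A <- 0L
  W <- 0L
  if (length(firsts)) {
    fdf <- do.call(rbind, firsts)
    fdf <- fdf[order(fdf$end_s, fdf$start_s), , drop = FALSE]
    idx <- match(fdf$activity_id, acts)
    W <- nrow(fdf) - oracle_lis(idx)
    A <- sum(pmax(fdf$attempts - 1L, 0L))
  }
  c(omissions = O, repetitions = R, order_errors = W, extra_attempts = A)
}

# AUC as the exhaustive pairwise Mann-Whitney probability (ties = 1/2)
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# arbitrary random session over a protocol: sequential non-overlapping
# events with random ids, attempts and completion flags (independent of the
# package's session generator)
random_session <- function(protocol, max_events = 14L, p_complete = 0.85) {
  n_ev <- sample(0:max_events, 1)
  total <- stats::runif(1, 60, 400)
  if (n_ev == 0L) {
    return(session_log("rand", 1L, activity_events(character(0), numeric(0),
                                                   numeric(0), integer(0),
                                                   logical(0)), total))
  }
  ids <- sample(protocol$activities, n_ev, replace = TRUE)
  bounds <- sort(stats::runif(2 * n_ev, 0, total))
  start <- bounds[seq(1, 2 * n_ev, by = 2)]
  end <- bounds[seq(2, 2 * n_ev, by = 2)]
  ev <- activity_events(ids, start, end,
                        attempts = sample(1:4, n_ev, replace = TRUE),
                        completed = stats::runif(n_ev) < p_complete)
  session_log("rand", 1L, ev, total)
}

# tiny deterministic cohort for structural/I-O tests
tiny_cohort <- function(seed = 42L) {
  cfg <- default_config()
  for (g in names(cfg$groups)) cfg$groups[[g]]$n <- 3L
  cfg$dropout <- 0
  generate_cohort(cfg, seed = seed)
}
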