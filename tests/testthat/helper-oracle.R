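# Independent brute-force scorer: deliberately naive, loop-based, written
# directly from the variable definitions, sharing no code with the package
# implementation. Used as the oracle for scoring-equivalence tests.

oracle_score <- function(hole, t, baited, max_duration = 450) {
  n <- length(hole)
  rewarded <- logical(n)
  seen <- integer(0)
  for (i in seq_len(n)) {
    if (hole[i] %in% baited && !(hole[i] %in% seen)) rewarded[i] <- TRUE
    seen <- c(seen, hole[i])
  }
  n_baited_visits <- 0L
  for (i in seq_len(n)) if (hole[i] %in% baited)
    n_baited_visits <- n_baited_visits + 1L
  wm <- if (n_baited_visits > 0) sum(rewarded) / n_baited_visits else NA_real_
  rm <- if (n > 0) n_baited_visits / n else NA_real_
  first_rew <- NA_integer_
  for (i in seq_len(n)) if (rewarded[i]) { first_rew <- i; break }
  rrm <- if (!is.na(first_rew)) 1 / first_rew else NA_real_
  srm <- NA_real_
  if (!is.na(first_rew)) {
    nb <- 0L; nt <- 0L
    for (i in first_rew:n) {
      nt <- nt + 1L
      if (hole[i] %in% baited) nb <- nb + 1L
    }
    srm <- nb / nt
  }
  all_found <- TRUE
  for (b in unique(baited)) if (!(b %in% hole)) all_found <- FALSE
  dur <- max_duration
  if (all_found) {
    found <- integer(0)
    for (i in seq_len(n)) {
      if (hole[i] %in% baited && !(hole[i] %in% found))
        found <- c(found, hole[i])
      if (length(found) == length(unique(baited))) { dur <- min(t[i], max_duration); break }
    }
  }
  ivi <- NA_real_
  if (n >= 2) {
    gaps <- numeric(0)
    for (i in 2:n) gaps <- c(gaps, t[i] - t[i - 1])
    ivi <- mean(gaps)
  }
  list(wm = wm, rm = rm, rrm = rrm, srm = srm,
       trial_duration = dur,
       lat_first_visit = if (n > 0) t[1] else max_duration,
       lat_first_reward = if (!is.na(first_rew)) t[first_rew]
                          else max_duration,
       ivi = ivi,
       total_visits = n,
       n_locations = length(unique(hole)),
       n_rewards = sum(rewarded))
}

# Random debounced visit sequence and baited set for property tests.
random_visit_seq <- function(max_len = 25) {
  n <- sample(0:max_len, 1)
  hole <- integer(0)
  if (n > 0) {
    hole <- sample(0:15, 1)
    while (length(hole) < n) {
      nxt <- sample(0:15, 1)
      if (nxt != hole[length(hole)]) hole <- c(hole, nxt)  # debounced stream
    }
  }
  t <- if (n > 0) cumsum(runif(n, 0.5, 20)) else numeric(0)
  list(hole = hole, t = t, baited = sample(0:15, 4))
}

# Raw lift stream with deliberate same-hole repeats for debounce tests.
random_lift_stream <- function(max_len = 30) {
  n <- sample(1:max_len, 1)
  hole <- sample(0:5, n, replace = TRUE)
  t <- cumsum(runif(n, 0, 15))
  list(hole = hole, t = t)
}

# Small fast cohort for pipeline-level tests.
small_spec <- function(seed = 42, ...) {
  cohort_spec(n_pairs = 4L, n_litters = 3L, dropout = NULL, seed = seed, ...)
}

md5sum_files <- function(paths) tools::md5sum(unname(paths))
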