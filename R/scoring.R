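# Per-trial behavioral variables. A trial is an ordered sequence of debounced
# visits (hole, t) against a set of baited holes. A baited hole yields its
# reward only on the first visit. Eleven variables are scored per trial:
# four memory ratios, four duration measures and three exploration counts.

#' Which visits yielded a reward
#'
#' A visit is rewarded iff its hole is baited and has not been visited
#' earlier in the same trial.
#'
#' @param hole Integer vector of visited hole indices, in visit order.
#' @param baited Integer vector of baited hole indices.
#' @return Logical vector, one element per visit.
#' @examples
#' rewarded_flags(c(0, 0, 1), baited = 0:3) # TRUE FALSE TRUE
#' @export
rewarded_flags <- function(hole, baited) {
  hole %in% baited & !duplicated(hole)
}

#' Working memory score of a trial
#'
#' Rewarded visits divided by all visits (including revisits) to baited
#' holes; `NA` if no baited hole was visited. Revisiting baited holes is the
#' working-memory error: the animal failed to remember it already collected
#' that reward.
#'
#' @inheritParams rewarded_flags
#' @return Ratio in \[0, 1\] or `NA`.
#' @export
working_memory <- function(hole, baited) {
  nb <- sum(hole %in% baited)
  if (nb == 0L) return(NA_real_)
  sum(rewarded_flags(hole, baited)) / nb
}

#' Reference memory score of a trial
#'
#' Visits to baited holes (including revisits) divided by all visits; `NA`
#' if the trial had no visits. Visiting unbaited holes is the
#' reference-memory error: the animal failed to remember which locations
#' are ever rewarded.
#'
#' @inheritParams rewarded_flags
#' @return Ratio in \[0, 1\] or `NA`.
#' @export
reference_memory <- function(hole, baited) {
  if (length(hole) == 0L) return(NA_real_)
  sum(hole %in% baited) / length(hole)
}

#' Rotational reference memory
#'
#' 1 divided by the number of visits up to and including the first rewarded
#' visit: orientation errors made while locating the baited pattern after
#' entering the arena. `NA` when no visit was rewarded.
#'
#' @inheritParams rewarded_flags
#' @return Ratio in (0, 1\] or `NA`.
#' @export
rotational_rm <- function(hole, baited) {
  k <- which(rewarded_flags(hole, baited))
  if (length(k) == 0L) return(NA_real_)
  1 / k[1]
}

#' Spatial-pattern reference memory
#'
#' Reference memory over the visit suffix starting at the first rewarded
#' visit: errors made while completing the baited pattern once found. `NA`
#' when no visit was rewarded.
#'
#' @inheritParams rewarded_flags
#' @return Ratio in (0, 1\] or `NA`.
#' @export
spatial_pattern_rm <- function(hole, baited) {
  k <- which(rewarded_flags(hole, baited))
  if (length(k) == 0L) return(NA_real_)
  suffix <- hole[k[1]:length(hole)]
  sum(suffix %in% baited) / length(suffix)
}

#' Score one trial
#'
#' Computes the eleven per-trial behavioral variables from a debounced visit
#' sequence. Latencies take the censored maximum (`max_duration`, 450 s by
#' default) when the event never occurred; the inter-visit interval is the
#' mean gap between successive visits and is `NA` with fewer than two
#' visits.
#'
#' @param hole Integer vector of visited holes, in visit order.
#' @param t Numeric vector of visit times (seconds from arena entry).
#' @param baited Integer vector of baited hole indices (all 16 during
#'   habituation).
#' @param duration Trial duration in seconds. Defaults to the time the last
#'   reward was collected, or `max_duration` if the animal did not collect
#'   all rewards.
#' @param max_duration Censoring value in seconds (default 450).
#' @return One-row data frame with columns `wm`, `rm`, `rrm`, `srm`,
#'   `trial_duration`, `lat_first_visit`, `lat_first_reward`, `ivi`,
#'   `total_visits`, `n_locations`, `n_rewards`, `ended_by`.
#' @export
score_trial <- function(hole, t, baited, duration = NULL, max_duration = 450) {
  sc <- .score_trial_list(as.integer(hole), t, baited, duration, max_duration)
  as.data.frame(sc, stringsAsFactors = FALSE)
}

.score_trial_list <- function(hole, t, baited, duration = NULL,
                              max_duration = 450) {
  stopifnot(length(hole) == length(t))
  rewarded <- hole %in% baited & !duplicated(hole)
  n_rewards <- sum(rewarded)
  all_found <- n_rewards == length(unique(as.integer(baited)))
  if (is.null(duration)) {
    duration <- if (all_found) min(t[rewarded][n_rewards], max_duration)
                else max_duration
  }
  k <- which(rewarded)
  n_baited_visits <- sum(hole %in% baited)
  n <- length(hole)
  list(
    wm = if (n_baited_visits) n_rewards / n_baited_visits else NA_real_,
    rm = if (n) n_baited_visits / n else NA_real_,
    rrm = if (length(k)) 1 / k[1] else NA_real_,
    srm = if (length(k)) {
      suffix <- hole[k[1]:n]
      sum(suffix %in% baited) / length(suffix)
    } else NA_real_,
    trial_duration = duration,
    lat_first_visit = if (n) t[1] else max_duration,
    lat_first_reward = if (length(k)) t[k[1]] else max_duration,
    ivi = if (n >= 2L) mean(diff(t)) else NA_real_,
    total_visits = n,
    n_locations = length(unique(hole)),
    n_rewards = n_rewards,
    ended_by = if (all_found) "all_rewards_found" else "timeout"
  )
}

#' Score every trial of an event log
#'
#' Debounces each trial's visit stream and applies [score_trial()], resolving
#' each trial's baited holes through the configuration registry (all 16
#' during habituation).
#'
#' @param events Event data frame (columns `pig_id`, `phase`, `trial`,
#'   `day`, `config`, `entrance`, `hole`, `t`).
#' @param registry Configuration registry (see [default_registry()]).
#' @param debounce Apply [debounce_events()] before scoring (default TRUE;
#'   a no-op on already-debounced streams).
#' @param window Debounce window, seconds.
#' @param max_duration Censoring value, seconds.
#' @return Data frame with one row per trial: identifiers (`pig_id`,
#'   `phase`, `trial`, `day`, `config`) followed by the [score_trial()]
#'   columns.
#' @export
score_cohort <- function(events, registry = default_registry(),
                         debounce = TRUE, window = 10, max_duration = 450) {
  id_cols <- c("pig_id", "phase", "trial", "day", "config")
  if (nrow(events) == 0L) {
    out <- events[, id_cols]
    sc <- score_trial(integer(0), numeric(0), 0:3)[0, ]
    return(cbind(out, sc))
  }
  key <- interaction(events$pig_id, events$phase, events$trial, drop = TRUE)
  idx <- split(seq_len(nrow(events)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  hole_all <- as.integer(events$hole)
  t_all <- as.numeric(events$t)
  baited_cache <- new.env(parent = emptyenv())
  pieces <- lapply(idx, function(i) {
    h <- hole_all[i]; tt <- t_all[i]
    if (debounce) {
      d <- debounce_events(h, tt, window = window)
      h <- d$hole; tt <- d$t
    }
    ckey <- paste0(events$phase[i[1]], ".", events$config[i[1]])
    b <- baited_cache[[ckey]]
    if (is.null(b)) {
      b <- baited_holes(events$config[i[1]], registry,
                        phase = events$phase[i[1]])
      baited_cache[[ckey]] <- b
    }
    .score_trial_list(h, tt, b, max_duration = max_duration)
  })
  num_cols <- setdiff(names(pieces[[1]]), "ended_by")
  sc <- data.frame(lapply(setNames(num_cols, num_cols), function(f)
    vapply(pieces, function(p) as.numeric(p[[f]]), numeric(1))))
  sc$ended_by <- vapply(pieces, `[[`, character(1), "ended_by")
  out <- cbind(events[first, id_cols], sc)
  rownames(out) <- NULL
  out[order(out$pig_id, match(out$phase, PHASES), out$trial), ]
}
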