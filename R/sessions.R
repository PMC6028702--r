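# Trial-block aggregation, learning-criterion detection and transition
# frames. Blocks are means of four successive trials, the analysis unit of
# the learning curves; criterion is reached after a phase-minimum number of
# trials once daily mean reference memory stays at or above threshold for
# two consecutive training days.

SCORE_VARS <- c("wm", "rm", "rrm", "srm", "trial_duration",
                "lat_first_visit", "lat_first_reward", "ivi",
                "total_visits", "n_locations", "n_rewards")

#' Aggregate per-trial scores into trial blocks
#'
#' Groups consecutive trials (per subject and phase) into blocks of
#' `block_size` and averages each behavioral variable over the non-missing
#' trials of the block. A final group of fewer than `block_size` trials
#' forms a partial block, flagged and (by convention downstream) excluded
#' from modeling.
#'
#' @param scores Per-trial scores data frame from [score_cohort()].
#' @param block_size Trials per block (default 4).
#' @param variables Score columns to aggregate.
#' @return Long data frame: `pig_id`, `phase`, `block`, `trial_lo`,
#'   `trial_hi`, `n_trials`, `partial`, `variable`, `mean` (NA if all
#'   trials missing), `n_contributing` (non-missing trials behind the mean).
#' @export
make_blocks <- function(scores, block_size = 4L,
                        variables = intersect(SCORE_VARS, names(scores))) {
  empty <- data.frame(pig_id = character(0), phase = character(0),
                      block = integer(0), trial_lo = integer(0),
                      trial_hi = integer(0), n_trials = integer(0),
                      partial = logical(0), variable = character(0),
                      mean = numeric(0), n_contributing = integer(0))
  if (nrow(scores) == 0L) return(empty)
  ord <- order(scores$pig_id, match(scores$phase, PHASES), scores$trial)
  s <- scores[ord, ]
  pp <- paste(s$pig_id, s$phase, sep = "\r")
  within <- stats::ave(seq_along(pp), pp, FUN = seq_along)
  block <- (within - 1L) %/% block_size + 1L
  gf <- factor(paste(pp, block, sep = "\r"),
               levels = unique(paste(pp, block, sep = "\r")))
  fi <- !duplicated(gf)
  head_df <- data.frame(
    pig_id = s$pig_id[fi], phase = s$phase[fi], block = block[fi],
    trial_lo = as.integer(tapply(s$trial, gf, min)),
    trial_hi = as.integer(tapply(s$trial, gf, max)),
    n_trials = as.integer(tabulate(gf)),
    stringsAsFactors = FALSE)
  head_df$partial <- head_df$n_trials < block_size
  out <- do.call(rbind, lapply(variables, function(v) {
    x <- s[[v]]
    nc <- as.integer(tapply(!is.na(x), gf, sum))
    sm <- tapply(x, gf, function(z) sum(z, na.rm = TRUE))
    cbind(head_df,
          data.frame(variable = v,
                     mean = ifelse(nc > 0L, as.numeric(sm) / nc, NA_real_),
                     n_contributing = nc, stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out[order(out$pig_id, match(out$phase, PHASES), out$block), ]
}

#' Detect learning-criterion attainment
#'
#' A subject completes a phase at the first trial `T` such that (a) `T` is
#' at least `phase_minimum` and (b) the daily mean reference memory of the
#' two consecutive training days ending at `T`'s day are both at least
#' `threshold`. `T` is always the final trial of a training day. The
#' `sliding` alternative replaces day-aligned daily means by two adjacent
#' sliding windows of `trials_per_day` trials ending at `T`.
#'
#' @param rm Numeric vector of per-trial reference memory scores, in trial
#'   order (missing values count as below threshold).
#' @param phase_minimum Minimum number of trials before the criterion can
#'   bind (44 for acquisition, 24 for the first reversal).
#' @param threshold Criterion level (default 0.7).
#' @param trials_per_day Trials per training day (default 2).
#' @param sliding Use the sliding-window variant (default FALSE).
#' @return List with `reached` (logical) and `trials_to_criterion`
#'   (integer, NA when not reached).
#' @export
detect_criterion <- function(rm, phase_minimum, threshold = 0.7,
                             trials_per_day = 2L, sliding = FALSE) {
  n <- length(rm)
  w <- as.integer(trials_per_day)
  if (w < 1L) stop("trials_per_day must be >= 1")
  if (!sliding && n %% w != 0L)
    stop(sprintf("trial count %d is not a whole number of %d-trial days",
                 n, w))
  rm_chk <- ifelse(is.na(rm), -Inf, rm)
  candidates <- integer(0)
  if (sliding) {
    ends <- seq_len(n)[seq_len(n) >= 2L * w]
    ok <- vapply(ends, function(tt) {
      mean(rm_chk[(tt - w + 1L):tt]) >= threshold &&
        mean(rm_chk[(tt - 2L * w + 1L):(tt - w)]) >= threshold
    }, logical(1))
    candidates <- ends[ok]
  } else {
    n_days <- n %/% w
    if (n_days >= 2L) {
      daily <- vapply(seq_len(n_days), function(d)
        mean(rm_chk[((d - 1L) * w + 1L):(d * w)]), numeric(1))
      ok <- which(daily[-1L] >= threshold & daily[-n_days] >= threshold) + 1L
      candidates <- ok * w
    }
  }
  candidates <- candidates[candidates >= phase_minimum]
  if (length(candidates) == 0L)
    return(list(reached = FALSE, trials_to_criterion = NA_integer_))
  list(reached = TRUE, trials_to_criterion = as.integer(min(candidates)))
}

#' Criterion results for a whole cohort
#'
#' Applies [detect_criterion()] per subject to the acquisition and first
#' reversal phases of a scores table.
#'
#' @param scores Per-trial scores from [score_cohort()].
#' @param minima Named vector of phase minima.
#' @inheritParams detect_criterion
#' @return Data frame `pig_id`, `phase`, `reached`, `trials_to_criterion`.
#' @export
criterion_table <- function(scores, minima = c(acquisition = 44L,
                                               reversal1 = 24L),
                            threshold = 0.7, trials_per_day = 2L,
                            sliding = FALSE) {
  out <- list()
  for (ph in names(minima)) {
    sub <- scores[scores$phase == ph, ]
    for (pid in unique(sub$pig_id)) {
      sc <- sub[sub$pig_id == pid, ]
      sc <- sc[order(sc$trial), ]
      res <- detect_criterion(sc$rm, minima[[ph]], threshold = threshold,
                              trials_per_day = trials_per_day,
                              sliding = sliding)
      out[[length(out) + 1L]] <- data.frame(
        pig_id = pid, phase = ph, reached = res$reached,
        trials_to_criterion = res$trials_to_criterion,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pig_id = character(0), phase = character(0),
                      reached = logical(0), trials_to_criterion = integer(0)))
  do.call(rbind, out)
}

#' Paired last/first blocks around a reversal transition
#'
#' For each subject having complete blocks in both phases, returns the last
#' (complete) block of the pre-reversal phase and the first block of the
#' post-reversal phase, the pair the transition models compare. Subjects
#' missing either phase are excluded and listed in the `excluded`
#' attribute.
#'
#' @param blocks Long block table from [make_blocks()].
#' @param pre,post Phase names on either side of the transition.
#' @param include_partial Allow partial blocks to serve as the last/first
#'   block (default FALSE).
#' @return Long data frame `pig_id`, `role` (`last_pre`/`first_post`),
#'   `phase`, `block`, `variable`, `mean`, with attribute `excluded`.
#' @export
transition_frame <- function(blocks, pre = "acquisition", post = "reversal1",
                             include_partial = FALSE) {
  use <- blocks[blocks$phase %in% c(pre, post), ]
  if (!include_partial) use <- use[!use$partial, ]
  pigs <- unique(use$pig_id)
  excluded <- character(0)
  pieces <- list()
  for (pid in pigs) {
    a <- use[use$pig_id == pid & use$phase == pre, ]
    b <- use[use$pig_id == pid & use$phase == post, ]
    if (nrow(a) == 0L || nrow(b) == 0L) {
      excluded <- c(excluded, pid)
      next
    }
    last_pre <- a[a$block == max(a$block), ]
    first_post <- b[b$block == min(b$block), ]
    last_pre$role <- "last_pre"
    first_post$role <- "first_post"
    pieces[[length(pieces) + 1L]] <- rbind(last_pre, first_post)
  }
  cols <- c("pig_id", "role", "phase", "block", "variable", "mean")
  out <- if (length(pieces)) do.call(rbind, pieces)[, cols]
         else data.frame(pig_id = character(0), role = character(0),
                         phase = character(0), block = integer(0),
                         variable = character(0), mean = numeric(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
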