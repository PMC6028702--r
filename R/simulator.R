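# Generative model of memory-guided holeboard foraging. An agent chooses
# holes sequentially from a multinomial that mixes uniform exploration with
# a preference for baited holes of strength lambda * rm_asymptote, where
# lambda in [0,1] is the current learning level. Working-memory lapses
# re-select already-visited holes; visit times accumulate through an
# exponential gap model; a trial ends at the last reward or at 450 s.

#' Agent parameters for the foraging simulator
#'
#' @param rm_asymptote Probability mass bias toward baited holes at full
#'   learning, in \[0, 1\]. At 1 (and no lapses) the fully trained agent
#'   produces perfect trials.
#' @param rm_rate Per-trial learning rate (> 0) of the saturating learning
#'   curve `lambda(t) = 1 - exp(-rm_rate * t)`.
#' @param wm_lapse Probability of re-choosing an already-visited hole, in
#'   \[0, 1).
#' @param visit_time_mean Mean seconds between successive visits (> 0);
#'   gaps are exponential.
#' @param entry_orientation_noise Expected number of extra unbaited visits
#'   forced before the first reward (Poisson, >= 0); models disorientation
#'   after entering from a random door.
#' @param reversal_reset Fraction of the learning level retained when the
#'   reward configuration is reversed (default 0.5; trained animals drop
#'   toward, but not to, naivety).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(rm_asymptote = 0.92, rm_rate = 0.035,
                         wm_lapse = 0.1, visit_time_mean = 12,
                         entry_orientation_noise = 0,
                         reversal_reset = 0.5) {
  stopifnot(rm_asymptote >= 0, rm_asymptote <= 1, rm_rate >= 0,
            wm_lapse >= 0, wm_lapse < 1, visit_time_mean > 0,
            entry_orientation_noise >= 0,
            reversal_reset >= 0, reversal_reset <= 1)
  structure(list(rm_asymptote = rm_asymptote, rm_rate = rm_rate,
                 wm_lapse = wm_lapse, visit_time_mean = visit_time_mean,
                 entry_orientation_noise = entry_orientation_noise,
                 reversal_reset = reversal_reset),
            class = "agent_params")
}

#' Learning level after a number of trials
#'
#' Saturating exponential learning curve `1 - exp(-rm_rate * t)`.
#'
#' @param rm_rate Per-trial learning rate.
#' @param t Effective trial count (>= 0).
#' @return Learning level in \[0, 1\].
#' @export
learning_level <- function(rm_rate, t) {
  1 - exp(-rm_rate * t)
}

#' Advance an agent's learning state by one trial
#'
#' State is the effective trial count `t_eff`; the learning level is
#' `learning_level(rm_rate, t_eff)`. [reset_learning()] applies the
#' multiplicative reversal reset by solving for the effective trial count
#' that yields the reduced level.
#'
#' @param t_eff Current effective trial count.
#' @return Updated effective trial count.
#' @export
update_learning <- function(t_eff) t_eff + 1

#' @rdname update_learning
#' @param rm_rate Learning rate.
#' @param reset Retained fraction of the learning level.
#' @export
reset_learning <- function(t_eff, rm_rate, reset = 0.5) {
  if (rm_rate <= 0) return(0)
  lam <- reset * learning_level(rm_rate, t_eff)
  lam <- min(lam, 1 - 1e-12)
  -log(1 - lam) / rm_rate
}

#' Simulate one holeboard trial
#'
#' @param baited Integer vector of baited hole indices.
#' @param lambda Current learning level in \[0, 1\].
#' @param params [agent_params()] object.
#' @param bias_noise Additive perturbation of the baited-hole preference for
#'   this trial (used to induce serially correlated trial-level residuals).
#' @param max_duration Trial timeout in seconds (default 450).
#' @return List with `hole`, `t` (visit vectors), `duration` and `ended_by`
#'   (`all_rewards_found` or `timeout`).
#' @export
simulate_trial <- function(baited, lambda, params = agent_params(),
                           bias_noise = 0, max_duration = 450) {
  baited <- as.integer(baited)
  n_rew <- length(baited)
  b <- min(max(lambda * params$rm_asymptote + bias_noise, 0), 1)
  is_baited <- logical(N_HOLES)
  is_baited[baited + 1L] <- TRUE
  w_full <- (1 - b) / N_HOLES + b * is_baited / n_rew
  visited <- logical(N_HOLES)
  hole <- integer(0); tt <- numeric(0)
  found <- 0L
  t_cur <- 0
  last <- -1L
  n_orient <- if (params$entry_orientation_noise > 0)
    rpois(1L, params$entry_orientation_noise) else 0L
  repeat {
    t_cur <- t_cur + rexp(1L, rate = 1 / params$visit_time_mean)
    if (t_cur > max_duration)
      return(list(hole = hole, t = tt, duration = max_duration,
                  ended_by = "timeout"))
    unv <- which(!visited)
    # forced orientation errors: unbaited, unvisited holes visited first
    choice <- NA_integer_
    if (n_orient > 0L) {
      cand <- unv[!is_baited[unv]]
      if (length(cand)) {
        choice <- if (length(cand) == 1L) cand else
          cand[sample.int(length(cand), 1L)]
        n_orient <- n_orient - 1L
      }
    }
    if (is.na(choice)) {
      revisit_cand <- which(visited)
      revisit_cand <- revisit_cand[revisit_cand != last]
      lapse <- length(revisit_cand) > 0L &&
        (length(unv) == 0L || runif(1L) < params$wm_lapse)
      if (lapse) {
        choice <- if (length(revisit_cand) == 1L) revisit_cand else
          revisit_cand[sample.int(length(revisit_cand), 1L)]
      } else {
        w <- w_full[unv]
        choice <- if (length(unv) == 1L) unv else
          unv[sample.int(length(unv), 1L, prob = w)]
      }
    }
    h <- choice - 1L
    if (!visited[choice] && is_baited[choice]) found <- found + 1L
    visited[choice] <- TRUE
    hole <- c(hole, h); tt <- c(tt, t_cur)
    last <- choice
    if (found == n_rew)
      return(list(hole = hole, t = tt, duration = min(t_cur, max_duration),
                  ended_by = "all_rewards_found"))
  }
}

#' Cohort specification for the foraging simulator
#'
#' Defaults emulate the design of a paired birth-weight holeboard study:
#' 20 sibling pairs (one low birth weight, LBW, one normal, NBW, same sex
#' and litter) from 15 litters, two trials per day, four phases
#' (habituation 4 trials; acquisition minimum 44, cap 76; first reversal
#' minimum 24, cap 44; second reversal fixed 20), criterion 0.7 on daily
#' mean reference memory over two consecutive days, and an LBW deficit in
#' the learning parameters.
#'
#' @param n_pairs Number of LBW/NBW sibling pairs (balanced over sex).
#' @param n_litters Number of litters the pairs are drawn from.
#' @param agent Baseline [agent_params()].
#' @param group_effects Additive shifts applied to LBW subjects' parameters
#'   (list with `rm_asymptote` and `rm_rate`).
#' @param sex_effects Additive shifts applied to male subjects (same shape).
#' @param litter_sd,subject_sd Standard deviations of litter- and
#'   subject-level random effects on `rm_asymptote`.
#' @param residual_ar1 Lag-1 autocorrelation of the per-trial preference
#'   noise, in (-1, 1).
#' @param residual_sd Marginal SD of that noise.
#' @param phase_min,phase_cap Named vectors of phase minima and caps
#'   (trials) for acquisition and first reversal.
#' @param reversal2_trials Fixed length of the second reversal.
#' @param habituation_trials Habituation trials (all 16 holes baited).
#' @param trials_per_day Trials per training day.
#' @param threshold Reference-memory criterion level.
#' @param dropout Data frame (`group`, `sex`, `phase`, `trial`) of censoring
#'   events: for each row, one matching subject stops contributing trials
#'   after `trial` of `phase` (`trial = 0` removes the whole phase). The
#'   default emulates two early deaths and one subject lame before the
#'   second reversal; use `dropout = NULL` for a complete cohort.
#' @param registry Reward-configuration registry.
#' @param seed Root seed; all subject-level streams derive from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 20L, n_litters = 15L,
                        agent = agent_params(),
                        group_effects = list(rm_asymptote = -0.04,
                                             rm_rate = -0.006),
                        sex_effects = list(rm_asymptote = 0, rm_rate = 0),
                        litter_sd = 0.04, subject_sd = 0.07,
                        residual_ar1 = 0.3, residual_sd = 0.08,
                        phase_min = c(acquisition = 44L, reversal1 = 24L),
                        phase_cap = c(acquisition = 76L, reversal1 = 44L),
                        reversal2_trials = 20L, habituation_trials = 4L,
                        trials_per_day = 2L, threshold = 0.7,
                        dropout = default_dropout(),
                        registry = default_registry(), seed = 1L) {
  stopifnot(n_pairs > 0, n_litters > 0, abs(residual_ar1) < 1)
  if (n_pairs %% 2L != 0L)
    stop("n_pairs must be even to balance the two sexes")
  structure(as.list(environment()), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_dropout <- function() {
  data.frame(group = c("LBW", "NBW", "LBW"),
             sex = c("F", "M", "F"),
             phase = c("habituation", "habituation", "reversal2"),
             trial = c(2L, 2L, 0L),
             stringsAsFactors = FALSE)
}

# Balanced assignment of configuration combinations within group x sex cells.
.assign_combinations <- function(md) {
  combo <- integer(nrow(md))
  for (g in GROUPS) for (s in SEXES) {
    i <- which(md$group == g & md$sex == s)
    combo[i] <- (sample.int(length(i)) - 1L) %% 4L + 1L
  }
  combo
}

#' Simulate a full holeboard cohort
#'
#' Generates subject metadata (paired, sex- and litter-balanced, with
#' birth weights), per-subject learning parameters with litter and subject
#' random effects, then plays every subject through habituation,
#' acquisition-to-criterion, first reversal-to-criterion and a fixed-length
#' second reversal, recording every visit. Phase lengths honor the phase
#' minima and caps; non-learners train to the cap. Reproducible: the same
#' spec (including `seed`) yields identical output.
#'
#' @param spec A [cohort_spec()].
#' @return List with `metadata` (one row per subject, including the latent
#'   learning parameters in columns prefixed `sim_`), `events` (one row per
#'   visit) and `weights` (weekly body weights, kg, weaning to 5 months).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n_pairs <- spec$n_pairs
  n <- 2L * n_pairs
  pair_sex <- rep(SEXES, each = n_pairs %/% 2L)
  pair_litter <- rep(seq_len(spec$n_litters), length.out = n_pairs)
  md <- data.frame(
    pig_id = sprintf("P%02d%s", rep(seq_len(n_pairs), each = 2L),
                     rep(c("L", "N"), n_pairs)),
    litter_id = sprintf("L%02d", rep(pair_litter, each = 2L)),
    pair_id = sprintf("pair%02d", rep(seq_len(n_pairs), each = 2L)),
    group = rep(c("LBW", "NBW"), n_pairs),
    sex = rep(pair_sex, each = 2L),
    round = rep(ifelse(seq_len(n_pairs) <= ceiling(n_pairs / 2), 1L, 2L),
                each = 2L),
    stringsAsFactors = FALSE)
  bw_lbw <- pmin(rnorm(n_pairs, 810, 90), 1040)
  bw_nbw <- pmax(rnorm(n_pairs, 1450, 220), 1060)
  md$birth_weight_g <- round(ifelse(md$group == "LBW",
                                    rep(bw_lbw, each = 2L),
                                    rep(bw_nbw, each = 2L)))
  md$combination <- .assign_combinations(md)

  # censoring assignments
  md$dropout_phase <- NA_character_
  md$dropout_trial <- NA_integer_
  if (!is.null(spec$dropout) && nrow(spec$dropout)) {
    for (k in seq_len(nrow(spec$dropout))) {
      d <- spec$dropout[k, ]
      i <- which(md$group == d$group & md$sex == d$sex &
                   is.na(md$dropout_phase))
      if (!length(i)) next
      i <- i[1]
      md$dropout_phase[i] <- d$phase
      md$dropout_trial[i] <- d$trial
    }
  }

  # latent learning parameters: litter + subject random effects on the
  # asymptotic baited-hole preference, fixed shifts for group and sex
  u_litter <- setNames(rnorm(spec$n_litters, 0, spec$litter_sd),
                       sprintf("L%02d", seq_len(spec$n_litters)))
  u_subj <- rnorm(n, 0, spec$subject_sd)
  is_lbw <- md$group == "LBW"
  is_m <- md$sex == "M"
  md$sim_rm_asymptote <- pmin(pmax(
    spec$agent$rm_asymptote +
      is_lbw * spec$group_effects$rm_asymptote +
      is_m * spec$sex_effects$rm_asymptote +
      u_litter[md$litter_id] + u_subj, 0.02), 0.995)
  md$sim_rm_rate <- pmax(
    spec$agent$rm_rate +
      is_lbw * spec$group_effects$rm_rate +
      is_m * spec$sex_effects$rm_rate, 0.003)
  md$sim_seed <- sample.int(.Machine$integer.max - 1L, n)

  events <- vector("list", n)
  for (i in seq_len(n)) {
    events[[i]] <- .simulate_pig(md[i, ], spec)
  }
  events <- do.call(rbind, events)
  rownames(events) <- NULL

  weights <- .simulate_weights(md)
  list(metadata = md, events = events, weights = weights)
}

# Play one subject through all four phases.
.simulate_pig <- function(pig, spec) {
  set.seed(pig$sim_seed)
  ag <- spec$agent
  asym <- pig$sim_rm_asymptote
  rate <- pig$sim_rm_rate
  cfgs <- schedule_phases(pig$combination)
  phi <- spec$residual_ar1
  sd_e <- spec$residual_sd
  drop_phase <- pig$dropout_phase
  drop_trial <- if (is.na(pig$dropout_trial)) Inf else pig$dropout_trial
  t_eff <- 0
  e_prev <- 0
  out <- list()
  phase_seq <- c("habituation", "acquisition", "reversal1", "reversal2")
  for (ph in phase_seq) {
    if (!is.na(drop_phase)) {
      at <- match(drop_phase, phase_seq)
      if (match(ph, phase_seq) > at) break
    }
    if (ph == "habituation") {
      baited <- 0:(N_HOLES - 1L)
      cfg <- "ALL"
      n_max <- spec$habituation_trials
      n_min <- n_max
      check_crit <- FALSE
    } else {
      cfg <- cfgs[[ph]]
      baited <- baited_holes(cfg, spec$registry, phase = ph)
      if (ph == "reversal2") {
        n_max <- spec$reversal2_trials; n_min <- n_max; check_crit <- FALSE
      } else {
        n_max <- spec$phase_cap[[ph]]
        n_min <- spec$phase_min[[ph]]
        check_crit <- TRUE
      }
      if (ph %in% c("reversal1", "reversal2"))
        t_eff <- reset_learning(t_eff, rate, ag$reversal_reset)
    }
    this_cap <- if (!is.na(drop_phase) && ph == drop_phase)
      min(n_max, drop_trial) else n_max
    rms <- numeric(0)
    trial <- 0L
    pig_ag <- ag
    pig_ag$rm_asymptote <- asym
    while (trial < this_cap) {
      trial <- trial + 1L
      lam <- learning_level(rate, t_eff)
      e_prev <- phi * e_prev + rnorm(1L, 0, sd_e * sqrt(1 - phi^2))
      tr <- simulate_trial(baited, lam, pig_ag, bias_noise = e_prev)
      nv <- length(tr$hole)
      if (nv) {
        out[[length(out) + 1L]] <- list(
          phase = rep.int(ph, nv), trial = rep.int(trial, nv),
          day = rep.int((trial - 1L) %/% spec$trials_per_day + 1L, nv),
          config = rep.int(cfg, nv),
          entrance = rep.int(ENTRANCES[sample.int(4L, 1L)], nv),
          hole = tr$hole, t = round(tr$t, 3))
      }
      # habituation (all holes baited) teaches the arena, not the pattern;
      # pattern learning starts at acquisition
      if (ph != "habituation") t_eff <- update_learning(t_eff)
      if (check_crit) {
        rms <- c(rms, reference_memory(tr$hole, baited))
        if (trial >= n_min && trial %% spec$trials_per_day == 0L) {
          res <- detect_criterion(rms, n_min, threshold = spec$threshold,
                                  trials_per_day = spec$trials_per_day)
          if (res$reached && res$trials_to_criterion == trial) break
        }
      }
    }
    if (!is.na(drop_phase) && ph == drop_phase) break
  }
  if (!length(out))
    return(data.frame(pig_id = character(0), phase = character(0),
                      trial = integer(0), day = integer(0),
                      config = character(0), entrance = character(0),
                      hole = integer(0), t = numeric(0)))
  cols <- lapply(names(out[[1]]), function(f)
    unlist(lapply(out, `[[`, f), use.names = FALSE))
  names(cols) <- names(out[[1]])
  data.frame(pig_id = pig$pig_id, cols, stringsAsFactors = FALSE)
}

# Linear group-distinct weekly growth from weaning (week 4) to 5 months
# (week 21); kg. Used for growth-model parity, not a physiological model.
.simulate_weights <- function(md) {
  weeks <- 4:21
  n <- nrow(md)
  slope <- ifelse(md$group == "LBW", 3.9, 4.4) + rnorm(n, 0, 0.25)
  w0 <- md$birth_weight_g / 1000 + ifelse(md$group == "LBW", 6.0, 6.8)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(pig_id = md$pig_id[i], week = weeks,
               weight_kg = round(w0[i] + slope[i] * (weeks - 4) +
                                   rnorm(length(weeks), 0, 1.2), 2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
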