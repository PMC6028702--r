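mk_scores <- function(rm, pig = "P1", phase = "acquisition") {
  n <- length(rm)
  data.frame(pig_id = rep(pig, n), phase = rep(phase, n),
             trial = seq_len(n), day = (seq_len(n) - 1) %/% 2 + 1,
             config = rep("A", n), rm = rm, wm = rm,
             stringsAsFactors = FALSE)
}

test_that("44 trials tile into 11 complete blocks", {
  bl <- make_blocks(mk_scores(runif(44)))
  rmb <- bl[bl$variable == "rm", ]
  expect_equal(nrow(rmb), 11L)
  expect_true(all(!rmb$partial))
  expect_equal(rmb$trial_lo, seq(1, 44, by = 4))
  expect_equal(rmb$trial_hi, seq(4, 44, by = 4))
})

test_that("a trailing short group forms a flagged partial block", {
  bl <- make_blocks(mk_scores(runif(6)))
  rmb <- bl[bl$variable == "rm", ]
  expect_equal(rmb$n_trials, c(4L, 2L))
  expect_equal(rmb$partial, c(FALSE, TRUE))
})

test_that("block means skip missing trials and count contributors", {
  bl <- make_blocks(mk_scores(c(0.5, NA, 0.7, 0.8)))
  rmb <- bl[bl$variable == "rm", ]
  expect_equal(rmb$mean, mean(c(0.5, 0.7, 0.8)), tolerance = 1e-12)
  expect_equal(rmb$n_contributing, 3L)
  # an all-missing block keeps an NA mean
  bl2 <- make_blocks(mk_scores(c(NA, NA, NA, NA)))
  expect_true(is.na(bl2$mean[bl2$variable == "rm"]))
  expect_equal(bl2$n_contributing[bl2$variable == "rm"], 0L)
})

test_that("blocking preserves per-phase grand means without missingness", {
  x <- runif(44)
  bl <- make_blocks(mk_scores(x))
  rmb <- bl[bl$variable == "rm", ]
  expect_equal(mean(rep(rmb$mean, each = 4)), mean(x), tolerance = 1e-12)
})

test_that("empty score table makes an empty block table", {
  expect_equal(nrow(make_blocks(mk_scores(numeric(0)))), 0L)
})

test_that("criterion binds at the phase minimum for early learners", {
  res <- detect_criterion(rep(0.9, 60), phase_minimum = 44)
  expect_true(res$reached)
  expect_equal(res$trials_to_criterion, 44L)
})

test_that("criterion is never reached below threshold", {
  res <- detect_criterion(rep(0.69, 76), phase_minimum = 44)
  expect_false(res$reached)
  expect_true(is.na(res$trials_to_criterion))
})

test_that("criterion lands at the close of the second qualifying day", {
  rm <- c(rep(0.6, 46), rep(0.9, 30))
  res <- detect_criterion(rm, phase_minimum = 44)
  expect_equal(res$trials_to_criterion, 50L)
  # first reversal minimum: same rule, lower floor
  rm2 <- rep(0.9, 30)
  expect_equal(detect_criterion(rm2, phase_minimum = 24)$trials_to_criterion,
               24L)
})

test_that("one sub-threshold day inside the window postpones criterion", {
  rm <- c(rep(0.9, 44), 0.2, 0.2, rep(0.9, 10))
  # day 23 fails, so the first qualifying pair of days is 24-25 -> trial 50
  expect_equal(detect_criterion(rm, phase_minimum = 46)$trials_to_criterion,
               50L)
})

test_that("raising any RM value never delays criterion (monotone)", {
  set.seed(9)
  for (i in 1:50) {
    rm <- runif(60, 0.3, 0.95)
    base <- detect_criterion(rm, phase_minimum = 44)
    j <- sample(60, 1)
    rm2 <- rm
    rm2[j] <- min(1, rm[j] + runif(1, 0, 0.5))
    up <- detect_criterion(rm2, phase_minimum = 44)
    if (base$reached) {
      expect_true(up$reached)
      expect_lte(up$trials_to_criterion, base$trials_to_criterion)
    }
  }
})

test_that("criterion validates whole training days", {
  expect_error(detect_criterion(rep(0.9, 45), phase_minimum = 44),
               "whole number")
})

test_that("sliding-window variant can fire off the day grid", {
  rm <- c(0.2, rep(0.9, 29))
  aligned <- detect_criterion(rm, phase_minimum = 4)
  slid <- detect_criterion(rm, phase_minimum = 4, sliding = TRUE)
  expect_equal(aligned$trials_to_criterion, 6L)  # days 2-3
  expect_equal(slid$trials_to_criterion, 5L)     # trials 2-5
})

test_that("transition frame pairs last complete pre with first post block", {
  sc <- rbind(mk_scores(runif(44)), mk_scores(runif(24), phase = "reversal1"))
  bl <- make_blocks(sc)
  tf <- transition_frame(bl)
  rmrows <- tf[tf$variable == "rm", ]
  expect_equal(rmrows$role, c("last_pre", "first_post"))
  expect_equal(rmrows$block, c(11L, 1L))
})

test_that("subjects missing a phase drop out of that transition only", {
  sc <- rbind(mk_scores(runif(44), pig = "P1"),
              mk_scores(runif(24), pig = "P1", phase = "reversal1"),
              mk_scores(runif(20), pig = "P1", phase = "reversal2"),
              mk_scores(runif(44), pig = "P2"),
              mk_scores(runif(24), pig = "P2", phase = "reversal1"))
  bl <- make_blocks(sc)
  t1 <- transition_frame(bl, "acquisition", "reversal1")
  t2 <- transition_frame(bl, "reversal1", "reversal2")
  expect_setequal(unique(t1$pig_id), c("P1", "P2"))
  expect_equal(unique(t2$pig_id), "P1")
  expect_equal(attr(t2, "excluded"), "P2")
  expect_equal(nrow(transition_frame(bl[0, ])), 0L)
})

test_that("criterion table spans phases and respects the minima", {
  sim <- simulate_cohort(small_spec(seed = 8))
  sc <- score_cohort(sim$events)
  cr <- criterion_table(sc)
  acq <- cr[cr$phase == "acquisition" & cr$reached, ]
  rev <- cr[cr$phase == "reversal1" & cr$reached, ]
  expect_true(all(acq$trials_to_criterion >= 44 &
                    acq$trials_to_criterion <= 76))
  expect_true(all(rev$trials_to_criterion >= 24 &
                    rev$trials_to_criterion <= 44))
})
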