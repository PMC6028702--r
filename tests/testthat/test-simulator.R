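test_that("fully trained lapse-free agent produces the perfect trial", {
  set.seed(11)
  baited <- default_registry()$A
  for (i in 1:20) {
    tr <- simulate_trial(baited, lambda = 1,
                         agent_params(rm_asymptote = 1, wm_lapse = 0))
    expect_equal(length(tr$hole), 4L)
    expect_setequal(tr$hole, baited)
    sc <- score_trial(tr$hole, tr$t, baited)
    expect_equal(c(sc$wm, sc$rm, sc$rrm, sc$srm), rep(1, 4))
  }
})

test_that("untrained non-revisiting agent needs ~13.6 visits for 4 rewards", {
  set.seed(12)
  baited <- sample(0:15, 4)
  ag <- agent_params(wm_lapse = 0, visit_time_mean = 0.01)
  n <- vapply(1:2000, function(i)
    length(simulate_trial(baited, lambda = 0, ag)$hole), numeric(1))
  # permutation oracle: E position of last of 4 marked in 16 = 4(16+1)/5
  e <- 4 * 17 / 5
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - e), 3 * se)
})

test_that("slow visitors time out at the maximum duration", {
  set.seed(13)
  tr <- simulate_trial(0:3, lambda = 1,
                       agent_params(visit_time_mean = 1e6))
  expect_equal(tr$ended_by, "timeout")
  expect_equal(tr$duration, 450)
  expect_equal(length(tr$hole), 0L)
})

test_that("learning curve saturates, is flat at rate 0, monotone otherwise", {
  expect_equal(learning_level(1e9, 1), 1)
  expect_equal(learning_level(0, 100), 0)
  lam <- learning_level(0.05, 0:80)
  expect_true(all(diff(lam) > 0))
  # reversal reset retains the configured fraction of the level
  t_eff <- 40
  lam0 <- learning_level(0.05, t_eff)
  t2 <- reset_learning(t_eff, 0.05, reset = 0.25)
  expect_equal(learning_level(0.05, t2), 0.25 * lam0, tolerance = 1e-10)
})

test_that("cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(small_spec(seed = 21))
  b <- simulate_cohort(small_spec(seed = 21))
  expect_identical(a, b)
  c <- simulate_cohort(small_spec(seed = 22))
  expect_false(identical(a$events, c$events))
})

test_that("cohort design is balanced and configurations rotated fairly", {
  sim <- simulate_cohort(cohort_spec(n_pairs = 20L, dropout = NULL, seed = 23))
  md <- sim$metadata
  expect_equal(nrow(md), 40L)
  expect_equal(sum(md$group == "LBW"), 20L)
  expect_equal(as.vector(table(md$sex)), c(20L, 20L))
  expect_equal(length(unique(md$litter_id)), 15L)
  # combinations balanced within each group x sex cell of 10
  for (g in c("LBW", "NBW")) for (s in c("F", "M")) {
    cell <- table(md$combination[md$group == g & md$sex == s])
    expect_true(max(cell) - min(cell) <= 1)
  }
  expect_true(all(md$birth_weight_g[md$group == "LBW"] <= 1050))
  expect_error(simulate_cohort(cohort_spec(n_pairs = 5L)), "even")
})

test_that("default censoring yields 38 subjects with training data", {
  sim <- simulate_cohort(cohort_spec(seed = 24))
  acq_pigs <- unique(sim$events$pig_id[sim$events$phase == "acquisition"])
  expect_equal(length(acq_pigs), 38L)
  rev2_pigs <- unique(sim$events$pig_id[sim$events$phase == "reversal2"])
  expect_equal(length(rev2_pigs), 37L)
})

test_that("block RM rises with asymptote, WM falls with lapse rate", {
  mean_score <- function(var, ...) {
    spec <- cohort_spec(n_pairs = 4L, n_litters = 3L, dropout = NULL,
                        group_effects = list(rm_asymptote = 0, rm_rate = 0),
                        phase_min = c(acquisition = 24, reversal1 = 0),
                        phase_cap = c(acquisition = 24, reversal1 = 0),
                        habituation_trials = 0L, reversal2_trials = 0L,
                        seed = 25, agent = agent_params(...))
    sc <- score_cohort(simulate_cohort(spec)$events)
    c(rm = mean(sc$rm, na.rm = TRUE), wm = mean(sc$wm, na.rm = TRUE))
  }
  lo <- mean_score("rm", rm_asymptote = 0.5)
  hi <- mean_score("rm", rm_asymptote = 0.95)
  expect_gt(hi[["rm"]], lo[["rm"]])
  lapse0 <- mean_score("wm", wm_lapse = 0.02)
  lapse1 <- mean_score("wm", wm_lapse = 0.3)
  expect_gt(lapse0[["wm"]], lapse1[["wm"]])
})

test_that("default cohort learning matches the expected study shape", {
  sim <- simulate_cohort(cohort_spec(seed = 26))
  sc <- score_cohort(sim$events)
  bl <- make_blocks(sc)
  rmb <- bl[bl$variable == "rm" & bl$phase == "acquisition" & !bl$partial, ]
  curve <- tapply(rmb$mean, rmb$block, mean)
  expect_gt(curve[[1]], 0.2)   # starts near chance (~0.25-0.35)
  expect_lt(curve[[1]], 0.45)
  cr <- criterion_table(sc)
  acq <- cr[cr$phase == "acquisition", ]
  expect_gt(mean(acq$reached), 0.85)  # nearly all subjects acquire the task
  ttc <- acq$trials_to_criterion[acq$reached]
  expect_true(all(ttc >= 44 & ttc <= 76))
  expect_gt(mean(ttc), 44)  # crossings spread beyond the minimum
})

test_that("cortisol generator is mean-preserving and reproducible", {
  md <- simulate_cohort(small_spec(seed = 27))$metadata
  spec0 <- cortisol_spec(hair_sdlog = 0, saliva_sdlog = 0,
                         subject_sdlog = 0, missing = NULL, seed = 1)
  ct <- simulate_cortisol(spec0, md)
  hw <- ct[ct$matrix == "hair" & ct$timepoint == "weaning", ]
  hw <- merge(hw, md[, c("pig_id", "group")])
  expect_equal(unique(hw$concentration[hw$group == "LBW"]), 33.20)
  expect_equal(unique(hw$concentration[hw$group == "NBW"]), 29.26)
  sal <- ct[ct$matrix == "saliva", ]
  expect_true(all(sal$concentration[sal$timepoint == "post"] >
                    sal$concentration[sal$timepoint == "pre"]))
  expect_identical(simulate_cortisol(spec0, md), ct)
})

test_that("default cortisol missingness drops the configured samples", {
  md <- simulate_cohort(cohort_spec(seed = 28))$metadata
  ct <- simulate_cortisol(cortisol_spec(seed = 2), md)
  # the two subjects censored during habituation left before sampling,
  # so 38 subjects are sampled: 35 usable weaning hair, 37 with saliva
  expect_equal(sum(ct$matrix == "hair" & ct$timepoint == "weaning"), 35L)
  sal_pigs <- unique(ct$pig_id[ct$matrix == "saliva"])
  expect_equal(length(sal_pigs), 37L)
})
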