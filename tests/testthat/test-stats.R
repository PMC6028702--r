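test_that("welch_t matches the textbook Welch-Satterthwaite formulas", {
  a <- c(0.7, 0.8, 0.9); b <- c(1.4, 1.5, 1.6)
  got <- welch_t(a, b)
  # independent hand computation from the definition
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t_exp <- (mean(a) - mean(b)) / sqrt(se2)
  df_exp <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                       (vb / length(b))^2 / (length(b) - 1))
  p_exp <- 2 * pt(-abs(t_exp), df_exp)
  expect_equal(got$t, t_exp, tolerance = 1e-12)
  expect_equal(got$df, df_exp, tolerance = 1e-12)
  expect_equal(got$p, p_exp, tolerance = 1e-12)
  expect_equal(got$r, sqrt(t_exp^2 / (t_exp^2 + df_exp)), tolerance = 1e-12)
})

test_that("welch_t is scale invariant and handles degenerate input", {
  a <- c(0.7, 0.8, 0.9); b <- c(1.4, 1.5, 1.6)
  g1 <- welch_t(a, b); g2 <- welch_t(10 * a, 10 * b)
  expect_equal(g1$t, g2$t); expect_equal(g1$df, g2$df)
  expect_equal(g1$p, g2$p)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  const <- welch_t(c(2, 2), c(2, 2))
  expect_equal(const$t, 0); expect_equal(const$p, 1)
})

test_that("contrast effect size follows r = sqrt(F / (F + df))", {
  expect_equal(effect_size_r(0, 20), 0)
  expect_gt(effect_size_r(1e12, 20), 0.999999)
  expect_equal(effect_size_r(34.30, 22), sqrt(34.30 / (34.30 + 22)))
  # printed F/r pairing of a large single-df contrast reproduces to ~0.01
  expect_lt(abs(effect_size_r(34.30, 22) - 0.79), 0.01)
  expect_error(effect_size_r(5, 20, df_num = 2), "single-df")
})

test_that("learning model is equivariant under response rescaling", {
  sim <- simulate_cohort(small_spec(seed = 31))
  sc <- score_cohort(sim$events)
  bl <- make_blocks(sc)
  acq <- bl[bl$phase == "acquisition", ]
  t1 <- fit_learning_model(acq, sim$metadata, "rm")
  acq10 <- acq
  acq10$mean <- acq10$mean * 10
  t2 <- fit_learning_model(acq10, sim$metadata, "rm")
  expect_equal(t1$F, t2$F, tolerance = 1e-6)
  expect_equal(t1$p, t2$p, tolerance = 1e-6)
  expect_equal(t1$term,
               c("group", "sex", "time_f", "group:sex", "group:time_f",
                 "sex:time_f"))
  expect_true(attr(t1, "structure") %in%
                c("subject_in_litter_ar1", "subject_in_litter", "subject"))
})

test_that("learning model reproduces the nested-design df pattern", {
  sim <- simulate_cohort(cohort_spec(seed = 32))
  sc <- score_cohort(sim$events)
  bl <- make_blocks(sc)
  tab <- fit_learning_model(bl[bl$phase == "acquisition", ], sim$metadata,
                            "rm")
  # 38 analyzable subjects in 15 litters, 11 common blocks:
  # subject-level terms tested on 38 - 15 - 3 = 20 df,
  # block-level terms on 38*11 - 38 - 30 = 350 df
  expect_equal(tab$df_den[tab$term == "group"], 20)
  expect_equal(tab$df_num[tab$term == "time_f"], 10)
  expect_equal(tab$df_den[tab$term == "time_f"], 350)
})

test_that("transition frame feeds the same model with a two-level factor", {
  sim <- simulate_cohort(small_spec(seed = 33))
  sc <- score_cohort(sim$events)
  bl <- make_blocks(sc)
  tf <- transition_frame(bl, "acquisition", "reversal1")
  tab <- fit_learning_model(tf, sim$metadata, "rm")
  expect_equal(tab$df_num[tab$term == "time_f"], 1)
  # the post-reversal drop in RM is large and reliably detected
  expect_lt(tab$p[tab$term == "time_f"], 0.001)
})

test_that("AIC selection drops the litter level when litter variance is 0", {
  wins <- 0L
  for (s in 1:8) {
    spec <- cohort_spec(n_pairs = 8L, n_litters = 6L, litter_sd = 0,
                        dropout = NULL,
                        phase_min = c(acquisition = 24, reversal1 = 0),
                        phase_cap = c(acquisition = 24, reversal1 = 0),
                        habituation_trials = 0L, reversal2_trials = 0L,
                        seed = 100 + s)
    sim <- simulate_cohort(spec)
    bl <- make_blocks(score_cohort(sim$events))
    sel <- select_random_structure(bl, sim$metadata, "rm",
                                   candidates = c("subject_in_litter",
                                                  "subject"))
    if (sel$best == "subject") wins <- wins + 1L
    expect_true(all(c("aic", "n_parameters") %in% names(sel)))
  }
  # without litter variance the litter-free structure fits equally well and
  # pays one variance parameter less
  expect_gte(wins, 6L)
})

test_that("AIC selection favors slopes when subjects diverge linearly", {
  # constructed block table with explicit per-subject random slopes
  slope_blocks <- function(seed, slope_sd) {
    set.seed(seed)
    n_pig <- 16L; n_blk <- 8L
    md <- data.frame(pig_id = sprintf("P%02d", 1:n_pig),
                     litter_id = rep(sprintf("L%d", 1:6),
                                     length.out = n_pig),
                     group = rep(c("LBW", "NBW"), n_pig / 2),
                     sex = rep(c("F", "M"), each = n_pig / 2))
    slope <- rnorm(n_pig, 0.05, slope_sd)
    bl <- expand.grid(pig_id = md$pig_id, block = 1:n_blk,
                      stringsAsFactors = FALSE)
    bl$variable <- "rm"
    bl$partial <- FALSE
    bl$mean <- 0.3 + slope[match(bl$pig_id, md$pig_id)] * bl$block +
      rnorm(nrow(bl), 0, 0.04)
    list(blocks = bl, metadata = md)
  }
  wins <- 0L
  for (s in 1:8) {
    d <- slope_blocks(200 + s, slope_sd = 0.04)
    sel <- select_random_structure(d$blocks, d$metadata, "rm",
                                   candidates = c("subject",
                                                  "subject_slopes"))
    if (sel$best == "subject_slopes") wins <- wins + 1L
  }
  expect_gte(wins, 6L)
  # and with homogeneous slopes the simpler structure is kept
  d0 <- slope_blocks(300, slope_sd = 0)
  sel0 <- select_random_structure(d0$blocks, d0$metadata, "rm",
                                  candidates = c("subject",
                                                 "subject_slopes"))
  expect_equal(sel0$best, "subject")
})

test_that("single-candidate selection returns that candidate", {
  sim <- simulate_cohort(small_spec(seed = 34))
  bl <- make_blocks(score_cohort(sim$events))
  sel <- select_random_structure(bl, sim$metadata, "rm",
                                 candidates = "subject_in_litter")
  expect_equal(sel$best, "subject_in_litter")
})

test_that("trials-to-criterion model recovers an injected group shift", {
  sim <- simulate_cohort(cohort_spec(seed = 35))
  sc <- score_cohort(sim$events)
  cr <- criterion_table(sc)
  tab <- suppressWarnings(trials_to_criterion_model(cr, sim$metadata))
  expect_setequal(tab$term, c("group", "sex", "group:sex"))
  gm <- attr(tab, "group_means")
  expect_gt(gm[["LBW"]], gm[["NBW"]])  # LBW needs more trials
})

test_that("trials-to-criterion model warns about and excludes non-reachers", {
  cr <- data.frame(pig_id = sprintf("P%02d", 1:12),
                   phase = "acquisition",
                   reached = c(rep(TRUE, 11), FALSE),
                   trials_to_criterion = c(44 + 2 * (0:10), NA))
  md <- data.frame(pig_id = sprintf("P%02d", 1:12),
                   litter_id = rep(sprintf("L%d", 1:3), each = 4),
                   group = rep(c("LBW", "NBW"), 6),
                   sex = rep(c("F", "F", "M", "M"), 3))
  expect_warning(tab <- trials_to_criterion_model(cr, md), "did not reach")
  expect_equal(attr(tab, "n"), 11L)
})

test_that("constant trials-to-criterion gives F near zero", {
  cr <- data.frame(pig_id = sprintf("P%02d", 1:12),
                   phase = "acquisition", reached = TRUE,
                   trials_to_criterion = 44)
  md <- data.frame(pig_id = sprintf("P%02d", 1:12),
                   litter_id = rep(sprintf("L%d", 1:3), each = 4),
                   group = rep(c("LBW", "NBW"), 6),
                   sex = rep(c("F", "F", "M", "M"), 3))
  tab <- suppressWarnings(trials_to_criterion_model(cr, md))
  expect_true(all(is.na(tab$F) | tab$F < 1e-6))
})

test_that("single-litter criterion data still yields a fitted model", {
  cr <- data.frame(pig_id = sprintf("P%02d", 1:8),
                   phase = "acquisition", reached = TRUE,
                   trials_to_criterion = c(50, 48, 52, 46, 44, 54, 44, 60))
  md <- data.frame(pig_id = sprintf("P%02d", 1:8), litter_id = "L1",
                   group = rep(c("LBW", "NBW"), 4),
                   sex = rep(c("F", "M"), each = 4))
  tab <- trials_to_criterion_model(cr, md)
  expect_equal(nrow(tab), 3L)
  expect_true(all(is.finite(tab$p)))
})

test_that("cortisol models find the injected group and stressor effects", {
  sim <- simulate_cohort(cohort_spec(seed = 36))
  ct <- simulate_cortisol(cortisol_spec(seed = 36), sim$metadata)
  res <- fit_cortisol_models(ct, sim$metadata)
  expect_setequal(names(res), c("hair_weaning", "hair_five_months", "saliva"))
  expect_equal(attr(res$hair_weaning, "n"), 35L)
  expect_equal(attr(res$saliva, "n"), 37L)
  # acute stressor: post > pre saliva, Sample term significant
  sal <- res$saliva
  expect_lt(sal$p[sal$term == "sample"], 0.01)
  sm <- attr(sal, "sample_means")
  expect_gt(sm[["post"]], sm[["pre"]])
  # chronic stress shift at weaning has the injected direction
  gm <- attr(res$hair_weaning, "group_means")
  expect_gt(gm[["LBW"]], gm[["NBW"]])
})

test_that("growth model and birth-weight contrast behave as designed", {
  sim <- simulate_cohort(cohort_spec(seed = 37))
  md <- sim$metadata
  bw <- welch_t(md$birth_weight_g[md$group == "LBW"] / 1000,
                md$birth_weight_g[md$group == "NBW"] / 1000)
  expect_lt(bw$t, -5)       # LBW far below NBW
  expect_gt(bw$r, 0.7)
  tab <- fit_growth_model(sim$weights, md)
  expect_lt(tab$p[tab$term == "group"], 0.05)
  expect_equal(tab$df_num[tab$term == "week_f"], 17)
})
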