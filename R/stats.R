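# The study-level statistical battery. Longitudinal models are linear mixed
# models fitted with nlme::lme under REML: fixed effects Birth-weight group,
# Sex, Trial-block and their two-way interactions; random intercepts for
# subject nested within litter; first-order autoregressive residual
# correlation across blocks within subject. F tests are sequential
# (anova.lme), with denominator degrees of freedom by nlme's containment
# method. Durations are log10 transformed.

#' Per-term F table of a fitted mixed model
#'
#' @param fit An `lme`, `gls` or `lm` fit.
#' @return Data frame `term`, `F`, `df_num`, `df_den`, `p`, `r` (contrast
#'   effect size, single-df terms only).
#' @export
term_table <- function(fit) {
  if (inherits(fit, "lm") && !inherits(fit, "lme")) {
    a <- anova(fit)
    terms <- rownames(a)
    keep <- terms != "Residuals"
    out <- data.frame(term = terms[keep], F = a$`F value`[keep],
                      df_num = a$Df[keep],
                      df_den = a$Df[!keep][1],
                      p = a$`Pr(>F)`[keep], stringsAsFactors = FALSE)
  } else {
    a <- anova(fit)
    terms <- rownames(a)
    keep <- terms != "(Intercept)"
    out <- data.frame(term = terms[keep], F = a$`F-value`[keep],
                      df_num = a$numDF[keep],
                      df_den = if ("denDF" %in% names(a)) a$denDF[keep]
                               else nrow(fit$residuals) - sum(a$numDF),
                      p = a$`p-value`[keep], stringsAsFactors = FALSE)
  }
  out$r <- ifelse(out$df_num == 1,
                  vapply(seq_len(nrow(out)), function(i)
                    effect_size_r(out$F[i], out$df_den[i]), numeric(1)),
                  NA_real_)
  rownames(out) <- NULL
  out
}

# Merge a long block table (one variable) with subject metadata into a
# modeling frame: y, group, sex, time_f (factor), time_num, litter_id,
# pig_id. Partial blocks are excluded by default.
.model_frame <- function(blocks, metadata, response,
                         include_partial = FALSE, max_blocks = NULL) {
  b <- blocks[blocks$variable == response, ]
  if ("partial" %in% names(b) && !include_partial) b <- b[!b$partial, ]
  if ("role" %in% names(b)) {
    b$time_num <- ifelse(b$role == "last_pre", 0, 1)
    b$time_f <- factor(b$role, levels = c("last_pre", "first_post"))
  } else {
    # learning curves are compared on the block grid common to all
    # subjects: blocks beyond a subject's phase minimum exist only for
    # slow learners and would leave empty group x block cells
    if (is.null(max_blocks) && nrow(b))
      max_blocks <- min(tapply(b$block, b$pig_id, max))
    if (!is.null(max_blocks)) b <- b[b$block <= max_blocks, ]
    b$time_num <- b$block
    b$time_f <- factor(b$block)
  }
  df <- merge(b, metadata[, c("pig_id", "litter_id", "group", "sex")],
              by = "pig_id")
  df$y <- df$mean
  df$group <- factor(df$group, GROUPS)
  df$sex <- factor(df$sex, SEXES)
  df <- df[!is.na(df$y), ]
  df[order(df$litter_id, df$pig_id, df$time_num), ]
}

.fixed_formula <- function() {
  y ~ group + sex + time_f + group:sex + group:time_f + sex:time_f
}

# Fit the longitudinal model with graceful degradation: full structure
# (subject-in-litter intercepts + AR(1)) first, then without AR(1), then
# subject intercepts only. The structure actually used is recorded.
.fit_longitudinal <- function(df, use_ar1 = TRUE) {
  ctrls <- list(nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                 returnObject = FALSE),
                nlme::lmeControl(opt = "optim", maxIter = 200,
                                 msMaxIter = 200, returnObject = FALSE))
  attempts <- list()
  if (use_ar1 && length(unique(df$time_num)) > 1L)
    attempts$subject_in_litter_ar1 <- function(ctrl)
      nlme::lme(.fixed_formula(), random = ~ 1 | litter_id / pig_id,
                correlation = nlme::corAR1(form = ~ time_num |
                                             litter_id / pig_id),
                data = df, method = "REML", control = ctrl)
  attempts$subject_in_litter <- function(ctrl)
    nlme::lme(.fixed_formula(), random = ~ 1 | litter_id / pig_id,
              data = df, method = "REML", control = ctrl)
  attempts$subject <- function(ctrl)
    nlme::lme(.fixed_formula(), random = ~ 1 | pig_id,
              data = df, method = "REML", control = ctrl)
  for (nm in names(attempts)) for (ctrl in ctrls) {
    fit <- tryCatch(suppressWarnings(attempts[[nm]](ctrl)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      attr(fit, "structure") <- nm
      return(fit)
    }
  }
  stop("no mixed-model structure converged")
}

#' Fit the longitudinal learning-curve model for one variable
#'
#' Linear mixed model of per-block means: Birth-weight group, Sex,
#' Trial-block and their two-way interactions as fixed effects; random
#' intercepts for subject nested within litter; AR(1) residual correlation
#' over blocks within subject; REML. Works unchanged on a reversal
#' transition frame (from [transition_frame()]), where the block factor has
#' the two levels last-pre/first-post. If the full random/correlation
#' structure fails to converge the model degrades (AR(1) dropped, then the
#' litter level) and the structure used is reported.
#'
#' @param blocks Long block table ([make_blocks()]) or transition frame.
#' @param metadata Cohort metadata.
#' @param response Variable to model (e.g. `"rm"`).
#' @param transform `"identity"` or `"log10"` (used for durations).
#' @param use_ar1 Model AR(1) residual correlation (default TRUE).
#' @param include_partial Include partial blocks (default FALSE).
#' @param max_blocks Truncate the learning curve to this many blocks;
#'   default: the largest block index present for every subject, so the
#'   group x block grid is complete.
#' @return [term_table()] data frame with attributes `structure` (random
#'   structure used), `ar1_phi` (estimated residual autocorrelation, if
#'   any) and `n` (observations).
#' @export
fit_learning_model <- function(blocks, metadata, response = "rm",
                               transform = c("identity", "log10"),
                               use_ar1 = TRUE, include_partial = FALSE,
                               max_blocks = NULL) {
  transform <- match.arg(transform)
  df <- .model_frame(blocks, metadata, response, include_partial, max_blocks)
  if (transform == "log10") {
    if (any(df$y <= 0)) stop("log10 transform requires positive values")
    df$y <- log10(df$y)
  }
  if (nrow(df) == 0L) stop(sprintf("no data for response '%s'", response))
  fit <- .fit_longitudinal(df, use_ar1 = use_ar1)
  out <- term_table(fit)
  attr(out, "structure") <- attr(fit, "structure")
  cs <- fit$modelStruct$corStruct
  attr(out, "ar1_phi") <- if (!is.null(cs))
    as.numeric(coef(cs, unconstrained = FALSE)) else NA_real_
  attr(out, "n") <- nrow(df)
  out
}

#' Select a random-effect structure by REML AIC
#'
#' Fits each candidate structure with identical fixed effects under REML
#' and returns the one with minimal AIC; ties (within `tol`) go to the
#' candidate with fewer variance-covariance parameters. Candidates that
#' fail to converge are dropped and reported.
#'
#' @param blocks,metadata,response,transform As [fit_learning_model()].
#' @param candidates Character vector naming structures among
#'   `"subject_in_litter"`, `"subject_in_litter_slopes"`, `"litter"`,
#'   `"subject"`, `"subject_slopes"`.
#' @param use_ar1 Include AR(1) residual correlation in every candidate.
#' @param tol AIC tie tolerance.
#' @return List: `best` (name), `aic` (named vector), `n_parameters`
#'   (named), `dropped` (names that failed), `model` (the winning fit).
#' @export
select_random_structure <- function(blocks, metadata, response = "rm",
                                    transform = c("identity", "log10"),
                                    candidates = c("subject_in_litter",
                                                   "subject_in_litter_slopes",
                                                   "litter", "subject",
                                                   "subject_slopes"),
                                    use_ar1 = FALSE, tol = 1e-6) {
  transform <- match.arg(transform)
  df <- .model_frame(blocks, metadata, response)
  if (transform == "log10") df$y <- log10(df$y)
  randoms <- list(
    subject_in_litter = ~ 1 | litter_id / pig_id,
    subject_in_litter_slopes = list(litter_id = ~ 1, pig_id = ~ time_num),
    litter = ~ 1 | litter_id,
    subject = ~ 1 | pig_id,
    subject_slopes = ~ 1 + time_num | pig_id
  )
  candidates <- match.arg(candidates, names(randoms), several.ok = TRUE)
  ctrls <- list(nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                 msMaxEval = 500, returnObject = FALSE),
                nlme::lmeControl(opt = "optim", maxIter = 200,
                                 msMaxIter = 200, returnObject = FALSE))
  corr <- if (use_ar1)
    nlme::corAR1(form = ~ time_num | litter_id / pig_id) else NULL
  fits <- list(); aic <- c(); npar <- c(); dropped <- character(0)
  for (nm in candidates) {
    fit <- NULL
    for (ctrl in ctrls) {
      fit <- tryCatch(
        suppressWarnings(nlme::lme(.fixed_formula(), random = randoms[[nm]],
                  correlation = if (nm %in% c("subject_in_litter",
                                              "subject_in_litter_slopes"))
                    corr else NULL,
                  data = df, method = "REML", control = ctrl)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      dropped <- c(dropped, nm)
      next
    }
    fits[[nm]] <- fit
    aic[nm] <- AIC(fit)
    npar[nm] <- length(unlist(coef(fit$modelStruct)))
  }
  if (!length(fits)) stop("no candidate random structure converged")
  best <- names(aic)[aic <= min(aic) + tol]
  if (length(best) > 1L) best <- best[which.min(npar[best])]
  list(best = best, aic = aic, n_parameters = npar, dropped = dropped,
       model = fits[[best]])
}

#' Mixed model for trials to criterion
#'
#' Birth-weight group, Sex and their interaction as fixed effects with
#' random litter intercepts, fitted to the subjects that reached criterion
#' in the given phase. Non-reachers are excluded with a warning. With a
#' single litter (or a non-converging litter term) an ordinary linear model
#' is used instead.
#'
#' @param criterion Criterion table ([criterion_table()]).
#' @param metadata Cohort metadata.
#' @param phase Phase to analyze (default `"acquisition"`).
#' @return [term_table()] with attributes `n` and `group_means`.
#' @export
trials_to_criterion_model <- function(criterion, metadata,
                                      phase = "acquisition") {
  cr <- criterion[criterion$phase == phase, ]
  if (any(!cr$reached)) {
    warning(sprintf("%d subject(s) did not reach criterion in %s; excluded",
                    sum(!cr$reached), phase))
    cr <- cr[cr$reached, ]
  }
  df <- merge(cr, metadata[, c("pig_id", "litter_id", "group", "sex")],
              by = "pig_id")
  df$group <- factor(df$group, GROUPS)
  df$sex <- factor(df$sex, SEXES)
  df$y <- as.numeric(df$trials_to_criterion)
  if (var(df$y) == 0) {
    out <- data.frame(term = c("group", "sex", "group:sex"), F = 0,
                      df_num = 1, df_den = nrow(df) - 4, p = 1, r = 0,
                      stringsAsFactors = FALSE)
    attr(out, "n") <- nrow(df)
    attr(out, "group_means") <- tapply(df$y, df$group, mean)
    attr(out, "group_sem") <- tapply(df$y, df$group,
                                     function(x) sd(x) / sqrt(length(x)))
    return(out)
  }
  fit <- if (length(unique(df$litter_id)) > 1L)
    tryCatch(suppressWarnings(
      nlme::lme(y ~ group + sex + group:sex, random = ~ 1 | litter_id,
                data = df, method = "REML",
                control = nlme::lmeControl(opt = "optim"))),
      error = function(e) NULL) else NULL
  if (is.null(fit)) fit <- lm(y ~ group + sex + group:sex, data = df)
  out <- term_table(fit)
  attr(out, "n") <- nrow(df)
  attr(out, "group_means") <- tapply(df$y, df$group, mean)
  attr(out, "group_sem") <- tapply(df$y, df$group,
                                   function(x) sd(x) / sqrt(length(x)))
  out
}

#' Welch's t-test with contrast effect size
#'
#' Two-sided Welch (unequal-variance) t-test via [stats::t.test()], with
#' the Welch-Satterthwaite fractional degrees of freedom and the contrast
#' effect size `r = sqrt(t^2 / (t^2 + df))`. When both groups are constant
#' and equal the statistic is defined as 0 (p = 1).
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return List `t`, `df`, `p`, `r`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1, r = 0,
                  mean_a = mean(a), mean_b = mean(b)))
    return(list(t = if (mean(a) > mean(b)) Inf else -Inf,
                df = length(a) + length(b) - 2, p = 0, r = 1,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  t <- unname(ht$statistic); df <- unname(ht$parameter)
  list(t = t, df = df, p = ht$p.value,
       r = sqrt(t^2 / (t^2 + df)), mean_a = mean(a), mean_b = mean(b))
}

#' Contrast effect size from a single-df F (or t) statistic
#'
#' Pearson's r for a single-degree-of-freedom contrast:
#' `r = sqrt(F / (F + df_den))`, equivalently `sqrt(t^2 / (t^2 + df))`.
#' Multi-df terms have no single contrast r and are refused.
#'
#' @param statistic F statistic (or squared t) of the contrast.
#' @param df_den Denominator degrees of freedom.
#' @param df_num Numerator degrees of freedom; must be 1.
#' @return Effect size r in \[0, 1\].
#' @examples
#' effect_size_r(34.30, 22) # about 0.78
#' @export
effect_size_r <- function(statistic, df_den, df_num = 1) {
  if (df_num != 1)
    stop("effect size r is defined for single-df contrasts only")
  stopifnot(statistic >= 0, df_den > 0)
  sqrt(statistic / (statistic + df_den))
}

#' Fit the cortisol models
#'
#' Hair cortisol (per timepoint): Birth-weight group, Sex and their
#' interaction as fixed effects, random litter intercepts. Salivary
#' cortisol: log10-transformed concentration with Birth-weight group, Sex,
#' Sample (pre/post) and all two-way interactions as fixed effects and
#' random slopes and intercepts for subject; if that structure does not
#' converge on the data at hand it degrades to random subject intercepts,
#' and the structure used is reported. Missing samples enter as unbalanced
#' data.
#'
#' @param cortisol Cortisol table ([read_cortisol()] /
#'   [simulate_cortisol()]).
#' @param metadata Cohort metadata.
#' @return List of [term_table()]s: `hair_weaning`, `hair_five_months`,
#'   `saliva`; each with attribute `n` (subjects analyzed).
#' @export
fit_cortisol_models <- function(cortisol, metadata) {
  md <- metadata[, c("pig_id", "litter_id", "group", "sex")]
  out <- list()
  for (tp in c("weaning", "five_months")) {
    sub <- merge(cortisol[cortisol$matrix == "hair" &
                            cortisol$timepoint == tp, ], md, by = "pig_id")
    sub$group <- factor(sub$group, GROUPS)
    sub$sex <- factor(sub$sex, SEXES)
    fit <- tryCatch(suppressWarnings(
      nlme::lme(concentration ~ group + sex + group:sex,
                random = ~ 1 | litter_id, data = sub, method = "REML",
                control = nlme::lmeControl(opt = "optim"))),
      error = function(e) lm(concentration ~ group + sex + group:sex,
                             data = sub))
    tab <- term_table(fit)
    attr(tab, "n") <- nrow(sub)
    attr(tab, "group_means") <- tapply(sub$concentration, sub$group, mean)
    out[[paste0("hair_", tp)]] <- tab
  }
  sal <- merge(cortisol[cortisol$matrix == "saliva", ], md, by = "pig_id")
  sal$group <- factor(sal$group, GROUPS)
  sal$sex <- factor(sal$sex, SEXES)
  sal$sample <- factor(sal$timepoint, c("pre", "post"))
  sal$sample_num <- as.numeric(sal$sample) - 1
  sal$y <- log10(sal$concentration)
  ctrl <- nlme::lmeControl(opt = "optim", returnObject = FALSE)
  fixed <- y ~ group + sex + sample + group:sex + group:sample + sex:sample
  fit <- tryCatch(
    suppressWarnings(
      nlme::lme(fixed, random = ~ 1 + sample_num | pig_id, data = sal,
                method = "REML", control = ctrl)),
    error = function(e) NULL)
  structure_used <- "subject_slopes_intercepts"
  if (is.null(fit)) {
    fit <- nlme::lme(fixed, random = ~ 1 | pig_id, data = sal,
                     method = "REML",
                     control = nlme::lmeControl(opt = "optim"))
    structure_used <- "subject_intercepts"
  }
  tab <- term_table(fit)
  attr(tab, "n") <- length(unique(sal$pig_id))
  attr(tab, "structure") <- structure_used
  attr(tab, "sample_means") <- tapply(sal$concentration, sal$sample, mean)
  out$saliva <- tab
  out
}

#' Growth model: weekly body weight
#'
#' Birth-weight group, Week and their interaction as fixed effects; random
#' slopes and intercepts for subject nested within litter. Week enters the
#' fixed part as a factor (one level per measurement week) and the random
#' slopes as numeric time.
#'
#' @param weights Weekly weight table (`pig_id`, `week`, `weight_kg`).
#' @param metadata Cohort metadata.
#' @return [term_table()] with attribute `n`.
#' @export
fit_growth_model <- function(weights, metadata) {
  df <- merge(weights, metadata[, c("pig_id", "litter_id", "group", "sex")],
              by = "pig_id")
  df$group <- factor(df$group, GROUPS)
  df$week_f <- factor(df$week)
  df$week_num <- df$week - min(df$week)
  ctrl <- nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200,
                           returnObject = FALSE)
  fit <- tryCatch(
    suppressWarnings(
      nlme::lme(weight_kg ~ group + week_f + group:week_f,
                random = list(litter_id = ~ 1, pig_id = ~ 1 + week_num),
                data = df, method = "REML", control = ctrl)),
    error = function(e) NULL)
  structure_used <- "subject_in_litter_slopes"
  if (is.null(fit)) {
    fit <- nlme::lme(weight_kg ~ group + week_f + group:week_f,
                     random = ~ 1 | litter_id / pig_id, data = df,
                     method = "REML",
                     control = nlme::lmeControl(opt = "optim"))
    structure_used <- "subject_in_litter"
  }
  out <- term_table(fit)
  attr(out, "n") <- length(unique(df$pig_id))
  attr(out, "structure") <- structure_used
  out
}
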