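# Generative model for the endocrine side of the study: hair cortisol
# (chronic stress; pg/mg) at weaning and at 5 months, and salivary cortisol
# (acute stress; ng/mL) before and after the first individual arena trial.
# Concentrations are lognormal around group x timepoint means with a
# subject-level random effect on the log scale.

#' Cortisol simulation specification
#'
#' Default means emulate a cohort with a pre-weaning chronic-stress shift in
#' the low-birth-weight group (hair, weaning: LBW > NBW) that has resolved
#' by 5 months, and a clear acute post-stressor rise in saliva for all
#' subjects.
#'
#' @param hair_mean Named vector of hair means (pg/mg) for
#'   `LBW.weaning`, `NBW.weaning`, `LBW.five_months`, `NBW.five_months`.
#' @param saliva_mean Named vector of saliva means (ng/mL) for `pre`,
#'   `post`.
#' @param hair_sdlog,saliva_sdlog Residual lognormal SDs (log scale).
#' @param subject_sdlog SD of the per-subject random effect (log scale),
#'   shared by a subject's repeated samples within a matrix.
#' @param missing Data frame (`group`, `sex`, `matrix`, `timepoint`) of
#'   samples to drop, one matching subject per row; the default emulates
#'   three insufficient hair samples at weaning and one subject without
#'   usable saliva. `NULL` keeps all samples.
#' @param seed Seed for the cortisol stream.
#' @return A list of class `cortisol_spec`.
#' @export
cortisol_spec <- function(hair_mean = c(LBW.weaning = 33.20,
                                        NBW.weaning = 29.26,
                                        LBW.five_months = 20.61,
                                        NBW.five_months = 21.84),
                          saliva_mean = c(pre = 2.0, post = 4.1),
                          hair_sdlog = 0.15, saliva_sdlog = 0.30,
                          subject_sdlog = 0.15,
                          missing = default_cortisol_missing(),
                          seed = 1L) {
  stopifnot(all(hair_mean > 0), all(saliva_mean > 0),
            hair_sdlog >= 0, saliva_sdlog >= 0, subject_sdlog >= 0)
  structure(as.list(environment()), class = "cortisol_spec")
}

#' @rdname cortisol_spec
#' @export
default_cortisol_missing <- function() {
  data.frame(group = c("LBW", "NBW", "NBW", "LBW"),
             sex = c("M", "M", "F", "M"),
             matrix = c("hair", "hair", "hair", "saliva"),
             timepoint = c("weaning", "weaning", "weaning", "*"),
             stringsAsFactors = FALSE)
}

#' Simulate hair and salivary cortisol samples
#'
#' Draws lognormal concentrations around the group x timepoint means of the
#' specification, with mean-preserving parameterization
#' (`meanlog = log(mean) - sdlog_total^2 / 2`) so that expected
#' concentrations equal the specified means.
#'
#' @param spec A [cortisol_spec()].
#' @param metadata Cohort metadata (from [simulate_cohort()] or
#'   [read_metadata()]).
#' @return Cortisol data frame (`pig_id`, `matrix`, `timepoint`,
#'   `concentration`).
#' @export
simulate_cortisol <- function(spec = cortisol_spec(), metadata) {
  set.seed(spec$seed)
  # subjects censored during habituation left the study before sampling
  left <- !is.na(metadata$dropout_phase) &
    metadata$dropout_phase == "habituation"
  metadata <- metadata[!left, ]
  n <- nrow(metadata)
  u_hair <- rnorm(n, 0, spec$subject_sdlog)
  u_sal <- rnorm(n, 0, spec$subject_sdlog)
  rows <- list()
  draw <- function(mean, u, sdlog) {
    tot2 <- sdlog^2 + spec$subject_sdlog^2
    exp(log(mean) - tot2 / 2 + u + rnorm(length(u), 0, sdlog))
  }
  for (tp in c("weaning", "five_months")) {
    mu <- spec$hair_mean[paste(metadata$group, tp, sep = ".")]
    rows[[length(rows) + 1L]] <- data.frame(
      pig_id = metadata$pig_id, matrix = "hair", timepoint = tp,
      concentration = round(draw(mu, u_hair, spec$hair_sdlog), 2),
      stringsAsFactors = FALSE)
  }
  for (tp in c("pre", "post")) {
    rows[[length(rows) + 1L]] <- data.frame(
      pig_id = metadata$pig_id, matrix = "saliva", timepoint = tp,
      concentration = round(draw(rep(spec$saliva_mean[[tp]], n), u_sal,
                                 spec$saliva_sdlog), 3),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(spec$missing) && nrow(spec$missing)) {
    used <- character(0)
    for (k in seq_len(nrow(spec$missing))) {
      m <- spec$missing[k, ]
      cand <- metadata$pig_id[metadata$group == m$group &
                                metadata$sex == m$sex &
                                !metadata$pig_id %in% used]
      if (!length(cand)) next
      pid <- cand[1]
      used <- c(used, pid)
      dropme <- out$pig_id == pid & out$matrix == m$matrix &
        (m$timepoint == "*" | out$timepoint == m$timepoint)
      out <- out[!dropme, ]
    }
  }
  rownames(out) <- NULL
  out
}
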