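# Readers/writers for the package's plain-text interchange formats. All
# tables are UTF-8 CSV with '.' decimal separators.
#
#   events:   pig_id,phase,trial,day,config,entrance,hole,t (one row per visit)
#   metadata: pig_id,litter_id,pair_id,group,sex,birth_weight_g,round,
#             dropout_phase,dropout_trial
#   cortisol: pig_id,matrix,timepoint,concentration
#   registry: YAML label -> four hole indices

EVENT_COLS <- c("pig_id", "phase", "trial", "day", "config", "entrance",
                "hole", "t")

#' Read a hole-visit event log
#'
#' One row per (debounced) visit. Validation failures report the offending
#' file row. Trials are identified by (`pig_id`, `phase`, `trial`).
#'
#' @param path CSV file path.
#' @param max_duration Maximum trial duration in seconds used for validation.
#' @return Data frame of visit events with the columns in the file order.
#' @seealso [write_event_log()]
#' @export
read_event_log <- function(path, max_duration = 450) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(EVENT_COLS %in% names(ev)))
    stop(sprintf("event log %s is missing columns: %s", path,
                 paste(setdiff(EVENT_COLS, names(ev)), collapse = ", ")))
  ev <- ev[, EVENT_COLS]
  if (nrow(ev) == 0L) {
    ev$hole <- integer(0); ev$t <- numeric(0)
    return(ev)
  }
  ev$hole <- as.integer(ev$hole)
  ev$t <- as.numeric(ev$t)
  .row_check(ev$hole < 0L | ev$hole >= N_HOLES, path,
             "hole index outside 0-15")
  .row_check(!ev$phase %in% PHASES, path, "unknown phase")
  .row_check(is.na(ev$t) | ev$t < 0, path, "invalid timestamp")
  .row_check(ev$t > max_duration, path,
             sprintf("timestamp exceeds maximum trial duration %g",
                     max_duration))
  key <- interaction(ev$pig_id, ev$phase, ev$trial, drop = TRUE)
  ooo <- unsplit(lapply(split(ev$t, key),
                        function(tt) c(FALSE, diff(tt) < 0)), key)
  .row_check(ooo, path, "timestamps not nondecreasing within trial")
  ev
}

.row_check <- function(bad, path, msg) {
  if (any(bad))
    stop(sprintf("%s, row %d: %s", path, which(bad)[1] + 1L, msg))
}

#' Write a hole-visit event log
#' @param events Data frame as returned by [read_event_log()] or
#'   [simulate_cohort()].
#' @param path Output CSV path.
#' @export
write_event_log <- function(events, path) {
  write.csv(events[, EVENT_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write cohort metadata
#'
#' Columns: `pig_id,litter_id,pair_id,group,sex,birth_weight_g,round,
#' dropout_phase,dropout_trial`. Empty dropout cells mean the subject
#' completed the experiment.
#'
#' @param path CSV file path.
#' @return Metadata data frame.
#' @export
read_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(dropout_phase = "character"))
  need <- c("pig_id", "litter_id", "pair_id", "group", "sex",
            "birth_weight_g", "round", "dropout_phase", "dropout_trial")
  if (!all(need %in% names(md)))
    stop(sprintf("metadata %s is missing columns: %s", path,
                 paste(setdiff(need, names(md)), collapse = ", ")))
  .row_check(!md$group %in% GROUPS, path, "group must be LBW or NBW")
  .row_check(!md$sex %in% SEXES, path, "sex must be F or M")
  .row_check(md$birth_weight_g <= 0, path, "birth weight must be positive")
  md$dropout_phase[md$dropout_phase == ""] <- NA_character_
  md
}

#' @rdname read_metadata
#' @param metadata Metadata data frame.
#' @export
write_metadata <- function(metadata, path) {
  write.csv(metadata, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read or write a cortisol sample table
#'
#' Columns `pig_id,matrix,timepoint,concentration`; `matrix` is `hair`
#' (timepoints `weaning`, `five_months`; pg/mg) or `saliva` (timepoints
#' `pre`, `post` around the first individual arena trial; ng/mL).
#'
#' @param path CSV file path.
#' @return Cortisol data frame.
#' @export
read_cortisol <- function(path) {
  cs <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pig_id", "matrix", "timepoint", "concentration")
  if (!all(need %in% names(cs)))
    stop(sprintf("cortisol table %s is missing columns: %s", path,
                 paste(setdiff(need, names(cs)), collapse = ", ")))
  .row_check(!cs$matrix %in% c("hair", "saliva"), path,
             "matrix must be hair or saliva")
  .row_check(cs$matrix == "hair" & !cs$timepoint %in% c("weaning", "five_months"),
             path, "hair timepoint must be weaning or five_months")
  .row_check(cs$matrix == "saliva" & !cs$timepoint %in% c("pre", "post"),
             path, "saliva timepoint must be pre or post")
  .row_check(!is.finite(cs$concentration) | cs$concentration <= 0, path,
             "concentration must be positive")
  cs
}

#' @rdname read_cortisol
#' @param cortisol Cortisol data frame.
#' @export
write_cortisol <- function(cortisol, path) {
  write.csv(cortisol, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a reward-configuration registry
#'
#' YAML mapping of configuration label to the four baited hole indices
#' (0-based, row-major).
#'
#' @param path YAML file path.
#' @return Named list of integer vectors, validated.
#' @export
read_registry <- function(path) {
  reg <- yaml::read_yaml(path)
  validate_registry(reg)
  lapply(reg, as.integer)
}

#' @rdname read_registry
#' @param registry Registry list.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  yaml::write_yaml(lapply(registry, as.integer), path)
  invisible(path)
}

#' Read or write a per-trial scores table
#'
#' Wide CSV with one row per trial and empty cells for undefined scores
#' (e.g. rotational reference memory in a trial with no rewarded visit).
#'
#' @param path CSV file path.
#' @return Scores data frame as produced by [score_cohort()].
#' @export
read_scores <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_scores
#' @param scores Scores data frame.
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
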