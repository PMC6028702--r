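# End-to-end drivers: simulate a dataset to disk, score it, and run the
# full analysis battery, mirroring the structure of a holeboard study
# report (memory measures x phases grid, trials to criterion, durations,
# exploration, cortisol, growth).

MEMORY_VARS <- c("wm", "rm", "rrm", "srm")
DURATION_VARS <- c("trial_duration", "lat_first_visit",
                   "lat_first_reward", "ivi")
EXPLORATION_VARS <- c("total_visits", "n_locations", "n_rewards")

#' Run configuration
#'
#' Collects every tunable constant of the pipeline, with the conventional
#' values as defaults, so sensitivity analyses (different criterion level,
#' block size, debounce window) need no code change.
#'
#' @param events,metadata,cortisol,weights,registry Input file paths
#'   (registry may also be a registry list).
#' @param out_dir Output directory.
#' @param phase_min,phase_cap Criterion phase minima and caps (trials).
#' @param reversal2_trials,habituation_trials Fixed phase lengths.
#' @param threshold Reference-memory criterion level.
#' @param window Debounce window, seconds.
#' @param max_duration Trial timeout / censoring value, seconds.
#' @param block_size Trials per block.
#' @param trials_per_day Trials per training day.
#' @param alpha Significance level used when flagging terms in the report.
#' @param sliding_criterion Use the sliding-window criterion variant.
#' @param seed Seed for any stochastic step.
#' @return List of class `run_config`.
#' @export
run_config <- function(events = NULL, metadata = NULL, cortisol = NULL,
                       weights = NULL, registry = default_registry(),
                       out_dir = ".",
                       phase_min = c(acquisition = 44L, reversal1 = 24L),
                       phase_cap = c(acquisition = 76L, reversal1 = 44L),
                       reversal2_trials = 20L, habituation_trials = 4L,
                       threshold = 0.7, window = 10, max_duration = 450,
                       block_size = 4L, trials_per_day = 2L, alpha = 0.05,
                       sliding_criterion = FALSE, seed = 1L) {
  stopifnot(threshold > 0, window > 0, max_duration > 0, block_size >= 1,
            trials_per_day >= 1, all(phase_min > 0), all(phase_cap > 0))
  structure(as.list(environment()), class = "run_config")
}

.resolve_registry <- function(registry) {
  if (is.character(registry)) read_registry(registry) else
    validate_registry(registry)
}

.prepare_out <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop(sprintf("output directory '%s' is not empty; use force = TRUE",
                 out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

#' Simulate a dataset to disk
#'
#' Runs [simulate_cohort()] and [simulate_cortisol()] and writes
#' `metadata.csv`, `events.csv`, `cortisol.csv`, `weights.csv`,
#' `registry.yaml` and a `manifest.json` recording the seed and package
#' version. Identical seeds give byte-identical files.
#'
#' @param spec A [cohort_spec()].
#' @param cortisol A [cortisol_spec()]; its seed defaults to the cohort's.
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the named vector of written paths.
#' @export
run_simulate <- function(spec = cohort_spec(), cortisol = NULL,
                         out_dir = "holeboard_data", force = FALSE) {
  .prepare_out(out_dir, force)
  if (is.null(cortisol)) cortisol <- cortisol_spec(seed = spec$seed)
  sim <- simulate_cohort(spec)
  cort <- simulate_cortisol(cortisol, sim$metadata)
  paths <- c(
    metadata = file.path(out_dir, "metadata.csv"),
    events = file.path(out_dir, "events.csv"),
    cortisol = file.path(out_dir, "cortisol.csv"),
    weights = file.path(out_dir, "weights.csv"),
    registry = file.path(out_dir, "registry.yaml"),
    manifest = file.path(out_dir, "manifest.json"))
  write_metadata(sim$metadata, paths["metadata"])
  write_event_log(sim$events, paths["events"])
  write_cortisol(cort, paths["cortisol"])
  write.csv(sim$weights, paths["weights"], row.names = FALSE, quote = FALSE)
  write_registry(spec$registry, paths["registry"])
  jsonlite::write_json(
    list(seed = spec$seed,
         package = as.character(utils::packageVersion("holeboard")),
         n_pigs = nrow(sim$metadata), n_events = nrow(sim$events)),
    paths["manifest"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Score a dataset: trials, blocks and criterion tables
#'
#' Chains debouncing, [score_cohort()], [make_blocks()] and
#' [criterion_table()], writing `scores.csv`, `blocks.csv` and
#' `criterion.csv` to the configured output directory. Deterministic.
#'
#' @param config A [run_config()] with `events` (and optionally `registry`)
#'   set.
#' @param write Write CSV outputs (default TRUE).
#' @return List with `scores`, `blocks`, `criterion`.
#' @export
run_score <- function(config, write = TRUE) {
  registry <- .resolve_registry(config$registry)
  events <- if (is.character(config$events)) read_event_log(config$events)
            else config$events
  scores <- score_cohort(events, registry, window = config$window,
                         max_duration = config$max_duration)
  blocks <- make_blocks(scores, block_size = config$block_size)
  criterion <- criterion_table(scores, minima = config$phase_min,
                               threshold = config$threshold,
                               trials_per_day = config$trials_per_day,
                               sliding = config$sliding_criterion)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scores(scores, file.path(config$out_dir, "scores.csv"))
    write.csv(blocks, file.path(config$out_dir, "blocks.csv"),
              row.names = FALSE, quote = FALSE, na = "")
    write.csv(criterion, file.path(config$out_dir, "criterion.csv"),
              row.names = FALSE, quote = FALSE, na = "")
  }
  list(scores = scores, blocks = blocks, criterion = criterion)
}

# Trial-level long table for the habituation model (Trial as fixed effect).
.habituation_blocks <- function(scores) {
  hab <- scores[scores$phase == "habituation", ]
  if (nrow(hab) == 0L) return(NULL)
  vars <- intersect(SCORE_VARS, names(hab))
  out <- do.call(rbind, lapply(vars, function(v)
    data.frame(pig_id = hab$pig_id, phase = "habituation",
               block = hab$trial, partial = FALSE, variable = v,
               mean = hab[[v]], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

.fit_or_note <- function(expr) {
  tryCatch(expr, error = function(e)
    structure(list(error = conditionMessage(e)), class = "fit_error"))
}

#' Run the full analysis battery
#'
#' Fits, for every behavioral variable, the longitudinal mixed model over
#' each analysis segment — acquisition, first transition, first reversal,
#' second transition, second reversal (and habituation, with Trial as the
#' repeated factor) — plus the trials-to-criterion, cortisol and growth
#' models. Durations are log10 transformed. Results are written as a
#' versioned JSON file and a human-readable report.
#'
#' @param config A [run_config()]; `metadata` and `events` (or
#'   pre-computed tables passed directly) are required, `cortisol` and
#'   `weights` optional.
#' @param scored Optional result of [run_score()] to avoid re-scoring.
#' @param write Write `results.json` and `report.txt` (default TRUE).
#' @return Nested list of term tables; see the JSON schema in the output.
#' @export
run_analyze <- function(config, scored = NULL, write = TRUE) {
  metadata <- if (is.character(config$metadata))
    read_metadata(config$metadata) else config$metadata
  if (is.null(scored)) scored <- run_score(config, write = write)
  blocks <- scored$blocks
  scores <- scored$scores
  criterion <- scored$criterion

  trans1 <- transition_frame(blocks, "acquisition", "reversal1")
  trans2 <- transition_frame(blocks, "reversal1", "reversal2")
  segments <- list(
    acquisition = blocks[blocks$phase == "acquisition", ],
    transition1 = trans1,
    reversal1 = blocks[blocks$phase == "reversal1", ],
    transition2 = trans2,
    reversal2 = blocks[blocks$phase == "reversal2", ])
  hab <- .habituation_blocks(scores)

  all_vars <- c(MEMORY_VARS, DURATION_VARS, EXPLORATION_VARS)
  learning <- list()
  for (v in all_vars) {
    transform <- if (v %in% DURATION_VARS) "log10" else "identity"
    for (seg in names(segments)) {
      learning[[v]][[seg]] <- .fit_or_note(
        fit_learning_model(segments[[seg]], metadata, response = v,
                           transform = transform))
    }
    if (!is.null(hab) && !(v == "rm"))  # habituation rm is 1 by construction
      learning[[v]][["habituation"]] <- .fit_or_note(
        fit_learning_model(hab, metadata, response = v,
                           transform = transform))
  }

  ttc <- list(
    acquisition = .fit_or_note(
      trials_to_criterion_model(criterion, metadata, "acquisition")),
    reversal1 = .fit_or_note(
      trials_to_criterion_model(criterion, metadata, "reversal1")))

  cortisol <- NULL
  if (!is.null(config$cortisol)) {
    ct <- if (is.character(config$cortisol)) read_cortisol(config$cortisol)
          else config$cortisol
    cortisol <- .fit_or_note(fit_cortisol_models(ct, metadata))
  }

  growth <- NULL
  if (!is.null(config$weights)) {
    wt <- if (is.character(config$weights))
      read.csv(config$weights, stringsAsFactors = FALSE) else config$weights
    bw <- welch_t(metadata$birth_weight_g[metadata$group == "LBW"] / 1000,
                  metadata$birth_weight_g[metadata$group == "NBW"] / 1000)
    growth <- list(birth_weight_welch = bw,
                   weight_model = .fit_or_note(fit_growth_model(wt, metadata)))
  }

  results <- list(schema = "holeboard-results/1",
                  alpha = config$alpha,
                  learning = learning, trials_to_criterion = ttc,
                  cortisol = cortisol, growth = growth)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(.results_json(results),
                         file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeLines(render_report(results),
               file.path(config$out_dir, "report.txt"))
  }
  invisible(results)
}

# strip non-serializable attributes, keep the useful ones as fields
.results_json <- function(x) {
  if (inherits(x, "fit_error")) return(list(error = x$error))
  if (is.data.frame(x)) {
    out <- list(terms = x)
    for (a in c("structure", "ar1_phi", "n"))
      if (!is.null(attr(x, a))) out[[a]] <- attr(x, a)
    for (a in c("group_means", "group_sem", "sample_means"))
      if (!is.null(attr(x, a))) out[[a]] <- as.list(attr(x, a))
    return(out)
  }
  if (is.list(x)) return(lapply(x, .results_json))
  x
}

#' Render a plain-text analysis report
#'
#' One grid row per measure x segment with the F, df and p of every fixed
#' term; significant terms (at the configured alpha) are starred. Followed
#' by trials-to-criterion, cortisol and growth sections.
#'
#' @param results Result list from [run_analyze()].
#' @return Character vector of report lines.
#' @export
render_report <- function(results) {
  alpha <- results$alpha
  lines <- c("Holeboard analysis report",
             strrep("=", 60))
  fmt_tab <- function(tab) {
    vapply(seq_len(nrow(tab)), function(i) {
      star <- if (!is.na(tab$p[i]) && tab$p[i] < alpha) " *" else ""
      sprintf("    %-22s F(%g,%g) = %8.2f, p = %6.4f%s",
              tab$term[i], tab$df_num[i], tab$df_den[i], tab$F[i],
              tab$p[i], star)
    }, character(1))
  }
  seg_label <- c(habituation = "Hab", acquisition = "Acq",
                 transition1 = "Trans I", reversal1 = "Rev I",
                 transition2 = "Trans II", reversal2 = "Rev II")
  for (v in names(results$learning)) {
    lines <- c(lines, "", sprintf("Measure: %s", v))
    for (seg in names(results$learning[[v]])) {
      res <- results$learning[[v]][[seg]]
      lines <- c(lines, sprintf("  %s:", seg_label[[seg]]))
      if (inherits(res, "fit_error"))
        lines <- c(lines, sprintf("    [not fitted: %s]", res$error))
      else lines <- c(lines, fmt_tab(res))
    }
  }
  for (ph in names(results$trials_to_criterion)) {
    res <- results$trials_to_criterion[[ph]]
    lines <- c(lines, "", sprintf("Trials to criterion (%s):", ph))
    if (inherits(res, "fit_error"))
      lines <- c(lines, sprintf("    [not fitted: %s]", res$error))
    else {
      gm <- attr(res, "group_means"); gs <- attr(res, "group_sem")
      lines <- c(lines,
                 sprintf("    LBW: %.2f +/- %.2f, NBW: %.2f +/- %.2f",
                         gm[["LBW"]], gs[["LBW"]], gm[["NBW"]], gs[["NBW"]]),
                 fmt_tab(res))
    }
  }
  if (!is.null(results$cortisol) &&
      !inherits(results$cortisol, "fit_error")) {
    for (nm in names(results$cortisol)) {
      lines <- c(lines, "", sprintf("Cortisol: %s", nm),
                 fmt_tab(results$cortisol[[nm]]))
    }
  }
  if (!is.null(results$growth)) {
    bw <- results$growth$birth_weight_welch
    lines <- c(lines, "", "Growth:",
               sprintf("    birth weight t(%.2f) = %.2f, p = %.3g, r = %.2f",
                       bw$df, bw$t, bw$p, bw$r))
    if (!inherits(results$growth$weight_model, "fit_error"))
      lines <- c(lines, fmt_tab(results$growth$weight_model))
  }
  lines
}
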