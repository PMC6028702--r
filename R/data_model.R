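# Domain constants and validated constructors for the holeboard arena,
# reward configurations, phase schedules and subject metadata.

N_HOLES <- 16L
ARENA_DIM <- 4L
N_BAITED <- 4L

PHASES <- c("habituation", "acquisition", "reversal1", "reversal2")
GROUPS <- c("LBW", "NBW")
SEXES <- c("F", "M")
ENTRANCES <- c("N", "E", "S", "W")

# Phase -> configuration combinations: four rotations of the A-D labels over
# acquisition, first reversal and second reversal.
COMBINATIONS <- data.frame(
  combination = 1:4,
  acquisition = c("A", "B", "C", "D"),
  reversal1   = c("C", "D", "A", "B"),
  reversal2   = c("B", "C", "D", "A"),
  stringsAsFactors = FALSE
)

#' Hole grid of the holeboard arena
#'
#' The arena holds 16 food bowls in a 4 x 4 matrix. Holes are indexed 0-15,
#' row-major, with row 0 nearest the north entrance.
#'
#' @return A data frame with columns `index` (0-15), `row` and `col` (0-3).
#' @examples
#' holes()
#' @export
holes <- function() {
  idx <- 0:(N_HOLES - 1L)
  data.frame(index = idx, row = idx %/% ARENA_DIM, col = idx %% ARENA_DIM)
}

#' Validate a reward-configuration registry
#'
#' A registry maps configuration labels (usually A-D) to the four baited hole
#' indices. Exactly four distinct holes per label, all in 0-15, labels unique.
#'
#' @param registry A named list of integer vectors.
#' @return The registry, invisibly, with integer-typed entries.
#' @export
validate_registry <- function(registry) {
  if (!is.list(registry) || is.null(names(registry)) || any(names(registry) == ""))
    stop("registry must be a named list of hole-index vectors")
  if (anyDuplicated(names(registry)))
    stop("duplicated configuration labels in registry")
  registry <- lapply(registry, function(x) as.integer(x))
  for (lab in names(registry)) {
    b <- registry[[lab]]
    if (length(b) != N_BAITED || anyDuplicated(b))
      stop(sprintf("configuration '%s' must contain exactly %d distinct holes",
                   lab, N_BAITED))
    if (any(b < 0L | b >= N_HOLES))
      stop(sprintf("configuration '%s' has hole indices outside 0-%d",
                   lab, N_HOLES - 1L))
  }
  invisible(registry)
}

#' Default reward-configuration registry
#'
#' Four distinct four-hole patterns, one per label A-D, each spreading its
#' baited holes over all quadrants of the arena so no configuration can be
#' solved by a fixed turning rule from one entrance. The exact layouts used by
#' any given laboratory differ; supply your own registry
#' ([read_registry()]) to match an apparatus.
#'
#' @return Named list of integer vectors of baited hole indices (0-based).
#' @examples
#' default_registry()
#' @export
default_registry <- function() {
  reg <- list(
    A = c(1L, 4L, 10L, 15L),
    B = c(2L, 7L, 8L, 13L),
    C = c(0L, 5L, 11L, 14L),
    D = c(3L, 6L, 9L, 12L)
  )
  validate_registry(reg)
  reg
}

#' Baited holes for a trial
#'
#' Resolves a configuration label against a registry; during habituation all
#' 16 holes are baited regardless of label.
#'
#' @param config Configuration label.
#' @param registry Registry as from [default_registry()].
#' @param phase Phase name; `"habituation"` returns all 16 holes.
#' @return Integer vector of baited hole indices.
#' @export
baited_holes <- function(config, registry = default_registry(),
                         phase = "acquisition") {
  if (identical(phase, "habituation")) return(0:(N_HOLES - 1L))
  if (!config %in% names(registry))
    stop(sprintf("unknown configuration label '%s'", config))
  as.integer(registry[[config]])
}

#' Phase schedule for a configuration combination
#'
#' Each subject is assigned one of four combinations that determine which
#' reward configuration it trains on during acquisition and the two reversal
#' phases. Habituation always baits all 16 holes.
#'
#' @param combination Integer 1-4.
#' @return Named character vector with elements `acquisition`, `reversal1`,
#'   `reversal2`.
#' @examples
#' schedule_phases(1) # A, C, B
#' @export
schedule_phases <- function(combination) {
  if (length(combination) != 1L || !combination %in% COMBINATIONS$combination)
    stop(sprintf("unknown combination '%s'; must be 1-4", combination))
  row <- COMBINATIONS[COMBINATIONS$combination == combination, ]
  c(acquisition = row$acquisition, reversal1 = row$reversal1,
    reversal2 = row$reversal2)
}

#' Validate a cohort metadata table
#'
#' Checks the sibling-pair design: every pair must contain exactly one
#' low-birth-weight (LBW) and one normal-birth-weight (NBW) subject of the
#' same sex from the same litter, ids must be unique and birth weights
#' positive. Report-only: violations are returned, not raised.
#'
#' @param pigs Metadata data frame with columns `pig_id`, `litter_id`,
#'   `pair_id`, `group`, `sex`, `birth_weight_g`.
#' @return A list with elements `violations` (character vector, possibly
#'   empty), `counts` (group x sex table) and `n_pigs`.
#' @export
validate_cohort <- function(pigs) {
  v <- character(0)
  if (anyDuplicated(pigs$pig_id))
    v <- c(v, sprintf("duplicated pig ids: %s",
                      paste(unique(pigs$pig_id[duplicated(pigs$pig_id)]),
                            collapse = ", ")))
  if (any(!pigs$group %in% GROUPS))
    v <- c(v, "group values outside {LBW, NBW}")
  if (any(!pigs$sex %in% SEXES))
    v <- c(v, "sex values outside {F, M}")
  if (any(pigs$birth_weight_g <= 0))
    v <- c(v, "non-positive birth weights")
  for (p in unique(pigs$pair_id)) {
    sub <- pigs[pigs$pair_id == p, ]
    if (nrow(sub) != 2L) {
      v <- c(v, sprintf("pair %s has %d member(s), expected 2", p, nrow(sub)))
      next
    }
    if (!setequal(sub$group, GROUPS))
      v <- c(v, sprintf("pair %s is not one LBW + one NBW", p))
    if (length(unique(sub$sex)) != 1L)
      v <- c(v, sprintf("pair %s mixes sexes", p))
    if (length(unique(sub$litter_id)) != 1L)
      v <- c(v, sprintf("pair %s spans litters", p))
  }
  counts <- table(group = factor(pigs$group, GROUPS),
                  sex = factor(pigs$sex, SEXES))
  list(violations = v, counts = counts, n_pigs = nrow(pigs))
}
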