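# Baseline and intervention scenarios: parameter overrides on top of the
# baseline configuration. S2/S3 raise neighbourhood outdoor-play frequency,
# S4/S5 add daily PE, S6/S7 force active travel, S8 combines domains.

SCENARIO_OVERRIDES <- list(
  S1 = list(),
  S2 = list(F_neigh = 2 / 5),
  S3 = list(F_neigh = 3 / 5),
  S4 = list(extra_pe_minutes = 30),
  S5 = list(extra_pe_minutes = 60),
  S6 = list(force_walk_school = TRUE),
  S7 = list(force_walk_all = TRUE),
  S8 = list(F_neigh = 2 / 5, extra_pe_minutes = 30,
            force_walk_school = TRUE)
)

#' Intervention scenario
#'
#' `S1` is the baseline (no overrides); `S2`/`S3` set the neighbourhood
#' outdoor-play frequency to 2/5 and 3/5; `S4`/`S5` add 30 and 60 minutes of
#' daily PE; `S6` makes all agents walk to school; `S7` makes all agents walk
#' to all activities; `S8` combines `F_neigh = 2/5`, +30 min daily PE and
#' walking to school.
#'
#' @param id one of `"S1"` to `"S8"`.
#' @return object of class `pa_scenario` with fields `id` and `overrides`.
#' @export
scenario <- function(id) {
  if (!id %in% names(SCENARIO_OVERRIDES)) {
    stop_config("unknown scenario '%s' (expected S1..S8)", id)
  }
  structure(list(id = id, overrides = SCENARIO_OVERRIDES[[id]]),
            class = "pa_scenario")
}

#' Apply a scenario's overrides to a parameter set
#'
#' Returns `base` with exactly the scenario's overrides applied; all other
#' parameters remain as in the baseline.
#'
#' @param base `pa_params`.
#' @param sc a `pa_scenario` or a scenario id string.
#' @return `pa_params`.
#' @export
apply_scenario <- function(base, sc) {
  if (is.character(sc)) sc <- scenario(sc)
  p <- unclass(base)
  p[names(sc$overrides)] <- sc$overrides
  validate_params(p)
  class(p) <- "pa_params"
  attr(p, "scenario") <- sc$id
  p
}
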