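# Per-minute MVPA accumulation: a Bernoulli draw each minute with probability
# A_eff * P_k, where P_k is the land-use/activity probability for the agent's
# gender and A_eff the (possibly peer-adjusted) tendency to be active.

#' Peer-adjusted effective activity tendency
#'
#' During joint activities (friend meetings; recess and PE in the school day)
#' an agent's tendency is partially adjusted towards the mean tendency of the
#' co-participating friends: `A_eff = (1 - delta) * A_i + delta * mean(A_f)`.
#' With no co-participating friends `A_eff = A_i`. Under the default
#' (transient) peer-influence mode the underlying `A_i` is never mutated.
#'
#' @param A_i agent's own tendency.
#' @param A_friends tendencies of co-participating friends (may be empty).
#' @param delta influence proportion in `[0, 1]`.
#' @return effective tendency.
#' @export
effective_tendency <- function(A_i, A_friends, delta) {
  if (length(A_friends) == 0) return(A_i)
  (1 - delta) * A_i + delta * mean(A_friends)
}

#' Per-minute MVPA probability
#'
#' `clamp(A_eff * P_k, 0, 1)`; products above 1 are clamped (the engine
#' counts clamping events).
#'
#' @param A_eff effective tendency.
#' @param P_k land-use/activity MVPA probability.
#' @return probability in `[0, 1]` (vectorised).
#' @export
p_mvpa <- function(A_eff, P_k) clamp(A_eff * P_k)

#' Draw one minute of MVPA
#'
#' @param A_eff effective tendency (see [effective_tendency()]).
#' @param P_k activity MVPA probability.
#' @return 0 or 1.
#' @export
mvpa_minute <- function(A_eff, P_k) rbinom(1, 1, p_mvpa(A_eff, P_k))

#' Aggregate an event log into a per-agent per-day MVPA ledger
#'
#' @param events event data.frame as returned by [run_day()] (columns
#'   `agent`, `day`, `type`, `duration`, `mvpa`).
#' @return data.frame with one row per agent-day: total MVPA minutes and
#'   minutes by activity type.
#' @export
mvpa_ledger <- function(events) {
  key <- interaction(events$agent, events$day, drop = TRUE)
  total <- tapply(events$mvpa, key, sum)
  out <- data.frame(agent = as.integer(sub("\\..*", "", names(total))),
                    day = as.integer(sub(".*\\.", "", names(total))),
                    mvpa = as.numeric(total))
  by_type <- tapply(events$mvpa, list(key, events$type), sum, default = 0)
  out <- cbind(out, as.data.frame(by_type))
  rownames(out) <- NULL
  out
}
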