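# Travel-mode choice (walk vs car) and movement on the road network.

#' Travel-mode model coefficients
#'
#' The walk probability is `plogis(b0 - b1 * distance_km + b2 * walkability -
#' b3 * n_cars * [trip != school])`. The empirical mode-choice regression this
#' stands in for is estimated from travel diaries that are not reproduced
#' here, so the defaults are documented placeholders satisfying the
#' qualitative dependencies (decreasing in distance, increasing in
#' walkability, decreasing in household cars for non-school trips) and chosen
#' so that `p_walk(500 m, 0.5, 0, school) ~ 0.9` and
#' `p_walk(3 km, 0.5, 2, other) ~ 0.2`. Agents without a household car always
#' walk regardless of the probability.
#'
#' The defaults put the distance slope at the upper end compatible with the
#' two anchors, so that mode choice is dominated by the length of the school
#' commute — the channel through which household cars influence children's
#' activity in this model.
#'
#' @param b0,b1,b2,b3 coefficients (defaults 2.5, 1.4, 0.8, 0.05).
#' @return named list of class `travel_model`.
#' @export
travel_model <- function(b0 = 2.5, b1 = 1.4, b2 = 0.8, b3 = 0.05) {
  structure(list(b0 = b0, b1 = b1, b2 = b2, b3 = b3),
            class = "travel_model")
}

travel_model_default <- function() travel_model()

#' Probability of walking a trip
#'
#' @param distance trip network distance, metres.
#' @param walkability length-weighted mean route walkability in `[0, 1]`.
#' @param n_cars household cars; agents with 0 cars always walk.
#' @param trip_type `"school"` (no car-count term) or `"other"`.
#' @param model a [travel_model()].
#' @return walk probability in `[0, 1]` (vectorised); exactly 1 when
#'   `n_cars = 0`.
#' @export
p_walk <- function(distance, walkability, n_cars = 0,
                   trip_type = c("school", "other"),
                   model = travel_model()) {
  trip_type <- match.arg(trip_type)
  cars_term <- if (trip_type == "other") model$b3 * n_cars else 0
  p <- stats::plogis(model$b0 - model$b1 * distance / 1000 +
                     model$b2 * walkability - cars_term)
  ifelse(rep_len(n_cars, length(p)) == 0, 1, p)
}

#' Simulate one trip on the road network
#'
#' Returns the walk or car segment for the journey: duration is
#' `ceiling(length / speed)` minutes (walk 33 m/min, car 500 m/min by
#' default), and the route's node path so per-minute positions can be
#' interpolated. Identical origin and destination give no event.
#'
#' @param env `pa_environment`.
#' @param origin,dest site ids or indices.
#' @param mode `"walk"` or `"car"`.
#' @param params `pa_params`.
#' @return list with `mode`, `minutes`, `length`, `path`; or `NULL` for a
#'   zero-length trip.
#' @export
travel <- function(env, origin, dest, mode = c("walk", "car"),
                   params = sim_params()) {
  mode <- match.arg(mode)
  r <- shortest_route(env, origin, dest)
  if (r$length == 0) return(NULL)
  speed <- if (mode == "walk") params$walk_speed else params$car_speed
  list(mode = mode, minutes = as.integer(ceiling(r$length / speed)),
       length = r$length, path = r$path)
}
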