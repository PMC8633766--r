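# Behavioural decision probabilities. Frequencies F are per-weekday
# probabilities (a frequency of 2/5 realises twice per 5-weekday week).
# Products can exceed 1 for large O or heavy presence; all probabilities are
# clamped to [0, 1] and clamping is counted by the engine.

#' Probability of after-school outdoor play
#'
#' Evaluated once per agent at school exit:
#' `F_as * O * s * m`, where `m = m_penalty` (default 1/3) if the agent is
#' driven home or has an organised sport session scheduled today, else 1.
#'
#' @param O agent's outdoor-play preference.
#' @param s deprivation multiplier of the home zone.
#' @param driven_home logical, travel mode home is car.
#' @param has_fsa_today logical.
#' @param params `pa_params`.
#' @return probability in `[0, 1]`.
#' @export
p_after_school_play <- function(O, s, driven_home, has_fsa_today,
                                params = sim_params()) {
  m <- ifelse(driven_home | has_fsa_today, params$m_penalty, 1)
  clamp(params$F_as * O * s * m)
}

#' Probability of spontaneous neighbourhood outdoor play
#'
#' The weekday-frequency-scale probability
#' `F_neigh * O * s * (1 + N_a * lambda')`, where `N_a` is the number of
#' agents currently playing outdoors within the presence radius (300 m) of the
#' agent's home and `lambda' = lambda` only when `N_a` reaches the presence
#' threshold (3 agents), otherwise 0. The engine converts this value to a
#' per-attempt probability through the frequency-to-attempt calibration (see
#' the package vignette).
#'
#' @param O,s as in [p_after_school_play()].
#' @param n_nearby count of agents playing outdoors within the radius.
#' @param params `pa_params`.
#' @return probability in `[0, 1]`.
#' @export
p_neighbourhood_play <- function(O, s, n_nearby, params = sim_params()) {
  lam <- ifelse(n_nearby >= params$presence_threshold, params$lambda, 0)
  clamp(params$F_neigh * O * s * (1 + n_nearby * lam))
}

#' Probability that a friend meeting takes place outdoors
#'
#' `gamma * mean(O) * s_host`, with the mean outdoor preference taken over the
#' host and all guests and the deprivation multiplier of the host's zone.
#'
#' @param O_participants numeric vector of O over host and guests.
#' @param s_host host-zone deprivation multiplier.
#' @param params `pa_params`.
#' @return probability in `[0, 1]`.
#' @export
p_outdoor_meeting <- function(O_participants, s_host, params = sim_params()) {
  clamp(params$gamma * mean(O_participants) * s_host)
}

#' Sample an activity duration
#'
#' Integer minutes drawn from an exponential distribution with the configured
#' mean (play and friend meetings 70 min, shopping 30 min by default),
#' at least 1 and truncated so the activity ends by `max_minutes` when given.
#'
#' @param type one of `"play"`, `"meeting"`, `"shop"`.
#' @param params `pa_params`.
#' @param n number of draws.
#' @param max_minutes optional truncation bound.
#' @return integer vector of minutes (`>= 1`).
#' @export
sample_duration <- function(type = c("play", "meeting", "shop"),
                            params = sim_params(), n = 1,
                            max_minutes = Inf) {
  type <- match.arg(type)
  mu <- if (type == "shop") params$shop_duration_mean else
    params$play_duration_mean
  d <- pmax(1, ceiling(rexp(n, 1 / mu)))
  pmin(d, pmax(1, max_minutes))
}

#' Schedule friend meetings for one weekday
#'
#' Agents are processed in a seed-shuffled order; each initiates a hosted
#' meeting with probability `F_friend`. Guests are drawn among the initiator's
#' friends who have no sport session that day and are not already invited to
#' another friend; beyond the first guest, each further eligible friend is
#' invited independently with `extra_guest_prob`, so one agent may host
#' several friends. A host may itself be a guest elsewhere (meetings are
#' sequenced within the day) but no agent is invited twice.
#'
#' @param pop `pa_population`.
#' @param fsa_today logical vector, agent has a sport session today.
#' @param params `pa_params`.
#' @return list with integer vectors `host` and list `guests` (parallel).
#' @export
schedule_friend_meetings <- function(pop, fsa_today, params = sim_params()) {
  n <- nrow(pop$agents)
  invited <- logical(n)
  hosts <- integer(0); guests <- list()
  if (params$F_friend <= 0) return(list(host = hosts, guests = guests))
  order_today <- sample.int(n)
  initiate <- runif(n) < params$F_friend
  for (i in order_today) {
    if (!initiate[i]) next
    elig <- pop$friends[[i]]
    elig <- elig[!fsa_today[elig] & !invited[elig]]
    if (length(elig) == 0) next
    k <- 1L
    if (length(elig) > 1) {
      k <- 1L + rbinom(1, length(elig) - 1L, params$extra_guest_prob)
    }
    g <- if (length(elig) == 1) elig else sample(elig, k)
    invited[g] <- TRUE
    hosts <- c(hosts, i)
    guests[[length(guests) + 1]] <- g
  }
  list(host = hosts, guests = guests)
}
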