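#' Default MVPA probability table
#'
#' Per-minute probability of performing MVPA by activity/land-use kind and
#' gender. The empirical accelerometer-derived values this table stands for are
#' not publicly printed, so these are documented placeholder defaults that
#' respect the qualitative ordering: outdoor kinds (parks, gardens, sports
#' fields, amenity spaces, schoolyard recess, PE, organised sport) carry higher
#' probabilities than indoor kinds (home, lessons, shopping); walking has its
#' own entry and car travel is zero. Any calibration against real data should
#' supply its own table via [sim_params()] or [read_mvpa_table()].
#'
#' @return data.frame with columns `kind`, `girl`, `boy`.
#' @export
default_mvpa_table <- function() {
  data.frame(
    kind = c("home", "lesson", "recess", "pe", "fsa",
             "park", "sports_field", "garden", "amenity",
             "shop", "walk", "car"),
    girl = c(0.04, 0.02, 0.25, 0.50, 0.42,
             0.30, 0.32, 0.28, 0.26,
             0.05, 0.34, 0.00),
    boy  = c(0.05, 0.03, 0.32, 0.55, 0.47,
             0.36, 0.38, 0.33, 0.31,
             0.06, 0.39, 0.00),
    stringsAsFactors = FALSE
  )
}

#' Read an MVPA probability table from CSV
#'
#' Expected columns: `kind`, `girl`, `boy`, probabilities in `[0, 1]`.
#'
#' @param path path to a CSV file.
#' @return data.frame usable as the `mvpa_table` entry of [sim_params()].
#' @export
read_mvpa_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "girl", "boy")
  if (!all(need %in% names(tab))) {
    stop_config("MVPA table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(tab$girl < 0 | tab$girl > 1 | tab$boy < 0 | tab$boy > 1)) {
    stop_config("MVPA probabilities must lie in [0, 1]")
  }
  tab
}

#' Global simulation parameters
#'
#' Single source of truth for the behavioural equations. Frequencies are
#' per-weekday probabilities (`2/5` means twice per 5-weekday week). Durations
#' are exponential means in minutes unless noted. The day runs 09:00-20:00 at
#' 1-minute resolution; school occupies 09:00-15:00.
#'
#' @param F_as after-school play frequency (default 2/5).
#' @param F_friend friend-meeting initiation frequency (default 2/5).
#' @param F_neigh neighbourhood outdoor-play frequency (default 1/5).
#' @param F_shop shopping frequency (default 1/5).
#' @param play_duration_mean mean minutes of play/meeting episodes (70).
#' @param shop_duration_mean mean minutes of shopping (30).
#' @param fsa_duration fixed minutes of an organised sport session (60).
#' @param gamma proportion of friend meetings held outdoors (0.5).
#' @param delta peer-influence proportion of the activity tendency (0.3).
#' @param lambda presence-feedback weight per nearby outdoor player (0.1).
#' @param presence_radius radius (m, straight line) around the home within
#'   which playing agents are counted (300).
#' @param presence_threshold minimum nearby players for the feedback to act (3).
#' @param m_penalty multiplier on after-school play when driven home or when
#'   an organised sport session is scheduled (1/3).
#' @param lesson_minutes,recess_minutes,pe_minutes school-day blocks
#'   (320/40/60); PE happens once per week per school and displaces lesson
#'   minutes so that the 360-minute school day is preserved.
#' @param extra_pe_minutes additional daily PE minutes (scenario dial, 0).
#' @param day_start,school_end,day_end minutes of day (540, 900, 1200).
#' @param attempt_prob per-minute probability that an idle agent runs the
#'   spontaneous activity-selection procedure (1/15, i.e. 4 times/hour).
#' @param detour_max maximum route extension for after-school play sites (500 m).
#' @param shop_range shop search radius from home (1000 m, network).
#' @param shop_density_radius radius defining "denser shopping areas" (200 m).
#' @param fsa_range maximum network distance home to sport venue (1500 m).
#' @param alpha,beta site-ranking coefficients (1/700, 0.7).
#' @param walk_speed,car_speed m/min (33, 500).
#' @param travel_model coefficients for the walk-probability logistic, see
#'   [travel_model()].
#' @param force_walk_school,force_walk_all scenario flags forcing walking.
#' @param peer_influence `"transient"` (default): the peer-adjusted tendency is
#'   effective during the joint activity only; `"persistent"`: the adjustment
#'   mutates the agent's tendency for the rest of the run.
#' @param extra_guest_prob probability that each further eligible friend is
#'   invited to a hosted meeting beyond the first guest (0.2).
#' @param mvpa_table data.frame as [default_mvpa_table()].
#' @param pe_extends_day if TRUE extra PE is appended after 15:00 instead of
#'   displacing lesson minutes (FALSE).
#' @return object of class `pa_params` (a validated list).
#' @export
sim_params <- function(F_as = 2 / 5, F_friend = 2 / 5, F_neigh = 1 / 5,
                       F_shop = 1 / 5,
                       play_duration_mean = 70, shop_duration_mean = 30,
                       fsa_duration = 60,
                       gamma = 0.5, delta = 0.3, lambda = 0.1,
                       presence_radius = 300, presence_threshold = 3,
                       m_penalty = 1 / 3,
                       lesson_minutes = 320, recess_minutes = 40,
                       pe_minutes = 60, extra_pe_minutes = 0,
                       day_start = 540, school_end = 900, day_end = 1200,
                       attempt_prob = 1 / 15,
                       detour_max = 500, shop_range = 1000,
                       shop_density_radius = 200, fsa_range = 1500,
                       alpha = 1 / 700, beta = 0.7,
                       walk_speed = 33, car_speed = 500,
                       travel_model = NULL,
                       force_walk_school = FALSE, force_walk_all = FALSE,
                       peer_influence = c("transient", "persistent"),
                       extra_guest_prob = 0.2,
                       mvpa_table = default_mvpa_table(),
                       pe_extends_day = FALSE) {
  p <- list(
    F_as = F_as, F_friend = F_friend, F_neigh = F_neigh, F_shop = F_shop,
    play_duration_mean = play_duration_mean,
    shop_duration_mean = shop_duration_mean, fsa_duration = fsa_duration,
    gamma = gamma, delta = delta, lambda = lambda,
    presence_radius = presence_radius,
    presence_threshold = presence_threshold, m_penalty = m_penalty,
    lesson_minutes = lesson_minutes, recess_minutes = recess_minutes,
    pe_minutes = pe_minutes, extra_pe_minutes = extra_pe_minutes,
    day_start = day_start, school_end = school_end, day_end = day_end,
    attempt_prob = attempt_prob, detour_max = detour_max,
    shop_range = shop_range, shop_density_radius = shop_density_radius,
    fsa_range = fsa_range, alpha = alpha, beta = beta,
    walk_speed = walk_speed, car_speed = car_speed,
    travel_model = travel_model %||% travel_model_default(),
    force_walk_school = force_walk_school, force_walk_all = force_walk_all,
    peer_influence = match.arg(peer_influence),
    extra_guest_prob = extra_guest_prob,
    mvpa_table = mvpa_table, pe_extends_day = pe_extends_day
  )
  validate_params(p)
  class(p) <- "pa_params"
  p
}

validate_params <- function(p) {
  freqs <- c(p$F_as, p$F_friend, p$F_neigh, p$F_shop)
  if (any(freqs < 0 | freqs > 1)) stop_config("frequencies must lie in [0, 1]")
  if (p$gamma < 0 || p$gamma > 1) stop_config("gamma must lie in [0, 1]")
  if (p$delta < 0 || p$delta > 1) stop_config("delta must lie in [0, 1]")
  if (p$lambda < 0) stop_config("lambda must be >= 0")
  if (any(p$mvpa_table$girl < 0 | p$mvpa_table$girl > 1 |
          p$mvpa_table$boy < 0 | p$mvpa_table$boy > 1)) {
    stop_config("MVPA table values must lie in [0, 1]")
  }
  school_len <- p$school_end - p$day_start
  lesson_pe_day <- p$lesson_minutes - p$pe_minutes -
    if (p$pe_extends_day) 0 else p$extra_pe_minutes
  if (lesson_pe_day < 0) {
    stop_config("PE minutes exceed available lesson minutes on PE days")
  }
  if (p$lesson_minutes + p$recess_minutes != school_len) {
    stop_config("lesson + recess minutes must fill the %d-minute school day",
                school_len)
  }
  invisible(TRUE)
}

#' Read simulation parameters from a YAML configuration file
#'
#' Scalars override [sim_params()] defaults; an optional `mvpa_table` path
#' entry points to a CSV readable by [read_mvpa_table()].
#'
#' @param path YAML file path.
#' @return `pa_params` object.
#' @export
sim_params_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_config("the 'yaml' package is required to read YAML configs")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$mvpa_table) && is.character(cfg$mvpa_table)) {
    cfg$mvpa_table <- read_mvpa_table(cfg$mvpa_table)
  }
  do.call(sim_params, cfg)
}

#' @export
print.pa_params <- function(x, ...) {
  cat("Simulation parameters (pa_params)\n")
  cat(sprintf("  frequencies/day: after-school %.2f, friends %.2f, neighbourhood %.2f, shopping %.2f\n",
              x$F_as, x$F_friend, x$F_neigh, x$F_shop))
  cat(sprintf("  peer influence delta = %.2f (%s), presence lambda = %.2f (radius %gm, threshold %d)\n",
              x$delta, x$peer_influence, x$lambda, x$presence_radius,
              x$presence_threshold))
  cat(sprintf("  school day %02d:%02d-%02d:%02d, lessons %d + recess %d + weekly PE %d min",
              x$day_start %/% 60, x$day_start %% 60, x$school_end %/% 60,
              x$school_end %% 60, x$lesson_minutes, x$recess_minutes,
              x$pe_minutes))
  if (x$extra_pe_minutes > 0) cat(sprintf(" (+%d daily)", x$extra_pe_minutes))
  cat("\n")
  if (x$force_walk_all) {
    cat("  travel: all agents walk to all activities\n")
  } else if (x$force_walk_school) {
    cat("  travel: all agents walk to school\n")
  }
  invisible(x)
}
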