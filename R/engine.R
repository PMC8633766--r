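# Discrete-time daily engine. The school day (09:00-15:00) is deterministic
# block structure and is simulated in bulk; the after-school window runs at
# 1-minute resolution so that presence feedback, spontaneous activity
# selection and meeting coordination see live agent state. MVPA for an event
# of known duration and constant per-minute probability is drawn as a single
# binomial, which is distributionally identical to per-minute Bernoulli draws.

ACT_TYPES <- c("lesson", "recess", "pe", "fsa", "play_after_school",
               "play_neighbourhood", "friend_meeting_indoor",
               "friend_meeting_outdoor", "shopping", "walk", "car", "home")
T_LESSON <- 1L; T_RECESS <- 2L; T_PE <- 3L; T_FSA <- 4L; T_PLAY_AS <- 5L
T_PLAY_N <- 6L; T_MEET_IN <- 7L; T_MEET_OUT <- 8L; T_SHOP <- 9L
T_WALK <- 10L; T_CAR <- 11L; T_HOME <- 12L
OUTDOOR_PLAY_TYPES <- c(T_PLAY_AS, T_PLAY_N, T_MEET_OUT)
BIG <- 9999999L

# MVPA-table row for each activity type with a fixed kind (0 = use site kind)
type_kind <- function(mvpa_table) {
  kind_idx <- function(k) match(k, mvpa_table$kind)
  c(kind_idx("lesson"), kind_idx("recess"), kind_idx("pe"), kind_idx("fsa"),
    0L, 0L, kind_idx("home"), 0L, kind_idx("shop"), kind_idx("walk"),
    kind_idx("car"), kind_idx("home"))
}

#' Precompute the simulation context
#'
#' Assembles every static quantity the daily engine needs: node-to-node
#' network distances, per-agent commute routes and their walkability,
#' candidate site sets (after-school detour-bounded, neighbourhood, shops in
#' range with density weights), presence neighbourhoods, school PE days
#' (drawn here, one weekday per school) and the per-attempt trigger
#' probabilities, initialised from the analytic fallback and refined by
#' [calibrate_attempt_rates()].
#'
#' @param env `pa_environment`.
#' @param pop `pa_population`.
#' @param params `pa_params`.
#' @return a context list consumed by [run_day()].
#' @export
precompute_context <- function(env, pop, params = sim_params()) {
  ag <- pop$agents
  n <- nrow(ag)
  Dnn <- igraph::distances(env$graph, weights = igraph::E(env$graph)$weight)

  home_node <- env$sites$node[ag$home]
  school_node <- env$sites$node[ag$school]
  route_len <- Dnn[cbind(home_node, school_node)]

  # length-weighted mean walkability of the school route, cached per pair
  pair_key <- paste(home_node, school_node)
  route_walk <- numeric(n)
  walk_cache <- new.env()
  for (i in seq_len(n)) {
    k <- pair_key[i]
    if (is.null(walk_cache[[k]])) {
      walk_cache[[k]] <- route_walkability(env, home_node[i], school_node[i])
    }
    route_walk[i] <- walk_cache[[k]]
  }

  # zone-level mean walkability stands in for route walkability on the many
  # short non-school trips (documented modelling simplification)
  emidx <- (env$nodes$x[env$edges$from] + env$nodes$x[env$edges$to]) / 2
  emidy <- (env$nodes$y[env$edges$from] + env$nodes$y[env$edges$to]) / 2
  ezone <- vapply(seq_along(emidx), function(k) {
    which_zone(emidx[k], emidy[k], env$zone_polys)
  }, 0L)
  zone_walk <- vapply(seq_len(nrow(env$zones)), function(z) {
    w <- env$edges$walkability[which(ezone == z)]
    if (length(w) == 0) mean(env$edges$walkability) else mean(w)
  }, 0)

  od <- which(env$sites$kind %in% OUTDOOR_KINDS)
  if (length(od) == 0) stop_config("environment has no outdoor play sites")
  od_node <- env$sites$node[od]
  od_kind_idx <- match(env$sites$kind[od], params$mvpa_table$kind)
  D_home_od <- Dnn[home_node, od_node, drop = FALSE]
  D_school_od <- Dnn[school_node, od_node, drop = FALSE]

  as_cand <- lapply(seq_len(n), function(i) {
    which(candidates_after_school(D_school_od[i, ], D_home_od[i, ],
                                  route_len[i], params))
  })
  od_x <- env$sites$x[od]; od_y <- env$sites$y[od]
  nearby_od <- lapply(seq_len(n), function(i) {
    hx <- env$sites$x[ag$home[i]]; hy <- env$sites$y[ag$home[i]]
    which(euclid(hx, hy, od_x, od_y) <= params$presence_radius)
  })

  shops <- which(env$sites$kind == "shop")
  D_home_shop <- Dnn[home_node, env$sites$node[shops], drop = FALSE]
  shop_density <- vapply(seq_along(shops), function(j) {
    sum(euclid(env$sites$x[shops[j]], env$sites$y[shops[j]],
               env$sites$x[shops[-j]], env$sites$y[shops[-j]]) <=
        params$shop_density_radius)
  }, 0)

  D_home_fsa <- NULL
  if (!is.null(pop$fsa)) {
    venues <- sort(unique(as.integer(pop$fsa$venue[!is.na(pop$fsa$venue)])))
    if (length(venues) > 0) {
      D_home_fsa <- Dnn[home_node, env$sites$node[venues], drop = FALSE]
      colnames(D_home_fsa) <- as.character(venues)
    }
  }

  schools <- sort(unique(ag$school))
  pe_day <- sample(5, length(schools), replace = TRUE)
  names(pe_day) <- as.character(schools)

  gtab <- params$mvpa_table
  Ptab <- cbind(girl = gtab$girl, boy = gtab$boy)
  rownames(Ptab) <- gtab$kind

  friends_meanA <- vapply(seq_len(n), function(i) {
    f <- pop$friends[[i]]
    if (length(f) == 0) NA_real_ else mean(ag$A[f])
  }, 0)

  # analytic fallback for per-attempt trigger probabilities: half the idle
  # attempts go to each of the two spontaneous activities
  att0 <- params$attempt_prob * (params$day_end - params$school_end) * 0.5
  list(env = env, pop = pop, params = params, n = n,
       A = ag$A, O = ag$O, s = ag$s, n_cars = ag$n_cars,
       gender_col = ifelse(ag$gender == "girl", 1L, 2L),
       home = ag$home, home_node = home_node, school = ag$school,
       route_len = route_len, route_walk = route_walk,
       zone_walk_agent = zone_walk[ag$zone],
       friends = pop$friends, friends_meanA = friends_meanA,
       fsa_days = pop$fsa$days, fsa_venue = pop$fsa$venue,
       od = od, od_node = od_node, od_kind_idx = od_kind_idx,
       od_large = env$sites$large[od],
       D_home_od = D_home_od, D_school_od = D_school_od,
       D_home_home = Dnn[home_node, home_node, drop = FALSE],
       as_cand = as_cand, nearby_od = nearby_od,
       shops = shops, D_home_shop = D_home_shop,
       shop_density = shop_density, D_home_fsa = D_home_fsa,
       pe_day = pe_day, Ptab = Ptab, type_kind = type_kind(gtab),
       q_neigh = params$F_neigh / (0.5 * att0) / 2,
       q_shop = params$F_shop / (0.5 * att0) / 2,
       q_friend = params$F_friend)
}

route_walkability <- function(env, a, b) {
  if (a == b) return(mean(env$edges$walkability))
  sp <- igraph::shortest_paths(env$graph, from = a, to = b,
                               weights = igraph::E(env$graph)$weight,
                               output = "epath")
  ep <- sp$epath[[1]]
  lens <- igraph::edge_attr(env$graph, "weight", ep)
  walks <- igraph::edge_attr(env$graph, "walkability", ep)
  sum(lens * walks) / sum(lens)
}

#' Simulate one weekday for the whole population
#'
#' Follows the daily procedure: travel to school, the 09:00-15:00 school day
#' (lessons, recess, weekly PE), the after-school play decision at school
#' exit, travel home, scheduled sport sessions and friend meetings, and the
#' spontaneous selection loop (4 attempts/hour on average while idle at home)
#' until the day ends at 20:00. Events of one agent tile the day without gaps
#' or overlaps; the morning commute is logged with a start before 09:00.
#'
#' @param env `pa_environment` (ignored when `context` is supplied).
#' @param pop `pa_population` (ignored when `context` is supplied).
#' @param params `pa_params` (ignored when `context` is supplied).
#' @param weekday 1-5.
#' @param seed optional integer seed (set before any draw).
#' @param context optional precomputed context from [precompute_context()].
#' @return data.frame of activity events (`agent`, `type`, `site`, `start`,
#'   `duration`, `n_co`, `mvpa`) with attributes `clamp_count`, `attempts`,
#'   `episodes` and `meetings_hosted`.
#' @export
run_day <- function(env, pop, params = sim_params(), weekday = 1,
                    seed = NULL, context = NULL) {
  force(env); force(pop); force(params); force(context)
  if (!is.null(seed)) set.seed(seed)
  ctx <- context %||% precompute_context(env, pop, params)
  run_day_ctx(ctx, weekday)
}

run_day_ctx <- function(ctx, weekday) {
  params <- ctx$params
  n <- ctx$n
  A_live <- ctx$A
  school_out <- params$school_end +
    if (params$pe_extends_day) params$extra_pe_minutes else 0L
  day_end <- params$day_end

  # --- event buffer ---------------------------------------------------------
  cap <- n * 24L
  ev_agent <- integer(cap); ev_type <- integer(cap); ev_site <- integer(cap)
  ev_start <- integer(cap); ev_dur <- integer(cap); ev_nco <- integer(cap)
  ev_mvpa <- integer(cap)
  nev <- 0L
  clamp_count <- 0L
  recv <- function(agents, types, sites, starts, durs, ncos, aeff) {
    keep <- durs > 0
    if (!any(keep)) return(invisible(NULL))
    m <- length(keep)
    agents <- agents[keep]; types <- rep_len(types, m)[keep]
    sites <- rep_len(sites, m)[keep]; starts <- rep_len(starts, m)[keep]
    durs <- durs[keep]; ncos <- rep_len(ncos, m)[keep]
    aeff <- rep_len(aeff, m)[keep]
    k <- length(agents)
    kind <- ctx$type_kind[types]
    sitek <- which(kind == 0L)
    if (length(sitek) > 0) {
      kind[sitek] <- ctx$od_kind_idx[match(sites[sitek], ctx$od)]
    }
    p_raw <- aeff * ctx$Ptab[cbind(kind, ctx$gender_col[agents])]
    clamp_count <<- clamp_count + sum(p_raw > 1)
    while (nev + k > cap) {
      cap2 <- cap * 2L
      length(ev_agent) <<- cap2; length(ev_type) <<- cap2
      length(ev_site) <<- cap2; length(ev_start) <<- cap2
      length(ev_dur) <<- cap2; length(ev_nco) <<- cap2
      length(ev_mvpa) <<- cap2
      cap <<- cap2
    }
    idx <- nev + seq_len(k)
    ev_agent[idx] <<- agents; ev_type[idx] <<- types; ev_site[idx] <<- sites
    ev_start[idx] <<- starts; ev_dur[idx] <<- durs; ev_nco[idx] <<- ncos
    ev_mvpa[idx] <<- rbinom(k, durs, clamp(p_raw))
    nev <<- nev + k
    invisible(NULL)
  }

  # --- fixed morning and school blocks -------------------------------------
  fsa_today <- ctx$fsa_days[, weekday]
  params_sched <- params
  params_sched$F_friend <- ctx$q_friend %||% params$F_friend
  meetings <- schedule_friend_meetings(ctx$pop, fsa_today, params_sched)

  walk_school <- params$force_walk_school || params$force_walk_all
  p_walk_school <- if (walk_school) rep(1, n) else
    p_walk(ctx$route_len, ctx$route_walk, ctx$n_cars, "school",
           params$travel_model)
  morning_walks <- runif(n) < p_walk_school
  commute_min <- as.integer(ceiling(ctx$route_len /
    ifelse(morning_walks, params$walk_speed, params$car_speed)))
  recv(seq_len(n), ifelse(morning_walks, T_WALK, T_CAR), NA_integer_,
       params$day_start - commute_min, commute_min, 0L, A_live)

  pe_today <- unname(ctx$pe_day[as.character(ctx$school)] == weekday)
  extra_pe <- if (params$pe_extends_day) 0L else params$extra_pe_minutes
  pe_min <- ifelse(pe_today, params$pe_minutes, 0L) + extra_pe
  lesson_total <- (params$school_end - params$day_start) -
    params$recess_minutes - pe_min
  l1 <- lesson_total %/% 2L; l2 <- lesson_total - l1
  A_school <- ifelse(is.na(ctx$friends_meanA), A_live,
                     (1 - params$delta) * A_live +
                       params$delta * ctx$friends_meanA)
  n_friends <- lengths(ctx$friends)
  recv(seq_len(n), T_LESSON, NA_integer_, params$day_start, l1, 0L, A_live)
  recv(seq_len(n), T_RECESS, NA_integer_, params$day_start + l1,
       rep(params$recess_minutes, n), n_friends, A_school)
  recv(seq_len(n), T_LESSON, NA_integer_,
       params$day_start + l1 + params$recess_minutes, l2, 0L, A_live)
  recv(seq_len(n), T_PE, NA_integer_, params$school_end - pe_min, pe_min,
       n_friends, A_school)
  if (params$pe_extends_day && params$extra_pe_minutes > 0) {
    recv(seq_len(n), T_PE, NA_integer_, params$school_end,
         rep(params$extra_pe_minutes, n), n_friends, A_school)
  }

  # --- after-school decisions ----------------------------------------------
  p_walk_home <- if (walk_school) rep(1, n) else
    p_walk(ctx$route_len, ctx$route_walk, ctx$n_cars, "school",
           params$travel_model)
  walks_home <- runif(n) < p_walk_home
  driven_home <- !walks_home
  p_as <- p_after_school_play(ctx$O, ctx$s, driven_home, fsa_today, params)
  plays_as <- runif(n) < p_as

  # --- dynamic state --------------------------------------------------------
  act <- integer(n)                  # 0 = idle at home
  act_end <- rep(BIG, n)
  act_site <- rep(NA_integer_, n)
  idle_start <- rep(school_out, n)
  plans <- vector("list", n)
  occ <- numeric(length(ctx$od))     # outdoor players per site
  fsa_pending <- fsa_today
  att_play <- 0L; att_shop <- 0L; ep_play <- 0L; ep_shop <- 0L
  meetings_hosted <- 0L

  other_mode <- function(i, dist) {
    if (params$force_walk_all || ctx$n_cars[i] == 0) return("walk")
    p <- p_walk(dist, ctx$zone_walk_agent[i], ctx$n_cars[i], "other",
                params$travel_model)
    if (runif(1) < p) "walk" else "car"
  }
  tmin <- function(dist, mode) {
    as.integer(ceiling(dist / if (mode == "walk") params$walk_speed else
      params$car_speed))
  }
  start_step <- function(i, t) {
    repeat {
      pl <- plans[[i]]
      if (length(pl) == 0) { on_home(i, t); return(invisible(NULL)) }
      step <- pl[[1]]
      plans[[i]] <<- pl[-1]
      dur <- min(step$dur, day_end - t)
      if (dur <= 0) next
      act[i] <<- step$type; act_end[i] <<- t + dur
      act_site[i] <<- step$site %||% NA_integer_
      if (step$type %in% OUTDOOR_PLAY_TYPES) {
        j <- match(act_site[i], ctx$od)
        occ[j] <<- occ[j] + 1
      }
      recv(i, step$type, act_site[i], t, dur, step$nco %||% 0L,
           step$aeff %||% A_live[i])
      return(invisible(NULL))
    }
  }
  on_home <- function(i, t) {
    if (fsa_pending[i] && !is.null(ctx$D_home_fsa)) {
      fsa_pending[i] <<- FALSE
      venue <- ctx$fsa_venue[i, weekday]
      d <- ctx$D_home_fsa[i, as.character(venue)]
      mode <- other_mode(i, d)
      tt <- tmin(d, mode)
      dur <- min(params$fsa_duration, day_end - t - 2L * tt)
      if (dur >= 1) {
        mcode <- if (mode == "walk") T_WALK else T_CAR
        plans[[i]] <<- list(
          list(type = mcode, site = venue, dur = tt),
          list(type = T_FSA, site = venue, dur = dur),
          list(type = mcode, site = ctx$home[i], dur = tt))
        start_step(i, t)
        return(invisible(NULL))
      }
    }
    act[i] <<- 0L; act_end[i] <<- BIG; act_site[i] <<- NA_integer_
    idle_start[i] <<- t
  }
  close_idle <- function(i, t) {
    recv(i, T_HOME, ctx$home[i], idle_start[i], t - idle_start[i], 0L,
         A_live[i])
  }
  plan_episode <- function(i, t, type, site, dist) {
    mode <- other_mode(i, dist)
    tt <- tmin(dist, mode)
    maxd <- day_end - t - 2L * tt
    if (maxd < 1) return(FALSE)
    dur <- sample_duration(if (type == T_SHOP) "shop" else "play", params, 1,
                           maxd)
    mcode <- if (mode == "walk") T_WALK else T_CAR
    plans[[i]] <<- list(
      list(type = mcode, site = site, dur = tt),
      list(type = type, site = site, dur = dur),
      list(type = mcode, site = ctx$home[i], dur = tt))
    close_idle(i, t)
    start_step(i, t)
    TRUE
  }

  # seed the 15:00 state; players go first in a seed-shuffled order so that
  # site occupancy feeds back into later agents' choices
  for (i in sample.int(n)) {
    mcode <- if (walks_home[i]) T_WALK else T_CAR
    mode <- if (walks_home[i]) "walk" else "car"
    if (plays_as[i] && length(ctx$as_cand[[i]]) > 0) {
      cand <- ctx$as_cand[[i]]
      ranks <- rank_site(ctx$D_school_od[i, cand], occ[cand],
                         ctx$od_large[cand], params)
      pick <- cand[select_site(ranks)]
      tt1 <- tmin(ctx$D_school_od[i, pick], mode)
      tt2 <- tmin(ctx$D_home_od[i, pick], mode)
      maxd <- day_end - school_out - tt1 - tt2
      dur <- sample_duration("play", params, 1, maxd)
      plans[[i]] <- list(
        list(type = mcode, site = ctx$od[pick], dur = tt1),
        list(type = T_PLAY_AS, site = ctx$od[pick], dur = dur),
        list(type = mcode, site = ctx$home[i], dur = tt2))
    } else {
      plans[[i]] <- list(
        list(type = mcode, site = ctx$home[i],
             dur = tmin(ctx$route_len[i], mode)))
    }
    start_step(i, school_out)
  }

  # participants of a scheduled meeting keep their evening free (no
  # spontaneous episodes) until the meeting launches or is cancelled
  meet_pending <- rep(TRUE, length(meetings$host))
  reserved <- integer(n)
  for (mi in seq_along(meetings$host)) {
    mem <- c(meetings$host[mi], meetings$guests[[mi]])
    reserved[mem] <- reserved[mem] + 1L
  }

  # --- minute loop ----------------------------------------------------------
  for (t in seq.int(school_out, day_end - 1L)) {
    done <- which(act_end == t)
    if (length(done) > 0) {
      for (i in done[sample.int(length(done))]) {
        if (act[i] %in% OUTDOOR_PLAY_TYPES) {
          j <- match(act_site[i], ctx$od)
          occ[j] <- occ[j] - 1
        }
        start_step(i, t)
      }
    }

    # launch pending friend meetings whose host and >=1 guest are idle
    if (any(meet_pending)) {
      for (mi in which(meet_pending)) {
        h <- meetings$host[mi]
        if (act[h] != 0L) next
        gs <- meetings$guests[[mi]]
        gs <- gs[act[gs] == 0L]
        if (length(gs) == 0) next
        parts <- c(h, gs)
        outdoor <- runif(1) < p_outdoor_meeting(ctx$O[parts], ctx$s[h],
                                                params)
        if (outdoor) {
          ranks <- rank_site(ctx$D_home_od[h, ], occ, ctx$od_large, params)
          pick <- select_site(ranks)
          site <- ctx$od[pick]
          dists <- ctx$D_home_od[parts, pick]
          mtype <- T_MEET_OUT
        } else {
          site <- ctx$home[h]
          dists <- c(0, ctx$D_home_home[cbind(gs, rep(h, length(gs)))])
          mtype <- T_MEET_IN
        }
        modes <- vapply(seq_along(parts),
                        function(k) other_mode(parts[k], dists[k]), "")
        tts <- vapply(seq_along(parts),
                      function(k) tmin(dists[k], modes[k]), 0L)
        maxd <- day_end - t - 2L * max(tts)
        if (maxd < 1) {
          mem <- c(h, meetings$guests[[mi]])
          reserved[mem] <- reserved[mem] - 1L
          meet_pending[mi] <- FALSE
          next
        }
        dur <- sample_duration("meeting", params, 1, maxd)
        t_end <- t + max(tts) + dur
        for (k in seq_along(parts)) {
          p <- parts[k]
          af <- intersect(ctx$friends[[p]], setdiff(parts, p))
          aeff <- effective_tendency(A_live[p], A_live[af], params$delta)
          if (params$peer_influence == "persistent" && length(af) > 0) {
            A_live[p] <- aeff
          }
          mcode <- if (modes[k] == "walk") T_WALK else T_CAR
          plans[[p]] <- list(
            list(type = mcode, site = site, dur = tts[k]),
            list(type = mtype, site = site, dur = t_end - (t + tts[k]),
                 nco = length(parts) - 1L, aeff = aeff),
            list(type = mcode, site = ctx$home[p], dur = tts[k]))
          close_idle(p, t)
          start_step(p, t)
        }
        mem <- c(h, meetings$guests[[mi]])
        reserved[mem] <- reserved[mem] - 1L
        meetings_hosted <- meetings_hosted + 1L
        meet_pending[mi] <- FALSE
      }
    }

    # spontaneous activity selection while idle at home
    idle <- which(act == 0L & reserved == 0L)
    if (length(idle) > 0) {
      firing <- idle[runif(length(idle)) < params$attempt_prob]
      for (i in firing) {
        if (runif(1) < 0.5) {
          att_play <- att_play + 1L
          if (params$F_neigh <= 0 || ctx$q_neigh <= 0) next
          na <- sum(occ[ctx$nearby_od[[i]]])
          lam <- if (na >= params$presence_threshold) params$lambda else 0
          p_raw <- ctx$q_neigh * ctx$O[i] * ctx$s[i] * (1 + na * lam)
          if (p_raw > 1) clamp_count <- clamp_count + 1L
          if (runif(1) < clamp(p_raw)) {
            ranks <- rank_site(ctx$D_home_od[i, ], occ, ctx$od_large, params)
            pick <- select_site(ranks)
            if (plan_episode(i, t, T_PLAY_N, ctx$od[pick],
                             ctx$D_home_od[i, pick])) {
              ep_play <- ep_play + 1L
            }
          }
        } else {
          att_shop <- att_shop + 1L
          if (params$F_shop <= 0 || ctx$q_shop <= 0) next
          if (runif(1) < clamp(ctx$q_shop)) {
            sel <- select_shop(ctx$D_home_shop[i, ], ctx$shop_density,
                               params)
            if (plan_episode(i, t, T_SHOP, ctx$shops[sel$shop],
                             ctx$D_home_shop[i, sel$shop])) {
              ep_shop <- ep_shop + 1L
            }
          }
        }
      }
    }
  }

  for (i in which(act == 0L)) close_idle(i, day_end)

  idx <- seq_len(nev)
  ev <- data.frame(agent = ev_agent[idx], type = ACT_TYPES[ev_type[idx]],
                   site = ev_site[idx], start = ev_start[idx],
                   duration = ev_dur[idx], n_co = ev_nco[idx],
                   mvpa = ev_mvpa[idx], stringsAsFactors = FALSE)
  attr(ev, "clamp_count") <- clamp_count
  attr(ev, "attempts") <- c(play = att_play, shop = att_shop)
  attr(ev, "episodes") <- c(play = ep_play, shop = ep_shop)
  attr(ev, "meetings_hosted") <- meetings_hosted
  ev
}
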