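# Synthetic agent population: demographics from zone-level distributions,
# behavioural attributes A (tendency to be active) and O (outdoor-play
# preference), formal sport activities (FSA) by socio-economic position, and a
# within-school friendship network.

SEP_LEVELS <- c("AB", "C1", "C2", "DE")

#' Population configuration
#'
#' Zone-level demographic distributions and attribute parameters. The default
#' SEP and car distributions follow the zone's deprivation quintile (affluent
#' zones carry more AB households and more cars); both can be overridden with
#' explicit per-quintile probability tables. FSA weekly session means are in a
#' 2:1 ratio between the highest (AB) and lowest (DE) SEP bands.
#'
#' @param sep_by_quintile 5 x 4 matrix of probabilities over
#'   `c("AB","C1","C2","DE")`, one row per deprivation quintile.
#' @param cars_by_quintile 5 x 3 matrix of probabilities over 0/1/2 household
#'   cars, one row per quintile.
#' @param fsa_mean_per_sep named numeric, mean weekly sport sessions by SEP
#'   (truncated-Poisson means; default AB 2, C1 1.6, C2 1.3, DE 1).
#' @param gender_prob probability of assigning `girl` (0.5).
#' @param A_mean,A_sd,O_mean,O_sd normal parameters of the activity tendency
#'   and outdoor preference (1 and 0.3); draws are truncated positive by
#'   resampling.
#' @param agents_per_home agents created per residential building (1).
#' @return object of class `population_config`.
#' @export
population_config <- function(sep_by_quintile = NULL, cars_by_quintile = NULL,
                              fsa_mean_per_sep = c(AB = 2, C1 = 1.6,
                                                   C2 = 1.3, DE = 1),
                              gender_prob = 0.5,
                              A_mean = 1, A_sd = 0.3, O_mean = 1, O_sd = 0.3,
                              agents_per_home = 1) {
  if (is.null(sep_by_quintile)) {
    sep_by_quintile <- rbind(
      c(0.40, 0.30, 0.20, 0.10),
      c(0.32, 0.28, 0.25, 0.15),
      c(0.25, 0.25, 0.25, 0.25),
      c(0.15, 0.25, 0.28, 0.32),
      c(0.10, 0.20, 0.30, 0.40))
  }
  if (is.null(cars_by_quintile)) {
    cars_by_quintile <- rbind(
      c(0.10, 0.45, 0.45),
      c(0.18, 0.47, 0.35),
      c(0.28, 0.47, 0.25),
      c(0.40, 0.45, 0.15),
      c(0.55, 0.37, 0.08))
  }
  colnames(sep_by_quintile) <- SEP_LEVELS
  if (any(abs(rowSums(sep_by_quintile) - 1) > 1e-8) ||
      any(abs(rowSums(cars_by_quintile) - 1) > 1e-8)) {
    stop_config("zone-level distributions must sum to 1")
  }
  if (any(sep_by_quintile < 0) || any(cars_by_quintile < 0)) {
    stop_config("probabilities must be non-negative")
  }
  if (!all(SEP_LEVELS %in% names(fsa_mean_per_sep))) {
    stop_config("fsa_mean_per_sep must name all of %s",
                paste(SEP_LEVELS, collapse = ", "))
  }
  cfg <- list(sep_by_quintile = sep_by_quintile,
              cars_by_quintile = cars_by_quintile,
              fsa_mean_per_sep = fsa_mean_per_sep[SEP_LEVELS],
              gender_prob = gender_prob,
              A_mean = A_mean, A_sd = A_sd, O_mean = O_mean, O_sd = O_sd,
              agents_per_home = agents_per_home)
  class(cfg) <- "population_config"
  cfg
}

# positive-truncated normal via resampling; sd = 0 collapses to the mean
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Synthesise the agent population
#'
#' Creates one agent per home (or `agents_per_home`), assigns the catchment
#' school of the home zone, draws SEP and household cars from the zone's
#' quintile-specific distributions, gender with `gender_prob`, and the
#' behavioural attributes A and O from truncated normals. Then assigns weekly
#' sport sessions ([assign_fsa()]) and builds the within-school friendship
#' network ([build_friendship_network()]). Deterministic for fixed `seed`.
#'
#' @param env `pa_environment`.
#' @param cfg `population_config`.
#' @param seed integer seed.
#' @return object of class `pa_population`: a list with `agents` (data.frame),
#'   `friends` (adjacency list), and `fsa` (weekday/venue assignment).
#' @export
synthesize_agents <- function(env, cfg = population_config(), seed = 1) {
  force(env); force(cfg)      # arguments may carry RNG-consuming promises
  set.seed(derive_seed(seed, 1))
  homes <- which(env$sites$kind == "home")
  home_idx <- rep(homes, each = cfg$agents_per_home)
  n <- length(home_idx)
  zone <- env$sites$zone[home_idx]
  q <- env$zones$simd_quintile[zone]
  sep <- vapply(q, function(qi) {
    sample(SEP_LEVELS, 1, prob = cfg$sep_by_quintile[qi, ])
  }, "")
  n_cars <- vapply(q, function(qi) {
    sample(0:(ncol(cfg$cars_by_quintile) - 1), 1,
           prob = cfg$cars_by_quintile[qi, ])
  }, 0L)
  gender <- ifelse(runif(n) < cfg$gender_prob, "girl", "boy")
  A <- rnorm_pos(n, cfg$A_mean, cfg$A_sd)
  O <- rnorm_pos(n, cfg$O_mean, cfg$O_sd)
  school <- env$catchments$school[zone]

  agents <- data.frame(
    id = paste0("ag", seq_len(n)), home = home_idx, zone = zone,
    simd_quintile = q, s = env$zones$s[zone], school = school,
    sep = sep, n_cars = n_cars, gender = gender, A = A, O = O,
    stringsAsFactors = FALSE)

  pop <- list(agents = agents, friends = NULL, fsa = NULL)
  class(pop) <- "pa_population"
  pop <- assign_fsa(pop, env, cfg, seed = derive_seed(seed, 2))
  pop <- build_friendship_network(pop, seed = derive_seed(seed, 3))
  pop
}

#' Assign weekly formal sport activity (FSA) sessions
#'
#' Weekly session counts are drawn from a Poisson truncated at 5 with a
#' per-SEP mean (higher SEP participates more; default means give the 2:1
#' AB:DE ratio). Sessions are placed on distinct weekdays at a venue of kind
#' leisure centre, sports field or school within 1.5 km network distance of
#' the home; when no venue is in range the nearest one is used and a warning
#' is recorded in `pop$fsa$fallback`.
#'
#' @param pop `pa_population` (agents already created).
#' @param env `pa_environment`.
#' @param cfg `population_config`.
#' @param seed integer seed.
#' @return updated `pa_population`.
#' @export
assign_fsa <- function(pop, env, cfg = population_config(), seed = 1) {
  force(pop); force(env); force(cfg)
  set.seed(seed)
  ag <- pop$agents
  n <- nrow(ag)
  venues <- which(env$sites$kind %in% FSA_KINDS)
  # network distances home-node -> venue-node
  home_nodes <- unique(env$sites$node[ag$home])
  venue_nodes <- unique(env$sites$node[venues])
  Du <- igraph::distances(env$graph, v = home_nodes, to = venue_nodes,
                          weights = igraph::E(env$graph)$weight)
  D <- Du[, match(env$sites$node[venues], venue_nodes), drop = FALSE]
  rownames(D) <- as.character(home_nodes)

  counts <- integer(n); days <- matrix(FALSE, n, 5)
  venue_of <- matrix(NA_integer_, n, 5)
  fallback <- 0L
  fsa_range <- 1500
  for (i in seq_len(n)) {
    mu <- cfg$fsa_mean_per_sep[[ag$sep[i]]]
    k <- if (mu <= 0) 0L else min(rpois(1, mu), 5L)
    counts[i] <- k
    if (k == 0) next
    di <- D[as.character(env$sites$node[ag$home[i]]), ]
    elig <- which(di <= fsa_range)
    if (length(elig) == 0) { elig <- which.min(di); fallback <- fallback + 1L }
    wd <- sample(5, k)
    days[i, wd] <- TRUE
    venue_of[i, wd] <- venues[sample(rep(elig, 2), k, replace = TRUE)]
  }
  ag$fsa_count <- counts
  pop$agents <- ag
  pop$fsa <- list(days = days, venue = venue_of, fallback = fallback)
  pop
}

#' Build the within-school friendship network
#'
#' Each agent is given 3-8 best friends among pupils of the same school via a
#' degree-constrained stub-matching random graph (target degrees uniform on
#' 3..8, capped at school size minus one). Friendship is symmetric and never
#' crosses schools.
#'
#' @param pop `pa_population`.
#' @param seed integer seed.
#' @return updated `pa_population` with `friends` as an adjacency list.
#' @export
build_friendship_network <- function(pop, seed = 1) {
  force(pop)
  set.seed(seed)
  ag <- pop$agents
  n <- nrow(ag)
  adj <- vector("list", n)
  for (sch in unique(ag$school)) {
    members <- which(ag$school == sch)
    m <- length(members)
    if (m < 2) next
    cap <- min(8L, m - 1L)
    lo <- min(3L, cap)
    edges <- school_friend_edges(m, lo, cap)
    for (e in seq_len(nrow(edges))) {
      a <- members[edges[e, 1]]; b <- members[edges[e, 2]]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  pop$friends <- lapply(adj, function(v) sort(unique(v)))
  pop
}

# stub-matching with retries; returns a 2-column matrix of within-school edges
school_friend_edges <- function(m, lo, hi) {
  for (attempt in 1:50) {
    deg <- sample(lo:hi, m, replace = TRUE)
    if (sum(deg) %% 2 == 1) {
      idx <- sample.int(m, 1)
      deg[idx] <- if (deg[idx] < hi) deg[idx] + 1L else deg[idx] - 1L
    }
    if (sum(deg) %% 2 == 1) next
    stubs <- rep(seq_len(m), deg)
    stubs <- sample(stubs)
    pairs <- matrix(stubs, ncol = 2)
    bad <- pairs[, 1] == pairs[, 2] |
      duplicated(cbind(pmin(pairs[, 1], pairs[, 2]),
                       pmax(pairs[, 1], pairs[, 2])))
    if (!any(bad)) return(pairs)
  }
  # fallback: greedy pairing ignoring exact degree targets
  edges <- matrix(0L, 0, 2)
  deg <- integer(m)
  target <- sample(lo:hi, m, replace = TRUE)
  ord <- sample.int(m)
  for (a in ord) {
    need <- target[a] - deg[a]
    if (need <= 0) next
    cand <- setdiff(which(deg < target), a)
    cand <- cand[!cand %in% edges[edges[, 1] == a, 2] &
                 !cand %in% edges[edges[, 2] == a, 1]]
    take <- head(cand[order(deg[cand])], need)
    for (b in take) {
      edges <- rbind(edges, c(a, b))
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    }
  }
  edges
}

#' Write a population to CSV
#'
#' One row per agent (id, zone, sep, gender, cars, A, O, fsa_count) plus a
#' two-column friendship edge list.
#'
#' @param pop `pa_population`.
#' @param agents_file,edges_file output CSV paths.
#' @return invisible NULL.
#' @export
write_population_csv <- function(pop, agents_file, edges_file) {
  ag <- pop$agents
  write.csv(ag[, c("id", "zone", "sep", "gender", "n_cars", "A", "O",
                   "fsa_count")], agents_file, row.names = FALSE)
  el <- do.call(rbind, lapply(seq_along(pop$friends), function(i) {
    js <- pop$friends[[i]]
    js <- js[js > i]
    if (length(js) == 0) return(NULL)
    cbind(i, js)
  }))
  write.csv(data.frame(from = el[, 1], to = el[, 2]), edges_file,
            row.names = FALSE)
  invisible(NULL)
}

#' @export
print.pa_population <- function(x, ...) {
  ag <- x$agents
  cat(sprintf("Agent population: %d children in %d schools\n",
              nrow(ag), length(unique(ag$school))))
  cat("  SEP:", paste(sprintf("%s=%.0f%%", SEP_LEVELS,
                              100 * prop.table(table(factor(ag$sep, SEP_LEVELS)))),
                      collapse = " "), "\n")
  deg <- lengths(x$friends)
  cat(sprintf("  friends per agent: %d-%d (mean %.1f); mean weekly FSA %.2f\n",
              min(deg), max(deg), mean(deg), mean(ag$fsa_count)))
  invisible(x)
}
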