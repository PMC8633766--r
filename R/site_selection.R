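# Rank-based site choice: exponential distance decay, presence attraction and
# a large-area bonus, followed by a sequential roulette over the ranked list.

#' Rank a candidate outdoor site
#'
#' `R = 0.6 * exp(-d * alpha) + 0.2 * exp(-beta / v) + 0.2 * a`, with
#' `alpha = 1/700` and `beta = 0.7`, distance `d` in metres, visitor count
#' `v` and the large-area flag `a` (area above 10,000 m^2). The presence term
#' is defined as 0 when `v = 0`, so an empty site gains nothing, and
#' increases towards 0.2 as more agents visit.
#'
#' @param d_j network distance to the site, metres.
#' @param v_j number of other agents currently at the site.
#' @param a_j 0/1 large-area flag.
#' @param params `pa_params` (supplies `alpha`, `beta`).
#' @return rank in `[0, 1]` (vectorised).
#' @export
rank_site <- function(d_j, v_j, a_j, params = sim_params()) {
  presence <- ifelse(v_j > 0, exp(-params$beta / v_j), 0)
  0.6 * exp(-d_j * params$alpha) + 0.2 * presence + 0.2 * a_j
}

#' Select a site by sequential roulette
#'
#' Candidates are examined in descending rank (ties broken by index); the
#' site under examination is accepted with probability `R_j / sum(R)`. When a
#' full pass rejects every candidate the examination wraps to the top and
#' repeats, so a site is selected almost surely. Zero-rank candidates are
#' dropped; if all ranks are zero the choice is uniform.
#'
#' @param ranks numeric vector of ranks (`>= 0`).
#' @return index into `ranks` of the selected candidate.
#' @export
select_site <- function(ranks) {
  stopifnot(length(ranks) > 0)
  keep <- which(ranks > 0)
  if (length(keep) == 0) return(sample.int(length(ranks), 1))
  ord <- keep[order(-ranks[keep])]
  q <- ranks[ord] / sum(ranks[ord])
  repeat {
    u <- runif(length(ord))
    hit <- which(u < q)
    if (length(hit) > 0) return(ord[hit[1]])
  }
}

# closed-form selection distribution of the sequential-wrap roulette;
# used by callers wanting the analytic law (and by the test oracle's dual)
roulette_distribution <- function(ranks) {
  q <- ranks / sum(ranks)
  miss <- cumprod(c(1, 1 - q))[seq_along(q)]
  first_pass <- miss * q
  first_pass / (1 - prod(1 - q))
}

#' Candidate sites for after-school play
#'
#' Outdoor-kind sites (garden, sports field, park, residential amenity) whose
#' visit extends the route home from school by at most `detour_max`
#' (default 500 m, about 15 minutes of walking): network distance
#' school-to-site plus site-to-home minus the direct route length.
#'
#' @param d_school_site,d_site_home numeric vectors of network distances (m)
#'   for each outdoor site.
#' @param route_home_length direct school-to-home network distance (m).
#' @param params `pa_params`.
#' @return logical vector marking admissible candidates.
#' @export
candidates_after_school <- function(d_school_site, d_site_home,
                                    route_home_length,
                                    params = sim_params()) {
  d_school_site + d_site_home - route_home_length <= params$detour_max
}

#' Select a shop, weighting denser shopping areas
#'
#' Among shops within `shop_range` (1000 m network distance) of home, a shop
#' is drawn with weight `1 + (number of other shops within
#' shop_density_radius of it)`, so members of shopping clusters are selected
#' more often. With no shop in range the nearest shop is used (fallback).
#'
#' @param d_home_shop network distances home to every shop (m).
#' @param shop_density per-shop count of other shops within the density
#'   radius.
#' @param params `pa_params`.
#' @return list with `shop` (index) and `fallback` (logical).
#' @export
select_shop <- function(d_home_shop, shop_density, params = sim_params()) {
  if (length(d_home_shop) == 0) stop_config("environment contains no shops")
  inrange <- which(d_home_shop <= params$shop_range)
  fallback <- FALSE
  if (length(inrange) == 0) {
    inrange <- which.min(d_home_shop)
    fallback <- TRUE
  }
  w <- 1 + shop_density[inrange]
  pick <- if (length(inrange) == 1) inrange else
    sample(inrange, 1, prob = w)
  list(shop = pick, fallback = fallback)
}
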