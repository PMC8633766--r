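# Shared fixtures, built once per test run and cached.

.fixtures <- new.env()

cached <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# small city: 6 zones, 48 homes, 2 schools of 24 pupils
small_env <- function() {
  cached("small_env", function() {
    synthetic_city(city_spec(nx = 3, ny = 2, homes_per_zone = 8, schools = 2,
                             parks = 2, sports_fields = 2, gardens = 3,
                             amenities = 2, leisure_centres = 1, shops = 4),
                   seed = 42)
  })
}

small_pop <- function() {
  cached("small_pop", function() {
    synthesize_agents(small_env(), population_config(), seed = 42)
  })
}

# default-sized city + population used by the heavier acceptance checks
default_env <- function() {
  cached("default_env", function() synthetic_city(city_spec(), seed = 7))
}

default_pop <- function() {
  cached("default_pop", function() {
    synthesize_agents(default_env(), population_config(), seed = 7)
  })
}

# study conditions for the frequency-fidelity checks: no sport sessions, no
# cars (all walk), O = 1, s = 1
flat_pop <- function() {
  cached("flat_pop", function() {
    cfg <- population_config(
      fsa_mean_per_sep = c(AB = 0, C1 = 0, C2 = 0, DE = 0), O_sd = 0,
      cars_by_quintile = matrix(rep(c(1, 0, 0), each = 5), 5, 3))
    pop <- synthesize_agents(default_env(), cfg, seed = 3)
    pop$agents$s <- 1
    pop
  })
}

# paired-seed scenario runs on the default city, shared between the scenario
# ordering and the correlation-structure checks
scenario_run <- function(id, days = 10, reps = 5, seed = 2024) {
  cached(paste0("run_", id, "_", days, "_", reps, "_", seed), function() {
    run_experiment(default_env(), default_pop(), id, days = days,
                   reps = reps, seed = seed)
  })
}

pop_mean <- function(run) mean(colMeans(run$rep_mean_daily))
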