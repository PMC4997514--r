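# Synthetic constituents and randomized partitioning problems used across
# the suite.  A synthetic constituent is anchored so that its saturation
# pressure at 298.15 K equals `psat_298` exactly (August form, C = 0).

synthetic_constituent <- function(name, psat_298, molar_mass = 100,
                                  gamma = 1, liquid_density = 1000) {
  B <- 3000
  A <- log10(psat_298) + B / 298.15
  constituent(name, molar_mass, c(A, B, 0), c(250, 400),
              gamma = gamma, liquid_density = liquid_density)
}

# Random small partitioning problem spanning sub- and supersaturated
# regimes.  Caller controls the RNG seed.
random_partition_problem <- function(k, temperature = 298.15) {
  specs <- lapply(seq_len(k), function(i)
    synthetic_constituent(paste0("s", i),
                          psat_298 = 10^stats::runif(1, -3, 2),
                          molar_mass = stats::runif(1, 20, 200),
                          gamma = stats::runif(1, 0.5, 2)))
  masses <- 10^stats::runif(k, 1, 4)
  volume <- 10^stats::runif(1, -2, 1.5)
  partition_problem(masses, specs, temperature, volume)
}

# Constant-rate single-tracer scenario on a dry chamber (no water
# background), for comparison with the closed-form single-zone solution
# C(t) = S/Q_a (1 - exp(-ACH t)).
tracer_scenario <- function(rate_ug_h, ach = 3, volume = 50,
                            duration = 2 * 3600, usage_duration = duration,
                            name = "tracer") {
  ch <- chamber_spec(volume, ach = ach, temperature = 298.15,
                     room_rh = 0, vent_rh = 0)
  # choose puff bookkeeping so that total mass / usage time = rate
  pph <- 60
  puff_ug <- rate_ug_h / pph
  src <- puff_source("exhaled", puff_aerosol_mass_mg = puff_ug / 1e3,
                     composition = c(tracer = 1),
                     exhaled_fractions = c(tracer = 1),
                     participants = 1, puffs_per_hour = pph,
                     usage_duration_s = usage_duration)
  evp_scenario(ch, src, duration = duration, name = name)
}

tracer_constituents <- function(psat_298 = 100) {
  list(tracer = synthetic_constituent("tracer", psat_298),
       water = default_constituents()$water)
}

conservation_error <- function(sim) {
  tot_in <- sim$cumulative_emitted + sim$initial_mass
  max(abs(sim$final_mass + sim$cumulative_vented - tot_in) /
        pmax(tot_in, 1e-300))
}
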