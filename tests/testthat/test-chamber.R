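test_that("chamber spec derives ventilation consistently and validates", {
  ch <- chamber_spec(113, fresh_air_flow = 255)
  expect_equal(ch$ach, 255 / 113)
  ch2 <- chamber_spec(39, ach = 6.81)
  expect_equal(ch2$fresh_air_flow, 39 * 6.81)
  expect_error(chamber_spec(39), "exactly one")
  expect_error(chamber_spec(39, ach = 2, fresh_air_flow = 78),
               "exactly one")
  expect_error(chamber_spec(-1, ach = 2), "volume")
  expect_error(chamber_spec(39, ach = 2, room_rh = 1.2), "humidities")
})

test_that("concentration is total mass over volume", {
  expect_equal(concentration(395.5, 113), 3.5)
  expect_equal(concentration(0, 113), 0)
  expect_equal(concentration(500, 50), 2 * concentration(500, 100))
  expect_error(concentration(-1, 10), "non-negative")
})

test_that("one explicit step removes Q_a dt C of a decaying pulse", {
  # impulse of 1000 ug at t=0 into a dry room with Q_a dt / V = 0.1
  ch <- chamber_spec(10, fresh_air_flow = 0.1 * 10 * 3600 / 10,
                     temperature = 298.15, room_rh = 0, vent_rh = 0)
  src <- puff_source("machine", puff_aerosol_mass_mg = 1,
                     composition = c(tracer = 1),
                     session_times_s = 0, puffs_per_session = 1,
                     puff_interval_s = 10)
  sc <- evp_scenario(ch, src, duration = 30, dt = 10)
  sim <- simulate_chamber(sc, constituents = tracer_constituents(),
                          emission_mode = "impulse")
  m <- sim$concentration[, "tracer"] * ch$volume
  expect_equal(unname(m), c(0, 1000, 900, 810))
})

test_that("constant-source run matches the closed-form single-zone solution", {
  S <- 3600            # ug/h
  ach <- 3
  sc <- tracer_scenario(S, ach = ach, volume = 50, duration = 2 * 3600)
  sim <- simulate_chamber(sc, constituents = tracer_constituents())
  Qa <- ach * 50
  analytic <- S / Qa * (1 - exp(-ach * sim$times / 3600))
  got <- sim$concentration[, "tracer"]
  sel <- sim$times > 0
  expect_lt(max(abs(got[sel] - analytic[sel]) / analytic[sel]), 0.01)
})

test_that("after cessation the trajectory decays exponentially at the air-change rate", {
  ach <- 2.25
  sc <- tracer_scenario(3600, ach = ach, volume = 50,
                        duration = 5400, usage_duration = 1800)
  sim <- simulate_chamber(sc, constituents = tracer_constituents())
  cc <- sim$concentration[, "tracer"]
  i0 <- which(sim$times == 1800)
  sel <- sim$times > 1800
  analytic <- cc[i0] * exp(-ach * (sim$times[sel] - 1800) / 3600)
  expect_lt(max(abs(cc[sel] - analytic) / analytic), 0.01)
})

test_that("global mass conservation holds to 1e-9 for every constituent", {
  sim <- simulate_chamber(builtin_scenario("czogala_run1"))
  expect_lt(conservation_error(sim), 1e-9)
  expect_true(all(sim$concentration >= 0))
  expect_true(all(sim$liquid >= 0) && all(sim$vapor >= 0))
  expect_true(all(diff(sim$times) > 0))
})

test_that("trajectories superpose linearly in the emission schedule", {
  sc1 <- tracer_scenario(1800, ach = 2, volume = 40, duration = 3600)
  sc2 <- modify_scenario(sc1, puffs_per_hour = 120)  # doubled source
  cst <- tracer_constituents()
  c1 <- simulate_chamber(sc1, constituents = cst)$concentration[, "tracer"]
  c2 <- simulate_chamber(sc2, constituents = cst)$concentration[, "tracer"]
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("an empty schedule leaves room water at its ventilation equilibrium", {
  ch <- chamber_spec(30, ach = 2, temperature = 296.15, room_rh = 0.4,
                     vent_rh = 0.4)
  src <- puff_source("exhaled", puff_aerosol_mass_mg = 5,
                     composition = c(tracer = 1),
                     exhaled_fractions = c(tracer = 0),
                     participants = 1, puffs_per_hour = 10,
                     usage_duration_s = 3600)
  sc <- evp_scenario(ch, src, duration = 3600)
  sim <- simulate_chamber(sc, constituents = tracer_constituents())
  w <- sim$concentration[, "water"]
  expect_equal(max(w), min(w), tolerance = 1e-12)
  expect_identical(max(sim$concentration[, "tracer"]), 0)
})

test_that("steady-state concentration is S/Q_a with a defined zero-flow error", {
  ch <- chamber_spec(113, fresh_air_flow = 255)
  expect_equal(steady_state_concentration(ch, 255), 1)
  expect_equal(steady_state_concentration(ch, 510), 2)
  expect_error(steady_state_concentration(chamber_spec(10, ach = 0), 100),
               "ventilation")
})

test_that("time to a fraction of steady state matches the first-order closed form", {
  ach <- 2.25
  sc <- tracer_scenario(3600, ach = ach, volume = 50, duration = 4 * 3600)
  sim <- simulate_chamber(sc, constituents = tracer_constituents())
  expect_identical(time_to_fraction_of_steady_state(sim, "tracer", 0), 0)
  # fraction 1 - 1/e crosses at 1/ACH hours
  t63 <- time_to_fraction_of_steady_state(sim, "tracer", 1 - exp(-1))
  expect_equal(t63 / 3600, 1 / ach, tolerance = 0.02)
  t98 <- time_to_fraction_of_steady_state(sim, "tracer", 0.98)
  expect_equal(t98 / 60, log(50) / ach * 60, tolerance = 0.03)
  expect_error(time_to_fraction_of_steady_state(sim, "nope", 0.5),
               "not in the result")
})

test_that("particle diameter follows the cube-root volume relation", {
  d <- mean_particle_diameter(1000, 1e6, 1000)
  # eight-fold reduction in per-particle mass halves the diameter
  expect_equal(mean_particle_diameter(125, 1e6, 1000), d / 2)
  expect_equal(mean_particle_diameter(1000, 8e6, 1000), d / 2)
  expect_error(mean_particle_diameter(100, 0, 1000), "positive")
  # diameter of a single 6.545e-14 g droplet of unit-density liquid: 0.5 um
  expect_equal(mean_particle_diameter(pi / 6 * 0.5e-6^3 * 1e12, 1, 1000),
               0.5, tolerance = 1e-9)
})

test_that("released droplets evaporate to (near) nothing within one step in the exposure chamber", {
  sim <- simulate_chamber(builtin_scenario("mEEC_baseline"),
                          duration = 600)
  # after the first 10 s step the mean diameter has collapsed from 0.5 um
  expect_lt(sim$particle_diameter[2], 0.05)
})

test_that("total concentrations are invariant under activity-coefficient perturbation", {
  consts <- default_constituents()
  perturb <- function(f) lapply(consts, function(sp)
    constituent(sp$name, sp$molar_mass, sp$antoine, sp$t_range,
                gamma = sp$gamma * f, liquid_density = sp$liquid_density))
  sc <- builtin_scenario("mEEC_baseline")
  base <- simulate_chamber(sc, duration = 3600, constituents = consts)
  up <- simulate_chamber(sc, duration = 3600,
                         constituents = perturb(1.5))
  dn <- simulate_chamber(sc, duration = 3600,
                         constituents = perturb(0.5))
  expect_equal(up$concentration, base$concentration, tolerance = 1e-12)
  expect_equal(dn$concentration, base$concentration, tolerance = 1e-12)
})

test_that("too-coarse stepping is flagged rather than silently wrong", {
  # a decaying pulse under > 1 air change per step would go negative
  ch <- chamber_spec(10, ach = 450, temperature = 298.15, room_rh = 0,
                    vent_rh = 0)
  src <- puff_source("machine", puff_aerosol_mass_mg = 1,
                     composition = c(tracer = 1),
                     session_times_s = 0, puffs_per_session = 1)
  sc <- evp_scenario(ch, src, duration = 60, dt = 10)
  expect_warning(
    expect_error(simulate_chamber(sc, constituents = tracer_constituents(),
                                  emission_mode = "impulse"),
                 "reduce 'dt'"),
    "air changes per step")
})

test_that("simulation results expose tidy accessors", {
  sim <- simulate_chamber(builtin_scenario("czogala_run2"))
  df <- as.data.frame(sim)
  expect_true(all(c("time_s", "nicotine_ug_m3", "nicotine_liquid_ug",
                    "nicotine_vapor_ug", "particle_diameter_um") %in%
                    names(df)))
  expect_identical(nrow(df), length(sim$times))
  sm <- summary(sim)
  expect_identical(sm$constituent, sim$constituents)
  expect_true(all(sm$peak_ug_m3 >= sm$mean_ug_m3 - 1e-12))
  expect_output(print(sim), "chamber_sim")
})
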