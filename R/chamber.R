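# Transient well-mixed single-zone chamber simulation.
#
# Explicit per-step mass balance for each constituent,
#   m_i(t + dt) = m_i(t) + mdot_in,i dt - Q_a dt C_i(t),  C_i = m_i / V_r,
# followed by re-partitioning of the new totals between droplet and vapor
# phase.  Removal acts on the total concentration C_i regardless of phase,
# so total-mass trajectories are independent of the partitioning (and of
# the activity coefficients); the partition determines the phase split and
# the particle diameter only.  Water additionally receives ventilation-air
# moisture inflow and starts from the room's relative humidity.

#' Define the room / chamber
#'
#' Exactly one of `ach` (air changes per hour) or `fresh_air_flow`
#' (m^3/h) must be given; the other is derived via
#' `fresh_air_flow = ach * volume`.  Only fresh air counts as removal;
#' recirculated air merely mixes and is not represented.
#'
#' @param volume Room volume in m^3 (include recirculation duct volume if
#'   relevant).
#' @param ach Air-change rate, 1/h.
#' @param fresh_air_flow Fresh-air ventilation flow, m^3/h.
#' @param temperature Air temperature in K (constant; released aerosol is
#'   assumed not to perturb it).
#' @param room_rh Initial relative humidity of the room air, in \[0, 1\].
#' @param vent_rh Relative humidity of the ventilation (fresh) air.
#' @return An object of class `"chamber_spec"`.
#' @examples
#' chamber_spec(113, fresh_air_flow = 255)  # ACH 2.26
#' @export
chamber_spec <- function(volume, ach = NULL, fresh_air_flow = NULL,
                         temperature = 293.15, room_rh = 0.5,
                         vent_rh = 0.5) {
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("'volume' must be a positive scalar (m^3)")
  if (is.null(ach) == is.null(fresh_air_flow))
    stop("give exactly one of 'ach' or 'fresh_air_flow'")
  if (is.null(ach)) {
    if (fresh_air_flow < 0) stop("'fresh_air_flow' must be >= 0")
    ach <- fresh_air_flow / volume
  } else {
    if (ach < 0) stop("'ach' must be >= 0")
    fresh_air_flow <- ach * volume
  }
  if (temperature <= 0) stop("'temperature' must be positive (K)")
  if (room_rh < 0 || room_rh > 1 || vent_rh < 0 || vent_rh > 1)
    stop("relative humidities must lie in [0, 1]")
  structure(list(volume = volume, ach = ach,
                 fresh_air_flow = fresh_air_flow,
                 temperature = temperature, room_rh = room_rh,
                 vent_rh = vent_rh),
            class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("<chamber_spec> %g m^3, ACH %.4g /h (%.4g m^3/h fresh air), T %.2f K, RH %g/%g\n",
              x$volume, x$ach, x$fresh_air_flow, x$temperature,
              x$room_rh, x$vent_rh))
  invisible(x)
}

#' Instantaneous room concentration
#'
#' C_i = m_i / V_r — total mass of the constituent (both phases) per room
#' volume; the ventilation air removes material at this concentration.
#'
#' @param total_mass Total per-constituent mass in the room, ug.
#' @param volume Room volume, m^3.
#' @return Concentration in ug/m^3.
#' @export
concentration <- function(total_mass, volume) {
  if (!is.numeric(volume) || volume <= 0) stop("'volume' must be positive")
  if (any(total_mass < 0)) stop("masses must be non-negative")
  total_mass / volume
}

# density (kg/m^3) of a liquid mixture with mass fractions y
.mixture_density <- function(y, densities) {
  1 / sum(y / densities)
}

#' Simulate a scenario
#'
#' Runs the explicit single-zone mass balance over the scenario horizon,
#' re-partitioning every constituent between droplet and vapor phase at
#' each step.  Fully deterministic.
#'
#' @param scenario An [evp_scenario()].
#' @param dt Time step in s (default: the scenario's, normally 10 s).  A
#'   warning is issued when `ach * dt` exceeds 0.1 air changes, where the
#'   explicit update degrades.
#' @param duration Horizon in s (default: the scenario's).
#' @param constituents Named list of [constituent()] objects covering the
#'   source composition plus water; defaults to [default_constituents()].
#'   Supply a modified list to perturb activity coefficients etc.
#' @param emission_mode `"uniform"` (spread each session's puffs evenly)
#'   or `"impulse"` (per-puff releases).
#' @param exhaled_water_rate Optional extra water inflow from exhaled
#'   breath, ug/s during the usage window (default 0: off).
#' @param solver_tol Partition-solver residual tolerance.
#' @return An object of class `"chamber_sim"` with the sampled times,
#'   per-constituent concentration / liquid / vapor trajectories, particle
#'   diameter trajectory, conservation ledgers and the scenario echo.
#' @examples
#' sim <- simulate_chamber(builtin_scenario("czogala_run2"))
#' summary(sim)
#' @export
simulate_chamber <- function(scenario, dt = NULL, duration = NULL,
                             constituents = NULL,
                             emission_mode = c("uniform", "impulse"),
                             exhaled_water_rate = 0,
                             solver_tol = 1e-10) {
  stopifnot(inherits(scenario, "evp_scenario"))
  emission_mode <- match.arg(emission_mode)
  if (is.null(dt)) dt <- scenario$dt
  if (is.null(duration)) duration <- scenario$duration
  if (dt <= 0 || duration <= 0) stop("'dt' and 'duration' must be positive")
  if (is.null(constituents)) constituents <- default_constituents()
  ch <- scenario$chamber
  src_names <- names(scenario$source$composition)
  need <- union(src_names, "water")
  miss <- setdiff(need, names(constituents))
  if (length(miss))
    stop("constituent properties missing for: ", paste(miss, collapse = ", "))
  consts <- constituents
  cn <- names(consts)
  k <- length(consts)
  if (ch$ach * dt / 3600 > 0.1)
    warning("ach * dt = ", signif(ch$ach * dt / 3600, 3),
            " air changes per step; reduce dt for an accurate explicit update")

  sched <- build_schedule(scenario, mode = emission_mode)
  Tk <- ch$temperature
  V <- ch$volume
  Qs <- ch$fresh_air_flow / 3600           # m^3/s
  nsteps <- as.integer(ceiling(duration / dt - 1e-9))
  iw <- match("water", cn)

  # water background: room preloaded at room_rh, ventilation carries vent_rh
  rho_sat_w <- equilibrium_vapor_density(consts[[iw]], 1, Tk) /
    consts[[iw]]$gamma                      # g/m^3, gamma-independent
  m <- numeric(k)
  m[iw] <- ch$room_rh * rho_sat_w * V * 1e6
  vent_in <- numeric(k)
  vent_in[iw] <- Qs * ch$vent_rh * rho_sat_w * 1e6   # ug/s

  # source-particle properties for diameter bookkeeping
  per_puff <- puff_emission_masses(scenario$source)
  rho_l <- vapply(consts, `[[`, 0, "liquid_density")[cn]
  if (sum(per_puff) > 0) {
    y_src <- per_puff[cn]; y_src[is.na(y_src)] <- 0
    y_src <- y_src / sum(y_src)
    rho_src <- .mixture_density(y_src, rho_l)
  } else rho_src <- mean(rho_l)
  d0_m <- scenario$initial_aerosol_diameter * 1e-6
  particle_mass_g <- rho_src * 1e3 * pi / 6 * d0_m^3   # g per fresh droplet

  times <- seq(0, nsteps) * dt
  conc <- liq <- vap <- matrix(0, nsteps + 1L, k, dimnames = list(NULL, cn))
  diam <- numeric(nsteps + 1L)
  n_particles <- 0
  cum_in <- cum_out <- numeric(k)
  m0 <- m
  w_prev <- rep(1, k)
  all_converged <- TRUE

  record <- function(row, m, pr, n_p) {
    conc[row, ] <<- m / V
    liq[row, ] <<- pr$liquid_masses
    vap[row, ] <<- pr$vapor_masses
    Ltot <- sum(pr$liquid_masses)
    diam[row] <<- if (n_p > 0 && Ltot > 0) {
      yl <- pr$liquid_masses / Ltot
      (6 * (Ltot * 1e-6) / (pi * .mixture_density(yl, rho_l) * 1e3 *
                              n_p))^(1 / 3) * 1e6
    } else 0
  }

  solve_state <- function(m, t) {
    pr <- solve_partition(partition_problem(m, consts, Tk, V),
                          w_init = w_prev, tol = solver_tol)
    if (!pr$converged) {
      all_converged <<- FALSE
      warning("partition solver flagged non-convergence at t = ", t, " s")
    }
    w_prev <<- pr$liquid_fractions
    pr
  }

  pr <- solve_state(m, 0)
  record(1L, m, pr, n_particles)

  for (s in seq_len(nsteps)) {
    t0 <- (s - 1) * dt
    e_src <- schedule_mass(sched, t0, t0 + dt)[cn]
    e_src[is.na(e_src)] <- 0
    ein <- e_src + vent_in * dt
    if (exhaled_water_rate > 0 && t0 < sched$usage_end)
      ein[iw] <- ein[iw] + exhaled_water_rate * dt
    out <- Qs * dt * m / V
    m_new <- m + ein - out
    if (any(m_new < -1e-9 * pmax(m, 1)))
      stop("negative mass at t = ", t0 + dt, " s; reduce 'dt'")
    m_new <- pmax(m_new, 0)
    cum_in <- cum_in + ein
    cum_out <- cum_out + out
    pr <- solve_state(m_new, t0 + dt)
    n_particles <- n_particles * (1 - Qs * dt / V) +
      sum(e_src) * 1e-6 / particle_mass_g
    record(s + 1L, m_new, pr, n_particles)
    m <- m_new
  }

  structure(list(times = times, concentration = conc, liquid = liq,
                 vapor = vap, particle_diameter = diam,
                 constituents = cn, scenario = scenario, dt = dt,
                 duration = duration, emission_mode = emission_mode,
                 usage_end = sched$usage_end,
                 initial_mass = stats::setNames(m0, cn),
                 cumulative_emitted = stats::setNames(cum_in, cn),
                 cumulative_vented = stats::setNames(cum_out, cn),
                 final_mass = stats::setNames(m, cn),
                 final_particle_count = n_particles,
                 solver_converged = all_converged),
            class = "chamber_sim")
}

# ---- derived quantities ----------------------------------------------------

#' Analytic steady-state concentration
#'
#' C_ss = S / Q_a for a constant source S into a ventilated, well-mixed
#' space; the closed-form plateau every constant-rate run approaches.
#'
#' @param spec A [chamber_spec()].
#' @param mean_emission_rate Source strength in ug/h.
#' @return Steady-state concentration, ug/m^3.
#' @export
steady_state_concentration <- function(spec, mean_emission_rate) {
  stopifnot(inherits(spec, "chamber_spec"))
  if (spec$fresh_air_flow <= 0)
    stop("no steady state without ventilation (fresh_air_flow = 0)")
  mean_emission_rate / spec$fresh_air_flow
}

.sim_col <- function(result, constituent) {
  stopifnot(inherits(result, "chamber_sim"))
  j <- match(constituent, result$constituents)
  if (is.na(j)) stop("constituent '", constituent, "' not in the result")
  result$concentration[, j]
}

#' Plateau concentration of a run
#'
#' The plateau is estimated as the mean concentration over the final 10 %
#' of the usage window (clamped to the simulated horizon when the run is
#' shorter than the usage window).
#'
#' @param result A [simulate_chamber()] result.
#' @param constituent Constituent name.
#' @return Plateau concentration, ug/m^3.
#' @export
plateau_concentration <- function(result, constituent) {
  cc <- .sim_col(result, constituent)
  ue <- min(result$usage_end, max(result$times))
  sel <- result$times >= 0.9 * ue & result$times <= ue
  mean(cc[sel])
}

#' Time to reach a fraction of the plateau
#'
#' First crossing time of `fraction` x plateau, with the plateau from
#' [plateau_concentration()].
#'
#' @inheritParams plateau_concentration
#' @param fraction Fraction of the plateau in \[0, 1\].
#' @return Time in s.
#' @export
time_to_fraction_of_steady_state <- function(result, constituent,
                                             fraction) {
  if (fraction < 0 || fraction > 1) stop("'fraction' must lie in [0, 1]")
  if (fraction == 0) return(0)
  cc <- .sim_col(result, constituent)
  thr <- fraction * plateau_concentration(result, constituent)
  idx <- which(cc >= thr)
  if (!length(idx))
    stop("trajectory never reaches ", fraction, " of its plateau")
  result$times[idx[1]]
}

#' Time after cessation to decay to a fraction of the cessation level
#'
#' Measures, from the end of the usage window, how long the constituent
#' takes to fall below `fraction` of its concentration at cessation.
#'
#' @inheritParams plateau_concentration
#' @param fraction Decay criterion (default 0.01, i.e. back to <= 1 %).
#' @return Elapsed time since cessation, s.
#' @export
decay_time_after_cessation <- function(result, constituent,
                                       fraction = 0.01) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must lie in (0, 1)")
  cc <- .sim_col(result, constituent)
  t0 <- result$usage_end
  i0 <- which.min(abs(result$times - t0))
  c0 <- cc[i0]
  if (c0 <= 0) stop("concentration already zero at cessation")
  after <- which(result$times > t0 & cc < fraction * c0)
  if (!length(after))
    stop("concentration never decays below ", fraction,
         " of its cessation value within the horizon")
  result$times[after[1]] - t0
}

#' Volume-equivalent mean particle diameter
#'
#' Diameter of the sphere holding the mean per-particle liquid mass at the
#' given mixture liquid density (fixed particle count; no coagulation or
#' deposition).
#'
#' @param liquid_mass Total droplet-phase mass, ug.
#' @param particle_count Number of particles (> 0).
#' @param liquid_density Mixture liquid density, kg/m^3.
#' @return Mean diameter in um.
#' @export
mean_particle_diameter <- function(liquid_mass, particle_count,
                                   liquid_density) {
  if (particle_count <= 0) stop("'particle_count' must be positive")
  if (liquid_mass < 0 || liquid_density <= 0)
    stop("invalid liquid mass or density")
  (6 * (liquid_mass * 1e-6) /
      (pi * liquid_density * 1e3 * particle_count))^(1 / 3) * 1e6
}

# ---- methods ---------------------------------------------------------------

#' @export
print.chamber_sim <- function(x, ...) {
  cat(sprintf("<chamber_sim> scenario '%s': %d steps of %g s (%.2f h)\n",
              x$scenario$name, length(x$times) - 1L, x$dt,
              x$duration / 3600))
  cat(sprintf("  constituents: %s\n", paste(x$constituents, collapse = ", ")))
  cat(sprintf("  solver converged everywhere: %s\n", x$solver_converged))
  invisible(x)
}

#' Summarise a simulation
#'
#' Per-constituent peak, mean-over-horizon, final and plateau
#' concentrations plus the final particle diameter.
#'
#' @param object A `"chamber_sim"`.
#' @param ... Unused.
#' @return A data.frame, one row per constituent.
#' @export
summary.chamber_sim <- function(object, ...) {
  cc <- object$concentration
  out <- data.frame(
    constituent = object$constituents,
    peak_ug_m3 = apply(cc, 2, max),
    mean_ug_m3 = colMeans(cc),
    final_ug_m3 = cc[nrow(cc), ],
    plateau_ug_m3 = vapply(object$constituents, function(nm)
      plateau_concentration(object, nm), 0),
    row.names = NULL)
  attr(out, "final_particle_diameter_um") <-
    object$particle_diameter[length(object$particle_diameter)]
  out
}

#' @export
as.data.frame.chamber_sim <- function(x, ...) {
  df <- data.frame(time_s = x$times)
  for (nm in x$constituents) {
    j <- match(nm, x$constituents)
    df[[paste0(nm, "_ug_m3")]] <- x$concentration[, j]
    df[[paste0(nm, "_liquid_ug")]] <- x$liquid[, j]
    df[[paste0(nm, "_vapor_ug")]] <- x$vapor[, j]
  }
  df$particle_diameter_um <- x$particle_diameter
  df
}

#' Plot concentration trajectories
#'
#' @param x A `"chamber_sim"`.
#' @param constituents Which constituents to draw (default all).
#' @param log Passed to [graphics::matplot()].
#' @param ... Further graphical parameters.
#' @export
plot.chamber_sim <- function(x, constituents = x$constituents, log = "",
                             ...) {
  j <- match(constituents, x$constituents)
  if (anyNA(j)) stop("unknown constituent in 'constituents'")
  graphics::matplot(x$times / 60, x$concentration[, j, drop = FALSE],
                    type = "l", lty = 1, col = seq_along(j),
                    xlab = "time (min)",
                    ylab = expression(concentration ~ (mu * g / m^3)),
                    log = log, ...)
  graphics::legend("topright", legend = constituents, col = seq_along(j),
                   lty = 1, bty = "n")
  invisible(x)
}
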