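# Emission sources, schedules and the built-in validation scenarios.

#' Define a puff source
#'
#' Two kinds of aerosol source are supported:
#' * `"machine"` — smoking-machine releases directly into the room.  The
#'   released aerosol has the e-liquid composition; puffs occur in discrete
#'   sessions (`session_times_s`, `puffs_per_session`, one puff every
#'   `puff_interval_s` seconds).
#' * `"exhaled"` — aerosol exhaled by users.  Per-puff constituent masses
#'   are the e-liquid composition scaled by per-constituent exhaled
#'   fractions (exhaled/inhaled ratio).  `participants` users each take
#'   `puffs_per_hour` puffs, distributed evenly over the usage window
#'   `[0, usage_duration_s]`.
#'
#' @param kind `"machine"` or `"exhaled"`.
#' @param puff_aerosol_mass_mg Aerosol mass delivered per puff, mg.
#' @param composition Named per-constituent mass fractions of the e-liquid
#'   (must sum to 1 within 1e-6).
#' @param exhaled_fractions Named per-constituent exhaled/inhaled ratios in
#'   \[0, 1\]; required for `kind = "exhaled"`.  Constituents absent from
#'   the vector are treated as not exhaled (fraction 0).
#' @param participants Number of users (exhaled only).
#' @param puffs_per_hour Puffs per participant per hour (exhaled only).
#' @param usage_duration_s Length of the usage window in s (exhaled only).
#' @param session_times_s Session start times in s (machine only).
#' @param puffs_per_session Puffs per session (machine only).
#' @param puff_interval_s Seconds between machine puffs (default 10).
#' @return An object of class `"puff_source"`.
#' @export
puff_source <- function(kind = c("machine", "exhaled"),
                        puff_aerosol_mass_mg, composition,
                        exhaled_fractions = NULL,
                        participants = 1L, puffs_per_hour = NULL,
                        usage_duration_s = NULL,
                        session_times_s = NULL, puffs_per_session = NULL,
                        puff_interval_s = 10) {
  kind <- match.arg(kind)
  if (!is.numeric(puff_aerosol_mass_mg) || puff_aerosol_mass_mg <= 0)
    stop("'puff_aerosol_mass_mg' must be positive")
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("'composition' must be a named vector of mass fractions")
  composition <- unlist(composition)
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-6)
    stop("'composition' fractions must be non-negative and sum to 1")
  if (kind == "exhaled") {
    if (is.null(exhaled_fractions))
      stop("'exhaled_fractions' is required for an exhaled source")
    exhaled_fractions <- unlist(exhaled_fractions)
    if (is.null(names(exhaled_fractions)))
      stop("'exhaled_fractions' must be named")
    if (any(exhaled_fractions < 0 | exhaled_fractions > 1))
      stop("exhaled fractions must lie in [0, 1]")
    if (is.null(puffs_per_hour) || puffs_per_hour < 0)
      stop("'puffs_per_hour' must be given (>= 0) for an exhaled source")
    if (is.null(usage_duration_s) || usage_duration_s <= 0)
      stop("'usage_duration_s' must be positive for an exhaled source")
    if (participants < 1) stop("'participants' must be >= 1")
  } else {
    if (is.null(session_times_s) || is.null(puffs_per_session))
      stop("machine sources need 'session_times_s' and 'puffs_per_session'")
    if (any(session_times_s < 0)) stop("session times must be >= 0")
    if (puffs_per_session < 1) stop("'puffs_per_session' must be >= 1")
    if (puff_interval_s <= 0) stop("'puff_interval_s' must be positive")
  }
  structure(list(kind = kind,
                 puff_aerosol_mass_mg = puff_aerosol_mass_mg,
                 composition = composition,
                 exhaled_fractions = exhaled_fractions,
                 participants = as.integer(participants),
                 puffs_per_hour = puffs_per_hour,
                 usage_duration_s = usage_duration_s,
                 session_times_s = session_times_s,
                 puffs_per_session = puffs_per_session,
                 puff_interval_s = puff_interval_s),
            class = "puff_source")
}

#' Per-puff emitted mass of each constituent
#'
#' Machine sources release the full per-puff aerosol mass at e-liquid
#' composition; exhaled sources scale each constituent by its exhaled
#' fraction.
#'
#' @param source A [puff_source()].
#' @return Named vector of ug emitted per puff per constituent.
#' @examples
#' src <- puff_source("machine", 10,
#'                    c(propylene_glycol = .418, glycerol = .418,
#'                      water = .146, nicotine = .018),
#'                    session_times_s = 0, puffs_per_session = 7)
#' puff_emission_masses(src)["nicotine"]   # 180 ug
#' @export
puff_emission_masses <- function(source) {
  stopifnot(inherits(source, "puff_source"))
  out <- source$puff_aerosol_mass_mg * 1e3 * source$composition
  if (source$kind == "exhaled") {
    ef <- source$exhaled_fractions[names(out)]
    ef[is.na(ef)] <- 0
    out <- out * ef
  }
  out
}

#' Total puff count of a source over its schedule
#' @param source A [puff_source()].
#' @return Total number of puffs (all participants, all sessions).
#' @export
total_puffs <- function(source) {
  stopifnot(inherits(source, "puff_source"))
  if (source$kind == "machine")
    length(source$session_times_s) * source$puffs_per_session
  else
    source$participants * source$puffs_per_hour *
      source$usage_duration_s / 3600
}

#' Assemble a simulation scenario
#'
#' @param chamber A [chamber_spec()].
#' @param source A [puff_source()].
#' @param duration Simulated horizon in s.
#' @param dt Time step in s (default 10).
#' @param initial_aerosol_diameter Mean diameter of freshly released
#'   droplets, um (default 0.5).
#' @param name Scenario label.
#' @return An object of class `"evp_scenario"`.
#' @export
evp_scenario <- function(chamber, source, duration, dt = 10,
                         initial_aerosol_diameter = 0.5, name = "custom") {
  stopifnot(inherits(chamber, "chamber_spec"), inherits(source, "puff_source"))
  if (!is.numeric(duration) || duration <= 0)
    stop("'duration' must be positive (s)")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive (s)")
  if (initial_aerosol_diameter <= 0)
    stop("'initial_aerosol_diameter' must be positive (um)")
  structure(list(name = name, chamber = chamber, source = source,
                 duration = duration, dt = dt,
                 initial_aerosol_diameter = initial_aerosol_diameter),
            class = "evp_scenario")
}

#' @export
print.evp_scenario <- function(x, ...) {
  ch <- x$chamber
  cat(sprintf("<evp_scenario> %s\n", x$name))
  cat(sprintf("  room: %g m^3, ACH %.3f /h (fresh air %.1f m^3/h), T %.2f K\n",
              ch$volume, ch$ach, ch$fresh_air_flow, ch$temperature))
  cat(sprintf("  source: %s, %g mg/puff, %g puffs total\n",
              x$source$kind, x$source$puff_aerosol_mass_mg,
              total_puffs(x$source)))
  cat(sprintf("  horizon: %g s at dt = %g s\n", x$duration, x$dt))
  invisible(x)
}

# ---- built-in scenarios ----------------------------------------------------

.czogala_composition <- c(propylene_glycol = 0.418, glycerol = 0.418,
                          water = 0.146, nicotine = 0.018)
.meec_composition <- c(propylene_glycol = 0.41, glycerol = 0.42,
                       water = 0.146, nicotine = 0.024)
# mean exhaled/inhaled ratios; water excluded (unquantified, not emitted)
.meec_exhaled <- c(propylene_glycol = 0.06, glycerol = 0.15,
                   water = 0, nicotine = 0.034)

.builtin <- function(name) {
  czogala <- function(ach, puffs) {
    evp_scenario(
      chamber_spec(volume = 39, ach = ach, temperature = 296.15),
      puff_source("machine", puff_aerosol_mass_mg = 10,
                  composition = .czogala_composition,
                  session_times_s = c(0, 1800),
                  puffs_per_session = puffs, puff_interval_s = 10),
      duration = 3600, name = name)
  }
  meec <- function(fresh_air_flow = 255, puffs_per_hour = 20,
                   usage_duration_s = 4 * 3600,
                   exhaled = .meec_exhaled) {
    evp_scenario(
      chamber_spec(volume = 113, fresh_air_flow = fresh_air_flow,
                   temperature = 296.15),
      puff_source("exhaled", puff_aerosol_mass_mg = 5.2,
                  composition = .meec_composition,
                  exhaled_fractions = exhaled,
                  participants = 9, puffs_per_hour = puffs_per_hour,
                  usage_duration_s = usage_duration_s),
      duration = 4 * 3600, name = name)
  }
  switch(name,
    czogala_run1 = czogala(9.86, 7),
    czogala_run2 = czogala(6.81, 7),
    czogala_run3 = czogala(6.83, 15),
    czogala_run4 = czogala(6.80, 15),
    mEEC_baseline = meec(),
    mEEC_high_exhale = meec(exhaled = replace(.meec_exhaled, "nicotine",
                                             0.16)),
    mEEC_half_puffs = meec(puffs_per_hour = 10),
    mEEC_ach5 = meec(fresh_air_flow = 5 * 113),
    mEEC_1h_use = meec(usage_duration_s = 3600),
    stop("unknown built-in scenario '", name, "'; see list_builtin_scenarios()")
  )
}

#' Built-in validation and sensitivity scenarios
#'
#' * `czogala_run1` .. `czogala_run4`: machine-generated releases into a
#'   39 m^3 room, two sessions (0 and 30 min) of 7 (low) or 15 (high)
#'   puffs at one puff per 10 s, nicotine 1.8 % e-liquid, ACH 9.86 /
#'   6.81 / 6.83 / 6.80, 60 min horizon.  Per-puff aerosol mass defaults
#'   to an assumed 10 mg (not reported with the source study).
#' * `mEEC_baseline`: 113 m^3 exposure chamber, 255 m^3/h fresh air
#'   (ACH 2.26), 9 participants each taking 10 puffs per 30 min
#'   (20 puffs/h) of a 5.2 mg/puff device, e-liquid
#'   PG/glycerol/water/nicotine = 41/42/14.6/2.4 % w/w, mean exhaled
#'   fractions 6 % / 15 % / - / 3.4 %, 4 h horizon.
#' * `mEEC_high_exhale`, `mEEC_half_puffs`, `mEEC_ach5`, `mEEC_1h_use`:
#'   one-factor sensitivity variants of the baseline (nicotine exhaled
#'   fraction 16 %, 10 puffs/h, ACH 5, usage only during hour 1).
#'
#' @param name One of [list_builtin_scenarios()].
#' @return An [evp_scenario()].
#' @examples
#' builtin_scenario("mEEC_baseline")
#' @export
builtin_scenario <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  .builtin(name)
}

#' @rdname builtin_scenario
#' @export
list_builtin_scenarios <- function() {
  c("czogala_run1", "czogala_run2", "czogala_run3", "czogala_run4",
    "mEEC_baseline", "mEEC_high_exhale", "mEEC_half_puffs", "mEEC_ach5",
    "mEEC_1h_use")
}

# ---- emission schedules ----------------------------------------------------

#' Build the emission schedule of a scenario
#'
#' Converts the puff source into per-constituent mass inputs over time.
#' `"uniform"` (default) spreads each session's puffs evenly over the
#' session window; `"impulse"` releases each puff's mass at its puff time.
#' Both variants emit exactly the same cumulative mass
#' (puffs x per-puff mass) by construction.
#'
#' @param scenario An [evp_scenario()].
#' @param mode `"uniform"` or `"impulse"`.
#' @return An object of class `"emission_schedule"`: for uniform mode a
#'   set of \[start, end) segments with per-constituent rates (ug/s); for
#'   impulse mode puff times with per-constituent masses (ug).
#' @export
build_schedule <- function(scenario, mode = c("uniform", "impulse")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "evp_scenario"))
  src <- scenario$source
  per_puff <- puff_emission_masses(src)
  if (src$kind == "machine") {
    sess_len <- src$puffs_per_session * src$puff_interval_s
    starts <- src$session_times_s
    ends <- starts + sess_len
    if (any(ends > scenario$duration + 1e-9))
      stop("a release session extends beyond the scenario duration")
    if (mode == "uniform") {
      rates <- outer(rep(src$puffs_per_session / sess_len, length(starts)),
                     per_puff)
      sched <- list(mode = "uniform", starts = starts, ends = ends,
                    rates = rates)
    } else {
      times <- as.vector(outer(
        (seq_len(src$puffs_per_session) - 1) * src$puff_interval_s,
        starts, `+`))
      sched <- list(mode = "impulse", times = sort(times),
                    masses = matrix(per_puff, nrow = length(times),
                                    ncol = length(per_puff), byrow = TRUE,
                                    dimnames = list(NULL, names(per_puff))))
    }
    usage_end <- max(ends)
  } else {
    if (src$usage_duration_s > scenario$duration + 1e-9)
      stop("usage window extends beyond the scenario duration")
    npuff <- total_puffs(src)
    if (mode == "uniform") {
      sched <- list(mode = "uniform", starts = 0,
                    ends = src$usage_duration_s,
                    rates = matrix(npuff * per_puff / src$usage_duration_s,
                                   nrow = 1,
                                   dimnames = list(NULL, names(per_puff))))
    } else {
      times <- (seq_len(npuff) - 0.5) * src$usage_duration_s / npuff
      sched <- list(mode = "impulse", times = times,
                    masses = matrix(per_puff, nrow = length(times),
                                    ncol = length(per_puff), byrow = TRUE,
                                    dimnames = list(NULL, names(per_puff))))
    }
    usage_end <- src$usage_duration_s
  }
  sched$constituents <- names(per_puff)
  sched$usage_end <- usage_end
  structure(sched, class = "emission_schedule")
}

#' Mass emitted by a schedule over a time window
#'
#' Exact integral of the schedule over \[t0, t1): uniform segments
#' contribute rate x overlap, impulses contribute their full mass when the
#' puff time falls inside the window.
#'
#' @param schedule An [build_schedule()] result.
#' @param t0,t1 Window bounds in s.
#' @return Named per-constituent mass, ug.
#' @export
schedule_mass <- function(schedule, t0, t1) {
  stopifnot(inherits(schedule, "emission_schedule"), t1 >= t0)
  k <- length(schedule$constituents)
  out <- numeric(k)
  names(out) <- schedule$constituents
  if (schedule$mode == "uniform") {
    ov <- pmax(0, pmin(schedule$ends, t1) - pmax(schedule$starts, t0))
    if (any(ov > 0)) out <- out + colSums(schedule$rates * ov)
  } else {
    sel <- schedule$times >= t0 & schedule$times < t1
    if (any(sel)) out <- out + colSums(schedule$masses[sel, , drop = FALSE])
  }
  out
}

#' Total mass a schedule will emit
#' @param schedule An [build_schedule()] result.
#' @return Named per-constituent cumulative mass, ug.
#' @export
schedule_total_mass <- function(schedule) {
  schedule_mass(schedule, 0, Inf)
}
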