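# Scenario execution, overrides, parameter sweeps, and on-disk export.

#' Apply one-factor overrides to a scenario
#'
#' Convenience for sensitivity analysis: returns a copy of the scenario
#' with the named fields replaced.  Ventilation may be set through either
#' `ach` or `fresh_air_flow` (the other is re-derived).
#'
#' @param scenario An [evp_scenario()].
#' @param ach,fresh_air_flow New ventilation (give at most one).
#' @param puffs_per_hour,usage_duration_s,participants Source overrides
#'   (exhaled sources only).
#' @param exhaled_fractions Named vector merged over the existing exhaled
#'   fractions.
#' @param puff_aerosol_mass_mg Per-puff aerosol mass override.
#' @param dt,duration Time-stepping overrides.
#' @param name New scenario label (default: old name + "(modified)").
#' @return A modified [evp_scenario()].
#' @export
modify_scenario <- function(scenario, ach = NULL, fresh_air_flow = NULL,
                            puffs_per_hour = NULL, usage_duration_s = NULL,
                            participants = NULL, exhaled_fractions = NULL,
                            puff_aerosol_mass_mg = NULL, dt = NULL,
                            duration = NULL, name = NULL) {
  stopifnot(inherits(scenario, "evp_scenario"))
  ch <- scenario$chamber
  if (!is.null(ach) && !is.null(fresh_air_flow))
    stop("give at most one of 'ach' and 'fresh_air_flow'")
  if (!is.null(ach) || !is.null(fresh_air_flow))
    ch <- chamber_spec(ch$volume, ach = ach,
                       fresh_air_flow = fresh_air_flow,
                       temperature = ch$temperature,
                       room_rh = ch$room_rh, vent_rh = ch$vent_rh)
  src <- unclass(scenario$source)
  for (f in c("puffs_per_hour", "usage_duration_s", "participants",
              "puff_aerosol_mass_mg")) {
    v <- get(f)
    if (!is.null(v)) {
      if (src$kind != "exhaled" && f %in% c("puffs_per_hour",
                                            "usage_duration_s",
                                            "participants"))
        stop("'", f, "' applies only to exhaled sources")
      src[[f]] <- v
    }
  }
  if (!is.null(exhaled_fractions)) {
    if (src$kind != "exhaled")
      stop("'exhaled_fractions' applies only to exhaled sources")
    src$exhaled_fractions[names(exhaled_fractions)] <-
      unlist(exhaled_fractions)
  }
  source2 <- puff_source(src$kind, src$puff_aerosol_mass_mg,
                         src$composition,
                         exhaled_fractions = src$exhaled_fractions,
                         participants = src$participants,
                         puffs_per_hour = src$puffs_per_hour,
                         usage_duration_s = src$usage_duration_s,
                         session_times_s = src$session_times_s,
                         puffs_per_session = src$puffs_per_session,
                         puff_interval_s = src$puff_interval_s)
  evp_scenario(ch, source2,
               duration = if (is.null(duration)) scenario$duration
                          else duration,
               dt = if (is.null(dt)) scenario$dt else dt,
               initial_aerosol_diameter = scenario$initial_aerosol_diameter,
               name = if (is.null(name))
                 paste0(scenario$name, " (modified)") else name)
}

#' Canonical flat configuration of a scenario
#'
#' Deterministic named character representation of every independent
#' input field (derived quantities such as the second ventilation
#' parameter are excluded).  Used to diff sensitivity variants.
#'
#' @param scenario An [evp_scenario()].
#' @return Named character vector.
#' @export
scenario_config <- function(scenario) {
  stopifnot(inherits(scenario, "evp_scenario"))
  ch <- scenario$chamber; src <- scenario$source
  num <- function(x) if (is.null(x)) "" else
    paste(format(x, digits = 15, trim = TRUE), collapse = ",")
  c(volume_m3 = num(ch$volume),
    fresh_air_flow_m3_h = num(ch$fresh_air_flow),
    temperature_K = num(ch$temperature),
    room_rh = num(ch$room_rh), vent_rh = num(ch$vent_rh),
    source_kind = src$kind,
    puff_aerosol_mass_mg = num(src$puff_aerosol_mass_mg),
    composition = paste(names(src$composition),
                        num(unname(src$composition)), sep = "=",
                        collapse = ";"),
    exhaled_fractions = if (is.null(src$exhaled_fractions)) "" else
      paste(names(src$exhaled_fractions),
            num(unname(src$exhaled_fractions)), sep = "=", collapse = ";"),
    participants = num(src$participants),
    puffs_per_hour = num(src$puffs_per_hour),
    usage_duration_s = num(src$usage_duration_s),
    session_times_s = num(src$session_times_s),
    puffs_per_session = num(src$puffs_per_session),
    puff_interval_s = num(src$puff_interval_s),
    duration_s = num(scenario$duration),
    dt_s = num(scenario$dt),
    initial_aerosol_diameter_um = num(scenario$initial_aerosol_diameter))
}

#' Export / import scenarios as JSON
#'
#' @param scenario An [evp_scenario()].
#' @param path Output (input) file path.
#' @return `scenario_to_json()` returns `path` invisibly;
#'   `scenario_from_json()` returns the rebuilt [evp_scenario()].
#' @export
scenario_to_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "evp_scenario"))
  ch <- scenario$chamber; src <- scenario$source
  x <- list(
    name = scenario$name,
    chamber = list(volume = ch$volume,
                   fresh_air_flow = ch$fresh_air_flow,
                   temperature = ch$temperature, room_rh = ch$room_rh,
                   vent_rh = ch$vent_rh),
    source = Filter(Negate(is.null), list(
      kind = src$kind,
      puff_aerosol_mass_mg = src$puff_aerosol_mass_mg,
      composition = as.list(src$composition),
      exhaled_fractions = if (is.null(src$exhaled_fractions)) NULL
                          else as.list(src$exhaled_fractions),
      participants = src$participants,
      puffs_per_hour = src$puffs_per_hour,
      usage_duration_s = src$usage_duration_s,
      session_times_s = src$session_times_s,
      puffs_per_session = src$puffs_per_session,
      puff_interval_s = src$puff_interval_s)),
    duration = scenario$duration, dt = scenario$dt,
    initial_aerosol_diameter = scenario$initial_aerosol_diameter)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname scenario_to_json
#' @export
scenario_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- chamber_spec(x$chamber$volume,
                     fresh_air_flow = x$chamber$fresh_air_flow,
                     temperature = x$chamber$temperature,
                     room_rh = x$chamber$room_rh,
                     vent_rh = x$chamber$vent_rh)
  s <- x$source
  src <- puff_source(s$kind, s$puff_aerosol_mass_mg,
                     unlist(s$composition),
                     exhaled_fractions = if (is.null(s$exhaled_fractions))
                       NULL else unlist(s$exhaled_fractions),
                     participants = if (is.null(s$participants)) 1L
                                    else s$participants,
                     puffs_per_hour = s$puffs_per_hour,
                     usage_duration_s = s$usage_duration_s,
                     session_times_s = s$session_times_s,
                     puffs_per_session = s$puffs_per_session,
                     puff_interval_s = if (is.null(s$puff_interval_s)) 10
                                       else s$puff_interval_s)
  evp_scenario(ch, src, duration = x$duration, dt = x$dt,
               initial_aerosol_diameter = x$initial_aerosol_diameter,
               name = x$name)
}

#' Run a scenario and export its artifacts
#'
#' Resolves the scenario (built-in name, JSON path, or [evp_scenario()]),
#' runs [simulate_chamber()], and — when `out_dir` is given — writes
#' `timeseries.csv` (time, per-constituent concentration and phase split,
#' particle diameter), `summary.csv` (peak / mean / final / plateau per
#' constituent) and `config.json` (fully resolved scenario).  Output is
#' bit-identical across reruns with identical inputs.
#'
#' @param scenario A built-in scenario name, path to a scenario JSON, or
#'   an [evp_scenario()].
#' @param out_dir Optional output directory (created if missing).
#' @param ... Overrides passed to [modify_scenario()].
#' @param dt,duration Time-stepping overrides (passed to the simulator).
#' @param constituents Optional property-set override for
#'   [simulate_chamber()].
#' @return The `"chamber_sim"` result, invisibly.
#' @export
run_scenario <- function(scenario, out_dir = NULL, ..., dt = NULL,
                         duration = NULL, constituents = NULL) {
  if (is.character(scenario)) {
    scenario <- if (file.exists(scenario)) scenario_from_json(scenario)
                else builtin_scenario(scenario)
  }
  stopifnot(inherits(scenario, "evp_scenario"))
  if (length(list(...)))
    scenario <- modify_scenario(scenario, ..., name = scenario$name)
  sim <- simulate_chamber(scenario, dt = dt, duration = duration,
                          constituents = constituents)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(sim),
                     file.path(out_dir, "timeseries.csv"),
                     row.names = FALSE)
    sm <- summary(sim)
    sm$final_particle_diameter_um <-
      attr(sm, "final_particle_diameter_um")
    utils::write.csv(sm, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    scenario_to_json(scenario, file.path(out_dir, "config.json"))
  }
  invisible(sim)
}

#' One-factor parameter sweep
#'
#' Reruns a scenario across a vector of values of a single override and
#' collects the per-constituent summaries in long format.
#'
#' @param scenario Anything [run_scenario()] accepts.
#' @param param Name of a [modify_scenario()] override (e.g. `"ach"`,
#'   `"puffs_per_hour"`).
#' @param values Vector of values to sweep.
#' @return A long data.frame: `param`, `value`, `constituent`, and the
#'   summary columns.
#' @export
run_sweep <- function(scenario, param, values) {
  if (is.character(scenario)) scenario <- builtin_scenario(scenario)
  out <- lapply(values, function(v) {
    args <- stats::setNames(list(v), param)
    sim <- do.call(run_scenario, c(list(scenario), args))
    sm <- summary(sim)
    cbind(param = param, value = v, sm)
  })
  do.call(rbind, out)
}
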