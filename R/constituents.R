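# Thermodynamic property model for aerosol constituents and the
# liquid-mixture relations used by the partitioning solver.

#' Universal gas constant, J/(mol K)
#' @noRd
R_GAS <- 8.314462618

#' Define a chemical constituent
#'
#' A constituent carries the thermodynamic identity needed by the
#' vapor-liquid partitioning model: molar mass, an Antoine-type saturation
#' vapor pressure curve with its valid temperature range, an activity
#' coefficient for Raoult-law corrections in the droplet mixture, and a
#' liquid density (used only for particle-diameter bookkeeping).
#'
#' The saturation pressure model is
#' \deqn{\log_{10} P_{sat}(T) = A - B / (T + C)}
#' with \eqn{P_{sat}} in Pa and \eqn{T} in kelvin.
#'
#' @param name Identifier, e.g. `"nicotine"`.
#' @param molar_mass Molar mass in g/mol.
#' @param antoine Numeric length-3 vector `c(A, B, C)` of Antoine
#'   coefficients (Pa / K basis, see Details).
#' @param t_range Numeric length-2 vector, valid temperature range in K.
#' @param gamma Activity coefficient (dimensionless, default 1: ideal
#'   Raoult behavior).
#' @param liquid_density Liquid-phase density in kg/m^3.
#' @return An object of class `"constituent"`.
#' @examples
#' w <- constituent("water", 18.015, c(10.19621, 1730.63, -39.724),
#'                  c(274, 373), liquid_density = 997)
#' saturation_pressure(w, 298.15)
#' @export
constituent <- function(name, molar_mass, antoine, t_range,
                        gamma = 1.0, liquid_density = 1000) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L ||
      !is.finite(molar_mass) || molar_mass <= 0)
    stop("'molar_mass' must be a positive finite scalar (g/mol)")
  antoine <- as.numeric(antoine)
  if (length(antoine) != 3L || any(!is.finite(antoine)))
    stop("'antoine' must be three finite coefficients c(A, B, C)")
  t_range <- as.numeric(t_range)
  if (length(t_range) != 2L || any(!is.finite(t_range)) ||
      t_range[1] >= t_range[2] || t_range[1] <= 0)
    stop("'t_range' must be an increasing pair of positive temperatures (K)")
  if (t_range[1] + antoine[3] <= 0)
    stop("Antoine denominator T + C must stay positive over 't_range' for '",
         name, "'")
  if (antoine[2] <= 0)
    stop("Antoine B must be positive so that P_sat increases with T ('",
         name, "')")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("'gamma' must be a positive finite scalar")
  if (!is.numeric(liquid_density) || length(liquid_density) != 1L ||
      !is.finite(liquid_density) || liquid_density <= 0)
    stop("'liquid_density' must be a positive finite scalar (kg/m^3)")
  structure(
    list(name = name, molar_mass = molar_mass, antoine = antoine,
         t_range = t_range, gamma = gamma, liquid_density = liquid_density),
    class = "constituent")
}

#' @export
print.constituent <- function(x, ...) {
  cat(sprintf("<constituent> %s: M = %.3f g/mol, gamma = %g, rho_l = %g kg/m^3\n",
              x$name, x$molar_mass, x$gamma, x$liquid_density))
  cat(sprintf("  log10 P[Pa] = %.5f - %.3f/(T %+.3f), valid %g-%g K\n",
              x$antoine[1], x$antoine[2], x$antoine[3],
              x$t_range[1], x$t_range[2]))
  invisible(x)
}

#' Saturation vapor pressure of a constituent
#'
#' Evaluates the constituent's Antoine-type curve.  Errors if `temperature`
#' falls outside the declared valid range.
#'
#' @param spec A [constituent()] object.
#' @param temperature Temperature(s) in K.
#' @return Saturation pressure(s) in Pa.
#' @export
saturation_pressure <- function(spec, temperature) {
  stopifnot(inherits(spec, "constituent"))
  temperature <- as.numeric(temperature)
  if (any(!is.finite(temperature)))
    stop("'temperature' must be finite (K)")
  out <- temperature < spec$t_range[1] | temperature > spec$t_range[2]
  if (any(out))
    stop(sprintf(
      "temperature %g K outside valid range [%g, %g] K for constituent '%s'",
      temperature[which(out)[1]], spec$t_range[1], spec$t_range[2],
      spec$name))
  a <- spec$antoine
  10^(a[1] - a[2] / (temperature + a[3]))
}

#' Default bundled constituents
#'
#' Reads the bundled property table (propylene glycol, glycerol, water,
#' nicotine) or a user-supplied replacement with the same columns:
#' `name, molar_mass_g_mol, antoine_A, antoine_B, antoine_C, T_min_K,
#' T_max_K, gamma_default, liquid_density_kg_m3`.
#'
#' @param file Optional path to a replacement CSV property table.
#' @return Named list of [constituent()] objects, in table order.
#' @examples
#' names(default_constituents())
#' @export
default_constituents <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "constituent_properties.csv",
                        package = "vapormix", mustWork = TRUE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "molar_mass_g_mol", "antoine_A", "antoine_B",
            "antoine_C", "T_min_K", "T_max_K", "gamma_default",
            "liquid_density_kg_m3")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("property table is missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    constituent(tab$name[i], tab$molar_mass_g_mol[i],
                c(tab$antoine_A[i], tab$antoine_B[i], tab$antoine_C[i]),
                c(tab$T_min_K[i], tab$T_max_K[i]),
                gamma = tab$gamma_default[i],
                liquid_density = tab$liquid_density_kg_m3[i])
  })
  names(out) <- tab$name
  out
}

#' Mole fractions of a liquid mixture from per-constituent masses
#'
#' @param liquid_masses Per-constituent liquid-phase masses (same mass
#'   unit for all, conventionally ug).
#' @param molar_masses Per-constituent molar masses, g/mol.
#' @return Mole fractions x_i summing to 1.
#' @examples
#' mole_fractions_from_masses(c(92, 18), c(92, 18))  # equal mole counts
#' @export
mole_fractions_from_masses <- function(liquid_masses, molar_masses) {
  liquid_masses <- as.numeric(liquid_masses)
  molar_masses <- as.numeric(molar_masses)
  stopifnot(length(liquid_masses) == length(molar_masses),
            all(is.finite(liquid_masses)), all(is.finite(molar_masses)),
            all(molar_masses > 0))
  if (any(liquid_masses < 0))
    stop("liquid masses must be non-negative")
  if (sum(liquid_masses) <= 0)
    stop("no liquid phase: all masses are zero, mole fractions undefined")
  n <- liquid_masses / molar_masses
  n / sum(n)
}

#' Mass fractions from mole fractions
#'
#' The mixture relation y_i = x_i M_i / sum_j x_j M_j.
#'
#' @param x Mole fractions summing to 1.
#' @param molar_masses Molar masses, g/mol.
#' @return Mass fractions y_i summing to 1.
#' @export
mass_fractions_from_mole_fractions <- function(x, molar_masses) {
  x <- as.numeric(x); molar_masses <- as.numeric(molar_masses)
  stopifnot(length(x) == length(molar_masses), all(molar_masses > 0))
  if (any(x < -1e-12) || abs(sum(x) - 1) > 1e-8)
    stop("mole fractions must be non-negative and sum to 1")
  w <- x * molar_masses
  w / sum(w)
}

#' Mixture molar mass
#'
#' M = sum_i x_i M_i for the droplet liquid phase.
#'
#' @inheritParams mass_fractions_from_mole_fractions
#' @return Mixture molar mass in g/mol.
#' @export
mixture_molar_mass <- function(x, molar_masses) {
  x <- as.numeric(x); molar_masses <- as.numeric(molar_masses)
  stopifnot(length(x) == length(molar_masses), all(molar_masses > 0))
  if (any(x < -1e-12) || abs(sum(x) - 1) > 1e-8)
    stop("mole fractions must be non-negative and sum to 1")
  sum(x * molar_masses)
}

#' Equilibrium vapor density over a droplet mixture
#'
#' Raoult-type vapor density of constituent i over a droplet in which its
#' mole fraction is x_i:
#' \deqn{\rho_{v,i} = \gamma_i x_i P_{sat,i}(T) M_i / (R T)}
#'
#' @param spec A [constituent()].
#' @param x_i Mole fraction of the constituent in the liquid, in \[0, 1\].
#' @param temperature Temperature in K.
#' @return Vapor density in g/m^3.
#' @examples
#' w <- default_constituents()$water
#' equilibrium_vapor_density(w, 1, 298.15)  # ~23 g/m^3
#' @export
equilibrium_vapor_density <- function(spec, x_i, temperature) {
  stopifnot(inherits(spec, "constituent"))
  x_i <- as.numeric(x_i)
  if (any(x_i < 0 | x_i > 1))
    stop("'x_i' must lie in [0, 1]")
  p <- saturation_pressure(spec, temperature)
  spec$gamma * x_i * p * spec$molar_mass / (R_GAS * temperature)
}
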