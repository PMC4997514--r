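# Per-timestep multicomponent vapor-liquid partitioning.
#
# For N constituents with total masses m_i in a room of volume V_r at
# temperature T, the liquid fraction w_i = m_li / m_i of every constituent
# satisfies the simultaneous system
#
#   f_i = m_i w_i^2 + w_i (a_i M + S_i - m_i) - S_i = 0 ,
#   S_i = sum_{j != i} m_j w_j ,   a_i = gamma_i P_sat,i(T) V_r / (R T) ,
#
# where M is the mixture molar mass of the droplet liquid (which itself
# depends on the w's).  The system is the exact restatement of Raoult
# equilibrium m_vi = a_i M_i x_i with x_i the liquid mole fraction.  A
# liquid phase exists iff the dew criterion sum_i m_i / (a_i M_i) > 1;
# otherwise everything sits in the vapor (w = 0 is always a root).

#' Volatility coefficient of a constituent in a room
#'
#' a_i = gamma_i P_sat,i(T) V_r / (R T), in mol.  The product a_i * M_i is
#' the saturated vapor mass capacity of the room for the pure constituent
#' (grams of i the room's air can hold at saturation).
#'
#' @param spec A [constituent()].
#' @param temperature Temperature in K.
#' @param volume Room volume in m^3.
#' @return Volatility coefficient in mol.
#' @examples
#' w <- default_constituents()$water
#' volatility_coefficient(w, 298.15, 113) * w$molar_mass  # ~2600 g
#' @export
volatility_coefficient <- function(spec, temperature, volume) {
  stopifnot(inherits(spec, "constituent"))
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("'volume' must be a positive scalar (m^3)")
  spec$gamma * saturation_pressure(spec, temperature) * volume /
    (R_GAS * temperature)
}

#' Define a partitioning problem
#'
#' Bundles the state handed to the equilibrium solver at one time step:
#' total per-constituent masses, the constituent property set, temperature
#' and room volume.
#'
#' @param total_masses Per-constituent total masses (liquid + vapor), ug.
#' @param constituents List of [constituent()] objects, same length/order.
#' @param temperature Temperature in K.
#' @param volume Room volume in m^3.
#' @return An object of class `"partition_problem"`.
#' @export
partition_problem <- function(total_masses, constituents, temperature,
                              volume) {
  total_masses <- as.numeric(total_masses)
  if (inherits(constituents, "constituent"))
    constituents <- list(constituents)
  stopifnot(is.list(constituents),
            all(vapply(constituents, inherits, TRUE, "constituent")))
  if (length(total_masses) != length(constituents))
    stop("'total_masses' and 'constituents' must have equal length")
  if (any(!is.finite(total_masses)) || any(total_masses < 0))
    stop("total masses must be finite and non-negative (ug)")
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("'volume' must be positive (m^3)")
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      temperature <= 0)
    stop("'temperature' must be positive (K)")
  nm <- vapply(constituents, `[[`, "", "name")
  names(total_masses) <- nm
  structure(list(total_masses = total_masses, constituents = constituents,
                 temperature = temperature, volume = volume),
            class = "partition_problem")
}

# Precompute a_i (ug per g/mol, i.e. a_i * M_i is in ug) and M_i.
.vle_coef <- function(problem) {
  M <- vapply(problem$constituents, `[[`, 0, "molar_mass")
  a_mol <- vapply(problem$constituents, volatility_coefficient, 0,
                  temperature = problem$temperature, volume = problem$volume)
  list(a = a_mol * 1e6, M = M,
       names = vapply(problem$constituents, `[[`, "", "name"))
}

# Mixture molar mass implied by liquid masses L (ug); fall back to the
# composition of the total masses when no liquid is present (the residual
# is identically zero there, so the value is immaterial but must be finite).
.mixture_M <- function(L, m, M) {
  if (sum(L) > 0) return(sum(L) / sum(L / M))
  if (sum(m) > 0) return(sum(m) / sum(m / M))
  mean(M)
}

#' Residuals of the simultaneous partitioning system
#'
#' Evaluates f_i at a trial liquid-fraction vector `w`, with the droplet
#' mixture molar mass computed self-consistently from the implied liquid
#' masses m_i w_i.  A root of all residuals is a consistent equilibrium
#' partition.
#'
#' @param w Liquid fractions, elementwise in \[0, 1\].
#' @param problem A [partition_problem()].
#' @return Per-constituent residuals (ug units).
#' @export
partition_residual <- function(w, problem) {
  stopifnot(inherits(problem, "partition_problem"))
  w <- as.numeric(w)
  m <- problem$total_masses
  if (length(w) != length(m))
    stop("'w' must have one entry per constituent")
  if (any(w < -1e-12 | w > 1 + 1e-12))
    stop("'w' must lie in [0, 1]")
  co <- .vle_coef(problem)
  L <- w * m
  M_mix <- .mixture_M(L, m, co$M)
  S <- sum(L) - L
  f <- m * w^2 + w * (co$a * M_mix + S - m) - S
  f[m <= 0] <- 0           # zero-mass constituents carry no constraint
  names(f) <- co$names
  f
}

.partition_result <- function(w, m, converged, residual_norm, iterations) {
  w <- pmin(pmax(w, 0), 1)
  ml <- w * m
  structure(list(liquid_fractions = w, liquid_masses = ml,
                 vapor_masses = m - ml, total_masses = m,
                 converged = converged, residual_norm = residual_norm,
                 iterations = iterations),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> converged: %s (residual %.3g, %d iterations)\n",
              x$converged, x$residual_norm, x$iterations))
  print(data.frame(w = x$liquid_fractions, liquid_ug = x$liquid_masses,
                   vapor_ug = x$vapor_masses))
  invisible(x)
}

# Residuals and scale with the mixture molar mass frozen at M_mix.
.f_frozen <- function(w, m, a, M_mix, jacobian = FALSE) {
  L <- w * m
  S <- sum(L) - L
  b <- a * M_mix + S - m
  f <- m * w^2 + w * b - S
  scale <- m + a * M_mix + S + 1e-300
  out <- list(f = f, scale = scale, err = max(abs(f) / scale))
  if (jacobian) {
    n <- length(w)
    J <- outer(w - 1, m)         # J[i, k] = m_k (w_i - 1), k != i
    diag(J) <- 2 * m * w + b
    out$J <- J
  }
  out
}

# Scaled residual with self-consistent M, over mass-carrying constituents.
.resid_sc <- function(w, m, a, M) {
  L <- w * m
  M_mix <- .mixture_M(L, m, M)
  fr <- .f_frozen(w, m, a, M_mix)
  act <- m > 0
  if (!any(act)) return(0)
  max(abs(fr$f[act]) / fr$scale[act])
}

#' Solve the per-timestep partitioning system
#'
#' Damped Newton iteration on the simultaneous system, with the droplet
#' mixture molar mass updated to self-consistency between Newton passes.
#' The fully-evaporated branch (all mass fits in the vapor phase,
#' sum_i m_i/(a_i M_i) <= 1) is detected analytically and returned
#' directly.  If Newton stalls, a damped per-constituent quadratic sweep
#' (Gauss-Seidel on the same system) finishes the job.
#'
#' @param problem A [partition_problem()].
#' @param w_init Optional initial liquid fractions (e.g. the previous time
#'   step's solution); defaults to all-liquid (1).
#' @param tol Convergence tolerance on the scaled residual norm.
#' @param max_iter Maximum outer iterations.
#' @return A `"partition_result"`: liquid fractions w (clamped to
#'   \[0, 1\]), liquid/vapor masses with exact closure m_li + m_vi = m_i,
#'   a convergence flag and the final residual norm.  Non-convergence is
#'   reported in the flag, never silently.
#' @examples
#' consts <- default_constituents()
#' pb <- partition_problem(c(5e4, 5e4, 1e6, 3e3), consts, 296.15, 0.1)
#' solve_partition(pb)
#' @export
solve_partition <- function(problem, w_init = NULL, tol = 1e-10,
                            max_iter = 100L) {
  stopifnot(inherits(problem, "partition_problem"))
  m <- problem$total_masses
  n <- length(m)
  co <- .vle_coef(problem)
  a <- co$a; M <- co$M
  zero <- .partition_result(numeric(n), m, TRUE, 0, 0L)
  names(zero$liquid_fractions) <- co$names
  if (all(m <= 0)) return(zero)
  # dew criterion: liquid phase exists iff the saturation ratio exceeds 1.
  # Just past the boundary the interior root merges with w = 0, so within
  # 1e-9 of it the all-vapor state is returned directly (the roots differ
  # by less than the boundary offset).
  dew <- sum(m / (a * M))
  if (dew <= 1 + 1e-9) return(zero)
  act <- which(m > 0)
  # w = 0 is always a root of the algebraic system but is unphysical here
  # (the vapor would be supersaturated).  A genuine interior root has
  # vapor masses m_vi = a_i M_i x_i, so sum_i m_vi/(a_i M_i) = sum x_i = 1;
  # acceptance requires that identity alongside the residual norm.
  vap_err <- function(w)
    abs(sum((1 - w[act]) * m[act] / (a[act] * M[act])) - 1)
  vtol <- 1e-8 * dew
  w <- numeric(n)
  w[act] <- if (!is.null(w_init)) pmin(pmax(as.numeric(w_init)[act], 0), 1)
            else 1
  if (sum(w[act] * m[act]) <= 0) w[act] <- 1   # need liquid to define M
  iters <- 0L
  finish <- function(w, err, it) {
    res <- .partition_result(w, m, TRUE, err, it)
    names(res$liquid_fractions) <- co$names
    res
  }
  for (outer in seq_len(max_iter)) {
    iters <- outer
    L <- w * m
    if (sum(L) <= 0) { w[act] <- 1; L <- w * m }
    M_mix <- .mixture_M(L, m, M)
    # Newton passes with M frozen
    wa <- w[act]
    for (inner in 1:50) {
      fj <- .f_frozen(wa, m[act], a[act], M_mix, jacobian = TRUE)
      if (fj$err < 0.1 * tol) break
      step <- tryCatch(solve(fj$J, -fj$f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        wn <- pmin(pmax(wa + lam * step, 0), 1)
        if (.f_frozen(wn, m[act], a[act], M_mix)$err < fj$err ||
            lam < 1e-8) break
        lam <- lam / 2
      }
      if (max(abs(wn - wa)) < 1e-15) { wa <- wn; break }
      wa <- wn
    }
    w[act] <- wa
    err <- .resid_sc(w, m, a, M)
    if (err < tol && vap_err(w) < vtol) return(finish(w, err, iters))
    if (err < tol) break   # converged onto the spurious all-vapor root
  }
  # first fallback: collapse the system to one scalar equation in the
  # total liquid moles N (from m_i = n_i M_i (1 + a_i/N)), bracketed by
  # bisection, then checked against the full residual.  Robust close to
  # the dew boundary where the Newton system is near-degenerate.
  Nmax <- sum(m[act] / M[act])
  h <- function(N) N - sum(m[act] / (M[act] * (1 + a[act] / N)))
  root <- tryCatch(
    stats::uniroot(h, c(Nmax * 1e-18, Nmax), tol = 1e-15 * Nmax,
                   maxiter = 5000L)$root,
    error = function(e) NULL)
  if (!is.null(root)) {
    w[act] <- 1 / (1 + a[act] / root)
    err <- .resid_sc(w, m, a, M)
    if (err < tol && vap_err(w) < vtol)
      return(finish(w, err, iters + 1L))
  }
  # second fallback: damped quadratic Gauss-Seidel sweeps on the same
  # system, from the all-liquid point (which cannot collapse to w = 0)
  if (is.null(root)) w[act] <- 1
  for (sweep in seq_len(5000L)) {
    L <- w * m
    M_mix <- .mixture_M(L, m, M)
    for (i in act) {
      S <- sum(w[act] * m[act]) - w[i] * m[i]
      b <- a[i] * M_mix + S - m[i]
      disc <- b^2 + 4 * m[i] * S
      w[i] <- max(0, min(1, (-b + sqrt(disc)) / (2 * m[i])))
    }
    err <- .resid_sc(w, m, a, M)
    if (err < tol && vap_err(w) < vtol)
      return(finish(w, err, iters + sweep))
  }
  warning("partition solver did not converge (residual ", signif(err, 3),
          "); result flagged")
  res <- .partition_result(w, m, FALSE, err, iters + 5000L)
  names(res$liquid_fractions) <- co$names
  res
}

#' Brute-force partitioning oracle
#'
#' Solves the physical equilibrium statement directly, independently of
#' the simultaneous algebraic system: for each constituent the vapor mass
#' is a_i M_i x_i with x_i its mole fraction in the droplet, and the
#' liquid moles n_i are found by cyclic bisection (one `uniroot` per
#' constituent against the other constituents' current liquid moles) until
#' self-consistent.  The fully-evaporated branch is detected by checking
#' whether the hypothetical all-vapor partial pressures satisfy
#' sum_i p_i / (gamma_i P_sat,i) <= 1.  Intended for verification at small
#' N; quadratic cost per sweep.
#'
#' @param problem A [partition_problem()] (N <= 8 recommended).
#' @param tol Convergence tolerance on liquid moles (relative).
#' @param max_sweeps Maximum Gauss-Seidel sweeps.
#' @return A `"partition_result"`.
#' @export
brute_force_partition <- function(problem, tol = 1e-12,
                                  max_sweeps = 2000L) {
  stopifnot(inherits(problem, "partition_problem"))
  m_ug <- problem$total_masses
  specs <- problem$constituents
  Tk <- problem$temperature
  V <- problem$volume
  k <- length(m_ug)
  M <- vapply(specs, `[[`, 0, "molar_mass")
  gam <- vapply(specs, `[[`, 0, "gamma")
  psat <- vapply(specs, saturation_pressure, 0, temperature = Tk)
  nm <- vapply(specs, `[[`, "", "name")
  m_g <- m_ug * 1e-6
  done <- function(w, conv, res) {
    out <- .partition_result(w, m_ug, conv, res, 0L)
    names(out$liquid_fractions) <- nm
    out
  }
  if (all(m_g <= 0)) return(done(numeric(k), TRUE, 0))
  # all-vapor feasibility: partial pressure if everything evaporates
  p <- (m_g / M) * R_GAS * Tk / V
  if (sum(p / (gam * psat)) <= 1) return(done(numeric(k), TRUE, 0))
  a_mol <- gam * psat * V / (R_GAS * Tk)      # mol
  n <- m_g / M                                # start all-liquid
  conv <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    n_old <- n
    for (i in seq_len(k)) {
      if (m_g[i] <= 0) { n[i] <- 0; next }
      Nm <- sum(n) - n[i]
      if (Nm <= 0) {
        # pure droplet limit: x_i = 1
        n[i] <- max(0, (m_g[i] - a_mol[i] * M[i]) / M[i])
      } else {
        g <- function(ni) ni * M[i] + a_mol[i] * M[i] * ni / (Nm + ni) -
          m_g[i]
        hi <- m_g[i] / M[i]
        n[i] <- if (g(hi) <= 0) hi
                else stats::uniroot(g, c(0, hi), tol = 1e-16 * max(hi, 1),
                                    maxiter = 2000L)$root
      }
    }
    if (max(abs(n - n_old)) <= tol * max(sum(n), 1e-300)) {
      conv <- TRUE
      break
    }
  }
  w <- ifelse(m_g > 0, (n * M) / m_g, 0)
  err <- tryCatch(
    max(abs(partition_residual(pmin(pmax(w, 0), 1), problem)) /
          (m_ug + 1e-300)),
    error = function(e) NA_real_)
  done(w, conv, err)
}
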