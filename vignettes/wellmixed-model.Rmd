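---
title: "The well-mixed chamber model behind vapormix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The well-mixed chamber model behind vapormix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vapormix)
```

## The problem

When an e-vapor product is used indoors, only part of the inhaled aerosol
is exhaled back into the room, and the exhaled droplets — mostly
propylene glycol, glycerol, water and nicotine — evaporate within
seconds as they dilute into room air.  What a bystander is exposed to is
therefore governed by three competing processes: the emission rate into
the space, removal by fresh-air ventilation, and the thermodynamic
partitioning of each constituent between the shrinking droplets and the
vapor phase.  `vapormix` simulates all three for a single well-mixed
zone and reports time-resolved concentrations of each constituent.

"Well-mixed" means the room is treated as one perfectly stirred volume:
each constituent has a single spatially uniform concentration
$C_i(t)$.  This is the standard single-zone assumption of regulatory
indoor-air screening models; it deliberately cannot resolve near-field
plumes or how far the visible cloud travels (that requires a
CFD/distributed model and is out of scope here).

## Model equations

For $N$ constituents indexed by $i$, with total room mass $m_i$ (µg)
split between liquid (droplet) and vapor phases, the model is:

**Mass balance** (explicit update over a step $\Delta t$):
$$ m_i(t+\Delta t) = m_i(t) + \dot m_{in,i}\,\Delta t
   - Q_a \,\Delta t\, C_i(t), \qquad C_i = m_i / V_r $$
where $Q_a$ is the *fresh-air* ventilation flow (m³/h) and $V_r$ the
room volume.  Removal acts on the total concentration regardless of
phase — droplets and vapor leave with the same air.  Recirculated air
only mixes and is not counted in $Q_a$.

**Phase split.**  At each step, thermodynamic equilibrium is assumed
between droplets and vapor (droplet evaporation times are ~10 s, the
same order as the time step, and much shorter than ventilation time
scales).  With $w_i = m_{li}/m_i$ the liquid fraction, Raoult-type
equilibrium $ \rho_{v,i} = \gamma_i x_i P_{sat,i}(T) M_i / (RT) $
combined with the mixture relations
$y_i = x_i M_i / \sum_j x_j M_j$ and $M = \sum_i x_i M_i$
collapses into $N$ simultaneous algebraic equations

$$ f_i = m_i w_i^2 + w_i\Big(a_i M + \sum_{j \ne i} m_j w_j - m_i\Big)
   - \sum_{j \ne i} m_j w_j = 0, \qquad
   a_i = \frac{(\gamma P_{sat})_i V_r}{R T}. $$

$a_i M_i$ is the saturated vapor mass the room can hold for pure $i$
(for water at 25 °C and 113 m³, about 2.6 kg).  The system is exact:
substituting $x_i$ from the liquid masses reproduces it identically, so
a root is a true Raoult equilibrium, not an approximation.

**Existence of a droplet phase.**  $w = 0$ is always a root of the
algebraic system, but it is only physical when the hypothetical
all-vapor state is subsaturated, i.e. when the dew criterion
$\sum_i m_i/(a_i M_i) \le 1$ holds (equivalently
$\sum_i p_i / (\gamma_i P_{sat,i}) \le 1$).  Above that threshold an
interior root with liquid exists; at a genuine interior root the vapor
masses satisfy $\sum_i m_{vi}/(a_i M_i) = \sum_i x_i = 1$, which the
solver uses to reject the spurious all-vapor root.

## Numerical scheme

* **Time stepping** is the explicit update exactly as written above,
  default $\Delta t = 10$ s.  It requires
  $\mathrm{ACH}\cdot\Delta t \ll 1$; the simulator warns above 0.1 air
  changes per step and raises an error if a mass would go negative
  (advising a smaller step).  At ACH 2.25/h and $\Delta t = 10$ s the
  discrete decay rate differs from the continuous one by 0.3 %.
* **Partition solver** (`solve_partition`): damped Newton on the
  simultaneous system with the mixture molar mass $M$ frozen during each
  Newton pass and updated to self-consistency between passes; residual
  tolerance $10^{-10}$ (scaled), at most 100 outer iterations, warm
  started from the previous step's solution.  Two safeguards handle the
  near-degenerate region where the dew sum barely exceeds 1 and the
  interior root merges with $w=0$: (i) within $10^{-9}$ of the boundary
  the all-vapor state is returned outright; (ii) otherwise a reduction
  of the system to a single scalar equation in the total liquid moles
  $N$ ($n_i = m_i/(M_i(1 + a_i/N))$), solved by bisection, restarts the
  iteration.  Non-convergence is flagged in the result, never silent.
* **Verification oracle** (`brute_force_partition`): an independent
  implementation that never touches the algebraic system — cyclic
  per-constituent bisection on the mole balance
  $n_i M_i + a_i M_i\, n_i/(N_{-i}+n_i) = m_i$ — used in the test suite
  to confirm agreement to $10^{-6}$ on randomized small systems.
* **Water** participates fully: the room starts preloaded with vapor
  water from its relative humidity, and ventilation air carries moisture
  in at `vent_rh` while the room's water leaves at $C_{water}$.  An
  optional exhaled-breath moisture source exists but is off by default
  (its magnitude is not quantified in the source studies).
* Because removal acts on total $C_i$, total-concentration trajectories
  are *provably independent* of the phase split — and hence of the
  activity coefficients, which are poorly known.  The suite asserts this
  by perturbing every $\gamma_i$ by ±50 % and checking bit-level
  identical concentration trajectories.  Only the phase split and the
  particle diameter respond to $\gamma$.

## Constituent properties

Saturation pressures use an Antoine-type form
$\log_{10} P_{sat}[\mathrm{Pa}] = A - B/(T + C)$ with coefficients in
`inst/extdata/constituent_properties.csv` (replaceable by the user):

* **water**: the standard 1–100 °C Antoine set converted from
  mmHg/°C to Pa/K; reproduces the steam-table 3169 Pa at 25 °C within
  0.35 %.
* **nicotine, propylene glycol, glycerol**: two-parameter August fits
  ($C=0$) anchored at CRC handbook 25 °C vapor pressures (0.038, 0.129
  and 1.06×10⁻⁴ mmHg respectively) and the normal boiling points
  (247 °C, 187.6 °C, 290 °C).  Two-point fits are adequate because the
  simulations stay within a few kelvin of room temperature; the
  anchors pin the low-temperature end where it matters.

Activity coefficients default to 1 (ideal Raoult behavior).  The source
studies never disclose the values they used; the ideal default makes the
assumption explicit and, as noted above, total concentrations do not
depend on it.  Temperature-dependent activity models (UNIFAC/NRTL),
nicotine protonation chemistry and Kelvin (curvature) effects are out of
scope.

## Emission scenarios

Two source kinds are built in (see `builtin_scenario()`):

* **Machine releases** (`czogala_run1..4`): a smoking machine vents
  aerosol at e-liquid composition directly into a 39 m³ room, two
  sessions (0 and 30 min) of 7 or 15 puffs at one puff per 10 s, ACH
  9.86/6.81/6.83/6.80, 60 min horizon.  The per-puff aerosol mass is not
  reported alongside the source study; the bundled default of 10 mg/puff
  is an explicit, documented assumption (`puff_aerosol_mass_mg`), as is
  the non-nicotine e-liquid split (41.8/41.8/14.6 PG/glycerol/water
  around the reported 1.8 % nicotine).
* **Exhaled sources** (`mEEC_*`): 9 participants in a 113 m³ exposure
  chamber with 255 m³/h fresh air (ACH 2.26), each taking 10 puffs per
  30 min of a 5.2 mg/puff device (e-liquid 41/42/14.6/2.4 %
  PG/glycerol/water/nicotine), with mean exhaled fractions 6 %
  (propylene glycol), 15 % (glycerol) and 3.4 % (nicotine).  Exhaled
  water is excluded from the source (unquantified); room and ventilation
  humidity provide the water background.

Puffs are spread uniformly over the usage window by default — back-to-
back 30-minute sessions at constant per-session puff counts are exactly
a constant emission rate — with an impulse-train option
(`emission_mode = "impulse"`) that emits identical cumulative mass.
Representing exhaled usage as participants × puffs-per-hour ×
usage-window (rather than explicit session lists) makes every
sensitivity variant a one-field change from baseline, which the suite
regression-tests by diffing resolved configurations.  Temperature
(23 °C) and relative humidity (50 %) of the chamber scenarios are
typical conditioned-space values; they are not reported by the studies
and do not influence the non-water concentration outputs.

Per-participant variability in exhalation (individual values are not
published, only the 3.4 % mean and 16 % maximum) is represented by the
`mEEC_high_exhale` variant, which sets every participant to the maximum.

## Particle size

Droplet number is tracked with fresh puffs entering at a 0.5 µm mean
diameter and leaving with ventilation at the same first-order rate as
mass; there is no coagulation, deposition or wall loss, as in the
underlying model.  The reported mean diameter is that of the
volume-equivalent sphere given the current droplet-phase mass, particle
count and mixture liquid density.  In the exposure-chamber scenarios the
droplets evaporate essentially completely within one 10 s step
(diameter below 0.05 µm), consistent with the ~11 s half-life measured
for exhaled e-cigarette aerosol.  Late in a multi-hour run a small
droplet phase can re-form once glycerol approaches its saturation ratio
together with ambient humidity; this hygroscopic re-condensation affects
only the phase split, not total concentrations.  Absolute particle
counts inherit the assumed initial diameter, so diameters should be read
relative to the 0.5 µm starting value.

## What the tests do and do not show

The suite verifies the machinery against independent closed forms: the
single-zone analytic solution $C(t) = S/Q_a(1 - e^{-\mathrm{ACH}\,t})$
and its decay counterpart (to <1 % at $\Delta t = 10$ s), exact mass
conservation ledgers (emitted + initial = in-room + vented, to $10^{-9}$
relative), the brute-force equilibrium oracle on 100 randomized 2–4
component systems, superposition in the source term, plateau scaling
with $1/\mathrm{ACH}$ and with source strength, and the headline
chamber quantities (plateau ≈ 3 µg/m³ nicotine at baseline usage,
~1.5 µg/m³ at half usage, 98 % of plateau after ~100 min, decay to 1 %
in ~2 h after cessation).  Problem sizes are desk scale throughout: 4 h
horizons at $\Delta t = 10$ s are 1440 steps and run in a few seconds.

Passing these tests shows the model solves its own equations correctly
under the stated study conditions.  It does not validate the model
against new measurements: real rooms are not perfectly mixed, real users
vary puff-by-puff, exhaled fractions carry wide inter-individual spread,
and the machine-release scenarios depend on an assumed per-puff aerosol
mass.  Those are input uncertainties, not solver properties, and the
sweep utilities (`run_sweep`, `modify_scenario`) are the intended way to
explore them.
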