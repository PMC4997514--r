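# vapormix

Well-mixed single-zone simulation of indoor air levels of e-vapor
constituents — nicotine, propylene glycol, glycerol and water — released
into a ventilated space, for exposure scientists and indoor-air
modellers who need time-resolved secondhand-exposure estimates without
running chamber studies for every combination of room size, ventilation
rate, device and usage pattern.

## The model

The room is one perfectly mixed zone of volume $V_r$ ventilated with
fresh air at flow $Q_a$ (air-change rate $\mathrm{ACH} = Q_a/V_r$).
Each constituent's total mass $m_i$ (droplet + vapor phase) follows the
explicit mass balance

$$ m_i(t+\Delta t) = m_i(t) + \dot m_{in,i}\Delta t
   - Q_a \Delta t\, C_i(t), \qquad C_i = m_i/V_r , $$

and at every step the totals are re-partitioned between droplet and
vapor phase by solving the multicomponent Raoult-type equilibrium

$$ m_i w_i^2 + w_i\Big(a_i M + \textstyle\sum_{j\ne i} m_j w_j - m_i\Big)
   - \textstyle\sum_{j\ne i} m_j w_j = 0 , \qquad
   a_i = \frac{(\gamma P_{sat})_i V_r}{RT} , $$

where $w_i$ is the liquid mass fraction of constituent $i$ and $M$ the
droplet mixture molar mass.  Saturation pressures come from bundled
Antoine-type fits; activity coefficients default to ideal ($\gamma=1$)
and provably do not affect total concentrations (removal acts on total
$C_i$).  An independent brute-force equilibrium solver is included and
used by the tests as an oracle.  See the vignette
(`vignettes/wellmixed-model.Rmd`) for assumptions, parameter choices and
limitations.

## Worked example

Nine participants spend 4 h in a 113 m³ exposure chamber ventilated
with 255 m³/h fresh air, each taking 10 puffs per 30 min from a
5.2 mg/puff device (2.4 % nicotine e-liquid, 3.4 % of inhaled nicotine
exhaled):

```r
library(vapormix)
sim <- simulate_chamber(builtin_scenario("mEEC_baseline"))
summary(sim)
#>        constituent peak_ug_m3 mean_ug_m3 final_ug_m3 plateau_ug_m3
#> 1 propylene_glycol   9.03e+01   8.03e+01    9.03e+01      9.03e+01
#> 2         glycerol   2.31e+02   2.06e+02    2.31e+02      2.31e+02
#> 3            water   1.02e+07   1.02e+07    1.02e+07      1.02e+07
#> 4         nicotine   2.99e+00   2.66e+00    2.99e+00      2.99e+00

plateau_concentration(sim, "nicotine")                      # 2.99 ug/m^3
time_to_fraction_of_steady_state(sim, "nicotine", 0.98)/60  # 103.5 min
```

Nicotine climbs to a plateau of about 3 µg/m³ — the emission rate
balanced by ventilation removal, $S/Q_a$ — reaching 98 % of it after
about 100 min, and stays flat while use continues.  That plateau is two
orders of magnitude below the 500 µg/m³ occupational permissible
exposure limit and below the 15 µg/m³ detection limit of the standard
occupational-hygiene nicotine method.  `plot(sim)` draws the
trajectories; `run_scenario("mEEC_baseline", out_dir = "out")` writes
`timeseries.csv`, `summary.csv` and the resolved `config.json`.

Sensitivity variants are one-field changes from baseline:

```r
run_sweep("mEEC_baseline", "ach", c(2.25, 5))   # plateau scales as 1/ACH
builtin_scenario("mEEC_half_puffs")             # 10 instead of 20 puffs/h
builtin_scenario("mEEC_1h_use")                 # cessation after hour 1
```

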