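# wormDEB

Dynamic energy budget (DEB) modelling for the endogeic earthworm
*Aporrectodea caliginosa*, with movement as an explicit part of the energy
budget. Endogeic worms feed by burrowing through the upper mineral soil, so
temperature, soil moisture and organic matter content act on growth and
reproduction *through* movement. `wormDEB` implements that coupling as a
tested simulation and calibration pipeline for ecophysiologists and
ecotoxicologists who need mechanistic predictions of earthworm life history
under changing soil conditions.

## The model in brief

Four state variables — structural length *L*, reserve *E*, maturity *E_H*,
reproduction buffer *E_R* — evolve under the standard DEB κ-rule:

    dE/dt  = p_A − p_C            p_C = E (v/L − r)
    dL/dt  = max(0, r)/3 · L      r   = (E v L⁻⁴ − p_M/κ) / (E L⁻³ + E_G/κ)
    dE_H/dt (juvenile)  or  dE_R/dt (adult) = (κ_R) · max(0, (1−κ) p_C − k_J min(E_H, EH_p))

Assimilation is gated by two scaled functional responses,
`p_A = f_OM · f_M · p_am · L²`: a Holling type-II response of soil organic
matter (`f_OM`, half-saturation `p_am/F_m`) and a threshold-linear response
of moisture (`f_M`, zero below the movement threshold `m_0`). The same
threshold drives the burrow rate `B = k_b L² max(0, M − m_0)` and the
diapausing fraction `D = exp(−b_w max(0, M − m_0))`; cast production (soil
egestion) is the ingestion flux divided by the soil's energy density
`μ_OM·OM`. All rates share a three-parameter Arrhenius temperature
correction with an upper boundary `T_H` above which the response inverts.
Maturity thresholds `EH_b` and `EH_p` trigger birth and puberty by event
detection during integration (`deSolve`).

## Worked example

Life-history predictions at the reference parameter set (feeding level
f = 1; the time from birth to puberty is reported at the 15 °C husbandry
temperature of the underlying growth studies, all other entries are
temperature-invariant):

```r
library(wormDEB)
round(predict_zero_variate(deb_params()), 3)
#> time_since_birth_at_puberty             length_at_birth
#>                      91.229                       1.507
#>             ultimate_length       fresh_weight_at_birth
#>                       6.603                       0.027
#>     fresh_weight_at_puberty       ultimate_fresh_weight
#>                       0.506                       2.233
```

So a worm born at 1.5 cm and 0.027 g reaches puberty 91 d after birth at
0.5 g, and grows towards an ultimate 6.6 cm and 2.2 g — matching the
published fitted values (92.9 d, 1.5 cm, 6.7 cm, 0.03 g, 0.5 g, 2.3 g)
within the rounding of the printed parameters.

A full life cycle from the egg under constant conditions (20 °C, 20 %
moisture, 4 % organic matter), with feeding driven by the environment:

```r
env  <- deb_environment(T_C = 19.95, M = 20, OM = 4)
traj <- simulate_deb(deb_scenario(env, duration = 400, initial = "egg"),
                     deb_params())
traj$events$age_at_birth     # 58.6 d  (40.2 d cocoon delay + development)
traj$events$age_at_puberty   # 122.8 d
tail(traj$states[, c("time", "Ww_g", "eggs_cum", "cast_g_per_d")], 1)
#>     time      Ww_g eggs_cum cast_g_per_d
#> 204  400 0.8679902 71.34846    0.9297365
```

At these conditions `f_OM·f_M ≈ 0.78`, so the adult plateaus well below the
f = 1 ultimate weight while producing ~71 egg equivalents by day 400 and
egesting ~0.93 g of casts per day.

Parameter recovery with the built-in synthetic experiment generator
(cast production at 7 temperatures, n = 8, CV 15 %):

```r
rs <- recovery_study(experiment_design("cast_temperature"),
                     free = c("T_A", "T_AH", "T_H"),
                     n_replicates = 50, seed = 1)
median(rs$estimates$estimate[rs$estimates$parameter == "T_H"]) - 273.15
#> [1] 20.70411   # generating boundary: 20.05 °C
```

A thin command-line wrapper for the same operations lives at
`inst/cli/wormdeb.R` (subcommands `simulate`, `predict-zero-variate`,
`fit`, `generate`, `recover`).

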