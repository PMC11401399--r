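# sfrtsim

An agent-based simulator of tumor–immune dynamics under fractionated
radiotherapy, for computational radiobiology and mathematical oncology.
It addresses a concrete treatment-design question: when does spatially
fractionated GRID radiotherapy (SFRT-GRID) — which deliberately shields
part of the tumor behind dose "valleys" — match or beat uniform
whole-tumor radiotherapy (WTRT), given that radiation kills infiltrating
immune cells along with cancer cells, and that immunogenic cancer-cell
death can recruit fresh anti-tumor effectors?

## The model

Three agent classes live on a 68 × 51 lattice of 20 µm nodes (≈1.39 mm²
of tissue, one cell per node, Δt = 1 h): cancer cells **C**, cytotoxic
effector cells **E**, and immunosuppressive regulatory cells **R**.
Cancer cells cycle (~24 h), divide into vacant Moore-neighborhood nodes,
are quiescent when fully surrounded, migrate (≤6 nodes/h), and die
spontaneously at `p_a = 3·10⁻³ h⁻¹`. Immune cells perform directed
random walks toward their nearest target (`w = 0.81·v + 0.19·u`,
15 sub-moves/h), deliver at most one "hit" per hour, kill a target that
takes **3 hits within one hour**, and are exhausted after **10**
lifetime hits. Deaths and mitoses at hour *t* recruit immune cells at
*t + 1* through four rate channels (`ζ_apoptosis`, `ζ_effector` with
postcode homing probability `µ`, `ζ_regulatory`, and the
radiation-immunogenicity channel `ζ_Tx ∈ {0, 0.01, 0.1}`).

Radiation survival follows the linear–quadratic model

    SF_i(d) = exp(−α_i d/ξ − β_i (d/ξ)²),  ξ = 1 (cycling), ξ = 3 (quiescent)

calibrated to SF(2 Gy) = 0.49 / 0.60 / 0.77 for C / E / R. Lethally hit
cells are removed 8 h after the fraction; survivors' cycles lengthen by
2 h/Gy. The standard course is 2 Gy × 35 weekday fractions (70 Gy);
GRID blocks have 11-node circular openings on a 30- or 35-node square
lattice with valleys at 15 % of peak dose. The headline outcome is the
tumor-eradication probability `TE = cleared replicates / replicates`
over a 15-week horizon, plus attribution of cancer deaths by mechanism
(apoptosis / effector-mediated / radiation) in the 7-day and 1-day
windows before clearance.

## Worked example

```r
library(sfrtsim)

# a synthetic mIHC-style slide: dense cancer mass, sparse immune infiltrate
slide <- generate_synthetic_slide(seed = 42)
init  <- build_initial_state(slide)   # kappa = 20 µm/node mapping
init
#> <initial_state> 1661 agents (C=1622, E=16, R=23), kappa=20, retention=0.646

config   <- abm_config()              # reference parameter set, zeta_tx = 0
schedule <- make_schedule("WTRT")     # 2 Gy x 35 weekday fractions
schedule
#> <treatment_schedule> WTRT: 35 fractions, 70 Gy total peak dose, open fraction 1.000

trajs <- run_replicates(init, config, schedule, replicates = 20, base_seed = 1)
tumor_eradication_probability(trajs)
#> [1] 0

config_hi <- abm_config(recruitment = recruitment_rates(zeta_tx = 0.1))
trajs_hi  <- run_replicates(init, config_hi, schedule, replicates = 20, base_seed = 1)
tumor_eradication_probability(trajs_hi)
#> [1] 0.1

summarize_outcomes(trajs_hi)$attribution$window_168h
#>   replicate apoptosis effector radiation   primary  tied
#> 1         1       259      773      2116 radiation FALSE
#> 2         7       181      813      1350 radiation FALSE
```

With `ζ_Tx = 0` (radiation kills but does not recruit), fractionated
WTRT always fails here: the tumor is driven to a nadir of a few dozen
cells, but repopulation outruns the log-cell kill while the effector
population stays at zero — so `TE = 0`. Making radiation death highly
immunogenic (`ζ_Tx = 0.1`) feeds the effector population in proportion
to radiation damage and tips a fraction of replicates into
immune-mediated eradication (here 2 of 20, cleared at hours 44 and 88);
the 7-day attribution table shows radiation as the dominant death
mechanism in those early WTRT clearances, with a large effector
contribution. `mean_dose()` and the GRID dose maps
(`build_grid_dose_map()`) quantify how much less physical dose
SFRT-GRID delivers (0.81 / 1.15 Gy mean per 2 Gy fraction at 30 % /
50 % open) while sheltering immune reservoirs in the valleys.

A thin CLI wraps the same functions (`exec/sfrtsim`): subcommands
`synth`, `dosemap`, `run`, `analyze`.

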