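---
title: "An on-lattice model of tumor-immune dynamics under whole-tumor and GRID radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An on-lattice model of tumor-immune dynamics under whole-tumor and GRID radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfrtsim)
```

## The model

`sfrtsim` simulates three interacting cell populations on a 2D lattice:
cancer cells (C), anti-tumor effector immune cells (E, a cytotoxic CD8+
T-cell proxy) and pro-tumor regulatory immune cells (R, a FOXP3+ Treg
proxy). The domain is a 68 x 51 grid of 20 um nodes (about 1.39 mm^2 of
tissue, one node per cell diameter); each node holds at most one agent,
boundaries are closed, and the timestep is 1 hour.

**Cancer agents** carry an individual cell-cycle length (drawn at birth
from a truncated normal centered on 24 h) and a position in that cycle.
Each hour a cancer cell

1. dies spontaneously with probability `p_a = 3e-3` (mean lifespan about
   14 days), freeing its node immediately;
2. advances its cycle by one hour if any Moore-neighborhood node is
   vacant, and is quiescent otherwise (space inhibition);
3. divides when the cycle completes, placing the daughter on a uniformly
   random vacant Moore node;
4. with probability `p_m = 0.9` performs up to 6 single-node random
   moves (2.3 um/min at 20 um nodes).

**Immune agents** migrate by a directed random walk: each of 15 hourly
sub-moves (5 um/min) finds the nearest target within a 50-node radius
(effectors target cancer cells, regulatory cells target effectors) and
steps into the vacant Moore node best aligned with
`w = (1 - eta) v + eta u`, where `u` points at the target, `v` is a
random unit vector and `eta = 0.19`; with no target in range the walk is
Brownian. After migrating, an immune cell delivers at most one "hit" to
one adjacent target per hour. A target dies when it accumulates three
hits within a single hour; fewer hits repair fully at the end of the
hour. An immune cell is exhausted and removed after 10 lifetime hits.

**Recruitment** converts the previous hour's death and mitosis ledger
into new immune agents: effectors at rate `zeta_apoptosis` per
spontaneous cancer death and `zeta_effector` per effector-mediated kill
(the latter placed within 10 nodes of a kill site with probability `mu`,
the "postcode" homing assumption), regulatory cells at
`zeta_regulatory` per mitosis, and effectors at `zeta_tx` per
radiation-induced death — the radiation-immunogenicity channel, studied
at the three levels 0 (none), 0.01 (low) and 0.1 (high). Rates multiply
integer counts; fractional parts are carried forward so long-run totals
are exact. All other recruits are placed uniformly on vacant nodes,
reflecting a uniform vasculature.

**Radiation** follows the linear-quadratic model. A cell of class *i*
survives a fraction of dose *d* with probability
`SF_i(d) = exp(-alpha_i d/xi - beta_i (d/xi)^2)`, with `xi = 1` for
actively cycling cells and `xi = 3` for quiescent ones. The per-class
parameters are calibrated so that `SF_C(2 Gy) = 0.49`,
`SF_E(2 Gy) = 0.60` and `SF_R(2 Gy) = 0.77`; the alpha/beta ratio
(default 10 Gy for cancer, 3 Gy for lymphocytes) only matters away from
2 Gy per fraction. Radiation death is not immediate: casualties are
removed 8 h after the fraction, and surviving cycling cancer cells have
their cycle lengthened by 2 h per Gy of nominal node dose.

**Treatment** is 2 Gy per weekday fraction for 7 weeks (35 fractions,
70 Gy). Whole-tumor radiotherapy (WTRT) irradiates every node
uniformly. SFRT-GRID irradiates through a virtual collimator block:
circular openings 11 nodes across on a square lattice of opening
centers (spacing 30 or 35 nodes), with shielded "valley" nodes
receiving 15% of the peak dose. Simulations run for at most 15 weeks
(treatment plus 8 weeks of follow-up) and stop early when the cancer
population reaches zero; the tumor-eradication probability TE is the
cleared fraction of independent replicates.

## Worked example

```{r example, eval = FALSE}
slide <- generate_synthetic_slide(seed = 42) # reference composition
init <- build_initial_state(slide) # kappa = 20 mapping, first-wins collisions
config <- abm_config(recruitment = recruitment_rates(zeta_tx = 0.1))
schedule <- make_schedule("WTRT") # 2 Gy x 35 weekday fractions

trajs <- run_replicates(init, config, schedule,
  replicates = 20, base_seed = 1
)
tumor_eradication_probability(trajs)
summarize_outcomes(trajs)$attribution$window_168h
```

## Choices made where the underlying description is open

Several aspects of the model are under-determined by its published
description; the package fixes them as follows and exposes each as a
configurable parameter.

- **Distance metric and boundaries.** Radius queries use Euclidean
  distance on node indices (matching the circular GRID openings);
  boundaries are closed, with no wraparound — the domain is a fixed
  tissue section.
- **Timestep phase order.** Each hour runs: recruit placement (from the
  previous hour's ledger), radiation if scheduled, agent updates in a
  uniformly shuffled order (avoiding raster-order artifacts), hit
  resolution, ledger close. Daughters born during an hour first act the
  following hour.
- **Collision policy at initialization.** When two table rows map to
  one node, the first row in file order wins; dropped counts are
  reported. Retention falls as the conversion factor `kappa` grows.
  This inverse trend is statistical rather than strict — bins at
  `kappa = 100` are not refinements of bins at `kappa = 80`, so single
  cell pairs can de-collide — but collision growth dominates on dense
  tables.
- **Cycle-length distribution.** Truncated normal, mean 24 h, SD 2 h,
  bounds [18, 30] h; the initial cycle position is uniform on
  [0, div_length/2].
- **Doomed cells.** A cell that failed its survival draw still occupies
  its node, may migrate, cannot divide, and can be killed earlier by
  effector hits (then attributed to the effector mechanism).
- **Immune radiosensitivity.** Immune agents do not cycle in this
  model, so they are irradiated at `xi = 1`; their SF(2 Gy) targets
  already encode their sensitivity.
- **Fractional recruits.** Floor-with-carry accumulators per channel:
  deterministic, and exact in the long run (total recruits differ from
  rate x deaths by less than one).
- **Postcode fallback.** If the radius-10 disk around the sampled kill
  site has no vacancy, the recruit is placed globally at random rather
  than discarded.
- **Exhaustion.** The 10-hit budget counts all delivered hits, lethal
  or repaired.
- **GRID geometry.** Opening centers are anchored to the domain
  midpoint and never move between fractions (perfect inter-fraction
  alignment; intra-fraction dose smearing is out of scope). A node is
  "open" when its center lies within the opening radius, inclusive.
  Note two internal tensions in the source description of the blocks:
  a peak-to-valley dose ratio of 15 would put valleys at ~6.7% of peak,
  but the stated valley level (15% of peak) is the only one consistent
  with the stated mean doses of 0.81 and 1.15 Gy per 2 Gy fraction at
  30% and 50% open fractions, so `valley_fraction = 0.15` is the
  default. Likewise, circular 11-node openings at spacings of 30 and 35
  nodes geometrically cover about 11% and 8% of the plane, not the
  stated 30% and 50%; `build_grid_dose_map()` therefore reports its
  realized open fraction, and `mean_dose()` accepts the open fraction
  as an explicit argument so that domain-average doses can be computed
  for the stated compositions.

## What the synthetic slide generator emulates

Real initial conditions are per-cell tables from multiplex IHC slides
of head-and-neck tumors, reduced to the three agent classes
(pan-cytokeratin+ to cancer; CD3+CD8+ to effector; CD3+CD4+FOXP3+ to
regulatory; macrophages and non-regulatory helpers ignored).
`generate_synthetic_slide()` emulates such a table: a Gaussian
cancer-cell mass in a 1360 um x 1020 um field with immune cells split
between uniform scatter and the tumor margin according to a `clustering`
weight. Low immune counts at low clustering emulate an immune desert;
high counts at high clustering an inflamed, infiltrated tumor.

It does **not** emulate tissue architecture (stroma, vessels, necrotic
cores), marker misclassification, segmentation artifacts, or the
irregular tumor outlines of real sections. Tests passing on synthetic
slides therefore validate the simulator's mechanics and statistics, not
any claim about real patient tissue.

## The reference parameter set and the study conditions

The four immune recruitment rates are not identifiable from first
principles; the model's published description estimates them by Latin
Hypercube screening and retains sets whose untreated dynamics are
biologically sensible. The package follows the same logic for its
reference defaults (`recruitment_rates()`), which were fixed once by a
coarse screen under three constraints, in this order:

1. untreated tumors must escape immune surveillance (a clinically
   detectable tumor has, by definition, evaded immunity);
2. WTRT whose only effect is DNA damage (`zeta_tx = 0`) must not
   eradicate: fractionated radiotherapy alone loses the repopulation
   race;
3. a highly immunogenic response (`zeta_tx = 0.1`) should measurably
   improve tumor control.

The reference values are `zeta_apoptosis = 0.01`, `zeta_effector = 8`
with `mu = 1`, `zeta_regulatory = 0.1`, and the reference synthetic
slide holds 2500 cancer cells with sparse immune infiltration (30
effectors, 40 regulatory cells, clustering 0.5). Rates are "cells
recruited per event" and may exceed one; the reference
`zeta_effector` sits at the top of the screened range and encodes
strong local amplification of cytotoxic activity around a kill site
(antigen release plus postcode homing).

A dynamical note on why the calibration constraints are in tension:
every effector source in the model scales with the cancer population
(deaths drive recruitment), and a kill requires three coincident hits,
so effector pressure is superlinear in the local effector-to-target
ratio. The system has a sharp ignition threshold: sparse effectors burn
out their 10-hit budgets on uncoordinated sub-lethal hits that repair
fully, while a sufficient local density ignites a self-amplifying kill
cascade (each kill recruits `zeta_effector` new effectors to the kill
site). Radiotherapy moves the system relative to this threshold in both
directions at once — it debulks the tumor (improving the
effector-to-target ratio) but also kills effectors (SF 0.60 per
fraction) and, only when radiation death is immunogenic, replenishes
them in proportion to the damage it causes. Under the reference set, a
treated tumor at `zeta_tx = 0` has essentially no effectors at any
point (the weak apoptosis channel recruits a handful over the whole
course), so eradication never occurs; at `zeta_tx = 0.1` each fraction
recruits tens of effectors, and the cascade ignites in a minority of
replicates — early, while the effector surge coincides with
radiation-driven tumor shrinkage, or during the post-weekend windows
when recruits persist unirradiated. Under immune-richer initial
conditions (several hundred margin-clustered effectors,
`generate_synthetic_slide(clustering = 0.9)` with high counts) the
cascade ignites without any treatment, which is why such compositions
fail the untreated-escape constraint and were not adopted as the
reference condition.

## Problem sizes and tolerances

Stochastic checks in the test suite use cohort sizes chosen so that the
acceptance bands are a small multiple of the Monte-Carlo standard
error: 1e5 survival draws for the LQ calibration (3 binomial SE around
SF(2 Gy)), about 1e4 agent lifetimes for the apoptosis clock (3 SE
around the 13.9-day analytic mean), and qualitative treatment contrasts
at 20 replicates (the replicate count is scaled down from 50, which
widens the TE standard error to about 0.11 at TE = 0.5). LQ calibration
is solved in closed form and reproduces its target to 1e-9;
dose-map averages agree with the open-fraction formula to 1e-12.

## Known limitations

- 2D, single-occupancy, fixed 20 um granularity; no cell pushing.
- Chemotaxis is abstracted to nearest-target-seeking; no chemokine
  fields.
- No re-oxygenation, radiosensitization or dose-smearing effects.
- Immune agents have no spontaneous death by default (a lifespan would
  be another free parameter); they die only by exhaustion, regulatory
  kills or radiation.
- The headline eradication percentages of the source study depend on
  four patient slides and supplementary parameter tables that are not
  public; the package reproduces the model's mechanics and its
  qualitative treatment contrasts, not those exact percentages.
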