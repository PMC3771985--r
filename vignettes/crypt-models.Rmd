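---
title: "Pedigree and niche models of the colonic crypt: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree and niche models of the colonic crypt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cryptsim)
```

## The biological problem

The colonic epithelium of the mouse renews itself every two to three days.
New cells are born from proliferative cells at the base of millions of
crypts — tubular pits in the epithelium — mature as they migrate along the
crypt wall, and are shed at the orifice.  How this production line is
regulated is contested.  Two idealised concepts bracket the possibilities:

* **Pedigree**: cell fate is preprogrammed.  Immortal stem cells sit
  attached at the crypt base and divide asymmetrically into one stem cell
  and one transit-amplifying (TA) cell; TA cells divide symmetrically
  through a fixed number of generations (default 5) and then both daughters
  leave the cycle for good (G0, "mature").
* **Niche**: fate is positional.  All divisions are symmetric; whatever
  sits in the supportive microenvironment at the base (the niche,
  modelled as the bottom fraction `proliferation_region` of the crypt)
  keeps cycling, and cells mature when they leave it — either only at
  birth (scheme A, `only_new_cells_mature = TRUE`) or also whenever a cell
  still in G1 crosses the boundary (scheme B).

`cryptsim` implements both inside one lattice-free, cell-centre simulator
so that the two concepts can be compared on equal terms: same geometry,
same cell cycle, same mechanics, different fate rules.

## Model components

### Geometry

The crypt wall is a monolayer, so it is unrolled into a 2D rectangle with
periodic left/right borders (an open cylinder): `y = 0` is the base,
`y = height` the orifice; cells whose centre passes the orifice are removed
and counted as produced.  The reference crypt holds 22 cells around and 32
along.  Dimensions are finely tuned so that exactly 704 mean-sized cells
fit at the equilibrium overlap: the effective diameter is
`2 * mean_radius - delta_eq` (9.5 um with the defaults), and width and
height are 22 and 32 multiples of it, which makes the perfect-packing
capacity of 704 exact by construction (a square arrangement; see the
limitations section for what the dynamics actually pack).

### Cell cycle (Smith-Martin with explicit growth)

Cells follow a two-phase cycle: a stochastic phase A, identified with G1,
left with constant probability per unit time (exactly
`1 - exp(-dt/g1_mean)` per step, so the law is independent of step size),
followed by a deterministic phase B = S + G2 + M.  TA cells use
G1/S/G2/M = 7.0/6.2/1.8/0.5 h; stem cells are slower at 22.5/20.0/6.0/1.5 h.
The niche model has a single proliferative class that cycles at the TA
rates.

Cells are elastic discs.  Each cell grows linearly in area during G1 and G2
at the class-wide rate `pi * mean_radius^2 / (g1 + g2)` per hour, so an
average cell doubles its area over an average cycle; at division the mother
splits into two daughters of half its area, placed symmetrically so they
just touch, along the vertical axis when `vertical_division_only` is set
(the calibrated scenarios) or a uniformly random axis otherwise.  Because
phase A is exponential, cell sizes vary; a maximum radius (7.5 um, slightly
above the dividing radius `sqrt(2) * 5 ~ 7.07`) caps runaway growth and a
minimum radius gates departure from G1 so that lineages cannot shrink
without bound.  The minimum is set at 4.5 um, below the typical birth
radius (~4.9-5.3 um): the gate then binds only in the small-cell tail and
the stochastic phase keeps its exponential mean — with a larger minimum
the gate would silently stretch every G1 by the time needed to grow to the
threshold, which contradicts the mean-7-h law the cycle is built on.

### Mechanics

The dynamics are overdamped: drag against the basement membrane dominates,
forces balance at every instant, and each contact force enters as a
velocity contribution (force over the drag coefficient eta).  The contact
law is Hookean with an equilibrium overlap `delta_eq` (default 0.5 um):
repulsion `k_over_eta * (overlap - delta_eq)` beyond it, and a constant
attraction `attr_over_eta` (cell adhesion, filopodia) below it out to a
reach `attr_distance`.  Positions advance by forward Euler — the
inertialess limit in which the named velocity-Verlet scheme degenerates —
and an instability detector aborts any run in which a cell moves more than
its own radius in one step.

**Calibration of `k_over_eta` and `dt`.**  The previously reported
estimate of the spring constant over drag (1e-7 /s) produces relaxation
times of months and cannot transport cells through the crypt at
physiological production rates, so the package calibrates the stiffness
from two a-priori requirements.  (i) *Quasi-static tissue*: at
the physiological production rate (~13 cells/h over 22 columns the top-row
migration speed is ~1.6e-3 um/s) the column of up to ~21 mature cells above
a contact must be dragged along by that contact's spring compression;
keeping that compression well below the cell radius requires
`k_over_eta ~ 0.05 /s`, which also makes the pair relaxation time
(`1/(2k) = 10 s`) far shorter than the hours-scale cell motion.  (ii)
*Stability*: explicit Euler with ~6 contacts per cell needs
`k * n * dt < 1`, hence the default step of 2 s.  Both remain configurable;
a 10-s step is stable below `k ~ 0.015 /s`.

The two remaining movement switches follow the study design: lateral
migration can be disabled (cells then move in vertical bands), and in the
pedigree model stem cells can be hard-anchored to their base positions.
Active migration, when enabled, adds a constant upward drift (default equal
in magnitude to the attraction speed) to every non-anchored cell; the
mechanism behind this switch is not specified in the source material and
this minimal upward bias is a reconstruction.

### Runs, steady state, measures

Every run starts from a single row of 22 cells at the base (stem cells in
the pedigree model), with unsynchronised cycle clocks, and grows the crypt
from there.  Steady state is detected from the hourly total-cell series:
the gradient is measured with a 12-h moving-average window, and the onset
is the first hour at which `|gradient| < 0.5` cells/h after the gradient
has been above that tolerance for a sustained full window.  The
"sustained" qualifier matters: a 22-cell founding population has division
lulls that briefly flatten the early series, and arming the detector on a
single positive sample would stop the run mid-growth.  Measurements are
then time-averaged over the following 3 simulated days:

* total cell number (reference 704),
* proliferative cell number (reference 200),
* cell production rate = cells removed at the orifice per hour,
* mature proportion, and
* mature-cell order: each cell's order is the fraction of its contact
  neighbours that are mature, and the statistic is the mean over mature
  cells.  It approaches 1 for a perfectly segregated mature compartment
  and is below 1 whenever proliferative and mature cells touch.  The
  indicator inside the neighbour sum is the unweighted mature fraction;
  weighting neighbours by contact area is a conceivable refinement that
  the available reference behaviour does not distinguish.

The production normalisation target defaults to 13 cells/h, which follows
from steady-state turnover (about 200 proliferative cells with a ~15.5-h
mean TA cycle), and is configurable.

### Labelling index and clonal ribbons

An LI experiment marks every S-phase cell at steady state; marks are
inherited and never cleared, and after a 1-h chase the labelled proportion
per crypt row (32 rows, binned by cell centre) is reported with replicate
means and standard deviations.  A clone experiment marks distinct base-row
cells; the ribbon gap statistic counts unmarked cells vertically
interposed between marked cells of the same clone within a column — a
formalisation chosen here so that the qualitative claim "gaps appear in
pedigree ribbons when lateral migration is allowed, but not in niche
ribbons" becomes testable.

### Sensitivity analysis

The relative sensitivity function `(p/f) df/dp` at the normal operating
point is estimated by a central finite difference of the normalised
response at `p0 (1 +/- delta)`, with `delta = 0.1` by default: 10% is
standard practice for empirical RSF estimation and stays near the
operating point.
Each function evaluation is the mean of replicate runs, and the same
replicate seeds are used at every evaluation point (common random numbers),
which cancels a large part of the Monte-Carlo noise from the paired
difference.  Standard errors over replicate pairings are reported.

### Parametric sweep and gating

`parameter_grid()` enumerates the full Cartesian product of the free
parameters (attraction strength and reach, active migration, lateral
migration, vertical-only division; plus maturation scheme and niche size
for the niche model): 72 pedigree and 576 niche parameter sets.
`gate_runs()` applies
the sequential gating used for model selection — first total cell number
(normalised within [0.99, 1.01]), then production rate (up to 1.12), then
cell-maturity criteria — and ranks survivors by production closest to 1,
breaking ties toward higher mature order.

## Adapted variants

Two hybrid variants bridge the concepts: the adapted pedigree model
removes all cell-cycle stochasticity (every phase A lasts exactly its
mean, cells out of phase), which sharpens its proliferative/mature
boundary; the adapted niche model replaces the hard niche boundary with a
position-dependent maturation probability — a linear ramp from 0 to 1
centred on the boundary with half-width 0.15 of the crypt height, the
simplest monotone profile that smooths the labelling-index shoulder.  Because a per-2-s-step Bernoulli would mature
every cell almost instantly wherever the ramp is positive, the
probabilistic rule is evaluated at birth and at hourly checkpoints for G1
cells, making the ramp value an approximate per-hour hazard.

## Numerical and degenerate-input choices

* Update order within a step is fixed: cycle advance and growth, niche
  fate checks, divisions, mechanics, removal.  The source material does
  not specify an order; this one is documented so runs are reproducible.
* Coincident cell centres (a measure-zero degeneracy after divisions)
  receive a uniformly random force direction from the run's seeded stream.
* All randomness in a run comes from one stream seeded by `(seed)`;
  replicate r of a batch uses `seed + r - 1`, so any replicate can be
  reproduced alone and batches are independent of execution order.
* `dt` must divide one hour exactly so that hourly bookkeeping is exact.

## Problem sizes used by the shipped tests

The packaged test-suite and acceptance script run the full-size crypt
(22 x 32) but scale replication to suite scale: 10 replicates for the
calibrated niche scenario (conventional replication is 30 runs), 2
replicates per evaluation point with a 2-day measurement window for the
sensitivity checks, and module-level dynamics tests on a 6 x 10 miniature
crypt.  These counts are the package's own choice of suite scale;
`simulate_crypt()` defaults to the full 30 replicates.  At suite scale
the sensitivity estimates resolve the strong responses (production and
cell number) but not the near-zero ones (order, niche mature proportion),
whose standard errors exceed their magnitudes.

## What the simulator does and does not show

The generator emulates crypt-scale consequences of single-cell rules:
steady-state cell numbers, production, spatial ordering, LI profiles and
clonal ribbons as they emerge from cycle + growth + mechanics + fate.  It
does not model 3D crypt shape (including the hemispherical base), crypt
buckling or basement-membrane deformation, molecular signalling (WNT
gradients are abstracted into the niche boundary), apoptosis, or
experimental LI measurement noise — so agreement with the reference
numbers supports the *consistency* of a concept with crypt-scale
observables, not the molecular mechanism behind it.  The pedigree model
with anchored stems cannot, by construction, reproduce monoclonal
conversion; that asymmetry between the concepts is a finding, not a bug.

## A worked comparison

```{r example}
niche <- simulate_crypt(crypt_scenario("niche-run296"), replicates = 10,
                        seed = 1)
summary(niche)

pedigree <- simulate_crypt(crypt_scenario("pedigree-run13"), replicates = 10,
                           seed = 1)
summary(pedigree)

sens <- cycle_sensitivity(crypt_scenario("niche-run296"), "g1",
                          replicates = 10, seed = 1)
print(sens)

li <- simulate_li(crypt_scenario("niche-run296"), replicates = 10, seed = 1)
plot(li)
```

## Known limitations

* The spring-constant calibration replaces an unusable literature value;
  absolute migration speeds therefore inherit the calibration, though
  steady-state counts and proportions are insensitive to it across the
  quasi-static regime.
* Steady-state totals of the calibrated scenarios run a few percent above
  the 704-cell packing capacity: cells pack denser than the square
  arrangement the tuning rule assumes (partially hexagonal order, plus
  production-driven compression).
* The mature-order indicator, gap statistic, active-migration mechanism,
  adapted-niche ramp and geometry tuning rule are reconstructions of
  under-specified components, each flagged above.
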