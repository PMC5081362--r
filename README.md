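# fibrostrand

Cell-based simulation of impulse conduction in engineered cardiac strands
containing myofibroblasts.

## What it is for

Cardiac fibrosis mixes unexcitable, depolarized myofibroblasts (MFBs, rest
about -36 mV) into the cardiomyocyte (CMC) syncytium, where they couple to
CMCs through gap junctions and slow or block conduction. `fibrostrand` is a
mechanistic, high-resolution two-dimensional monodomain simulator of
patterned-growth CMC strands (3000 x 80 um cultures) for researchers in
computational cardiac electrophysiology. It reproduces, at the level of
individual cells, how three MFB arrangements change conduction: MFBs
embedded *within* the strand (endogenous), MFBs seeded *on top* of it
(coating, CMC-sized or twice-CMC-sized), and MFB *inserts* bridging a gap in
the strand.

The model, briefly:

* **Tissue**: a jittered anisotropic Voronoi tessellation into convex cell
  polygons (mean CMC footprint `pi*L*W/4` with L = 60, W = 20 um),
  discretized on a 2.5 um lattice into a resistor-capacitor network. Gap
  junctional coupling per contact is `G = gamma * L_c` (gamma = 77.4 nS/um
  CMC-CMC, 5x smaller when an MFB is involved), redistributed evenly over
  the discretized staircase boundary; cytoplasmic resistivity 124 Ohm cm;
  cell capacitance `C_m (2A + T P)` with `C_m` = 1 uF/cm^2.
* **Membranes**: a modified Luo-Rudy I ventricular model for CMCs (Korhonen
  inward rectifier, no background current, accelerated and +6 mV-shifted
  L-type Ca2+ gating, g_K = 0.5 mS/uF, g_Na = 8.1 mS/uF; rest at -78.4 mV)
  and a passive fitted current for MFBs (rest at -36.1 mV).
* **Numerics**: operator splitting at a fixed 0.005 ms step — Rush-Larsen
  gate updates from 0.01 mV lookup tables, forward-Euler Ca2+, and
  Crank-Nicolson diffusion solved by a one-time sparse Cholesky
  factorization and two triangular solves per step (compiled core).
* **Protocols**: quiescent equilibration with spontaneous-activity
  detection, stimulation at one strand extremity, per-node maps of RMP,
  activation time and dV/dt_max, conduction velocity by regression of
  earliest activation over 25-75% of the strand, and conduction delays
  across MFB inserts from two-segment extrapolation.

See `vignettes/fibrostrand-methods.Rmd` for assumptions, calibrations and
numerical choices.

## A worked example

A control strand versus a strand with 30% endogenous MFBs:

```r
library(fibrostrand)

tess    <- tessellate_strand(c(3000, 80), spec_cmc(), rng_seed = 11)
control <- assign_endogenous(tess, 0,   rng_seed = 11)
fibrotic<- assign_endogenous(tess, 0.3, rng_seed = 11)

m0 <- stimulate_and_measure(control,  equil = list(equil_dt = 0.05))
m1 <- stimulate_and_measure(fibrotic, equil = list(equil_dt = 0.05))
glance(m0); glance(m1)
```

```
# A tibble: 1 x 8
  configuration mfb_density    cv mean_rmp mean_dvdt_max spontaneous blocked
  <chr>               <dbl> <dbl>    <dbl>         <dbl> <lgl>       <lgl>
1 control                 0  40.4    -78.5          103. FALSE       FALSE
# A tibble: 1 x 8
  configuration mfb_density    cv mean_rmp mean_dvdt_max spontaneous blocked
1 endogenous          0.298  26.0    -73.3          64.2 FALSE       FALSE
```

The control strand conducts at about 40 cm/s with a mean maximal upstroke
velocity around 103 V/s, matching the calibration targets of 41.4 cm/s and
106.8 V/s. Embedding 30% MFBs depolarizes the strand by ~5 mV (reducing Na+
channel availability), cuts dV/dt_max by ~40%, and slows conduction by about
a third — the MFBs act at once as depolarizing current sources, capacitive
loads and resistive obstacles. `tidy(m1)` returns the per-node maps;
`autoplot(m1)` draws the activation isochrones and `autoplot(fibrotic)` the
cellular architecture.

Scenario sweeps (density grids, replicate tissues, perturbations such as
strongly coupled or artificially excitable MFBs) run through
`scenario_config()` + `run_scenario()`; a thin command-line front end is
installed at `inst/cli/fibrostrand`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes from scratch, using only the installed package: the resting
potentials of both membrane models (root of the steady-state I-V), the mean
single-CMC and large-MFB capacitances and the monolayer capacitance per unit
area emerging from seeded tessellations under the geometric capacitance
rule, and the mean resting potential of 3000 x 80 um strands containing 40%
endogenous MFBs (three tissue realizations, drift-terminated equilibration),
writing one JSON object with one numeric value per quantity.
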