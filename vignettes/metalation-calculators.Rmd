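---
title: "Predicting in vivo protein metalation from metal availabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting in vivo protein metalation from metal availabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalation)
```

## The problem

Most metalloproteins bind the "wrong" metals more tightly than their
cognate one: at a flexible site, complex stability follows the
Irving–Williams series (Mn²⁺ < Fe²⁺ < Co²⁺ < Ni²⁺ < Cu⁺/Cu²⁺ > Zn²⁺)
regardless of which metal the protein needs. Cells solve this by buffering
the *availability* of each metal inversely to that series: the tighter a
metal binds, the lower the free concentration of its exchangeable,
labile-bound pool. Whether a protein acquires a given metal in vivo
therefore depends on a competition between the protein and the cytosolic
buffer, and between the metals themselves.

This package turns that picture into numbers for *Escherichia coli* JM109
(DE3) grown in LB media under three conditions — aerobic, anaerobic, and
after H₂O₂ exposure — and implements the full calibration pipeline by which
such condition-specific availabilities are inferred from the transcriptional
state of the cell's own metal sensors.

## Availabilities as free energies

An availability is expressed as the free energy of forming a metal complex
that would be 50% saturated at the buffered concentration:

$$\Delta G_{\mathrm{Metal}} = RT\,\ln[\mathrm{Metal}]$$

with $R = 8.314\times10^{-3}$ kJ K⁻¹ mol⁻¹ and $T = 298.15$ K (the
convention the availability estimates were derived under; both are
overridable through `thermo_constants()`, e.g. to probe growth temperature,
but the defaults are deliberately fixed). The same relationship applied to a
protein's dissociation constant $K_D$ gives the free energy of forming its
half-saturated complex, so the *gradient*
$\Delta\Delta G = RT\ln K_D - RT\ln[\mathrm{M}]$ measures how favourably
the metal partitions from the buffer onto the protein.

## The competitive occupancy calculator

For a single site of maximum stoichiometry 1, with enabled metals $i$ at
availability $[\mathrm{M}_i]$ and affinity $K_{D,i}$, define
$r_i = [\mathrm{M}_i]/K_{D,i}$. The fractional occupancy is

$$\theta_i = \frac{r_i}{1 + \sum_j r_j}
          = \frac{e^{-\Delta\Delta G_i/RT}}{1 + \sum_j e^{-\Delta\Delta G_j/RT}},$$

the partition function of the states {empty, bound by metal $i$}. The
"1 +" term is the unmetalated site; competition from the intracellular
buffer is embodied in the fixed buffered concentrations themselves, which
the molecule of interest is assumed not to deplete. `metal_occupancy()`
evaluates both algebraic forms and insists they agree to $10^{-10}$
relative; the enumeration is also checked against an independent
partition-function oracle in the test suite. Multi-site cooperative binding
and metal-bridged assemblies (β-value affinities in M⁻²) are out of scope.

```{r hypb}
hypb <- protein_affinities(c("Ni2+" = 6e-14, "Zn2+" = 2.2e-11), name = "HypB")
metal_occupancy(hypb, availability_preset("anaerobic"))
```

The shipped presets (`availability_preset()`) store the published
availability table exactly as printed, including per-condition standard
deviations where the condition was not boundary-defining. Because the
printed values are rounded (the original calculators carried unrounded
two-significant-figure internals), occupancies recomputed from the presets
can drift from published occupancies by up to about two percentage points;
package tests use that tolerance. The zinc entry is the two-sensor midpoint
(below); `zinc = "zur"` / `zinc = "zntr"` select the single-sensor values.
`whatif_availability()` overrides any availability for bespoke simulations.

## The sensor model

Each availability derives from a DNA-binding metalloregulator whose
operator occupancy reports the buffered concentration of its cognate metal.
The model couples three equilibria over five species — apo sensor $P$,
metalated sensor $PM$, free operator $D$, and the two sensor–operator
complexes $PD$ and $PMD$:

* $P + M \rightleftharpoons PM$, $K_\mathrm{metal}$ (tightest allosteric site)
* $P + D \rightleftharpoons PD$, $K_\mathrm{DNA,apo}$
* $PM + D \rightleftharpoons PMD$, $K_\mathrm{DNA,holo}$

under mass balance for sensor and operator, with the buffered metal treated
as an infinite reservoir (fixed $[M]$). Metal binding to DNA-bound sensor
is implied by thermodynamic cycle closure rather than a fourth independent
constant — the minimal model consistent with the constants that are
actually tabulated for these sensors. Totals convert from molecules per
cell via a default cell volume of $10^{-15}$ L (configurable; the volume is
an input of the same standing as the affinities). Eliminating $PM$, $PD$,
$PMD$ reduces the system to a quadratic in $P$, solved in the numerically
stable form; the test suite checks it against a brute-force nested-bisection
solver that never performs the elimination.

The transcriptional readout depends on the sensor class: co-repressors
(MntR, Fur, Zur, NikR) and activators (ZntR, CueR) report
$\theta = PMD/D_\mathrm{tot}$ (rising with metal), de-repressors (RcnR)
report $\theta = PD/D_\mathrm{tot}$ (falling with metal).

**Sensor abundance.** The tabulated inputs give molecules per cell at low
and at elevated metal but no blending rule. The package interpolates
linearly in the sensor's fractional metal saturation
$[M]/([M]+K_\mathrm{metal})$ for co-repressors and activators, where the
readout and the abundance rise together and monotonicity is preserved. For
de-repressors a saturation-tracking abundance makes the derepression
readout non-monotone (by about $2\times10^{-5}$ in $\theta$ for tenfold
abundance spans), which would make occupancy-to-concentration inversion
ill-posed; the default there is the fixed mean of the two abundances.
`abundance_mode` exposes all variants (`"saturation"`, `"low"`, `"high"`,
`"mean"`).

**Inversion.** `invert_sensor_response()` bisects on $\log_{10}[M]$ over a
default bracket of $10^{-25}$–$10^{-1}$ M (all realistic availabilities
with wide margin), to $10^{-6}$ relative tolerance on concentration, after
verifying the target occupancy lies within the attainable range implied by
finite sensor abundance; out-of-range targets raise an error that reports
that range. `sensor_response_curve()` tabulates the forward map and marks
the 0.01/0.99 dynamic-range boundaries and their log-scale midpoint.

## From Cq tables to availabilities

Quantification cycles arrive amplicon-efficiency-corrected; the pipeline is
strictly base-2 from there.

1. **QC** (`qc_filter()`): a condition is excluded when its mean
   reference-gene (*rpoD*) Cq shifts by more than 2 cycles from the control
   condition, unless a second reference gene (*gyrA*) passes the same test;
   an individual sample is rejected when its no-template or minus-RT
   control Cq, rounded to the nearest integer difference, is fewer than 10
   cycles above the sample Cq. Exclusions are returned as a
   machine-readable report; nothing is dropped silently.
2. **Fold changes** (`fold_change()`): per-replicate
   $2^{-\Delta\Delta C_q}$ relative to the mean of the minimum-expression
   condition.
3. **Fractional response** (`fractional_response()`): the observed fold
   change is placed linearly within the dynamic range, anchored at
   occupancy 0.99 (minimum expression) and 0.01 (maximum) for repressors —
   $\theta_D = 0.99 - 0.98\,(fc_\mathrm{obs}-1)/(fc_\mathrm{max}-1)$ — and
   mirrored ($\theta_{DM} = 0.01 + 0.98\,(\cdot)$) for activators, so
   $\theta_D + \theta_{DM} = 1$ for equal inputs. Anchoring uses the mean
   fold change of the boundary condition, consistent with the baseline
   being defined by a condition mean. Fold changes outside
   $[1, fc_\mathrm{max}]$ are clamped to the nearest anchor with a warning:
   beyond the boundaries, expression no longer tracks availability, so
   clamping is the only estimate the calibration supports.
4. **Inversion and aggregation** (`calibrate_availability()`): each
   replicate's $\theta$ is inverted to a concentration and the replicates
   are averaged *on the concentration scale* (matching how triplicated
   buffered-concentration determinations are averaged in practice; the
   standard deviation is likewise taken over raw replicate concentrations,
   not through the log transform). Boundary-defining conditions
   ($\theta$ exactly 0.01 or 0.99) carry no standard deviation.
5. **Zinc midpoint** (`zinc_midpoint()`): zinc is bracketed by two sensors,
   Zur (*znuA*) and ZntR (*zntA*); the single calculator availability is
   the geometric mean of the two sensor means — the midpoint on the
   log-scaled concentration axis, and the only mean that reproduces the
   published midpoint rows from the published sensor rows.

## Synthetic data and what passing tests show

The sensor constants measured for the *Salmonella* regulator set are not
redistributed here; `inst/extdata/sensors_synthetic.yaml` contains clearly
labelled synthetic placeholders whose dynamic ranges were chosen to bracket
the packaged availability presets. `generate_synthetic_qpcr()` runs the
pipeline in reverse — truth concentration → occupancy → fold change →
$\Delta\Delta C_q$ → replicate Cq values with Gaussian noise — and emits a
ground-truth sidecar, so the entire calibration chain is testable without
any external data: recovery is exact (to $10^{-3}$ relative) at zero Cq
noise and stays within two standard deviations of truth at 0.3 cycles of
noise across 100 simulated experiments (three biological replicates each,
the replication level of the real protocol).

The generator emulates the *structure* of real experiments (replicate
counts, reference-gene drift, boundary anchoring), not their biology: Cq
noise is Gaussian and homoscedastic, amplification efficiency is ideal, and
the synthetic sensor constants are placeholders. Passing round-trip tests
therefore validates the pipeline's internal consistency — not the accuracy
of any particular sensor parameterization, which must come from measured
constants supplied by the user.

## Validation problem sizes

The test suite exercises the equilibrium solver against its brute-force
oracle on 50 randomized parameter sets (relative tolerance $10^{-4}$),
forward/inverse round trips on 100 randomized draws ($10^{-4}$), the
dual-form occupancy identity on randomized affinity sets spanning
$K_D = 10^{-20}$–$10^{-3}$ M ($10^{-10}$), and full-pipeline recovery on
100 synthetic qPCR experiments. The published worked simulations (HypB
anaerobic; SodA aerobic/H₂O₂ with reported and with series-consistent
affinities) are reproduced from the packaged presets within two percentage
points, the drift attributable to preset rounding.

## Known limitations

* Single 1:1 site only; no cooperativity, no multi-molecule assemblies, no
  buffer depletion by overexpressed protein.
* One sensor per metal (two for zinc): cross-reactivity of a sensor for
  non-cognate metals is not modelled.
* Equilibrium thermodynamics throughout: kinetically trapped metalation
  (e.g. metals locked in during folding) shows up as a *disparity* from
  predictions, not as a prediction.
* The availability presets are strain- and condition-specific (JM109 (DE3),
  LB media); simulations for other systems should treat them as a starting
  point, not ground truth.
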