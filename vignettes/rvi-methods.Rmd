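---
title: "Methods: re-entry vulnerability mapping on an idealized infarct sheet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: re-entry vulnerability mapping on an idealized infarct sheet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r setup}
library(rvimap)
```

# Overview

`rvimap` implements the **Re-entry Vulnerability Index (RVI)** together with
the in-silico test-bed needed to study it: an idealized two-dimensional
infarct sheet, a monodomain tissue simulator with an S1–S2 pacing protocol,
activation/repolarization marker extraction, sparse clinical-style recording
grids, and closed-form synthetic marker fields for analytic validation.

For a pair of recording sites $(i, j)$ where $j$ activates strictly after
$i$ and lies within a search radius $R$ of it, the index is

$$\mathrm{RVI}(i, j) = RT_i - AT_j,$$

the repolarization time at the proximal site minus the activation time at
the distal site. When a premature wavefront blocks across a line and
re-enters around it, tissue just distal to the block activates late relative
to proximal repolarization, driving RVI down; sites with
$\mathrm{RVI} < 50\ \mathrm{ms}$ are flagged as the *vulnerable region*,
the candidate ablation target.

# The idealized infarct geometry

`build_idealized_infarct_sheet()` discretizes a square sheet (default
$40 \times 40$ mm at 0.2 mm resolution, i.e. 40,000 square elements) with a
circular scar of radius 15 mm split by a vertical conducting channel — the
*isthmus* — of width 4 mm, surrounded by a 0.5 mm border-zone (BZ) rim.
Regions are labeled per node: `MYO` (healthy), `BZ`, `SCAR`, and
`ISTHMUS` membership is recoverable with `isthmus_nodes()`. Scar is a
no-flux hole in the domain: it neither conducts nor contributes to the
Laplacian stencil.

```{r}
mesh <- build_idealized_infarct_sheet(infarct_spec())
ggplot2::autoplot(mesh)
```

# Tissue model

## Monodomain equation

The simulator solves the monodomain reaction–diffusion equation on the
regular grid with an explicit forward-Euler step and a 5-point Laplacian.
Face diffusivities are harmonic means of the two adjacent nodal
diffusivities, which correctly handles the jump at the border-zone
interface in the slow-conduction variant; scar faces carry zero flux. The
bulk diffusivity is

$$D = \frac{\sigma}{10\,\beta C_m} = \frac{0.068}{10 \cdot 0.14 \cdot 1}
    \approx 0.0486\ \mathrm{mm^2/ms}.$$

## Ionic model

Membrane kinetics follow a two-variable Mitchell–Schaeffer formulation
(normalized voltage $v$, recovery gate $h$), chosen because its action
potential duration (APD) has a closed-form restitution curve

$$\mathrm{APD}(DI) = \tau_{close}
  \ln\!\frac{1 - (1 - h_{min})\,e^{-DI/\tau_{open}}}{h_{min}},
  \qquad h_{min} = \frac{4\tau_{in}}{\tau_{out}},$$

which makes calibration to APD targets a one-dimensional root find rather
than a parameter search.

## Parameter table

| parameter | default | units | rationale |
|---|---|---|---|
| `tau_in` | 0.3 | ms | depolarization time scale; sets upstroke speed |
| `tau_out` | 6 | ms | repolarization time scale; with `tau_in` fixes $h_{min} = 0.2$ |
| `tau_open` | 120 | ms | gate recovery in healthy tissue; sets restitution steepness |
| `tau_close_myo` | 90.04 | ms | calibrated so steady-state myocardial APD at BCL 500 ms is 176 ms |
| `bz_apd_prolongation` | 1.448467 | – | multiplies `tau_close` in the BZ; calibrated so BZ/isthmus APD is 229 ms |
| `bz_tau_open_scaling` | 160/120 | – | slows BZ recovery of excitability (post-repolarization refractoriness); see below |
| `v_gate` | 0.13 | – | threshold of the gating switch |
| `sigma` | 0.068 | S/m | bulk conductivity |
| `beta` | 0.14 | 1/µm | surface-to-volume ratio |
| `cm` | 1 | µF/cm² | membrane capacitance |
| `dt` | 0.02 | ms | explicit time step (see stability below) |

The two calibrated values are not hand-picked: `calibrate_ionic_params()`
recomputes them from scratch by bisecting `tau_close` against the measured
APD of a paced 1D strip (the closed-form restitution underestimates tissue
APD by roughly 25% because diffusive loading shortens the effective
plateau, so calibration uses the simulated strip, not the formula). The
shipped defaults are the fixed point of that procedure.

## Why `bz_tau_open_scaling` exists

In the plain Mitchell–Schaeffer model the excitability gate recovers almost
as soon as the voltage repolarizes: effective post-repolarization
refractoriness is only $\tau_{open}\ln\frac{1-h_{min}}{1-h_c} \approx
0.03\,\tau_{open}$ (a few ms), where $h_c = \tfrac{9}{8} h_{min}$ is the
propagation threshold from the cubic front-speed analysis. A premature
stimulus therefore conducts decrementally through the isthmus instead of
blocking, and no re-entry is possible at any coupling interval.

Real infarct border zone exhibits marked post-repolarization
refractoriness. We model this with one extra parameter: `tau_open` in the
BZ is multiplied by `bz_tau_open_scaling`, slowing recovery of
excitability after each beat. This restores the qualitative S1–S2
behaviour the test-bed is built to exhibit — unidirectional block at the
proximal isthmus mouth for short coupling intervals, with the premature
wave re-entering through the distal mouth, and plain capture at long
coupling intervals. The default value was chosen, via 1D-cable and
full-sheet scans, as a value for which coupling interval 220 ms blocks and
250 ms conducts; note the 2D block window is wider than the 1D cable
prediction because the proximal mouth sits only ~5 mm from the stimulus
strip and therefore sees a much shorter diastolic interval.

## Numerical choices

* **Time step.** `dt = 0.02` ms, checked at run time against the explicit
  stability bound $\min\!\big(\mathrm{d}x^2 / (4 D_{max}),\,
  \tau_{in}/10\big)$; violating it is an error, not a warning.
* **Markers.** AT is the *first* upward crossing of $-40$ mV within each
  beat window (first-activation convention; later re-activations within
  the window are ignored), RT the first downward crossing after AT.
  Crossings are linearly interpolated between samples, and the RT search
  is *not* truncated at the window end, so long APDs near a window
  boundary are not clipped.
* **Beat windows** are defined relative to each stimulus onset, so markers
  are comparable across beats (`marker_beat()` selects one labeled beat,
  e.g. `"S2"` or `"S1_3"`).

# RVI computation

`build_rvi_map()` enumerates all ordered pairs within radius $R$ with
strictly increasing AT (ties are *not* downstream) and aggregates
per-pair values with one of three interpolations:

* `minimum` — per proximal electrode, the minimum RVI over its downstream
  pairs (most sensitive; the clinical default);
* `average` — per proximal electrode, the mean;
* `nearest_neighbor` — each pair's value is deposited at the mesh node
  nearest the pair midpoint (ties broken toward the lower node index) and
  node values are averaged, yielding a node-indexed rather than
  electrode-indexed map.

`quantify_vulnerable_region()` counts sites strictly below the 50 ms
threshold and converts to area when node areas are available;
`rvi_sweep()` tabulates size and lowest RVI across methods and radii.
The bundled `reference_region_tables()` reproduce the published growth of
the minimum-method vulnerable region with search radius (fold change 8.6
on the 2D sheet from $R=4$ to $16$ mm; 6.7 on the biventricular table from
$R=2$ to $8$ mm), and `consistency_report()` recomputes those fold changes
from any such table.

# Recording grids

Four placers model mapping densities from research-grade to clinical:

* `place_high_density()` — every non-scar node;
* `place_decapolar()` — a 10-electrode catheter with the clinical
  2–8–2 mm repeating spacing (span 42 mm, so it does not fit the default
  40 mm sheet lengthwise — use an origin/direction that keeps all
  electrodes in-bounds);
* `place_fan()` — several decapolar arms fanned from a common origin at
  configurable angles, approximating a multi-spline catheter;
* `place_multipolar_random()` — seeded random cluster placement with a
  per-cluster node fraction, for sensitivity studies of sparse coverage.

Every grid records its host mesh node and whether it sits on scar;
electrodes farther than one grid step from any node are an error rather
than silently snapped.

# Synthetic fields and analytic validation

`planar_wave_field()` and `line_of_block_field()` generate closed-form
AT/RT maps. For a planar wave with conduction velocity $cv$ and uniform
APD, the minimum-method map is exactly $\mathrm{APD} - R/cv$ in the
interior — a one-line oracle for the whole pipeline. For a line of block,
`analytic_negative_strip()` returns the exact predicted vulnerable region:
the $R$-neighbourhood of the block *shadow* (the late-activating
rectangle) minus the shadow itself. This includes not only the proximal
strip below the line but also the *flank bands* along the shadow's sides,
where lateral cross-pairs straddle the early/late boundary; ignoring the
flanks understates the region substantially. The region exists iff
$\mathrm{APD} - \Delta_{AT} < \mathrm{threshold}$ and its most negative
value is $\mathrm{APD} - \Delta_{AT} - R/cv$.

`add_marker_noise()` perturbs AT/RT with independent Gaussian noise in a
canonical (electrode, beat) order, so results are reproducible for a fixed
seed and invariant to input row order.

# Limitations

* The tissue model is 2D, isotropic and phenomenological: no fibre
  architecture, no transmural gradients, no electrotonic APD
  heterogeneity beyond the two-region calibration.
* Post-repolarization refractoriness is represented by a single scaling of
  `tau_open`, not by a biophysical ionic mechanism.
* Markers come from the transmembrane voltage, not from simulated
  electrograms; clinical AT/RT annotation error is modeled only as
  additive Gaussian noise.
* The explicit solver is deliberately simple; very fine meshes will want
  the time step reduced per the stability bound and will be slow.
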