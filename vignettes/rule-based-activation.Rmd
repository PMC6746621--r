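---
title: "Rule-based eikonal models of ventricular activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based eikonal models of ventricular activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cardioeik` predicts the electrical activation sequence of the ventricles
from non-invasive inputs: a labeled anatomical mesh, a pacing site, and a
QRS duration from the surface ECG. The physics is the anisotropic eikonal
equation

$$ \sqrt{\nabla t(x)^\top M(x)^{-1} \nabla t(x)} = 1, \qquad
   M(x) = v_l^2\, f f^\top + v_t^2 (I - f f^\top), $$

whose solution $t(x)$ is the first-arrival time of the depolarization
wavefront given local conduction velocities: $v_l$ along the myofiber
direction $f$ and $v_t = \rho\, v_l$ transverse to it. Only arrival times
are modeled; membrane kinetics, extracellular potentials and ECG
morphology are out of scope (full reaction--eikonal treatments report
arrival-time agreement with the pure eikonal solution at the percent
level, which is far below the measurement errors of interest here).

Working units are millimetres and milliseconds throughout, so velocities
in m/s are numerically equal to mm/ms and need no conversion.

### Fibers

Myofiber orientation is assigned by the standard transmural helix rule:
the local circumferential direction (long-axis gradient crossed with the
transmural gradient) is rotated about the transmural axis by an angle
interpolated linearly from +60 degrees at the endocardium to -60 degrees
at the epicardium. The angles are configurable; conclusions of this model
family are known to be robust to moderate fiber perturbations, which is
why a rule-based surrogate for DT-MRI is acceptable. Degenerate apex
elements, where the two coordinate gradients align, fall back to
projecting a fixed reference vector onto the plane normal to the
transmural axis.

### Substrate variants

Six rule-based substrates capture the main conduction heterogeneities
discussed for dyssynchronous ventricles:

| variant            | rule                                                        |
|--------------------|-------------------------------------------------------------|
| `NORMAL`           | uniform $v_l$ everywhere                                     |
| `SCAR`             | $v_l = 0$ (complete block) in scar-labeled elements          |
| `ANTERIOR_BLOCK`   | $v_l = 0$ in the anterior LV free wall (functional block)    |
| `POSTERIOR_BLOCK`  | $v_l = 0$ in the posterior LV free wall                      |
| `SLOW_SEPTUM`      | septal $v_l$ = 50% of bulk                                   |
| `FEC`              | 1 mm endocardial layer with six-fold $v_l$ (Purkinje surrogate) |

Key parameter defaults, all configurable: anisotropy ratio $\rho = 0.4$
(transverse velocity 40% of longitudinal), FEC fold-increase 6 (swept over
1--10), FEC layer thickness 1 mm, septal factor 0.5. Block and scar are
genuinely non-traversable ($v_l = 0$), not merely slow; nodes with no
conducting path from the stimulus receive `+Inf` and are excluded from,
but counted alongside, the total activation time.

The FEC fold-increase multiplies the longitudinal velocity; the
transverse velocity follows through the global anisotropy ratio. The
layer applies to both LV and RV endocardium, with an optional
`LOWER_THIRD` extent (apex-base coordinate < 1/3) reflecting the apical
concentration of Purkinje arborizations. Layer membership is decided by
element-centroid distance to the labeled endocardial faces; on meshes
coarser than the layer thickness the first element layer touching the
surface is used instead, so the layer never silently disappears.

### Calibration

The single free scalar is the bulk longitudinal velocity. It is fitted by
equating the simulated total activation time (TAT, latest minus earliest
activation) with the measured QRS duration, to a tolerance of 5 ms.
Because the eikonal equation obeys the exact scaling law
$t(\alpha v) = t(v)/\alpha$, one solve determines the answer analytically
(`method = "scaling"`, two solves including verification); a brute-force
grid search (`method = "grid"`) is retained as a cross-check and gives
the same velocity to grid resolution.

Two physiological screens constrain model selection: the fitted velocity
must lie in the experimentally reported 0.07--0.75 m/s range, and the
latest activated site must not be septal (endocardial mapping of LBBB
places it near the LV lateral wall).

### Validation metrics

Mapping points carry a local activation time (LAT) normalized as a
percentage of the QRS duration. Against a simulated map the package
computes, per point:

* **temporal error** = (simulated LAT% - measured LAT%) x QRSd / 100;
  positive means the model activates later (slower) than measured;
* **distance error** = minimum Euclidean distance from the (projected)
  point to the simulated isochrone of the measured LAT, located by linear
  interpolation along every mesh edge crossing the level.

Variants are compared by one-way ANOVA with Tukey HSD post-hoc tests on
the per-point errors, and ranked by mean distance error.

## Design choices where the design was open

* **Isochrone matching tolerance.** "Matching" the measured LAT defaults
  to an exact level-set crossing (`match_tol_pct = 0`), with the
  tolerance exposed as a parameter; distance error is provably 0 iff the
  point's own simulated LAT matches within the tolerance, and shrinks
  monotonically as the tolerance grows.
* **Distance metric.** Euclidean in 3D. A within-tissue geodesic is
  arguably defensible but is not what "minimum distance to the nearest
  tissue" most plainly denotes; with sub-centimetre errors on ventricular
  scales the difference is small.
* **Out-of-range measurements.** A measured LAT outside the simulated
  span is scored against the nearest extreme isochrone and flagged,
  rather than dropped, so per-case means stay defined in the presence of
  outliers.
* **Functional-block footprint.** No published geometric definition of
  the anterior/posterior block regions exists, so the LV free wall is
  split into halves by circumferential angle about the LV long axis, with
  the septal bisector defining 0 degrees and "anterior" covering (0, 180)
  degrees under a right-handed convention. This is a stand-in and is
  labeled as such; the substrate rules consume only the resulting labels.
* **Indexing.** All R-level indices are 1-based, the native convention of
  the language and of every mature R mesh/graph package; files on disk
  use the 0-based connectivity their formats require.
* **Aggregation.** With one synthetic case the statistical comparison
  pools per-point errors within the study; multi-case leave-one-out
  averaging of per-case means (as one would do across a patient cohort)
  is a straightforward outer loop left to the caller.

## Numerics

The solver is a label-correcting fast-iterative method on tetrahedra: a
min-heap orders tentative times, and popping a node re-runs the 1-, 2-
and 3-point anisotropic local updates on all incident elements,
re-inserting any improved node. Unlike strict fast marching this
tolerates the causality violations that anisotropic metrics induce on
lattice tetrahedra. Two numerical details matter:

* **Tie robustness.** The closed-form interior minimizers of the local
  updates suffer catastrophic cancellation when two arrival times tie;
  discriminants are clamped at zero and the metric-orthogonal projection
  is always evaluated as an extra candidate. Every candidate is checked
  against the true objective, so extra candidates are free and missing
  branches are fatal -- the symptom of the unclamped version was a
  violation of the exact scaling law at the percent level.
* **Source ball initialization.** First-order updates overestimate near a
  point source where the front is strongly curved. Nodes within a ball
  (default radius 8 mean edge lengths) of each stimulus are seeded with
  the straight-segment travel time under the slowest metric among the
  elements the segment crosses. Segments are validated by point-in-element
  sampling, so a segment crossing a cavity or blocked tissue is rejected;
  the seed is therefore always an upper bound on the true time and can
  only be improved by the main loop. On homogeneous slabs at 1 mm spacing
  this brings the worst-case error against the anisotropic closed form
  below 3% in every direction (not only along lattice edges), and the
  solution never undershoots the true time.

An independent cross-check is provided by `edge_graph_times()`: Dijkstra
over the mesh edge graph with anisotropic edge weights, a different
algorithm and code path whose times are a guaranteed upper bound (paths
are restricted to edges); the solver must stay at or below it on every
mesh.

The transmural coordinate solves a graph Laplacian (edge weights =
1/length) with endocardium 0 and epicardium 1, which obeys the discrete
maximum principle; near free side boundaries the truncated stencils
distort it away from the continuum harmonic solution, which is harmless
for its uses here (helix interpolation and the lower-third rule) and is
covered by the bounds-only invariant.

Degenerate inputs are rejected early with named errors: non-positive
dimensions, spacing that does not divide the slab, geometrically
impossible ellipsoid parameters, empty stimulus sets, stimuli entirely
inside blocked tissue, meshes missing the label arrays, and mixed element
types in files.

## The synthetic study

No patient meshes or recordings are distributed, so the package generates
its own study conditions:

* an idealized two-ellipsoid biventricular mesh (default: LV cavity
  semi-axes 20 x 20 x 40 mm, 10 mm LV wall, half-thickness RV wall, 2 mm
  lattice, basal truncation) with the full label set;
* a ground-truth activation map, by default the FEC variant at
  0.33 m/s bulk velocity (the center of the physiologically plausible
  range and the field's typical fitted value) paced at the RV apex;
* a synthetic coronary-vein EAM: points laid along a few apex-to-base
  polylines on the LV free-wall epicardium, perturbed by 3 mm Gaussian
  spatial jitter (re-projected, emulating the registration error that
  mapping chains report as projection RMS of a few mm) and 5% Gaussian
  LAT noise, all driven by a single mandatory seed.

What this emulates: the spatial layout, coverage and noise scale of
coronary-vein mapping during RV pacing, and the model-selection
experiment run on it. What it does not emulate: real anatomical
variability, scar heterogeneity and border zones, catheter-contact
artifacts, and registration bias between modalities. Passing the
study-level tests therefore demonstrates internal consistency and
discriminative power of the metrics under known truth -- not clinical
accuracy on real data.

Problem sizes were chosen so a full six-variant study with calibration
runs in well under a minute on a laptop core (about 16,500 nodes / 72,000
tetrahedra at 2 mm spacing; each eikonal solve takes a fraction of a
second), which makes property-based testing of the whole pipeline
practical. The acceptance margins for the study-level checks are set from
the noise floor of the synthetic recording (3 mm spatial jitter): the
FEC-ratio sweep must show a 5--10 fold plateau with spread below 3 mm,
and lower-third-only FEC must not beat the normal model by more than 20%.

## Known limitations

* Transverse isotropy only: no sheet/normal orthotropy.
* Homogeneous parameters within each labeled region; no border-zone
  gradients around scar.
* The eikonal model ignores wavefront curvature and bath-loading effects
  on velocity; QRS duration enters only as a scalar duration.
* The idealized ellipsoid anatomy is a stand-in; all algorithms operate
  on labels and coordinate fields so imported patient meshes are
  first-class, but none are shipped.
* Fast marching accuracy degrades on highly graded or sliver meshes; the
  shipped generators produce regular lattices where the verified
  tolerances hold.
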