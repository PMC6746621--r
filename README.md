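# cardioeik

Rule-based anisotropic eikonal simulation of ventricular electrical
activation, for planning cardiac resynchronization therapy (CRT) from
non-invasive data.

Heart-failure patients with dyssynchronous activation (e.g. left bundle
branch block) benefit from CRT, and the response depends on where the LV
pacing lead lands — ideally at the latest-activating, non-scarred region.
Predicting that region before the implant requires only a patient anatomy
(CT/CMR segmentation), the pacing site, and the QRS duration from a
12-lead ECG. `cardioeik` implements the modeling chain end to end for
researchers in computational cardiac electrophysiology:

- **Eikonal activation model.** Arrival times solve
  `sqrt(grad(t)' M^-1 grad(t)) = 1` with a transversely isotropic
  conduction tensor: velocity `v_l` along the myofiber axis and
  `v_t = 0.4 v_l` across it. The solver is a label-correcting
  fast-iterative method on tetrahedra (Rcpp), verified against the
  closed form `t = sqrt(x' G x)` to <3% at 1 mm spacing and bounded by an
  independent edge-graph Dijkstra oracle.
- **Rule-based fibers.** Transmural helix rule, +60° (endo) to −60° (epi).
- **Six conduction substrates.** normal; scar (complete block);
  anterior/posterior functional block; slow septum (50%); fast
  endocardial conduction (FEC — a 1 mm endocardial layer at six-fold
  velocity, surrogate for the Purkinje system).
- **Calibration.** The bulk velocity is fitted so that the total
  activation time equals the QRS duration within 5 ms, using the exact
  eikonal scaling law (a grid-search mode is included as a cross-check).
  Physiological screens: fitted CV in 0.07–0.75 m/s, latest activated
  site not septal.
- **Validation metrics** against electro-anatomical mapping (EAM) points:
  temporal error (ΔLAT% × QRSd; positive = model slower) and isochrone
  distance error (minimum distance to the simulated isochrone of the
  measured activation time), with one-way ANOVA + Tukey HSD comparison
  across substrate variants.
- **Synthetic study generator.** Idealized slab and biventricular
  geometries with full anatomical labels, plus coronary-vein-like noisy
  EAM samples, so the entire pipeline runs with no patient data.

## Worked example

A six-variant model-selection study on the synthetic biventricular
anatomy, with ground truth = FEC at 0.33 m/s paced at the RV apex and 50
noisy epicardial mapping points:

```r
library(cardioeik)
cfg <- study_config(seed = 7)          # defaults: biventricular mesh, FEC truth
rep <- run_study(cfg)
print(rep)
```

```
StudyReport: truth FEC, QRSd 172.2 ms, 50 EAM points
  NORMAL          cv 0.791 m/s, dist 14.63 mm, temp -21.77 ms, constraints FAIL: fitted conduction velocity 0.791 m/s outside [0.07, 0.75] m/s
  SCAR            cv 0.791 m/s, dist 14.48 mm, temp -21.66 ms, constraints FAIL: fitted conduction velocity 0.791 m/s outside [0.07, 0.75] m/s
  ANTERIOR_BLOCK  cv 0.792 m/s, dist 18.18 mm, temp -24.55 ms, constraints FAIL: fitted conduction velocity 0.792 m/s outside [0.07, 0.75] m/s
  POSTERIOR_BLOCK cv 0.798 m/s, dist 21.41 mm, temp -26.55 ms, constraints FAIL: fitted conduction velocity 0.798 m/s outside [0.07, 0.75] m/s
  SLOW_SEPTUM     cv 1.081 m/s, dist 8.91 mm, temp -6.14 ms, constraints FAIL: fitted conduction velocity 1.081 m/s outside [0.07, 0.75] m/s
  FEC             cv 0.330 m/s, dist 2.69 mm, temp -1.31 ms, constraints pass
  ranking: FEC > SLOW_SEPTUM > SCAR > NORMAL > ANTERIOR_BLOCK > POSTERIOR_BLOCK
```

Reading the output: every candidate substrate is calibrated to the same
QRS duration, then scored against the mapping points. The FEC candidate
recovers the generating velocity (0.330 m/s), achieves a mean distance
error of 2.7 mm (the noise floor of the synthetic recording), and is the
only variant passing both physiological constraints — candidates without
a fast endocardial layer need implausibly fast bulk myocardium
(≈0.8–1.1 m/s) to reproduce the same total activation time.
`sweep_fec_ratio(cfg)` reproduces the companion experiment: the distance
error improves as the FEC fold-increase grows from 1, plateaus for
five- to ten-fold layers, and restricting the layer to the lower third
of the ventricles performs no better than the normal model.

A thin CLI over the same functions is installed at
`inst/cli/cardioeik` (subcommands `mesh`, `simulate`, `study`, `sweep`,
with YAML study configs). Meshes and activation maps are written as
legacy-ASCII VTK (viewable in ParaView) or CARP-style text files; EAM
recordings as CSV.

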