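---
title: "Virtual quadripolar lead design trials: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual quadripolar lead design trials: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

quadlead is an in-silico trial platform for multipoint pacing (MPP) in
cardiac resynchronization therapy (CRT). A quadripolar LV lead carries 4
electrodes; a *lead design* is a choice of 4 electrode positions out of 8
candidates spaced along an epicardial vein track, and a *configuration* is
the subset of 1 or 2 of its electrodes actually stimulated together with
the RV electrode. The package simulates ventricular activation for every
configuration in every candidate vein on a cohort of virtual anatomies,
scores electrical synchrony against an RV-only pacing baseline, and asks
which single 4-electrode design serves a whole cohort nearly as well as a
personalised design would. This vignette describes the model, its
assumptions and parameters, and the design choices that were genuinely
open.

## Activation model

Ventricular activation is modelled with the anisotropic eikonal equation

$$\sqrt{\nabla T^\top \, V \, \nabla T} = 1,\qquad T = t_0 \text{ at sources},$$

where $T(x)$ is the activation time (ms) and $V(x)$ the symmetric
squared-velocity tensor ((mm/ms)$^2$). Healthy myocardium is transversely
isotropic,

$$V = v_f^2\, f f^\top + (k_{xf} v_f)^2 (I - f f^\top),$$

with fibre direction $f$, fibre velocity $v_f$ = 0.5 mm/ms and cross-fibre
ratio $k_{xf}$ = 0.6. A fast endocardial conduction (FEC) layer, one
element thick on the endocardial surfaces up to an apicobasal fraction of
0.33 (the bottom third) by default, conducts isotropically at
$k_{FEC} \cdot v_f$ with $k_{FEC} = 5$; it is the usual surrogate for the
Purkinje system in eikonal models. Working in mm and ms makes velocities
numerically equal to m/s, which removes a whole class of unit bugs.

The solver (`solve_eikonal()`, C++ core) is a label-correcting
fast-iterative method with a per-tetrahedron local solver: a node's
arrival time is minimized over the opposite face of each incident
tetrahedron, solving the face, edge and vertex characteristic cases in
closed form in the travel-time metric $M = V^{-1}$. Convergence tolerance
is 1e-8 ms. Two numerical choices deserve a note:

* **Multi-source solves are min-compositions.** The first-arrival solution
  for several sources is by definition the pointwise minimum of the
  single-source solutions. A joint iterative solve violates this where
  fronts collide — the linear face update interpolates across the kink in
  $\min(T_1, T_2)$ and arrives spuriously early (we measured up to
  ~2.6 ms on a 9 mm mesh). `solve_eikonal()` therefore solves each unique
  source separately and composes minima, which is exact and lets the
  campaign reuse one solve per electrode across all 36 configurations.
* **Verification.** The solver is tested against closed-form travel times
  $\sqrt{e^\top V^{-1} e}$ in homogeneous tensors, and against a Dijkstra
  oracle on the mesh edge graph (edge weight from the mean incident
  tensor), which is a strict upper bound because graph paths are a subset
  of admissible paths. The gap between oracle and solver does **not**
  vanish under refinement — the edge-graph metric has a scale-invariant
  direction-dependent error — so the refinement check asserts instead that
  the solver's error against the closed form decreases.

Scar is a first-order surrogate: LV elements whose wall is thinner than a
threshold (5 mm by default in the scar scenarios, 6 mm as an alternative)
are non-conducting and excluded from metric denominators. An element that
is both thin and endocardial counts as scar, the stronger pathological
statement. What the model leaves out: membrane kinetics, repolarization
and ECG synthesis; activation time stands in for QRS duration.

## Synchrony metrics

`compute_tat()` is the maximum activation time over active-tissue nodes
(total activation time, the QRS-duration surrogate). `compute_at090()` is
the time at which 90% of the active biventricular myocardial volume has
activated; element activation time is the mean of its four node times,
which is the unbiased estimate of the element's contribution to the
volume CDF (the alternative — last node, i.e. fully-activated element — is
config-visible in the code but not default). AT090 is the primary metric
because TAT is hostage to small late regions: with an RV apical source the
RV outflow tract often activates last no matter what the LV lead does, so
TAT can sit still while bulk synchrony improves. Reductions are reported
against the subject's RV-only baseline, in ms and in percent; positive
means improvement and worsening keeps its sign.

## Synthetic anatomies

Image-derived patient anatomies are not shipped with this package
(external meshes can be supplied in VTU or CARP-style text formats). The
generator (`generate_biventricular_mesh()`) builds an idealized synthetic
stand-in: a truncated prolate-ellipsoid LV shell fused with a thinner
crescent RV shell, offset outward from the LV epicardium over a
septum-centred sector and welded back onto it at the sector edges and
towards the apex, so the mesh is one face-connected component with
labelled surfaces (LV endo, RV endo, epicardium, flat base). Meshing is a
structured shell parameterization split into conforming tetrahedra (the
quad/prism diagonals follow the smaller global node id, so neighbouring
cells always agree); no external mesh generator is involved and
generation is bitwise deterministic.

Cohort defaults encode the one anatomical contrast the whole analysis
rests on — HF hearts are larger and thinner-walled than
reverse-remodelled (RR) ones:
HF mean LV cavity ≈ 180 mL with an 8 mm wall, RR ≈ 120 mL with a 10 mm
wall, both with a 10% coefficient of variation on the length parameters
(truncated normal draws, per-subject seeds derived from the cohort seed).
These are configurable generator defaults with plausible magnitudes, not
estimates of any measured population. Consequently the pipeline
reproduces the *structure* of a virtual trial (counts, orderings,
monotonicities, qualitative HF-vs-RR differences) but not per-patient
activation times of any real cohort;
passing tests say nothing about any individual's anatomy. Mesh
resolution is set by a target edge length (6 mm default; tests use
9–10 mm); the wall is always at least two elements thick.

Fibres follow a simplified rule: one linear transmural rotation of the
helix angle from +60° (endo) to −60° (epi) in the local wall-tangent
plane. The full Laplace–Dirichlet rule-based method is out of scope; the
simplification keeps the anisotropy structure the eikonal model needs.

## Coordinates, AHA map, veins

`compute_uvc()` provides the coordinate fields everything else is
anchored to. The transmural coordinate ρ solves a Laplace problem per
ventricle (endo = 0, epi = 1; linear tetrahedral FEM, direct sparse
factorization; the septal surface facing the RV cavity is the LV's outer
shell, and the LV–RV interface is the attached RV wall's inner shell).
The apicobasal coordinate z is the normalized geodesic distance ratio
$d_{apex}/(d_{apex}+d_{base})$ computed with unit-speed eikonal solves: a
raw harmonic interpolant between a near-point apex and the broad basal
plane collapses nearly all of its variation into the apical
neighbourhood (median z ≈ 0.89 on the default mesh), which would break
every consumer that reads z as an apicobasal fraction — the AHA bands,
the FEC extent ("bottom third") and electrode placement at z = 0.8. The
distance ratio keeps exact boundary values and tracks the arc fraction.
The rotational angle φ is measured about the LV long axis with φ = 0 on
the anterior free wall, increasing towards the lateral wall (
there is no universal convention for the rotational origin; this one is
config-exposed via `anterior_angle`).

The 17-segment AHA map uses z-bands 0.15 (apex cap) / 0.45 (apical) /
0.72 (mid) — the standard equal-thirds convention with a small cap, also
config-exposed since no cut-offs are printed anywhere authoritative. The
five vein tracks are meridian slices of the LV epicardium at angles
anchored to the basal segments: IN at the 4/5 border (150°), IL at the
centre of 5 (120°), LA at the 5/6 border (90°), AL at the centre of 6
(60°), AN at the 6/1 border (30°); borders are means of adjacent segment
centres. Eight electrodes sit at 7.5 mm arc intervals (52.5 mm span) from
the z = 0.8 basal end, each snapped to the nearest epicardial mesh node
(ties to the lowest index). Wall thickness is element-wise and computed
as exact point-to-surface distances (centroid to endo plus centroid to
outer shell): gradient-ray constructions tilt near the insulated base and
mis-measure by up to 30%. One honest caveat: at the basal rim both
surfaces end on the truncation plane and the corner wedge is genuinely
wider than the nominal wall, so uniformity checks exclude z > 0.9.

## Campaign, optimization, statistics

`run_campaign()` produces the tidy response matrix: one row per subject ×
vein × configuration with TAT/AT090 and their reductions; design-level
responses (`evaluate_designs()`) are table lookups — the best of the 10
configurations a design admits — identical to simulating per design at a
fraction of the cost. Patient-based optima are exact argmaxes with
deterministic tie-breaks (lexicographic configuration name, then
anatomical vein order). Cohort-based selection collects each subject's
optimal configuration at its best vein and finds the minimum number of
4-electrode designs covering them all by exhaustive search over cover
sizes 1, 2, 3, … across the 70 designs — the universe is tiny, so exact
search is cheap and a greedy cover is kept only as a cross-check. An
optional tolerance ε (default 0) lets near-ties count as optimal. The
primary design is the single design covering the most subjects, ties
broken lexicographically — a deliberate convention, since no natural
tie-break exists among equally-covering sets.

Response clustering is Ward agglomeration in its distance-input form
("Ward2", Murtagh–Legendre): `stats::hclust(method = "ward.D2")` on
Euclidean distances, pinned by a regression fixture and checked against a
hand-rolled Lance–Williams recurrence in the tests. The cluster count for
reports defaults to 4.

Statistics mirror the trial's analysis plan: one-sided Wilcoxon
signed-rank tests of the reductions against zero (exact for n ≤ 25
without ties; zeros dropped by the Wilcoxon convention, Pratt handling
available), Mann–Whitney comparisons between cohorts and against
personalised optima (exact for $n_x n_y \le 400$ without ties), Bonferroni
correction over each comparison family, significance at p < 0.01. Effect
sizes are always reported alongside p-values; with thousands of simulated
records, p-values alone would say little.

## Sensitivity analysis

`run_oat_sensitivity()` repeats the campaign and the design optimization
for eleven one-at-a-time scenarios: FEC extent 0.70 and 1.00, fibre
velocity 0.07 and 0.8 mm/ms, $k_{xf}$ 0.29 and 1, $k_{FEC}$ 7 and 10, RV
pacing moved to the septal mid-wall, and scar thresholds 5 and 6 mm. A
scenario that does not differ from the baseline in exactly one ingredient
is rejected. The monotonicities these scenarios must respect (faster
conduction never delays any node; a larger scar threshold never speeds
anything up) are asserted per record, not just on means.

## Problem sizes and determinism

The test suite and the acceptance script run everything at deliberately
small scale: cohorts of 1–3 subjects per arm at 9–10 mm edge length
(roughly 3–6k tetrahedra each), two to five veins, and solver
verification cubes at 1–2.5 mm. These sizes were chosen so the full grid
structure (36 configurations, 70 designs, 11 scenarios) is exercised
end to end while a complete run stays in the minutes range on one core;
the model itself has no scale-dependent switches, so larger cohorts and
finer meshes only change runtime. Every stochastic step (cohort draws)
derives per-subject seeds from a single configuration seed; solver,
placement and optimization are deterministic, and rerunning an identical
configuration reproduces the response matrix bitwise.

## Known limitations

Idealized anatomy (no trabeculation, valves, real coronary veins, or
four-chamber context); straight-line vein tracks; a single linear fibre
rotation; eikonal-only electrophysiology with no repolarization or ECG;
thickness-threshold scar as a first-order surrogate; and synthetic
morphological variability in place of measured anatomy. The RV attaches
to the LV epicardium along welded bands, so septal conduction between the
ventricles is cruder than in image-derived meshes. These bound what the
package can claim: it is a platform for studying the *logic* of lead
design selection, not a patient-specific predictor.
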