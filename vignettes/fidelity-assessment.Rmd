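---
title: "Shape fidelity assessment by stochastic ICP: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape fidelity assessment by stochastic ICP: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`meshfidelity` quantifies how faithfully a fabricated or scanned surface
model duplicates a reference model. This vignette documents the model
and its assumptions, the tunable parameters, the synthetic validation
harness, and the numerical and design decisions — including the points
where the underlying method is genuinely under-determined and a choice
had to be made.

## The fidelity model

Fidelity is defined as the signed deviation between the reference
model's vertices and the test model's surface *after optimal rigid
alignment*. The pipeline is:

1. **Alignment** (`icp_align`). Stochastic point sets of size $N$ are
   drawn area-uniformly from the test surface; each point is paired with
   the exact closest point on the reference triangle set. The rigid
   transform minimising
   $F(R,T)=\sum_{i=1}^{N}\lvert Rp_i+T-z_i\rvert^2$
   over those pairs has the closed form $T = C_z - R\,C_p$ with $R$ from
   the SVD of the cross-covariance $H=\sum_i \tilde p_i\tilde z_i^{\top}$:
   $R=VU^{\top}$, or $V\,\mathrm{diag}(1,1,-1)\,U^{\top}$ when
   $\det(VU^{\top})=-1$, which excludes reflections. Correspondence and
   update alternate; accepted steps strictly decrease $F$. The inner loop
   stops when the per-point improvement drops below a tolerance $\tau$;
   an outer loop then redraws a fresh point sample and repeats until the
   across-round improvement is also below $\tau$.
2. **Deviation mapping** (`signed_deviation`). For every reference
   vertex, the distance to the exact closest point on the aligned test
   surface, signed by the angle-weighted outward vertex normal:
   positive = test surface outside the reference (overbuilt material),
   negative = inside (undercut). The sign convention is a package
   decision — "upper deviation" then reads as the worst overbuild and
   "lower deviation" as the worst undercut, matching fabrication
   intuition.
3. **Summary** (`summarize_fidelity`). Mean signed error, maximum
   (upper) and minimum (lower) deviation, and the population
   ($\div N$) standard deviation, reported in mm and rounded to two
   decimals in printed output.

Assumptions: both meshes are in millimetres; the alignment is rigid
(no scale, no deformation — scale compensation belongs to the
fabrication workflow, not the metric); deviations are measured from the
reference's vertices only, so the reference mesh's tessellation sets the
measurement locations. The symmetric (Hausdorff-style) two-sided variant
is deliberately out of scope.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_points` (N) | 5000 | points | stochastic sample size per round; statistical resolution of the alignment |
| `tau` | 1e-6 | mm² | convergence tolerance on the *per-point mean* objective |
| `max_inner_iters` | 100 | — | cap on transform updates per sample round |
| `max_outer_rounds` | 5 | — | cap on resampling rounds |
| `init` | `"auto"` | — | multistart initialisation (see below) |
| `seed` | 1 | — | master seed; all sampling derives child seeds from it |

Comparing *per-point mean* objectives (rather than raw sums) keeps inner
rounds (fixed $N$) and outer rounds (fresh samples) commensurable; with
equal $N$ it is equivalent to comparing raw $F$ values. $\tau$ is not
prescribed by the method itself; $10^{-6}$ mm² corresponds to an RMS
step change of $10^{-3}$ mm, an order of magnitude below the 0.01 mm
reporting precision.

Nearest-point ties are broken by the lowest face index, so runs are
bit-for-bit reproducible. Degenerate (zero-area) faces are dropped with
a warning rather than rejected, so meshes from real scanners remain
usable. Rank-deficient point configurations in the rotation update
(collinear/coplanar sets) produce a warning and the minimum-norm SVD
choice.

## Initialisation

Plain ICP is a local optimiser: from an identity start it reliably
recovers only modest rotations. Because the validation harness applies
rotations up to 180°, `icp_align` initialises with centroid alignment
plus a small multistart over candidate rotations: the identity and the
four proper sign combinations of the principal axes of the two surfaces.
The principal axes are computed from the *exact* area-weighted second
moment of each mesh (an analytic per-triangle integral, not a sampled
covariance), so for a rigid copy of a shape with distinct principal
moments one candidate starts essentially at the true pose. Candidates
are scored by a short inner run at reduced sample size, and scoring
stops early once a candidate's RMS residual is below the 0.01 mm
reporting precision. `init = "centroid"` disables the multistart and
reproduces the bare centroid-plus-identity start.

For shapes with degenerate moments (sphere, cube) the principal axes are
arbitrary, but such shapes have symmetry groups: any symmetry-related
pose is an equally valid alignment, and the fidelity statistics are
unaffected. Tests of exact transform recovery therefore use an
asymmetric shape (the blob fixture), while symmetric shapes are checked
at the level of the deviation statistics.

## The centroid equations

The centroids $C_p$, $C_z$ that decouple translation from rotation are
implemented as arithmetic means. Writing them as bare sums would break
$T = C_z - R\,C_p$ dimensionally whenever the two point sets have
different sizes, and "center of the point set" is only well-defined as
the mean.

## The validation harness

`random_deform` implements the perturbation operator `random(M, R, V)`:

* **V** (fraction in [0, 1]): $\lceil V\cdot n\rceil$ of the $4\times
  4\times 4$ FFD lattice control points are displaced by vectors drawn
  uniformly in the ball of radius 10% of the longest bounding-box axis
  (`max_displacement_fraction = 0.10`), then every vertex is mapped
  through the trivariate Bernstein tensor product of the lattice
  (the classical Sederberg–Parry free-form deformation).
* **R** (flag): a uniform random rotation about the centroid — axis
  uniform on the sphere, angle uniform in (0°, 180°].
* **M** (flag): a random translation, each component uniform within
  ±1 bounding-box diagonal.

The composition order distortion → rotation → translation is fixed and
recorded, together with the applied transform and the displaced control
points, in a ground-truth record so tests are unambiguous. The
translation bound is a package choice (only the distortion is bounded by
the method's 10% rule); it exercises the alignment's basin of attraction
without being pathological. The $4^3$ lattice is likewise a package
choice: coarse enough for smooth, visible distortions, fine enough that
$V=0.1$ displaces at least 6 control points. The 10% displacement cap is
applied at every $V$ by default and is configurable.

For a fixed seed, the displaced control sets are *nested* across
increasing $V$: a random permutation of the control points is truncated
at $\lceil V\cdot n\rceil$, and displacement vectors are attached to
permutation positions. Raising $V$ at the same seed therefore adds
distortion on top of the previous deformation, which makes
severity-trend comparisons across $V$ paired rather than merely
distributional.

## Fixture geometries and tessellation resolution

`benchmark_geometries()` provides five watertight fixtures of increasing
complexity — cube, sphere, capped cylinder, torus, and a "blob" (a
sphere with a smooth, seeded, low-order random radial perturbation,
standing in for an organ-like free-form shape).

Tessellation resolution matters for the zero-row validation: a rigidly
moved *faceted* copy of a curved shape can be aligned
surface-accurately at a pose that is offset within the tessellation's
symmetry, in which case vertices of one tessellation sit above facet
interiors of the other and the measured deviation equals the facet chord
(sagitta) error, not zero. ICP's point correspondences cannot resolve
offsets below the facet scale (tangential sliding is a known fixed point
of the update), so the suite adopts the same remedy the method assumes
in practice — finely tessellated STL models: resolutions are chosen so
the chord error of every curved fixture stays below 0.0025 mm at the
20 mm size, half the 0.005 mm threshold under which a statistic rounds
to 0.00. Concretely (the problem sizes used throughout the tests): cube
192 faces, sphere ≈ 39 600, cylinder 576, torus ≈ 53 900, blob ≈ 36 500
faces; alignment uses $N = 5000$ sample points; zero-row validation runs
100 seeded trials per perturbation class per geometry, and the severity
trend uses 20 paired seeds per $V \in \{0.1, 0.3, 0.5, 0.7\}$ on the
cube.

What the harness emulates — and what it does not: it covers rigid
misplacement and smooth bounded shape distortion with exact ground
truth. It does not emulate scanner noise, holes or topological defects,
partial overlap, or tessellation *differences* between reference and
test (real scans are remeshed independently of the CAD reference).
Passing the validation therefore demonstrates the metric's invariances
and its response to known distortion, not robustness to acquisition
artefacts.

## Benchmark aggregation

`run_benchmark` crosses geometries × perturbation specs × trials,
running the full pipeline each time. Cells are aggregated by the median
(robust to the occasional alignment local minimum); per-trial rows are
kept, and non-converged runs are flagged in their rows rather than
dropped.

## Contrast calibration utility

`fit_curve`/`target_concentration` fit and invert the ordinary
least-squares line relating CT attenuation (HU) to contrast-agent
concentration, valid over the fitted concentration range; extrapolation
warns. The shipped CSV templates carry the standard concentration grids
(0.008–0.04 g/ml for metal powders, 0.02–0.10 ml/ml for iomeprol) with
the HU column left to be filled from the user's own scanner, since
attenuation is scanner- and protocol-dependent. A possible breakpoint at
high concentration (departure from linearity) is not modelled.

## Known limitations

* Rigid alignment only; a globally mis-scaled test model shows up as a
  spatially structured deviation field, not a scale estimate.
* Deviations are sampled at reference vertices; error concentrated
  between vertices of a coarse reference mesh can be under-reported.
* The ICP objective is non-convex; the multistart handles rigid copies
  and moderate distortions of the fixture suite, but heavily distorted
  or highly symmetric inputs can still converge to a non-global pose.
  Non-convergence within the iteration caps is reported via the
  `converged` flag, never silently.
* For strongly distorted meshes ($V$ near 1) the FFD can in principle
  self-intersect; no repair is attempted.
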