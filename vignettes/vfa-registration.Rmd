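---
title: "Attribute-constrained surface registration by vector field analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attribute-constrained surface registration by vector field analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfareg)
```

## The problem

Automatic patient registration for image-guided head surgery must align an
intraoperative surface acquisition (here modeled after a mechanically
positioned A-mode ultrasound scan of the occiput) with a preoperative
CT-derived surface model, without fiducials and without a manual
pre-alignment. Plain iterative-closest-point style methods solve this only
locally: started more than a few tens of degrees from the true pose they
converge to a wrong local minimum.

vfareg implements a registration approach that attacks this with three
ingredients:

1. **Form attributes.** Distinct anatomical features (the individual sutures
   of the Lambda fissure, the external occipital protuberance) carry
   distinct non-negative integer labels. Matching is *binary*: a moving
   point may only be matched to a fixed point of the same class. This is
   realized exactly as the limit of the weighted 4-D distance
   $\mathrm{dist}_w(p,q) = \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2 +
   w\,\Delta a^2}$ for very large $w$ (default $10^9$).
2. **A Gaussian scale-space energy.** With $d_n$ the constrained closest
   distance of moving point $n$, the registration energy is
   $E_\sigma = \sum_n \left(1 - e^{-d_n^2/\sigma^2}\right)$,
   a smoothed version of the Hooke spring energy $\sum_n d_n^2$: near
   alignment $E_\sigma \approx \sum d_n^2/\sigma^2$, far away each term
   saturates at 1. The aperture $\sigma$ (default 10, on mm coordinates)
   sets the smoothing scale.
3. **Vector field analysis (VFA).** The negative gradient of the per-point
   potential defines a force field pulling the moving cloud onto the fixed
   one. The curl of that field characterizes the rigid motion it induces;
   the attributed point of minimal curl magnitude (the *vortex*) is the
   instant center of rotation (ICR), and the pose is re-parameterized so
   rotations pivot about it during optimization. This decouples rotation
   from translation, which is what gives the method its wide convergence
   basin.

The classic Gaussian-fields (GF) formulation is included as the baseline:
identical energy shape, but *soft* attribute matching (the attribute
difference is added to the distance with a moderate weight, default
$\sigma^2$) and rotations about the coordinate origin.

## Matching and fields

Binary matching is computed as an independent nearest-neighbour search per
attribute class — mathematically the exact $w \to \infty$ limit of the
weighted distance, and numerically safer than evaluating with $w = 10^9$
(which swamps the spatial term in floating point). The finite-$w$
brute-force search is kept as a test oracle. Moving points whose class is
absent from the fixed cloud are a contract violation and raise
`vfa_missing_class_error`; silently dropping them would hide acquisition
problems. Background points (attribute 0) never participate in matching and
are carried only for visualization and error maps.

The analytic per-point gradient treats the correspondence as locally fixed
(correspondence switches happen on a measure-zero set of poses, the
standard treatment in closest-point methods). The curl of the scattered
force field is estimated per point by a Gaussian-weighted least-squares
affine fit over its `k_neighbors` (default 12) nearest neighbours; the curl
is read off the antisymmetric part of the fitted Jacobian. The fit is exact
on affine fields. Two numerical guards matter in practice:

* Points sampled from a surface band cannot constrain the out-of-plane
  derivative; singular directions of the neighbourhood below $10^{-7}$ of
  the leading one contribute zero derivative (truncated pseudo-inverse).
  Collinear neighbourhoods are an error (`vfa_degenerate_neighborhood_error`).
* On a partially saturated field, force *and* curl decay like
  $e^{-d^2/\sigma^2}$, so the raw curl argmin would always select the most
  disengaged point of the cloud — the opposite of a vortex. `find_vortex()`
  therefore only considers points whose force magnitude is at least 1% of
  the field maximum, and breaks ties by smaller force, then lower index.

## Optimization

Both drivers minimize $E_\sigma$ over the six pose parameters (extrinsic
x–y–z Euler angles in degrees, translation in mm; rotation about the
configured pivot) with a BFGS quasi-Newton iteration and Armijo
backtracking (shrink 0.5, constant $10^{-4}$, at most 30 halvings).
Correspondences are recomputed at every objective evaluation; gradients
freeze them at the evaluation pose. The ICR is detected once before
optimization (`refresh_icr_every = 0`); periodic re-detection is available
but made no measurable difference in our experiments.

Two further choices are part of the method as implemented here, and both
were driven by measurements on the synthetic data:

**Translation initialization.** With $\sigma = 10$ and initial offsets of
hundreds of mm, every energy term is saturated and the gradient underflows:
no gradient method can start there. The optimizer therefore starts at the
translation that aligns the attributed-point centroids of the two clouds
(`center_initialization = TRUE`). This is the translation half of the
rotation/translation decoupling; rotations start at zero.

**A widened line search at stall ("stepping out").** The registration
energy over the rotation group is multi-modal: half-turn poses that bring
parts of a feature set close to itself form genuine local minima, and a
strictly monotone descent started at a random orientation frequently
terminates in one. Whenever a convergence test triggers (or no Armijo step
is admissible, or a 25-iteration window shows less than 0.1% relative
progress), the line search widens before convergence is declared: a
deterministic set of candidate poses is evaluated, and the best candidate
that *strictly improves* on the incumbent resumes the descent. Because only
improving candidates are ever accepted, the accepted-step energy trace
remains non-increasing — all exploratory oscillation stays inside the line
search. For the VFA driver the candidates come from the ICR
parameterization: single- and double-axis rotation offsets relative to the
current pose plus a fixed 30° Euler net, each with the translation re-solved
by centroid alignment under the probed rotation. The GF baseline runs the
same optimizer, but its classical formulation provides no pivot structure
to derive such candidates from; it only probes along its current descent
directions, which in practice never escapes a half-turn minimum. This
reproduces the qualitative published behavior of the two methods: the GF
basin ends at roughly ±30° while VFA converges from the whole rotation
range (see the basin-sweep evaluation below).

Convergence is reported when the gradient norm falls below
`gradient_tolerance` ($10^{-6}$) or an accepted step decreases the energy
by less than `function_tolerance` ($10^{-9}$) and the widened search finds
no better pose; hitting `max_iterations` (500) reports `converged = FALSE`.

## The synthetic phantom and scan

No public data accompanies the method, so the package generates its own
study conditions:

* `make_phantom()` builds a skull-like dome: quasi-uniform points
  (Fibonacci spiral, default 5000) on a spherical cap spanning elevations
  $[-65°, 90°]$ with base radius 90 mm, radially perturbed by a smooth
  seeded bump field (amplitude 5 mm) that breaks all rotational symmetries.
  Three suture-like arms (120 points each, classes 1–3) radiate as
  great-circle arcs of 150° from a "Lambda" junction at elevation 55°, with
  a seeded transverse meander (amplitude 8 mm) and band scatter (2.5 mm);
  a compact 60-point blob (class 4) sits 90° away. Two geometric properties
  are deliberate: the features are spread so their centroid falls within
  0.25 radii of the cloud centroid (the method requires features evenly
  distributed about the principal axes), and the arms meander because an
  exact great-circle arc maps onto itself under a half-turn about its
  circle axis — a self-symmetry real sutures do not have, which would
  manufacture artificial registration ambiguities.
* `simulate_amode_scan()` emulates the polar acquisition: rays on an
  inclusive 1° grid over azimuth $[0°, 360°]$ and elevation $[-60°, 60°]$
  (361 × 121 nodes) from the shell center; each ray takes the radius of the
  nearest cloud point within a 0.75° cone, Gaussian radial noise (default
  0.3 mm — an assumption at the lower edge of clinically reported error,
  not a measured sensor property) and 30% ray dropout (matching the
  reported loss of correctly measured points through soft tissue). Scan
  points inherit the attribute of the surface point that produced them.
  The mechanical kinematics of the real positioning device are not
  modeled; registration only consumes the resulting cloud.

What passing tests on this generator do *not* show: real CT segmentations
and ultrasound reconstructions have structured (non-Gaussian) noise,
occlusions, and attribute-marking errors at feature boundaries; the
phantom's features are cleanly labeled by construction. Conclusions about
absolute clinical accuracy therefore do not transfer; the generator is
designed to exercise the algorithmic claims (convergence basins, energy
shape, field analysis), not to certify accuracy on patients.

## Evaluation tools

* `tre()` computes the target registration error at labeled corresponding
  target points; `phantom_targets()` places them on the far side of the
  dome from the features, mimicking anterior-skull targets whose error is
  amplified by the lever arm.
* `distance_map()` gives the per-fixed-point nearest-neighbour distance to
  the registered moving cloud, clamped by default to the clinical color
  scale [0.3 mm, 1.5 mm].
* `basin_sweep()` rotates the moving cloud about a principal axis through
  its attributed centroid in 5° steps, registers from each start, and flags
  runs whose residual is within 10% of the sweep's best (plus an absolute
  floor of $10^{-6}$, which only matters when the best residual is
  numerically zero).
* `energy_surface()` evaluates $E_\sigma$ on a 2-D grid over a pair of
  rotation angles. The grid covers $[0°, 360°)$ half-open: an inclusive
  grid would contain the identity at both 0° and 360° and no grid could
  have a unique minimum.

## Numerical choices and conventions

* Euler convention: extrinsic (fixed-axis) composition
  $R = R_z(\psi) R_y(\theta) R_x(\phi)$, angles in degrees everywhere,
  including serialized transforms. Transforms are always built from
  parameters and never decomposed back into angles, which sidesteps the
  gimbal non-uniqueness entirely; inverses and compositions carry their
  rotation matrix directly.
* Nearest-neighbour ties break to the lowest fixed index, identically in
  the fast path and the brute-force oracle.
* Matched distances are recomputed from the coordinate differences of the
  winning pairs; the expanded-form distance matrix used for the argmin is
  only accurate to about $\sqrt{\varepsilon}$ near zero.
* The registration drivers evaluate energy and Jacobian through an internal
  precomputed-matrix path; `energy_of_params()` / `jacobian_of_params()`
  are the public reference implementations and the test suite asserts
  agreement to $10^{-10}$.
* Problem sizes in the test suite: the standard pair is the default
  generator output (5420-point phantom, 420 attributed; ~7000-point scan,
  ~460 attributed); self-registration experiments run 20 random
  displacements; basin sweeps run 5° steps over ±180° on three axes for
  both methods. These sizes were chosen to exercise the method at the same
  attributed-point scale as the application it models (about 400 marked
  points per cloud).

## Worked example

```{r example, eval = FALSE}
phantom <- make_phantom(phantom_config(seed = 1))
scan <- simulate_amode_scan(phantom, scan_config(seed = 1))

truth <- rigid_transform(c(14, 177, 176), c(0, 16.5, -33))
moving <- displace(scan, truth)

fit <- register_vfa(phantom, moving)
glance(fit)
autoplot(fit)

targets <- phantom_targets(phantom)
tre_rep <- tre(targets, transform_cloud(targets, truth), fit$transform)
glance(tre_rep)
```

## Known limitations

* The stepping-out candidates make the VFA driver's global behavior
  specific to rigid 6-parameter registration; the bare
  `quasi_newton_minimize()` with default ray probes is a local method.
* The curl estimator needs locally 2-D neighbourhoods; degenerate (curve-
  or point-like) feature sets raise errors rather than producing silent
  nonsense.
* Registration quality degrades gracefully with noise, but the binary
  matching assumes attribute labels are consistent between the clouds; a
  systematically mislabeled feature class acts as an adversarial
  constraint.
* Energies of different runs are comparable only at equal attributed point
  counts ($E_\sigma$ scales with $N$).
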