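---
title: "Subtomogram averaging with subtomo: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtomogram averaging with subtomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtomo)
```

## The problem

Cryo-electron tomography images cellular volumes in three dimensions. Many
copies of a macromolecule can be cropped out of tomograms as small cubic
*subtomograms* and averaged to amplify their common signal — provided each
copy's unknown rotation and translation are first estimated. Two features
make this harder than ordinary template matching:

* **The missing wedge.** A single-axis tilt series only measures Fourier
  coefficients whose in-plane angle (in the plane spanned by the beam
  direction and the axis perpendicular to the tilt axis) falls inside the
  tilt range, typically ±60°. Every particle is therefore a *filtered* view
  of the structure, and the filter rotates with the particle.
* **Extreme noise.** Per-particle signal-to-noise ratios near or below 1
  are normal, so scores must be contrast-invariant and the search
  exhaustive rather than local.

`subtomo` implements the complete computational core of that workflow:
missing-wedge-aware alignment by locally normalized cross-correlation,
iterative wedge-compensated averaging with threshold selection and
multireference classification (MRA), PCA on a blockwise cross-correlation
matrix, a membrane-geometry tool that turns annotated tomogram sections
into oriented particle positions, and a first-come-first-served task pool
with file semaphores. Everything is validated against synthetic phantoms
with known ground truth.

## Conventions

These are fixed package-wide and stated here once:

* **Euler angles**: ZXZ intrinsic, *active*, degrees. A triplet
  $(a, b, c)$ denotes $R = R_z(a)\,R_x(b)\,R_z(c)$ applied to the density
  (the grid stays put). The three angles play the roles familiar from
  subtomogram-averaging practice: azimuthal rotation, tilt, in-plane
  (narot) rotation. The inverse triplet is $(-c, -b, -a)$.
* **Rotation centre**: the voxel at 0-based index $\lfloor L/2 \rfloor$ on
  each axis. This is also where the DC term of a centred (fftshifted)
  spectrum sits, so real-space and Fourier-space centres coincide for any
  $L$.
* **Interpolation**: trilinear, with out-of-cube voxels filled by the
  volume mean (an unbiased choice for masked correlation statistics). The
  identity rotation is returned bit-for-bit. The rotation kernel is the
  package's one piece of compiled code; everything around it is plain R on
  top of the FFT.
* **Wedge geometry**: tilt axis along the 2nd array axis, beam along the
  3rd. A coefficient $(k_1, k_2, k_3)$ survives a wedge
  $[\theta_{\min}, \theta_{\max}]$ iff $\mathrm{atan2}(k_3, k_1)$, folded
  into $[-90°, 90°]$ by Friedel symmetry, lies in the range. Asymmetric
  ranges are supported. The mask spans the full cube so that the full
  range $(-90, 90)$ is the exact identity; the *retained fraction*
  reported by `wedge_fraction_retained()` is measured inside the Nyquist
  sphere, where the in-plane angle is uniformly distributed and the
  analytic value $(\theta_{\max}-\theta_{\min})/180$ holds — over the full
  cube the corners inflate the count ($0.711$ instead of $2/3$ for ±60°),
  a pure square-versus-disc artefact with no physical content.
* **Fractional shifts** use Fourier phase ramps; the unpaired Nyquist
  frequency of an even-sized axis cannot carry a pure phase ramp and
  receives the real cosine factor instead, keeping the operator
  real-to-real. On Nyquist-free (i.e. properly bandlimited) data,
  fractional shifts compose and invert exactly.
* **Tables**: positions are 0-based voxel indices internally and 1-based
  in table files; the conversion happens only at the I/O boundary. Shifts
  and angles are relative and never converted. A table row stores the
  template→particle transform: `particle ≈ shift(rotate(template, euler),
  shift)`; averaging applies its inverse.

## The alignment model

For each candidate rotation $g$ on an angular grid, the template $T$ is
rotated, bandpassed, filtered with the particle's wedge $W$, and normalized
to zero mean and unit variance under the alignment mask $m$. The particle
$p$ is bandpassed once. The score of translation $t$ is the locally
normalized cross-correlation

$$\mathrm{cc}(t) \;=\; \frac{\sum_x m(x)\,T_g(x)\,p(x+t)}
{M\,\sigma_p(t)}, \qquad M = \sum_x m(x),$$

where $\sigma_p(t)$ is the standard deviation of the particle under the
mask displaced by $t$. Because mean and variance are recomputed at every
translation, the score is invariant under affine changes of the particle's
contrast — the property that makes template matching usable in
low-contrast tomograms. All translations are scored at once through
spectral convolutions of $p$ and $p^2$ with $m$, and the implementation is
pinned against a brute-force sliding-window evaluation to $10^{-6}$.

Numerical guards: translations where $\sigma_p(t)$ falls below $10^{-6}$
times the global particle standard deviation score 0 (flat regions must
not divide by almost-zero); scores are deterministic, with ties broken by
the lowest rotation index and then the lexicographically smallest shift.

The per-rotation order is rotate → bandpass → wedge-filter → normalize.
Bandpass and wedge are both diagonal in Fourier space and commute, so only
the position of normalization (last) matters.

### Angular grids

Grids are parametrized by a cone half-angle and sampling step plus an
in-plane range and step. Directions are placed ring by ring on the
spherical cap, each ring holding $\mathrm{round}(360\sin\theta/\Delta)$
points; the tilt to azimuth $\phi$ is applied by conjugation,
$R_z(\phi)R_x(\theta)R_z(-\phi)$, so that azimuthal placement never leaks
into the in-plane angle (composing $R_z(\phi)R_x(\theta)$ directly would
inject spurious in-plane rotations of size $\phi$ as $\theta \to 0$).
Duplicate poses are removed by greedy quaternion clustering at an absolute
tolerance of $10^{-4}$ degrees. `refine_grid()` divides ranges and steps
by `factor^level` around a previous pose for coarse-to-fine refinement.
Binning (`project_config(binning = b)`) Fourier-crops volumes by $2^b$ and
rescales the reported shifts.

## Wedge-compensated averaging

Averaging selected particles voxel-wise would embed each particle's
missing wedge into the average. Instead the package averages in Fourier
space with coverage weights: each selected particle is moved into the
reference frame (unshift, then unrotate), its spectrum added to a
numerator, and its *rotated wedge mask* added to a denominator; the
average is the inverse transform of numerator over denominator. A
coefficient measured in 30 of 100 particles is then correctly averaged
over those 30, not diluted by 70 zeros.

One numerical decision deserves emphasis. Where the summed coverage is
close to zero, the numerator contains only interpolation leakage (rotated
binary masks are trilinearly resampled and not exactly binary), and
dividing by a tiny floor would amplify that leakage by orders of
magnitude — enough to destroy the average outright. Coefficients whose
coverage falls below $\max(0.5,\; 10^{-3} K_{\mathrm{sel}})$ — less than
half of one particle's worth of measurement — are therefore set to zero
rather than divided. The validation suite checks the behaviour this
matters for: two noise-free copies with complementary half-wedges
$(-90,0)$ and $(0,90)$ average to correlation $\ge 0.99$ with the phantom
although each copy alone stays below $0.99$, and 100 randomly posed
noise-free copies average to $\ge 0.99$.

### Iteration, selection and MRA

`run_project()` runs the full engine: align every particle against each of
the $K$ current references (grids centred on each particle's current
pose), assign each particle to its best-correlating reference
(`mra_assign`, ties to the lowest index), select per reference — either
the best fraction by cross-correlation or an absolute threshold — and
average the selection into the next reference. The selection threshold is
applied *after* MRA assignment, per reference. All intermediate tables and
averages are persisted under iteration-stamped folders (`ite_0001`, ...).
The engine itself is deterministic and uses no randomness; the project
seed exists for the synthetic module.

## Classification

`ccmatrix()` computes the pairwise matrix of zero-shift correlations of
aligned, bandpassed, masked particles. Wedges are handled by comparing
only coefficients *jointly* measured by both particles (the intersection
of their rotated, binarized wedge masks), so missing data never masquerade
as disagreement. The matrix is assembled from independent rectangular
blocks — each a task for the pool — and the blockwise result is
identical to the monolithic one because every entry is computed by the
same expression. `pca_components()` double-centres the matrix and
eigendecomposes it, the classical-scaling construction; coordinates are
eigenvectors scaled by the square roots of non-negative eigenvalues.
Negative eigenvalues (wedge-intersection correlation matrices need not be
Gram matrices) are truncated in the coordinates and reported unchanged.

## Membrane geometry

The membrane workflow turns a handful of user-clicked seed points on one
tomogram section into a triangulated surface carrying regularly spaced,
normal-oriented particles:

1. **Tracking** (`propagate_membrane_points`): each point searches the
   next section within `search_radius` voxels for the maximum *ridge
   response* — the positive Laplacian of the lightly smoothed section.
   A ridge detector is used deliberately: membranes are dark *lines* in a
   section, and the gradient magnitude of a symmetric line profile is zero
   exactly on the membrane and peaks on both flanks, which mistracks the
   centre by the profile width. The peak is refined to sub-pixel precision
   by a parabolic fit. Points whose response falls below a floor are
   flagged unpropagated, never fabricated; the workflow anchors this floor
   at half the median response at the user's own seeds, because a floor
   relative to the current section cannot stop propagation on sections the
   membrane never reaches (an all-noise section is self-normalizing).
   Tracking stops when fewer than three points, or fewer than half,
   propagate.
2. **Resampling** (`resample_spline`): cubic splines (periodic for closed
   contours) parametrized by chord length, resampled at equal arc-length
   steps of `control_spacing`; realized spacings are uniform to ~2%.
3. **Triangulation** (`triangulate_surface`): rings are stitched pairwise
   into triangle bands with target edge `mesh_parameter`. The workflow
   selects rings spaced `mesh_parameter` apart along the *meridian arc*,
   not in $z$ — near a pole one section step spans several voxels of
   meridian — and closes each pole by extrapolating the meridian profile
   (mean ring radius versus $z$) with a fitted circle, emitting synthetic
   rings down to an apex instead of one flat fan. Face normals are
   oriented away from the interior centroid. The mesh is finally smoothed
   with the shrink-free Taubin scheme ($\lambda = 0.5$, $\mu = -0.53$,
   32 iterations in the workflow) to damp sub-voxel detection noise.
4. **Seeding** (`particles_on_surface`): dense face-candidate points are
   accepted greedily, in a deterministic pseudo-random order, under a
   minimum distance of $0.8 \times$ `particle_spacing`, saturating near
   one particle per `particle_spacing`$^2$ of area. Each particle's
   orientation rotates the z-axis onto its face normal; the in-plane
   angle, undetermined by a normal, is set to 0 and left to downstream
   alignment.

Parameters, all in voxels: `control_spacing` (spline control point
distance; default used in validation: 3), `mesh_parameter` (target
triangle edge; 3), `particle_spacing` (4), `search_radius` (5).

## The synthetic module

`make_phantom()` builds smooth compact densities with no self-symmetry
beyond the identity (an asymmetric sphere cluster, a dumbbell with unequal
heads, an L with unequal arms), so alignment tests cannot succeed by
accident. `simulate_dataset()` produces particles as
`wedge(shift(rotate(template)))` plus Gaussian noise; noise is added
*after* wedge filtering because noise enters at acquisition time and fills
the missing wedge in real data. SNR is variance-based and measured under
the default alignment mask: noise variance equals masked signal variance
divided by SNR, verified by a variance oracle at SNR 1. Random rotations
are sampled uniformly on the rotation group via normalized quaternions —
not uniform Euler angles, a classic pitfall — and guarded by a test that
the mean pairwise rotation angle matches the closed-form value
$90° + 360°/\pi^2 \approx 126.5°$. `simulate_membrane_tomogram()` provides
dark spherical or planar membrane shells with analytic surface
descriptions for the geometry oracles.

What the generator does *not* emulate: contrast transfer functions, dose
weighting and tilt-dependent damage, tilt-series alignment errors, and
structured (non-Gaussian) background. Passing tests therefore demonstrate
correctness of the algorithms under the stated noise model, not
performance on any particular experimental data set.

## Parallelism

The task pool dispatches independent per-particle tasks first-come,
first-served: an idle worker immediately claims the next unprocessed task,
which balances heterogeneous task durations and heterogeneous workers. Three
coordination modes exist: an in-process master queue, and two file
semaphores for settings where workers share only a file system — claim by
atomic `mkdir`, or claim by hard-link creation (atomic even on NFS).
Results are merged by task id in input order, never by completion order,
so project outputs are bit-identical across worker counts and scheduling
accidents; the suite verifies exactly-once execution under both semaphores
(200 tasks × 20 repetitions) and bitwise equality of a project run with 1
and 4 workers. Claims that never produced a result (a crashed worker) are
detectable on disk and re-executed by the master, marked as reclaimed in
the audit log.

## Validation scale and reported checks

The problem sizes in the test suite and in `scripts/acceptance.R` are the
package's chosen validation conditions: 16³ volumes for exact-equivalence
oracles; 50 particles of side 32 at SNR 1 under a ±60° wedge on a
10°-step grid for pose recovery (the noise-free variant uses integer true
shifts, since sub-voxel displacement caps the attainable correlation of an
integer-translation search); 2 × 20 particles of side 24 at SNR 2 for
two-class MRA; a radius-30 sphere in a 96³ brick for the membrane chain.
At SNR 1 neighbouring 10° grid poses are genuinely confusable, so pose
recovery is judged within one grid step; exact grid-point identification
saturates near 90% under these conditions regardless of mask or bandpass.

## Known limitations

* Exhaustive angular scanning only — no FFT-accelerated rotational search
  or local gradient refinement; cost grows linearly with grid size.
* Trilinear interpolation bounds the fidelity of rotated wedges and
  high-frequency detail; averages of many randomly posed copies plateau
  near correlation 0.995 with the ground truth for this reason.
* The membrane tracker assumes the membrane is the dominant ridge within
  the search radius; it will follow a nearby stronger ridge if one exists.
* Fourier cropping requires the binning factor to divide the side length.
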