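---
title: "Volumetric ECGI: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric ECGI: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(volmap)
```

# The problem

Electrocardiographic imaging (ECGI) estimates the electrical activity of
the heart from multi-electrode body-surface potential recordings and a
geometric model of the torso and heart.  The classical formulation treats
the region between the epicardium and the torso skin as a source-free,
homogeneous, quasi-static volume conductor and solves a Cauchy problem for
Laplace's equation: given potentials `g` measured at `M` electrodes on the
insulated torso surface, estimate the potentials `h` on the epicardial
surface.  Discretizing with the boundary element method yields a dense
transfer matrix `A` with `A h = g`.  Because only the outer surface of the
heart carries unknowns, this formulation cannot represent intramural or
septal activation directly, which is precisely where clinical localization
of ectopic beats is hardest.

The volumetric formulation implemented in this package instead keeps the
heart inside the conductor and models a scalar *current-source density*
`f` throughout the myocardial volume, governed by the Poisson equation
`-lap(phi) = f` with an insulated torso boundary.  The physical source
model is the bidomain surrogate `f = div(sigma_i grad Vm)`: the divergence
of the intracellular current driven by the transmembrane voltage `Vm`,
nonzero only in the myocardium.  A pure-Neumann Poisson problem admits a
solution only when the net source vanishes, so every time slice of `f`
must satisfy the existence (compatibility) condition `integral f dV = 0`.

The link between electrode potentials and volumetric sources is the
Neumann Green's function of the torso: for electrode position `y_i`,
`G(y_i, .)` solves `-lap G = delta_{y_i}` with uniform compensating
boundary flux `-1/Area` (`Area` the torso surface area).  Sampling `G` at
the `P` myocardial nodes gives row `i` of the transfer matrix `B`, and the
discrete forward model is `g = B W f`, where `W = diag(w)` holds the
lumped nodal volume weights — the quadrature of the volume integral.  The
same vector `w` is the single row of the discrete existence constraint
`w' f = 0`.

Both inverse problems are severely ill-posed and are stabilized by
zero-order Tikhonov regularization,

* epicardial: `min ||A h - g||^2 + lambda ||h||^2`,
* volumetric: `min ||B W f - g||^2 + lambda ||f||^2` subject to `w' f = 0`,

with the regularization parameter chosen by the L-curve criterion.  The
constrained problem is reduced exactly onto the null space of `w'` with a
Householder basis and solved as an unconstrained Tikhonov problem there;
one SVD of the (reduced) operator is shared across all time samples and
all `lambda` values.

# Discretization choices

**Finite elements.**  The torso is meshed with first-order (P1)
tetrahedra.  The pure-Neumann stiffness matrix has the constants in its
null space; we factorize once with one interior node grounded and re-gauge
every solution to zero mean over the torso-boundary nodes.  For compatible
loads this is algebraically identical to a null-space-deflated solve.  The
forward load of a source field is the lumped quadrature `w * f`, so the
discrete compatibility `sum(w f) = 0` holds by construction whenever `f`
comes from the weak-form source computation: `compute_sources()` returns
`f = -(K_H Vm) / w` with `K_H` the heart-restricted stiffness, and the
column sums of the load vanish identically because constants are in the
stiffness null space.

**The electrode singularity.**  A unit point load at a boundary vertex is
the worst case for P1 elements: the discrete Green's function carries an
O(h) error near the electrode that pollutes the whole row.  The default
assembly therefore splits off the known singular behavior of a point
source on a smooth insulated boundary,

    S(x) = 1/(2 pi r) - (H / 4 pi) * log(r + d_n),

where `r` is the distance to the electrode, `d_n` the depth below the
tangent plane, and `H` the local mean curvature estimated by an
osculating-sphere fit of the two-ring vertex neighborhood.  On a sphere
this `S` equals the exact Neumann Green's function up to a constant, which
is why it removes essentially all of the near-singularity error.  The FEM
then solves only for the smooth remainder, driven by the residual boundary
flux `-1/Area - dS/dn`, integrated with a consistent P1 rule (subdivision
quadrature near the electrode; faces incident to the electrode vertex
carry no residual load, since the flux of `S` vanishes identically on flat
faces through the electrode).  On a 7200-tet ball this reduces the
relative L2 error of `B` against the analytic Legendre series from ~6% to
~0.5%.  A `"plain"` assembly mode (nodal Dirac load, no splitting) is kept
because it is *exactly* reciprocal to `forward_solve()` on the same mesh —
the property used by the discrete consistency tests.  The row gauge of `B`
is zero mean; for compatible sources a per-row constant shifts predictions
by `c * (w' f) = 0`, so the Neumann gauge freedom provably cannot leak
into predictions or solutions.

**Boundary elements.**  The epicardial baseline uses vertex collocation
with panel-lumped linear weighting.  The double-layer diagonal is closed
by the solid-angle row-sum identity, which makes constant potentials an
exact discrete solution (the `A 1 = 1` test holds to machine precision).
The single layer is *not* lumped through panel means: on a triangular
lattice whose subdivision frequency is divisible by three, panel means
annihilate an alternating three-coloring mode and make the operator
exactly singular.  We use a vertex-charge discretization (lumped vertex
area over distance) with hat-weighted subdivision quadrature for near and
singular panels instead.  A central-dipole oracle in concentric spheres
agrees to ~0.2% at the default resolution.

**Meshing.**  No general tetrahedralizer is available to this package, so
the mesher is a radially layered lattice: a geodesic icosphere of
frequency `nu` provides the angular connectivity, layers follow the
(analytic or ray-cast) radii of the torso, epicardial and endocardial
surfaces, and the prisms between layers are split into three tetrahedra
with the index-ordering rule that guarantees conforming diagonals.  This
covers every star-shaped domain, which includes all phantoms in scope.
Boundary-layer nodes lie exactly on the input surfaces.

# The synthetic phantom

The phantom emulates the ingredients of a torso-tank-style simulation at
desk scale: a 150 mm torso sphere; a myocardial shell between 35 and
50 mm (optionally eccentric); 128 electrodes on a deterministic Fibonacci
lattice snapped to distinct torso-boundary vertices; a propagating
activation front; and calibrated additive noise.  Default resolutions
mirror the regime of the reference setting: ~12 mm torso-surface edges,
~3.5-4 mm myocardial edges.

Activation is an *eikonal surrogate*: ground-truth local activation times
(LATs) are shortest-path distances over the myocardial edge graph divided
by a conduction velocity of 0.8 mm/ms (a physiological bulk ventricular
value).  The transmembrane surrogate is a compact raised-cosine upstroke
of unit amplitude and 5 ms duration centered at each node's LAT — exactly
resting before, exactly plateaued after, steepest at the LAT.  Sources
follow from the weak-form divergence, signals from the FEM forward solve,
and white Gaussian noise is added at 20 dB SNR, defined on the global
signal (all electrodes and samples pooled); the per-lead alternative
exists but is off by default.  The noisy signals are conditioned with the
simulated-data chain (zero-phase 10th-order Butterworth low-pass at
50 Hz); clinical recordings would instead receive the powerline comb
(50/100/150/200 Hz notches), the 40 Hz low-pass and the 0.67 Hz high-pass.
All filters are applied forward-backward because activation markers are
phase-sensitive; attenuations in dB therefore double relative to a
single-pass design.

The forward model is homogeneous by default, but
`conductivity_regions()` can place spherical inclusions (e.g. a 0.7 S/m
blood pool or 0.0389 S/m lung analogs against a 0.8 S/m background) into
the forward operator while the inverse transfer stays homogeneous —
deliberate forward/inverse model mismatch for robustness experiments.
Eccentric (`heart_offset_mm`) and ellipsoidal (`torso_axes`,
`heart_axes`) variants break the concentric symmetry.

What the phantom does *not* emulate: bidomain ionic dynamics, fiber
anisotropy, realistic organ anatomy, real torso
asymmetry, repolarization.  Tests passing on the phantom demonstrate the
correctness and the relative behavior of the two inverse formulations
under a known ground truth; they do not by themselves establish clinical
accuracy on anatomical geometry.

# Activation mapping

Reconstructed per-node signals are low-pass smoothed (windowed-sinc FIR,
default 40 Hz cutoff), differentiated, and transformed into a sum of
single-lobe sinusoidal wavelets centered at negative-slope samples with
weights proportional to slope amplitude; the LAT is the argmax of the
transformed signal.  All convolutions are circular and summed in a fixed
tap order, so the marker is *exactly* equivariant under circular time
shifts and invariant under amplitude scaling (ties are broken after
quantizing the transform to 2^-40 relative resolution).

A polarity subtlety deserves emphasis.  The true bidomain-surrogate source
at a node has a positive-going deflection at activation, and on noiseless
source fields the positive-slope convention recovers the ground truth
almost perfectly.  The *reconstructed* source field behaves differently:
a Tikhonov solution is a filtered back-projection of surface potentials
and inherits their deflection sign, so reconstructed traces follow the
unipolar-electrogram convention — steepest *negative* deflection at
activation.  Empirically the difference is decisive on the phantom
(LAT-to-truth correlation ~0.97 with the electrogram convention against
~0.5 with the source convention on clean reconstructions).  `compute_lat()`
exposes the choice through its `polarity` argument; fitted reconstructions
default to the electrogram convention, raw `Vm`/source fields to the
positive-slope convention.

The earliest-activation site is the centroid of the nodes with LAT
strictly below the 10th percentile (linear-interpolation percentile), with
a fallback to the minimum-LAT nodes when the strict set is empty; this is
more robust than the single earliest node.  Localization error is reported
both as the Euclidean distance and as the edge-graph geodesic over the
myocardial tetrahedral graph (both methods are scored on that same graph,
after snapping each point to its nearest heart node and adding the
snapping offsets).  The edge-graph geodesic overestimates the continuous
geodesic by a bounded lattice-inflation factor (<10% on the meshes used).

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `torso_radius_mm` / shell radii | 150 / 50 / 35 | mm | phantom geometry |
| `electrode_count` | 128 | – | body-surface sampling |
| `heart_volume_edge_mm` | 3.5 | mm | myocardial mesh resolution |
| `conduction_velocity_mm_ms` | 0.8 | mm/ms | eikonal front speed |
| `upstroke_duration_ms` | 5 | ms | raised-cosine rise time |
| `sample_rate_hz` | 1000 | Hz | acquisition rate |
| `snr_db` | 20 | dB | global additive-noise level |
| `lambda` | `"auto"` | – | Tikhonov weight, L-curve selected |
| `percentile` | 10 | % | earliest-site node subset |
| wavelet half-width | auto (2x median upstroke width, 2-30 ms) | ms | LAT transform support |

The L-curve grid spans `[1e-8, 1e2] * sigma_1^2` with 60 log-spaced
points; one `lambda` serves the whole recording (per-sample selection is
not exposed — a single spatial operator and a single noise level make a
single parameter the standard choice).  A degenerate, cornerless L-curve
(e.g. an identity-like operator on noiseless data) falls back to the
smallest grid value with a warning.

# Numerical conventions

* Coordinates are millimetres, right-handed; node indexing is 1-based.
* Signals are re-referenced to zero electrode mean per sample, and the
  inverse solves work in the same reference-free quotient space (operator
  columns centered).  `re_reference = FALSE` restores the full space.
* The additive potential constant of every Neumann solve is fixed to zero
  mean over torso-boundary nodes.
* The torso is a homogeneous unit-conductivity conductor in both transfer
  operators, so absolute source units are arbitrary; `sigma_i` is an
  amplitude factor only.
* Degenerate inputs are masked, not fatal, where the science allows it:
  flat traces yield invalid LAT entries; an all-equal LAT map still has a
  well-defined earliest site (all valid nodes).

# Benchmark design

The paired benchmark mirrors a 16-beat layout: 6 beats from a basal-analog
cap around the top pole of the shell, 6 from the inner (septal-analog)
wall — the region surface methods handle worst — and 4 from the outer
(free-wall-analog) wall.  Both methods always see the *same* conditioned
signals per case and noise replicate.  Problem sizes at the defaults:
~31.5k mesh nodes, ~11.3k myocardial nodes, 128 electrodes, ~150-200 time
samples per beat, 16 cases with 10 noise replicates in the test suite (4
in the acceptance script).  On this phantom the volumetric method roughly
halves the median geodesic localization error globally and cuts it by a
factor of 2-3 for inner-wall beats.  For free-wall beats the epicardial
baseline is already close to the source and shows no disadvantage (on
this symmetric phantom it is in fact slightly better there); the
volumetric gain is concentrated exactly where surface methods
struggle — deep and basal origins — which is the qualitative ordering
reported for anatomical simulations at full scale.  The absolute millimetre errors here are
smaller than anatomical-geometry values because the phantom is smaller,
symmetric, and free of model mismatch; only directions and ratios are
meaningful points of comparison.

# Known limitations

* The mesher requires star-shaped surfaces; strongly concave torsos are
  out of scope (no general tetrahedralizer is bundled).
* Zero-order Tikhonov reconstructions of a thin wavefront are heavily
  smoothed; pointwise source amplitudes are not quantitative, and only
  coarse phantoms make pointwise field recovery meaningful.  Activation
  *timing* is the robust output.
* The L-curve corner is undefined for noiseless or degenerate data; the
  fallback is deliberate and warned about.
* The AHA 17-segment labeling assumes an approximately convex LV with a
  meaningful long axis; labels near ring boundaries depend on the apex-cap
  fraction (default 0.2).
* Signals I/O is plain CSV; meshes are legacy ASCII VTK / OFF / STL.
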