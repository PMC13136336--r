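# volmap — volumetric electrocardiographic imaging of cardiac activation

`volmap` reconstructs cardiac electrical activation from multi-electrode
body-surface potential recordings (ECGI: electrocardiographic imaging).
It implements two inverse formulations side by side:

* **Epicardial ECGI** (the classical baseline): a Cauchy problem for
  Laplace's equation in the source-free volume between the heart and the
  insulated torso, discretized with a boundary element method, estimating
  potentials `h` on the epicardial surface from `A h = g`.
* **Volumetric ECGI**: a Poisson inverse *source* problem.  A scalar
  current-source density `f = div(sigma_i grad Vm)` lives throughout the
  myocardial volume; Neumann Green's functions `G(y_i, x)` of the
  insulated torso (computed by P1 finite elements, one solve per
  electrode) link it to the electrode potentials through `g = B W f`,
  where `W` holds nodal volume weights.  Each time slice obeys the source
  existence condition `integral f dV = 0`.

Both are solved by zero-order Tikhonov regularization with L-curve
selection of `lambda`; the volumetric problem additionally enforces the
existence condition exactly (`w' f = 0`, via an exact null-space
reduction):

    h^ = argmin ||A h - g||^2 + lambda ||h||^2
    f^ = argmin_{w'f = 0} ||B W f - g||^2 + lambda ||f||^2

Reconstructed per-node signals are turned into local activation time
(LAT) maps by a sinusoidal-wavelet transform that weights negative-slope
samples by slope amplitude; the earliest-activation site is the centroid
of the nodes below the 10th LAT percentile, and localization error against
a known origin is reported as Euclidean and mesh-geodesic distance.  The
package ships a self-contained synthetic phantom (torso sphere, myocardial
shell, 128 electrodes, eikonal activation front, bidomain-surrogate
sources, 20 dB noise) so the whole chain runs without any external data.

Who this is for: researchers in computational electrophysiology and
bioelectric inverse problems who want a transparent, fully scripted
reference implementation of volumetric source-based ECGI next to the
classical epicardial formulation, with analytic oracles and a paired
localization benchmark.

## Worked example

One septal-wall ectopic beat, end to end:

```r
library(volmap)

spec <- phantom_spec()          # 150 mm torso, 35-50 mm shell, 128 electrodes
ops  <- build_operators(spec)   # mesh + FEM/BEM transfer operators (~3 min)

sc   <- benchmark_scenario(ops$geom)        # 6 base / 6 septal / 4 free wall
beat <- simulate_phantom_beat(ops$geom, sc$origin_node[7],
                              op = ops$op, graph = ops$graph)
gcond <- condition_signals(beat$noisy, "simulated")

fit <- solve_volumetric(ops$prep_vol, gcond)
fit
#> ECGI volumetric reconstruction
#>   nodes x samples : 11260 x 184
#>   lambda          : 0.004359 (L-curve)
#>   rel. residual   : 0.03487
#>   max |w'f|       : 4.22e-15

lat <- compute_lat(fit)
hn  <- which(ops$geom$mesh$heart_node_mask)
site <- earliest_site(lat, ops$geom$mesh$vertices[hn, ])
site
#> earliest_site: centroid (32.63, 19.80, -1.47) mm from 1106 nodes (< p10)

localization_error(ops$geom$mesh$vertices[sc$origin_node[7], ],
                   site$centroid, ops$geom$mesh, graph = ops$graph)
#> localization_error: euclidean 3.80 mm, geodesic 8.56 mm
```

The printed fit shows the reconstruction size (myocardial nodes x time
samples), the L-curve-selected regularization weight, the relative data
residual at that weight, and the worst violation of the source existence
condition (zero to solver precision).  The earliest-site centroid is then
compared against the seeded beat origin: for this deep septal-analog beat
the volumetric reconstruction lands within a few millimetres (3.8 mm
Euclidean, 8.6 mm geodesic), while the epicardial baseline
(`solve_epicardial(ops$prep_epi, gcond)` scored the same way) comes in at
10.5 mm Euclidean / 16.4 mm geodesic — roughly twice as far.

The paired comparison over all 16 beats:

```r
bm <- run_benchmark(run_config(spec = spec, n_seeds = 2), ops = ops)
bm
#> ecgi_benchmark: 16 cases x 2 seeds, methods: epicardial, volumetric
#>   epicardial  euclidean_mm mean   6.35 +-  3.20 mm, median   5.61 mm
#>   epicardial  geodesic_mm  mean   9.86 +-  4.18 mm, median   9.71 mm
#>   volumetric  euclidean_mm mean   6.09 +-  3.59 mm, median   4.41 mm
#>   volumetric  geodesic_mm  mean   7.84 +-  4.10 mm, median   5.49 mm
#>   reduction (euclidean_mm): 4.2%
#>   reduction (geodesic_mm): 20.5%
```

Median geodesic error roughly halves globally, and the largest gains come
from the inner-wall (septal-analog) beats — the pattern that motivates
volumetric source imaging.  Absolute millimetre values are phantom-scale
quantities and smaller than anatomical-geometry errors; the directions and
ratios are the meaningful output.

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/volmap", package="volmap"))') \
    benchmark --out results/ --seeds 2
```

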