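---
title: "Vortex-map QA for deformable registration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vortex-map QA for deformable registration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirqa)
```

## The problem and the metric

A deformable registration returns a displacement field
$\vec u = u\,\hat i + v\,\hat j + w\,\hat k$ on the voxel grid, in mm.
Registration being an ill-posed inverse problem, a solution can match the
image intensities well while describing tissue motion no solid organ could
perform. The canonical symptom is local circulation: neighbouring vectors
that rotate around a point or abruptly change direction. The vorticity

$$\nabla \times \vec u =
  \left(\frac{\partial w}{\partial y} - \frac{\partial v}{\partial z}\right)\hat i +
  \left(\frac{\partial u}{\partial z} - \frac{\partial w}{\partial x}\right)\hat j +
  \left(\frac{\partial v}{\partial x} - \frac{\partial u}{\partial y}\right)\hat k$$

measures exactly this microscopic circulation. `dirqa` evaluates it
voxelwise and reduces it to the scalar **vortex map**
$|\nabla \times \vec u|$ (Euclidean norm). Smooth, anatomically plausible
fields give values near zero; fragmented or swirling fields give high
values. Since displacement (mm) is differentiated with respect to position
(mm), the map is dimensionless. Clinical literature occasionally attaches
"mm" to curl ranges; we treat that as a units slip and report the map
unitless throughout.

The Euclidean norm was one of several possible scalar reductions (a single
component, or the largest component, would also colour-code); it was chosen
because it is rotation-invariant — the map does not change when patient
axes are permuted — and is the standard vorticity magnitude.

## Discretisation

Derivatives use second-order central differences
$(f_{i+1}-f_{i-1})/2h$ at interior voxels and first-order one-sided
differences on the two boundary slabs, with $h$ the physical spacing of the
axis; anisotropic grids (e.g. $1 \times 1 \times 2.5$ mm CT) are handled
per axis. Consequences worth knowing:

- the scheme is *exact* on fields affine in the coordinates, so the rigid
  rotation $\vec u = \vec\omega \times \vec r$ calibrates the whole
  pipeline: its map equals $2|\vec\omega|$ at every voxel including
  boundaries, to rounding error;
- interior values are exact for quadratic polynomial fields (gradients of
  quadratic potentials give an exactly zero interior map);
- non-polynomial analytic fields (e.g. the compactly supported radial
  expansion, which involves $|\vec r - \vec c|$) are analytically curl-free
  but retain an $O(h^2)$ discretisation residual — about $10^{-3}$ for the
  default expansion fixture, not $10^{-12}$;
- direction matrices other than identity are accepted; differentiation
  happens in index space scaled by spacing, the curl vector is expressed in
  the image axis frame, and the magnitude is frame-independent, so no
  resampling ever occurs.

NaN or infinite displacements are rejected when a `vector_field` is
constructed rather than propagated silently into the map.

## Summary statistics and hotspot detection

`field_stats()` reports min, max, mean and the 99th percentile (type-7
linear interpolation between order statistics) over an optional mask. The
**maximum** is the primary figure of merit, matching how map ranges are
quoted in practice; p99 is added because the maximum is a single-voxel
statistic and can be dominated by one aberrant voxel.

Hotspot identification in the field is inherently visual; `dirqa`
operationalises it as connected components of the suprathreshold set
`map > threshold`. Defaults: threshold 5 (the nonphysical band edge),
26-connectivity, minimum region size 3 voxels (a single- or two-voxel
component is more plausibly a numerical spike than a physical defect; this
size is a design choice, not an empirical constant). Labels are assigned in
scan order and regions are returned ranked by peak value, ties broken by
ascending label, so the output order is deterministic. Each region carries
its voxel count, physical volume, peak value and location, and the
intensity-weighted physical centroid.

## Plausibility bands and structure proximity

Observed practice puts clinically valid solutions at curl values roughly
in $[0, 5]$ and clearly nonphysical ones at 5 and above, with values above
3 typical of regions where an algorithm struggled. `classify()` therefore
uses two configurable thresholds, `borderline_min = 3` and
`valid_max = 5`:

- `plausible` — map max below 3;
- `borderline` — max in $[3, 5)$;
- `nonphysical` — max at or above 5.

The verdict depends on the *global* maximum only. This is deliberately
conservative and deliberately incomplete: a hotspot far from any structure
of clinical interest may be acceptable, the way a gamma-index failure in
irrelevant tissue is. Rather than fold location into an automatic verdict,
`structure_report()` surfaces, per structure mask, the peak value inside
the mask, the minimum centroid-to-surface distance over detected regions
(0 when a region intersects the mask) and an intersection flag — leaving
the location-based judgement to the physician. Whether the bands should be
applied to the global maximum or to per-region peaks is genuinely open;
the global maximum was chosen as the stricter and simpler reading, and
per-region peaks remain available in the report.

## The synthetic module: what it emulates, and what it does not

The generator reproduces, at desk scale, the ingredients of a phantom QA
protocol and the failure modes seen in clinical registration:

- **Phantom**: constant-HU cylinder and cube inserts (voxel-centre
  containment, so counts are deterministic) on a $-1000$ HU background,
  default spacing $1 \times 1 \times 2.5$ mm to mirror a CT acquisition
  with 2.5 mm slices.
- **Analytic fields** (translation, rigid rotation, compact radial
  expansion, gradients of quadratic potentials) with closed-form curl for
  calibration; the expansion mimics tumour growth/shrinkage between scans
  and its default magnitudes keep displacements under 10 voxels.
- **Random smooth fields** from a uniform cubic B-spline lattice with
  uniformly drawn node displacements — the parametric-registration model of
  smoothness. Coarser lattices are stronger regularisers: over paired
  seeds, widening the node spacing does not increase the map maximum.
- **Defect injection**: a compactly supported swirl
  $\Delta\vec u = \vec\omega \times (\vec r - \vec c)\, w(|\vec r - \vec c|/R)$
  with the bump $w(t) = (1-t^2)^2$. Because $w$ has zero slope at the
  centre, the injected peak curl is close to $2|\vec\omega|$ (within 10%),
  which makes defect strength a controlled dial.
- **Artifacts**: a crosshair streak (extreme-HU lines on one slice) and an
  HU-calibration offset inside a mask — the two CBCT corruption modes that
  break a monomodality registration.
- **Demons fixture**: a plain Thirion-style demons loop. Per iteration the
  force $(f - m\circ(\mathrm{id}+u))\,\nabla f / (|\nabla f|^2 + (f -
  m\circ(\mathrm{id}+u))^2)$ is added (denominator floored at $10^{-9}$,
  the standard stabilisation in flat regions; intensities internally
  rescaled to unit range; per-iteration step capped at half a voxel), and
  each displacement component is optionally Gaussian-smoothed — the demons
  regularisation. The QA metric is algorithm-independent, so a full
  diffeomorphic implementation is unnecessary: the fixture only needs to
  produce genuinely smooth fields with smoothing on and genuinely jagged
  ones with it off, which it does.

What the generator does **not** emulate: CBCT scatter physics and noise
texture, partial-volume effects beyond soft insert edges, sliding-organ
interfaces, and real multi-organ anatomy. Passing the synthetic suite
therefore demonstrates that the metric, detection and classification
machinery are correct and calibrated — not that the default bands are
clinically validated for any particular site; band validation requires
patient studies.

## The phantom experiment

`phantom_protocol()` assembles the end-to-end study: a clean "moving"
phantom (two cylinders, one cube control); a "fixed" target in which the
cylinders are expanded between scans and which carries a streak artifact
and an HU-offset region (in the clinical analogue the artifact-laden CBCT
is the registration *target*, which is also where the artifacts must be
for them to generate demons forces — the force is proportional to the
fixed-image gradient); demons registration without field smoothing, the
low-regularisation regime where artifacts do damage. Expected physics,
which the tests assert: the two strongest detected hotspot regions fall
inside (3-voxel-dilated) artifact masks, while the cleanly expanded
inserts, whose deformation is real and smooth, peak lower than both
artifact hotspots.

## Problem sizes and runtime choices

The suite runs calibrations at $64^3$ ($1 \times 1 \times 2.5$ mm),
oracle comparisons on ten seeded $16^3$ fields, defect recovery on ten
seeded $32^3$ fields, demons contrasts on five $32^3$ translated-sphere
configurations (40–60 iterations), and the phantom experiment at $64^3$
with 60 demons iterations. These sizes were chosen so the complete loop —
generation, registration, metric, detection, classification — exercises
every code path at CT-like anisotropy while a full run of the suite stays
in the half-minute range; the metric itself is a handful of vectorised
array passes and handles $256^3$ fields in seconds.

## Known limitations

- Boundary derivatives are first-order; a one-voxel rind of the map is
  slightly less accurate than the interior (exact only for affine fields).
  Hotspot decisions are rarely boundary decisions, but masks can exclude
  the rind if needed.
- Grids must match; `dirqa` never resamples. Mismatched field/image/mask
  grids are an error, not a warning.
- The demons fixture is monomodality, first-order, and deliberately
  minimal; it is a test-field generator, not a registration tool.
- Displacements are assumed stored in mm. Fields stored in voxel units
  must be flagged (`units = "voxels"` / `--field-units voxels`), which
  multiplies by spacing on load; there is no reliable way to auto-detect
  the convention from file headers.
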