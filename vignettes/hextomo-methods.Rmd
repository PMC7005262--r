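---
title: "hextomo: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hextomo: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hextomo)
```

# The problem

Bacterial chemosensory arrays are membrane-bound crystals: core signalling
units (CSUs) — two chemoreceptor trimers-of-dimers (ToDs) bridged by a CheA
dimer and two CheW monomers — tile the inner membrane in an extended
hexagonal lattice. In cryo-electron tomography of minicells the array follows
the curved membrane, so hundreds of subvolumes extracted along the surface
sample many orientations, and averaging them produces an isotropic 3D map
despite the missing wedge of single-axis tilting. `hextomo` implements this
subtomogram-averaging chain at desk scale, with a synthetic forward model
rich enough that every stage can be graded against exact ground truth.

This vignette explains the models, the scoring function, the tunable
parameters, and the design decisions taken where the underlying protocol
leaves choices open. It states no empirical result that the package's tests
and acceptance scripts do not themselves compute.

# The synthetic world

## Geometry

`place_hex_array()` places particles on a hexagonal lattice with two site
conventions: `"honeycomb"` puts ToD symmetry axes on honeycomb vertices
(3 first-shell neighbours at the ToD spacing, 6 second-shell neighbours at
√3 times it — the array lattice constant, e.g. 7.4 nm → 12.8 nm), and
`"centers"` puts one CSU-scale particle per unit cell on the triangular
lattice of hexagon centres (6 neighbours at the lattice constant; 120 Å is
the working default, matching the curation annulus). Surfaces are planes or
spherical caps (minicell geometry, default radius 2000 Å); on a cap the
planar lattice is mapped by an azimuthal equidistant projection about the
cap axis, which preserves radial arc lengths and compresses azimuthal
distances by at most ~1% over a 20° cap.

**In-plane coherence.** Chemosensory arrays are orientationally ordered: a
CSU's in-plane orientation is locked to the lattice direction. The generator
therefore gives every particle an in-plane angle that follows the local
lattice frame, with one random (seeded) lattice azimuth per array. This
matters operationally: only a coherent array can be matched by a multi-CSU
reference, and with independent per-particle angles (available as
`inplane = "random"`) no reference can represent the neighbourhood of any
particle. Orientations use ZYZ intrinsic Euler angles in degrees; the motif
reference axis is +z; the particle axis is the outward surface normal.

## Density, wedge and noise

The pseudo-CSU motif (`make_csu_motif()`) is a parametric stand-in for the
real density: two membrane-normal cylinders (the ToD pair, 74 Å apart along
the motif x axis) spanning z = −100…+30 Å about the membrane mid-plane, plus
a baseplate disc (the CheA/CheW layer) below, all with Gaussian-softened
edges and exact C2 symmetry about +z. `render_tomogram()` sums rotated motif
copies at the ground-truth poses and adds a Gaussian-profile membrane
(spherical shell or slab, half-thickness 14 Å, amplitude 0.5 of the motif
peak).

The missing wedge is applied either by direct Fourier masking
(`apply_missing_wedge()`: tilt axis y, beam z; a coefficient is sampled iff
|kz| ≤ |kx|·tan(max tilt), so ±60° removes one third of each kx–kz plane in
angular measure) or by the slower, more faithful projection route
(`project_and_wbp()`: parallel-beam projections at the scheme's angles, ramp
weighting, back-projection, optional binning). The two degradation paths
agree to correlation > 0.9 inside a central mask, which the test suite
verifies. Noise is white Gaussian at a stated volume-variance SNR — the
alignment under test is contrast-model-agnostic, so no CTF or phase-plate
model is simulated.

What the generator does **not** emulate: electron dose and damage, CTF and
phase-plate contrast, gold fiducials, tilt-series alignment errors,
membrane deformations beyond a perfect sphere/plane, conformational
heterogeneity, and crowding by other cellular material. A green recovery
test therefore establishes that the inference machinery is correct under the
stated geometry and noise model, not that it would reach any particular
resolution on real data.

# Alignment

## The score

`constrained_ncc()` scores a reference pose against a subvolume as a masked,
locally normalized cross-correlation, restricted to the Fourier components
the subvolume actually sampled:

* the reference is mask-weighted and mean-removed under the mask, then its
  spectrum is multiplied by the binary wedge support;
* the subvolume's local mean and variance under the (prior-rotated) mask are
  computed for every candidate shift by FFT convolution, so a perfect match
  scores exactly 1 with a binary mask;
* only shifts within the translational limit (60 Å per axis by default) are
  considered, and the integer peak is refined by per-axis parabolic
  interpolation.

With soft masks or wedge filtering the normalization can overshoot 1
marginally; reported scores are clamped to [−1, 1] while raw values rank
candidates. `cone_angular_search()` wraps this in an exhaustive rotation
search: axis deviations up to the cone half-angle on a quasi-uniform grid
(azimuth count ∝ sin of the deviation) crossed with an in-plane sweep; a C2
reference halves the sweep (`sym = 2`). Ties break toward the smaller
angular distance to the prior, then the lower grid index — the same rule the
brute-force oracle in the test suite applies.

## Context references

A subtomogram is a crop of a wedge-filtered *infinite* scene: wedge-smeared
density from structure outside the box leaks into the crop. A reference
built from an isolated model lacks that context, which biases the
translation peak by several Å for membrane-array data. The context path of
`cone_angular_search()` therefore rotates a *larger* array model
(`make_array_reference()`, the motif plus its coherent lattice neighbours on
the fitted membrane) to the prior orientation, applies the wedge at full
size in the tomogram frame, and crops to the alignment box — the crop then
carries the same out-of-box contributions as the data. Candidates are
applied as small residual rotations of the crop, which is accurate for the
local refinements that use it; wedge-filtered crops are memoised across
particles sharing a quantised prior.

## Two-stage refinement

`iterative_refine()` runs the two-stage protocol: stage 1 inside a soft
cylinder covering a multi-CSU footprint plus the membrane slab (default
radius 120 Å, z −120…45 Å, 3-voxel cosine edges), stage 2 inside the same
cylinder cropped below the membrane with a tighter angular budget and the
context reference. Defaults: 573 Å boxes, 60 Å shifts, stage-1 in-plane step
10°, stage-1 search binned by 2, stage-2 in-plane step 1°, early stop when
the mean score changes by < 1e-4, abort if it *drops* by > 0.05
(divergence). Stages flagged `renormal` re-derive each particle's axis from
the fitted surface normal at its aligned position — the membrane constrains
the axis far better than a per-particle search — keeping the fitted in-plane
angle. Mask radius and z-range are capped to the box; 64-voxel boxes are the
supported minimum for the default motif.

Two numerical notes discovered during validation and worth recording. First,
an infinite flat membrane slab lies entirely inside the missing wedge in
Fourier space, so in a planar world the membrane contributes almost nothing
to the data while small masked reference discs retain some slab power; very
small boxes therefore bias z and are refused by the mask cap. Second, on a
sphere the azimuthal-equidistant lattice mapping plus wedge leakage leaves
an irreducible ~1.5–3 Å bias in the *ground truth itself* away from the cap
centre; the quantitative recovery benchmark consequently runs on the planar
world (identical code paths, exact lattice), while the spherical world is
exercised end to end in the pipeline test.

# Curation

All geometric cleaning operates per tomogram (positions are only comparable
inside one physical volume). `collapse_duplicates()` merges connected
components of the 10 Å threshold graph (single linkage) into their centroid,
keeping the best-scoring member's orientation, and re-applies itself in the
rare event two centroids fall back within the threshold — so the result is
idempotent with minimum pairwise distance above the threshold.
`neighbor_filter()` keeps particles with strictly more than 3 others in the
closed annulus 120 ± 20 Å, in a single non-iterative pass.
`estimate_lattice_spacing()` reports per-particle nearest-neighbour
distances but takes the modal spacing from *all* pairwise distances near the
NN scale: under jitter the min-of-neighbours statistic is biased several
percent low, while the symmetric first peak of the full distance histogram
is not.

# Averaging and validation

`average_subvolumes()` accumulates each particle's Fourier coefficients
after one inverse trilinear resampling into the reference frame, together
with its analytically rotated binary wedge support, and divides the summed
coefficients by the summed support (floored at ε = 0.01): orientation
diversity fills the wedge. Half-sets are tomogram-disjoint
(`split_half_sets()`, greedy balance of particle counts). `compute_fsc()`
uses one-Fourier-voxel shells and linear interpolation at the 0.5 and 0.143
crossings; a never-crossing curve returns the Nyquist resolution with a
flag. `local_resolution()` evaluates windowed FSC in a cosine-tapered
spherical window (24 voxels by default) on a 20 Å grid; `local_filter()`
blends a ladder of global low-passes so a constant resolution map reproduces
a single global filter. `symmetrize_c2()` searches a ±10° cone (1° steps)
of two-fold axes by the masked correlation of the map with its 180° rotation,
optionally refines the axis origin in-plane, and averages the map with its
rotation about the best axis.

# Dose–response module

`simulate_fret_trace()` produces YFP/CFP ratio traces: per stimulus window a
step drop of amplitude A·Lʰ/(Kʰ+Lʰ) relative to the saturating drop,
exponential adaptation during the window, and a methylation overshoot after
removal (simulated, not quantified). `fractional_inhibition()` measures each
drop as pre-stimulus baseline (median of the preceding 20 s) minus plateau
(median of the final half of the window), normalised by the saturating drop
and clipped to [0, 1]. `hill_fit()` fits the standard Hill form with free
exponent by `nls` (port algorithm) — the "multi-site" designation in the
source protocol refers to this form, and only K½ and h are reported there,
so no explicit partition function is fitted. Bootstrap confidence intervals
resample residuals inflated by √(n/(n−3)) to account for the three fitted
parameters; without the inflation, coverage in the end-to-end simulation
falls measurably short of nominal.

# Choices a maintainer might revisit

* Centre convention: cube centre = 0-based voxel `floor(N/2)` on every axis,
  everywhere (extraction, rotation, masks, FFT layout).
* The default voxel size, 4.48 Å, is 2.24 Å detector pixels binned by two —
  implied, not printed, in the source protocol.
* The neighbour filter counts *all* particles in the annulus, not k-nearest
  only, and runs once (no re-filtering), the simplest reading of the
  protocol.
* Pipeline stage 2 keeps the full 60 Å translational freedom (iterative
  global alignment); the generic `refinement_config()` stage-2 default is
  a quarter of it, fitting the "local refinement" description.
* The pipeline collapses duplicates a second time after refinement:
  stage-1 scatter can leave two seeds per lattice site further apart than
  the collapse threshold, and they only converge during local refinement.
* No B-factor sharpening anywhere.

# Known limitations

The rotation kernel is trilinear (interpolation loss ~1% correlation per
resampling at the working band); the SO(3) grid is quasi-uniform, not exact
Hopf sampling; the wedge model is a binary support with no dose or tilt
weighting; the iterative refinement defaults to an external array-model
reference rather than bootstrapping from seed averages (the in-plane-blind
seed average cannot break the lattice azimuth degeneracy without many more
iterations than a desk-scale budget allows; `reference = NULL` still
provides the seed-average route). Sphere-cap worlds carry the Å-scale
ground-truth frustration described above; treat sub-voxel accuracy claims on
curved lattices with care.
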