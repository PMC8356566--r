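---
title: "Depth-resolved OCT-A slab processing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved OCT-A slab processing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaslabs)
```

## The problem

OCT angiography (OCT-A) detects blood flow as the temporal variability of the
OCT signal across B-scans repeated at the same lateral location: perfused
voxels decorrelate between repeats, static tissue does not.  In adults the
perifoveal capillaries organize into three depth strata — the superficial
(SCP), intermediate (ICP) and deep (DCP) capillary plexuses — and depth
resolution comes from projecting the flow volume over slabs bounded by offsets
from segmented retinal layer junctions.  In preterm infants the retina is
still developing: layers are thinner, the secondary (deep) vasculature may not
exist yet, and cystoid macular edema — fluid spaces almost exclusively inside
the inner nuclear layer (INL) — distorts boundary-referenced slabs.  Adult
slab conventions therefore do not transfer.

This package implements the full processing chain for depth-resolved
visualization of the infant perifoveal vasculature from repeated-B-scan
acquisitions: speckle-variance flow computation, retinal boundary
segmentation with manual-correction import, anatomically referenced offset
slab schemes, en face projection with an offset-sweep collage for parameter
exploration, a display enhancement chain, and blend-mode color compositing.
Because clinical volumes from the target population are not publicly
available, the package ships a synthetic retinal phantom with known ground
truth, so that every stage is quantitatively testable.

## Coordinate model and conventions

The canonical voxel order is `(repeat, bscan, depth, ascan)`.  Depth index 0
is on the vitreous side and increases toward the choroid, so "above a
junction" always means a smaller depth index and offsets *above* are
*negative*.  Boundary surfaces store fractional depth positions on a 0-based
scale; file formats (CSV boundaries, sidecar JSON) use 0-based lateral
indices, while the R API uses R's native 1-based array indices.  Slab
intervals are half-open `[upper, lower)` with half-up rounding of fractional
endpoints; the deepest slab of a scheme closes its outer boundary inclusively
so a zero-offset scheme partitions the ILM to OPL/ONL band exactly (the
conservation property the tests verify with sum projection).  Columns where
the resolved upper surface lies at or below the lower one (thin retina near
the foveal pit) are *empty*, never inverted.

## Flow computation

`speckle_variance()` computes the per-voxel *population* variance across the
N repeats, `flow = mean((I - mean(I))^2)`.  The divide-by-N choice is
deliberate: the repeats are the complete set of observations at a location,
and the alternative (N-1) only rescales flow globally, which no downstream
stage is sensitive to (projection, normalization and thresholding are all
scale-equivariant up to the enhancement normalization, which removes scale
entirely).  Variance is computed on linear intensity; log-compressed exports
must be linearized by the caller.

`align_repeats()` compensates axial bulk motion with a per-B-scan rigid
integer shift (bounded by `max_shift_px`, chosen by maximizing correlation
with the first repeat).  Full 3-D motion correction is out of scope; the
handheld-acquisition use case assumes volumes already selected for minimal
motion artifact.  `mask_low_signal()` zeroes flow where the mean structural
intensity falls strictly below a caller-chosen quantile of its distribution,
suppressing variance noise in the vitreous and below the retina.  The
quantile should roughly match the signal-free fraction of the volume: the
pipeline default (0.05) is deliberately conservative; on the phantom, whose
vitreous plus sub-retinal space is roughly 45% of voxels, a floor of 0.3
removes essentially all vitreous flow noise.

## Boundary segmentation

The segmenter is a *baseline*, not a re-implementation of any clinical tool:
the pipeline contract is "boundaries in, slabs out", and imported boundaries
(e.g. from dedicated segmentation software, reviewed and corrected by
graders) are first-class via `load_boundaries()` and `apply_corrections()`.

Per B-scan, each junction is a minimum-cost path across A-scans (dynamic
programming with a maximum per-column step of `max_jump`, default 2 px) on an
edge-score image, searched inside an anatomically ordered band below the
previously found junction, which enforces the non-crossing invariant by
construction.  The edge score combines:

* the signed axial gradient (dark-to-bright for the vitreous/ILM junction,
  bright-to-dark for IPL/INL and OPL/ONL);
* band contrast — mean intensity 1–3 px above minus 1–4 px below — which
  keeps thin bright vessels from posing as junctions (tissue below a vessel
  stays bright, below a true bright-to-dark junction it does not);
* for the IPL/INL search only, a bonus for brightness 6–16 px below the
  candidate edge.  This is the anatomical discriminator between the two
  bright-to-dark junctions: below the IPL/INL the dark INL is followed by the
  *bright* OPL band, whereas below the OPL/ONL the ONL stays dark.  Without
  it, columns where intermediate-plexus vessels hug the IPL/INL junction can
  pull an entire B-scan's path down to the OPL/ONL, whose raw edge strength
  is nearly identical;
* a small depth penalty (0.002 per px inside the band) as a tie-break toward
  the shallowest adequate edge — each junction is anatomically the *first*
  strong transition below its predecessor, and the RPE otherwise competes
  with the ILM.

Integer paths get parabolic sub-pixel refinement on the cost column.  A
constant (degenerate) B-scan yields flat traces at the band centres with a
warning.  The default search bands (ILM within 2–75% of depth, IPL/INL 8–48
px below the ILM, OPL/ONL 8–34 px below the IPL/INL) assume the ~4.37 µm/px
axial sampling; at other samplings they scale accordingly.

`apply_corrections()` splices replacement traces with a linear cross-fade
over a configurable margin at patch edges that lie strictly inside the
surface (so full-surface replacements are exact).  A corrected junction is
clamped between its anatomical neighbours — the corrected surface yields, the
untouched ones are not dragged — and every clamped position is counted and
reported.  `smooth_boundaries()` is a 2-D median filter (default 5×5),
removing isolated path spikes without blurring the foveal depression.

## Slab schemes

A scheme is an ordered, contiguous list of slabs, each bounded by a reference
junction plus a whole-pixel offset (1 px = 4.37 µm at the default sampling;
`offset_um_to_px()` rejects micrometre values more than 0.01 px from a whole
pixel, catching unit mix-ups).  Two schemes are built in:

* **Term** (three-layer, for eyes with formed secondary vasculature):
  SCP from the ILM to 8.74 µm (2 px) above the IPL/INL junction; ICP from
  there to 34.96 µm (8 px) above the OPL/ONL junction; DCP from there to the
  OPL/ONL junction.  Referencing the ICP/DCP boundary to the OPL/ONL junction
  rather than the IPL/INL keeps anomalous INL flow in cystoid edema assigned
  to the ICP, to which it is anatomically more connected — the scheme's
  robustness to edema comes from this choice, not from any cyst-specific
  processing (cyst-distorted boundaries are handled through manual
  correction import only).
* **Early** (two-layer, before the secondary vasculature forms): a
  superficial vascular complex (SVC) above the IPL/INL junction and a deep
  vascular complex (DVC) from there to the OPL/ONL junction.

`sweep_offsets()` reproduces the parameter-exploration workflow: the target
slab is projected for every combination of SCP/ICP boundary offset (0–4 px
above IPL/INL) and ICP/DCP boundary candidate (1–5 px below IPL/INL, or 5–10
px above OPL/ONL — 55 combinations by default), and `write_montage()` tiles
the labelled cells for side-by-side comparison.  Offset selection itself is a
grader-consensus judgement and deliberately not automated.

The default projection operator is the maximum over the slab's depth
interval, the prevailing convention for rendering capillaries in en face
OCT-A (a bright vessel anywhere in the slab should appear regardless of slab
thickness); mean and sum are selectable, and sum is what makes the
conservation property exact.

## Enhancement chain

Each projected slab passes through, in order:

1. **Min-max normalization** to [0, 1]; a constant image maps to zeros.
2. **Low-intensity-preserving threshold** (default 0.25).  "Preserve
   intensities below the threshold" admits two readings; the default clips
   values at the threshold and rescales by its inverse, preserving all
   sub-threshold (capillary) structure while saturating bright vessels —
   consistent with the goal of visualizing capillaries.  The alternative
   (zeroing values at or above the threshold) is available as
   `threshold_mode = "zero_above"`.
3. **Row-wise CLAHE** with 8 tiles across each row.  Each row is processed
   independently as a 1-D signal: per-tile histograms (256 bins over [0, 1])
   are clipped at `clip_limit` × tile size (fractional clip counts allowed),
   the excess is redistributed uniformly over all bins, and the mapping is
   the CDF re-anchored so the lowest bin maps to black — the classic
   histogram-equalization min-normalization, which keeps an all-black row
   black.  Pixels interpolate linearly between the mappings of the two
   nearest tile centres.  The clip limit (0.01) and bin count (256) are
   package defaults in the usual range for CLAHE implementations; only the
   tile count is prescribed by the workflow the chain reproduces.

Every stage maps [0, 1] into [0, 1], and row *r* of the CLAHE output depends
only on row *r* — both properties are regression-tested by perturbation.

## Compositing

The display overlay uses two Photoshop-style blend primitives, implemented
exactly: *subtract* (`clamp(base − layer, 0, 1)`) removes SCP shadow artifacts
from the ICP slab, and *lighten* (per-pixel channel maximum) superimposes the
gradient-mapped slabs (SCP yellow, ICP cyan, DCP magenta).  Gradient maps are
linear black-to-color ramps; display gamma is left to the viewer.  Shadow
subtraction applies to the ICP only — the DCP is never attenuated.  The
two-layer composite (SVC yellow, DVC magenta) applies no subtraction by
default, since the subtract step is specific to the ICP; it can be enabled
with `subtract_shadow = TRUE`.

## The phantom

`generate_phantom()` builds a repeated-B-scan acquisition with known truth.
Design choices, made once:

* **Geometry**: 4 repeats × 64 B-scans × 128 A-scans × 160 depth px at 4.37
  µm/px.  The repeat count and axial scale match the clinical acquisition
  pattern (so every pixel offset means the same thing); the lateral raster is
  scaled down from the clinical 250–500 × 500 so a full-pipeline run takes
  seconds.  Layer depths (ILM at 30 px, IPL/INL at 70, OPL/ONL at 90, an RPE
  band below) approximate an infant macula at this sampling, deformed by a
  smooth Gaussian foveal pit in which the inner layers thin.
* **Vessels** are random curved tubes with Gaussian cross-sections: SCP
  spread through the GCL band (with fewer, larger, more tortuous trunks in
  the early stage), ICP in a thin stratum just below the IPL/INL junction,
  DCP centred in the band above the OPL/ONL junction (4 px above it, the
  middle of the term scheme's DCP slab).  All plexuses avoid a foveal
  avascular zone, largest for the DCP.  Morphological realism is limited to
  curvature and caliber — sufficient for testing slab assignment, not for
  visual realism claims.
* **Flow** is per-repeat Gaussian intensity jitter at vessel voxels
  (amplitude 0.25 in reflectivity units), the signal speckle variance
  detects; there is no phase or Doppler model.  Vessels are mildly
  hyperreflective so they survive structural masking.
* **Speckle** is multiplicative Gaussian noise (σ = 0.05) independent per
  repeat and voxel.  Real OCT speckle is partially correlated between
  repeats and non-Gaussian; independence makes the background variance floor
  *harsher* for flow detection than reality, which is the conservative
  direction for testing.  One consequence: background variance scales with
  intensity squared, so the flow-off sanity check compares the
  intensity-normalized variance (variance / squared mean), which is
  identically distributed across voxels under the multiplicative model.
* **Edema** (optional) carves dark ellipsoidal cysts, near-black at the
  core, confined to the INL near the fovea.
* **Stages**: `term` has all three plexuses; `early` forces ICP/DCP tube
  counts to zero and dilates the superficial trunks.
* **Reproducibility**: one seed; each component (layers, vessels, cysts,
  flow, speckle) draws from a sub-seed derived from it, so toggling one
  component does not reshuffle the others.

What passing phantom tests does *not* show: performance on real infant
volumes with motion artifact, shadowing, real speckle statistics, or
pathology beyond the modelled cysts.  The phantom validates the *machinery*
(geometry, arithmetic, invariants, end-to-end recovery), not clinical
accuracy.

`evaluate_slab_assignment()` tabulates ground-truth vessel voxels against the
slab intervals that contain them; per-plexus recall is the package's
quantitative stand-in for the visual criterion of minimizing ICP projections
onto the DCP.

## Problem sizes and numerical choices

The test suite and the acceptance script run the default-geometry phantom
(64 × 128 × 160, four repeats) for end-to-end checks and 8–30 voxel-scale
random fixtures for oracle comparisons (tolerance 1e-10 against brute-force
loops); smaller phantoms (16–24 B-scans) are used where only determinism or
plumbing is exercised.  Degenerate rules are explicit: constant images
normalize to zero, empty slab columns project to zero, degenerate correlation
in alignment means zero shift, constant B-scans segment to band centres with
a warning.  Image quantization is round-half-up, compensated for the TIFF
writer's truncation so stored integers equal `floor(v * (2^bits - 1) + 0.5)`
exactly.  HDF5 volumes round-trip bit-identically; 16-bit TIFF volumes
round-trip to within one quantization step with the scale recorded in the
sidecar.

## Known limitations

* The segmenter finds three junctions only and assumes the layered
  reflectivity pattern of the perifoveal region; it is not a general retinal
  segmenter and has no cyst model (edema is handled through correction
  import and the term scheme's OPL/ONL referencing).
* Alignment is axial-only and integer-pixel.
* The CLAHE is 1-D by design (per row); it will not reproduce 2-D tiled
  implementations.
* PNG output is 8-bit (16-bit grayscale output uses TIFF).
* Offset optimization is exploratory (sweep + collage), not automated.
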