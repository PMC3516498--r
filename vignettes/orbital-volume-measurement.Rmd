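---
title: "Measuring bony orbital volume by serial coronal slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring bony orbital volume by serial coronal slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitovol)
```

## The measurement model

The bony orbit is approximately a cone or four-sided pyramid opening
anteriorly at the orbital rim (about 40 mm wide by 35 mm high in adults)
and tapering over roughly 45 mm to the apex at the optic canal. Its volume
is hard to measure directly because the inner border is irregular and
perforated — the superior and inferior orbital fissures and the
infraorbital groove interrupt every cross-section.

`orbitovol` measures the orbit the way an operator working slice-by-slice
would, but deterministically:

* **Canonical frame.** A rigid transform computed from two user-marked
  landmarks — the most dorsal points of the right and left orbital entries
  — maps the scan into a frame where the inter-orbital line is parallel to
  the left–right axis and the landmark midpoint is the origin
  (`canonical_transform()`). The coronal plane $y = 0$ through these
  landmarks is the *orbital frame plane*. The rotation is minimal: roll
  about the inter-orbital axis is left untouched unless rim landmarks are
  provided, in which case the mean superior–inferior rim axis is brought
  vertical. This mirrors how an operator levels the two orbits on screen
  before measuring; heads posed too far off for landmarks to be placed are
  simply not measurable, which is also how badly positioned scans were
  handled in practice.
* **Serial coronal slices.** Slices are taken at
  $y_k = -(k-1)\,\Delta$, $k = 1,\dots,n$, with $\Delta = 4.8$ mm and
  $n = 5$ by default, covering rim to apex at adult scale. Extraction uses
  the nearest native grid plane — never interpolation — because the
  protocol measures on native CBCT planes (0.3 mm increment).
* **Closed bony contour.** On each slice the bone mask (intensity
  threshold, see below) is traced from a seed inside the cavity: rays are
  cast in 720 directions and, along each ray, the first pixel of a
  wall-scale bone component marks the inner boundary; the crossing radius
  is refined by bisection to the cavity/bone pixel interface. Where no
  bone is found within the search radius (a fissure), the nearest boundary
  points flanking the interruption are joined by a straight chord —
  provided the chord is at most `max_gap_mm` (default 10 mm, comfortably
  above fissure widths at adult scale); longer gaps raise an "unclosable
  contour" error rather than guessing.
* **Area and volume.** A pixel belongs to the filled region iff its centre
  is inside or on the closed contour; the area is exactly
  (pixel count) × (pixel area), with no smoothing correction, so a
  brute-force point-in-polygon count is an exact oracle. The orbital
  volume is the Cavalieri sum $V = \Delta \sum_k A_k$.
* **Bilateral comparison.** The protocol's repeated-measures design has 3
  raters measuring each slice 3 times on each side. Per slice, the 9
  operated-side areas are paired with the corresponding (same rater, same
  repeat) healthy-side areas and compared with a paired t-test. A slice is
  *flagged* when the two-sided $p <$ `alpha` (0.05) **and** the operated
  mean is smaller — the question is one-directional (is the operated orbit
  smaller?) but the retained p-value is two-sided. No multiple-testing
  correction is applied across the five slices, matching the original
  protocol. Cases classify as **A** (flags 1–4 all set, flag 5 free),
  **C** (no flags), else **B**; patterns with ≥ 4 flags that still miss
  one of the first four are B with an `atypical` tag, since the taxonomy
  never anticipated them.

### What is assumed

* The cavity cross-section is *star-shaped* around the seed: every inner
  boundary point is visible from the seed. Conic and pyramidal cavities
  (and healthy orbital sections) satisfy this; a severely concave
  post-traumatic defect might not, and the radial trace would clip the
  concavity.
* Bone is separable from soft tissue by one global threshold per slice.
  CBCT grey values are not Hounsfield-calibrated, so the default
  `bone_threshold = "auto"` performs a two-class histogram split
  (maximum between-class variance) and takes the midpoint of the two
  class means; it requires the bone/soft-tissue contrast to dominate the
  slice histogram.
* The two entry-dorsal landmarks are placed by the user. Automatic
  landmarking is out of scope.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| `interval_mm` | 4.8 | mm | protocol slice spacing; 5 slices span rim→apex |
| `n_slices` | 5 | – | adult orbit depth ≈ 45 mm; configurable for other anatomies |
| `alpha` | 0.05 | – | protocol significance level |
| `bone_threshold` | `"auto"` | intensity | CBCT is uncalibrated; two-class split per slice |
| `max_gap_mm` | 10 | mm | upper bound for bridgeable fissures at adult scale |
| `n_raters`, `n_repeats` | 3, 3 | – | protocol repeated-measures design |
| `frame_offset_mm` | 0 | mm | slice 1 on the frame plane; whether the original procedure placed it half an interval behind is unrecorded, so the offset is exposed |

`close_boundary()` adds three numerical knobs: `n_rays` (720, i.e. 0.5°
angular resolution), `max_radius_mm` (30 mm search radius around the
seed), and `min_span_deg` (120° — a bone component must be visible over at
least a third of the view from the seed to count as enclosing wall, which
rejects noise specks and implanted spheres as boundary candidates).

## The phantom: what it emulates, what it does not

`generate_phantom()` builds CBCT-like volumes with *analytically known*
geometry so that every pipeline stage can be checked without scan data:

* bilateral elliptic-cone cavities (default rim 40 × 35 mm, depth 45 mm,
  centres 64 mm apart), voxelized at 0.3 mm isotropic — the cone gives
  closed-form cross-section areas
  $A(u) = \pi \frac{w}{2} \frac{h}{2} (1 - u/D)^2$ and volumes at every
  depth; a rectangular-pyramid alternative is available;
* a bony wall of constant thickness (2 mm) with two radial-sector gaps per
  side emulating the superior and inferior orbital fissures (3 mm wide,
  mirrored between sides so the noiseless phantom is bit-exactly
  midsagittally symmetric);
* a short anterior lip (one wall thickness, extrapolated cone law) ventral
  of the rim plane, so the bony frame does not end in a knife edge — as in
  anatomy, where the rim is continuous with the facial skeleton; without
  it, any posed scan resampled back to canonical orientation interpolates
  the frame-plane wall against empty space and the slice-1 contour
  fragments;
* abstract intensities (background 0, cavity 100, bone 1000) — CBCT is not
  HU-calibrated anyway — with seeded additive Gaussian noise (default
  sd 50, i.e. 18:1 bone contrast-to-noise, typical of maxillofacial CBCT
  bone imaging), constrained so bone exceeds soft intensities by ≥ 5 sd;
* optional implanted spheres (18 or 20 mm diameter) rendered at bone
  intensity;
* an optional rigid *pose* applied to the geometry itself (not by
  resampling), for alignment-recovery experiments with exactly known
  rotations.

The phantom deliberately omits: trabecular texture, beam hardening and
scatter, soft-tissue anatomy (globe, muscles, fat), the true four-walled
orbital shape, and partial-volume physics beyond voxel-centre sampling.
Passing phantom tests therefore demonstrates the *geometry and statistics*
of the pipeline — segmentation accuracy on clean bone, estimator
behaviour, calibration of the tests — not robustness to scanner artifacts
or anatomical variation.

`analytic_volume()` extrapolates the cone law ventral of the rim
(negative depths): the natural reference for a Cavalieri sum whose first
slice sits *on* the rim is the midpoint-rule slab
$[-\Delta/2,\, (n-1)\Delta + \Delta/2]$, which extends half an interval in
front of the rim plane.

## Numerical choices

* **Nearest-plane slice extraction**; ties round half up via `round()`.
* **Trilinear interpolation** for rigid resampling (compiled), with
  out-of-source voxels set to the source minimum so that later bone
  thresholding treats fill as dark background. Indices within $10^{-7}$ of
  a grid point are snapped, making identity, whole-voxel shifts and
  grid-aligned flips exact.
* **Sub-pixel boundary placement.** The radial hit is bisected to the
  interface between the last cavity pixel's cell and the first bone
  pixel's cell, an unbiased estimate of the wall position with ± half a
  pixel of jitter that averages out around the contour; measured areas on
  the default phantom land within 0.8% of the analytic sections.
* **Pixel-centre inclusion rule** (`fill_and_measure()`): centre
  inside-or-on the polygon. Whether the original software's red fill
  included its green border pixels is unrecorded; the centre rule is this
  package's convention and makes the brute-force oracle exact.
* **Chord bridging** across fissures (rather than morphological closing):
  deterministic, parameter-light, and directly implements "connect the
  nearest bony boundaries with a straight line". The chord-vs-arc sliver
  changes default-phantom slice areas by well under 1%. On very small
  phantoms (≲ 10 mm cavities at 0.4 mm voxels) the voxel-ragged cut face
  can bias chord endpoints mid-wall and the effect grows to ~2% — a
  scale-dependent discretization effect worth knowing about when designing
  miniature fixtures.
* **Degenerate inputs.** Zero-variance paired differences raise an error
  (the all-zero case can opt into the $t = 0, p = 1$ convention);
  constant slices defeat the auto threshold and error out; single-point
  contours fill one pixel; an unmeasurable slice aborts the orbit with a
  partial-result condition carrying the completed slices.
* **Seed propagation.** Slice $k$'s seed is slice $k-1$'s filled-region
  centroid, following the cavity as it drifts toward the apex; a fixed
  seed can exit the cavity in oblique orbits.

## Design decisions that were genuinely open

* **Pairing unit for the t-test.** The protocol never states what was
  paired. Pairing the 9 (rater, repeat) measurements across sides is the
  only reading that yields a within-case, per-slice paired test of the
  kind the published per-case tables report, so that is what
  `slice_significance()` does — documented prominently because it is an
  interpretation.
* **Significance vs direction under the null.** The per-slice *flag* is
  directional (smaller operated side), so under the null it fires at about
  $\alpha/2$; the calibration quantity reported by the acceptance script
  is the rate of two-sided $p < \alpha$, which is what "significant at
  0.05" means in the protocol.
* **Slice-1 position.** The frame plane itself (offset 0), exposed as
  `frame_offset_mm`.
* **Roll.** Fixed to zero without rim landmarks: the entry-dorsal line
  constrains only two axes, and inventing a roll would be arbitrary.
* **Rater noise in the pipeline.** A deterministic program re-measuring
  the same volume reproduces identical areas, so `run_pipeline()` emulates
  the human repeated-measures design with seeded multiplicative Gaussian
  noise (default sd 2% of area per measurement, optional per-rater bias) —
  a 2% tracing CV is a realistic figure for manual slice outlining at
  these scales.

## Known limitations

* Star-shaped cavities only (radial trace); severe concavities clip.
* One global threshold per slice; strong intensity gradients across a
  slice would need local thresholding.
* The Cavalieri estimator's accuracy gain from finer slicing saturates at
  the voxelization noise floor: on the default phantom the error falls
  from 0.09% (4.8 mm) to 0.05% (2.4 mm) but does not reliably shrink
  further at 1.2 mm, where per-slice discretization fluctuation (~0.05%)
  dominates the midpoint-rule error.
* Landmarks are trusted as given; no consistency check against the image.
* Implanted spheres are ignored by the angular-span filter only while
  they subtend less than `min_span_deg` from the seed; a seed placed very
  close to a large implant defeats the filter — place seeds away from the
  implant centre.
* DICOM series ingestion is out of scope (convert to NIfTI upstream), and
  NRRD is not read.

## Problem sizes used in validation

The test-suite and acceptance script measure, per run: one default
adult-scale phantom (401 × 198 × 171 voxels at 0.3 mm) per condition
(symmetric, 10%-shrunk, 7°-posed), five to nine slices per orbit, 2000
simulated cases for null calibration and 20 per cohort condition — sizes
at which the whole validation completes in about a minute each for the
suite and the acceptance script on a single CPU.
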