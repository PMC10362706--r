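---
title: "Projection-method facial volumetry: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-method facial volumetry: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facevol)
```

## The measurement problem

Serial 3D facial surface scans (structured-light scanning, exported as OBJ
triangle meshes in mm) can in principle quantify how the soft tissue of the
cheek changes after an intervention such as third-molar extraction. Two
obstacles make the naive approach — segment the cheek on every scan and
difference the volumes — unreliable:

1. **Boundary reproducibility.** The buccal region has no sharp anatomical
   boundary, so independently re-drawing it on every time point injects
   operator variance directly into the volume difference.
2. **No closed solid.** A facial scan is an open shell; "the volume of the
   cheek" needs a reference surface to close against.

The projection method in this package addresses both. The region boundary is
drawn **once**, on the baseline (T0) scan, as surface paths connecting
anthropometric landmarks. It is then *transferred* to the follow-up scans
geometrically: the boundary loop is swept ±10 mm along the normal of the
mid-sagittal plane into an open band (the *ring model*), and each registered
follow-up scan is cut along that band. The volume reference is the
mid-sagittal plane itself: the soft-tissue volume (STV) of a buccal patch is
the volume of the solid between the patch and its orthogonal projection onto
that plane, and the soft-tissue volume change (STVC) is the difference of
STVs between time points (later minus earlier). Because every time point is
cut by the *same* swept boundary and measured against the *same* plane,
boundary-placement error cancels in the difference.

The companion hard-tissue pipeline measures what was removed in the bone:
serial CBCT volumes are rigidly aligned per jaw, bone and teeth are selected
by an intensity window, the two segmentations are Boolean-subtracted, and the
change voxels inside operator-drawn selection boxes are counted
(hard-tissue volume change, HTVC, in ml; 1 ml = 1000 mm³, negative for
loss).

## Pipeline steps and their assumptions

**Registration** (`crop_upper_third`, `icp_register`). Follow-up scans are
registered to T0 using only the upper third of the face (by height range
along the frame's vertical axis), which is assumed rigid over the follow-up
period; the buccal region itself is excluded so that true soft-tissue change
cannot bias the alignment. The ICP variant is point-to-plane with uniform
vertex subsampling (default 5 000 samples drawn from the vertices that start
inside the fixed region's bounding box, with a 25 mm margin for the initial
misalignment), rejection of correspondences landing on boundary triangles of
the fixed region, a 3x-median distance cap, and a Gauss-Newton update per
iteration. Iterations stop when the RMS point-to-plane residual improves by
less than `tol` (default 1e-4 mm) or at `max_iter` (default 100). Identity
initialization is assumed adequate: serial scans of a seated subject differ
by a few degrees and millimetres.

**Mid-sagittal frame** (`laser_origin`, `build_frame`). The scanner's
orthogonal lasers are recorded as polylines. Both traces are reduced to
total-least-squares 3D lines; their closest-approach midpoint is the origin
(traces must approach within 2 mm). The horizontal plane passes through the
origin and the two farthest-apart points of the complete (unreflected)
horizontal trace; the vertical axis is its normal; Line 2 joins the origin
to the farthest vertical-trace point; the mid-sagittal plane is spanned by
the vertical axis and Line 2; and the projection direction is its normal,
oriented to the subject's right. Sign conventions are fixed by the trace
ordering (horizontal: left to right; vertical: inferior to superior). The
frame is built once, on T0, since all later scans are registered into T0
coordinates. Degenerate configurations (Line 2 within 0.1° of the vertical
axis, or a vertical trace lying in the horizontal plane) are errors.

**Region** (`chin_footpoint`, `surface_path`, `extract_buccal`). The
interactive "draw" operation is formalized as shortest edge-walks (Dijkstra
with Euclidean edge weights, via igraph) between the mesh vertices nearest
each landmark: posterotragion (pt') to alare (al'), al' to exocanthion
(ex'), ex' to cheilion (ch'), ch' to the chin footpoint cf' (the foot of the
perpendicular from ch' onto the mandible lower-border polyline), then along
the remaining border points back to pt'. The upper closure al'-ex' is not
anatomically prescribed anywhere; a direct surface path is the minimal
assumption and the loop composition is configurable through the landmark
set. The enclosed sub-mesh is found by cutting the face-adjacency graph
along the loop and keeping the component with no open mesh edge outside the
loop — a leak (the loop failing to separate the mesh) or an ambiguous
multi-component interior is an error, not a guess.

**Boundary transfer and cut** (`extrude_ring`, `boolean_cut`). The ring
model is the T0 boundary loop swept ±10 mm along the projection direction
(the sweep half-length is the protocol's printed value; it is configurable,
and any registered scan point inside the loop but beyond the band is an
error). The Boolean subtraction between the ring and an open scan shell is
implemented as curve cutting: scan faces are classified by projecting their
centroids along the sweep direction into the T0 boundary polygon
(point-in-polygon in the plane), the enclosed connected component is kept,
and its border is the cut curve. On open, non-watertight scan shells this is
equivalent to the mesh Boolean for every configuration in which the Boolean
is well defined, and it does not require watertight inputs. Self-cutting T0
with its own ring reproduces the original patch exactly.

**Volume** (`stv`, `stvc`). STV uses signed prism summation: for each
triangle, (signed distance of its centroid to the mid-sagittal plane) x
(area of the triangle projected onto the plane), summed and reported in ml.
For a patch that projects injectively onto the plane this equals the volume
of the closed solid between patch and plane; it is the natural
generalization otherwise, and it needs no solid construction. The patch must
lie on one side of the plane: opposite-signed faces up to 0.1% of the patch
area are clipped, more is an error (cheek patches never approach the
mid-sagittal plane in practice; the policy makes the failure loud instead of
silent).

**Deviation analysis** (`compare_surfaces`). For each reference vertex the
signed closest-point distance to the test surface is computed (positive
outside, along the reference normal; correspondences beyond 10 mm, the
sweep half-length, are discarded). Summaries use the population formulas
mu = mean(X), SD = sqrt(mean((X - mu)²)), RMS = sqrt(mean(X²)), so
RMS² = mu² + SD² holds identically; SD deliberately uses 1/N, not 1/(N-1),
to match the protocol's printed definition. Signed distances are used
because the reported per-period mean distances can be negative.

**CBCT** (`read_dicom_series`, `align_jaw`, `threshold_segment`,
`mask_subtract`, `htvc`). The segmentation window defaults to [550, 3300] —
the midpoints of the protocol's per-patient ranges (lower bound 400-700,
upper bound 2000-4600); both bounds are parameters because bone density
varies by patient and the protocol has the operator tune them. Jaw alignment
accepts an operator transform unchanged (manual mode) or refines it
automatically by maximizing normalized cross-correlation over a jaw box; the
automatic search does a coarse translation grid scan (half-range 3 mm, step
one voxel) before the 6-parameter Nelder-Mead refinement, because trilinear
resampling of near-piecewise-constant CT intensities creates voxel-period
local optima that trap a simplex started at zero. Both subtraction
directions are computed: tissue present at T0 and absent at T2 counts
negative (lost), the reverse positive, and HTVC is gained minus lost — an
extraction therefore yields a negative HTVC, matching the convention in
which resorption is reported as a negative volume. The DICOM layer is a
minimal reader/writer for uncompressed explicit-VR little-endian CT slices
(geometry tags and 16-bit pixel data); slices are stacked sorted by the
projection of the image position onto the slice normal, so on-disk file
order is irrelevant.

## The synthetic phantoms: what they emulate, and what they do not

`make_face_series` builds a cheek-like patch as a height field x = g(y, z)
over a 120 mm square footprint (x lateral = projection direction, z
vertical), triangulated at 0.5 mm — the scale of a structured-light scan of
one cheek. Because the surface is analytic, every downstream quantity has a
closed form. The default family is a flattened anisotropic
(superellipsoid-like) cheek. A spherical cap is also available but is used
only for volume oracles: a sphere slides on itself under rotations about its
center, so surface registration on a spherical patch has a three-parameter
family of equally good optima and recovery of a known perturbation is not
identifiable — an instructive degeneracy, and the reason the default phantom
is deliberately not a sphere (a real face has no continuous symmetry
either).

Follow-up scans differ from baseline by:

- a rigid perturbation (default a few degrees and millimetres about the
  patch centroid, the magnitude of session-to-session repositioning);
- optional Gaussian bumps displacing the surface along the projection
  direction, A·exp(-rho²/2sigma²); each adds exactly 2·pi·A·sigma² mm³ of
  projected volume, giving the STVC ground truth (bump specifications are
  validated to keep the truncated tail below 0.1%);
- optional along-normal Gaussian noise (0.2 mm is the scanner's nominal
  accuracy scale).

Laser traces are emitted as the analytic curves the two laser planes leave
on a virtual full face: a horizontal arc at laser height and a mid-sagittal
profile curve, with constants chosen so that the two fitted laser lines
cross exactly on the midline, as the physical lasers do on a real face. The
landmark set is stylized: the landmarks carry the anatomical codes and
ordering but sit at fixed template positions scaled into the patch
footprint.

`make_cbct_series` builds a voxel phantom (default 112³ at 0.25 mm) with a
soft-tissue background (100), a 1.5 mm cortical-bone box shell (3000), a
marrow interior (200), and a "tooth" sphere (2800, default r = 8 mm)
validated to lie inside the marrow cavity; T2 lacks the tooth. The analytic
truth is -4/3·pi·r³ ≈ -2.14 ml, deliberately in the range of a wisdom
tooth plus surrounding alveolar change.

What passing these tests shows — and does not show. The phantoms prove the
geometry is implemented correctly: boundary transfer, projection volumes,
registration, voxel counting and their compositions recover analytic truth
within stated tolerances. They do not emulate scanner texture artifacts,
facial expression or posture change, hair or occlusion holes in the mesh,
CBCT beam hardening or metal artifacts, or operator variability in landmark
placement. Results on real scans inherit those error sources on top of the
geometric ones quantified here.

## Numerical choices

- Closest-point queries use exact point-to-triangle projection over a
  uniform spatial grid (compiled); distances are exact, not vertex-sampled.
- Dijkstra ties are resolved deterministically by igraph's fixed vertex
  ordering; identical inputs give identical patches.
- The point-in-polygon classification is a crossing test; queries exactly on
  a polygon edge are avoided by construction (face centroids never lie on
  the projected loop through mesh vertices).
- `stv` treats |signed distance| ≤ 1e-9 mm as on-plane to keep the
  wrong-side check from tripping on floating fuzz for patches touching the
  plane.
- ICP convergence is declared on RMS improvement < 1e-4 mm; the transform is
  updated by exponential-map composition, so the rotation stays exactly
  orthonormal over iterations.
- Rater tables use `stats::aov` mean squares; the ICC(2,1) interval is the
  Shrout-Fleiss F-based interval (the conventional choice when only a 95%
  CI is reported without a named method).

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) runs, per
package defaults: 20 bump-recovery phantoms at 0.5 mm resolution
(~115 000 triangles each) through the full pipeline; 50 ICP
perturbation-recovery trials (rotations to 10°, translations to 10 mm); a
static noisy phantom for null stability; a 112³ CBCT removal phantom; and
20 replicate 100x2 rater tables. These sizes put Monte-Carlo error well
below the tolerance being checked while keeping a full run in the
low minutes on one CPU.

## Known limitations

- The buccal boundary composition fixes the upper closure as a direct
  al'-ex' path; protocols that run al' to ch' directly can supply a
  different landmark loop but there is no preset for it.
- `boolean_cut` classifies whole faces by centroid; the cut boundary is a
  mesh edge path, not a re-triangulated intersection curve. The resulting
  area error is below 0.1% at scan resolutions and cancels between time
  points, but single-patch areas carry half-triangle jitter at the border.
- STV is not defined (raises an error) for patches genuinely crossing the
  mid-sagittal plane; measuring midline regions (nose, lips) requires a
  different reference plane, which the API accepts but provides no preset
  for.
- The DICOM layer reads only the uncompressed explicit-VR little-endian
  profile it writes; clinical exports in other transfer syntaxes must be
  converted upstream.
- Automatic jaw alignment assumes the initial misalignment is within the
  coarse search range (default ±3 mm after the operator's initialization);
  it is a refinement step, not a global registration.
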