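---
title: "Quantifying mCNV lesions from en-face OCTA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mCNV lesions from en-face OCTA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Myopic choroidal neovascularization (mCNV) is an abnormal growth of new
blood vessels under the retina in pathologic myopia. Optical coherence
tomography angiography (OCTA) images this vasculature non-invasively as a
2D en-face projection: bright, tortuous vessels on a dark background,
typically exported as 1024x1024 8-bit frames at 170 pixels/mm. Clinicians
track lesion activity through a standard panel of nine vascular biomarkers
— lesion area, vessel area, vessel density, total vessel length, junction
count, junction density, mean vessel diameter, box-counting fractal
dimension, and arc-chord tortuosity. `octaquant` computes this panel from
a manually delineated lesion, in batch, with every tunable parameter
exposed.

Delineation stays manual by design: the lesion boundary is a clinical
judgement. The package accepts it either as a pre-cropped image whose
outside-contour pixels are cleared to 0, or as an explicit binary mask
file.

## The two-branch pipeline

After shared preprocessing — 8-bit conversion, clearing outside the region
of interest (ROI), and a percentile contrast stretch — the image is
processed along two branches that consume the same preprocessed input:

* **Branch 1 (area biomarkers).** Gaussian blur (sigma 1 px) denoises the
  frame; a Hessian-based Frangi vesselness filter enhances tubular
  structure; local median thresholding (window radius 8 px) binarizes it.
  Vessel area is the vessel-pixel count over scale²; vessel density is
  vessel area over lesion area.
* **Branch 2 (skeletal biomarkers).** A Mexican-hat (Ricker wavelet)
  filter with neighbourhood radius 13 px band-passes vessel-scale
  structure; the same local median thresholder binarizes the response;
  sub-vessel-scale holes are filled; binary thinning produces a
  1-pixel-wide skeleton; the skeleton is tagged into endpoints, slab runs
  and junction clusters, pruned, and measured. Vessel length, junctions,
  fractal dimension and tortuosity come from this branch; junction density
  (junctions/length) and mean diameter (area/length) combine the two
  branches.

### Filters

The Gaussian kernel is the normalized
$G(x,y)=\tfrac{1}{2\pi\sigma^2}e^{-(x^2+y^2)/2\sigma^2}$, the Ricker
wavelet
$\psi(x,y)=\tfrac{1}{\pi\sigma^4}\bigl(1-\tfrac{x^2+y^2}{2\sigma^2}\bigr)e^{-(x^2+y^2)/2\sigma^2}$
truncated to its $(2r{+}1)^2$ window with $\sigma=r/3$ (so it decays to
~0 at the window edge) and re-centred to exact zero sum. All convolutions
replicate edges; replication avoids the dark halo a zero pad would paint
around the lesion boundary, which would bias vessel area there.

The vesselness filter computes, per scale $\sigma$, the scale-normalized
Hessian eigenvalues $|\lambda_1|\le|\lambda_2|$ and

$$V = \exp\!\Bigl(-\frac{R_B^2}{2\beta^2}\Bigr)\Bigl(1-\exp\!\Bigl(-\frac{S^2}{2c^2}\Bigr)\Bigr),
\qquad R_B=\frac{\lambda_1}{\lambda_2},\; S=\sqrt{\lambda_1^2+\lambda_2^2},$$

zero wherever $\lambda_2>0$ (bright vessels on dark background), maximum
over scales $\{1, 1.5, 2, 2.5, 3\}$ px, $\beta=0.5$, and $c$ set
adaptively to half the maximal Hessian Frobenius norm at each scale.
These are the original vesselness conventions; all are configurable. Two
numerical details matter: the discrete second-derivative kernels are
re-centred to exact zero sum (otherwise truncation residue makes a
constant image respond), and a scale whose maximal $S$ is below $10^{-6}$
(intensity units on the 0–255 scale) is treated as flat, since at that
level the "structure" is FFT round-off.

### Local median thresholding

A pixel is vessel iff its intensity strictly exceeds the median of its
$(2r{+}1)\times(2r{+}1)$ window (clipped at the borders) minus an offset.
Ties go to background, so constant regions produce nothing. Clipped border
windows can contain an even number of pixels; the median is defined as the
$\lceil n/2\rceil$-th smallest value (lower median), which is
deterministic on integers. The implementation is a sliding 256-bin
histogram; the test suite pins it against a brute-force double-loop oracle
on random images.

The *batch pipeline* default offset is −5 (a pixel must beat its local
median by more than 5 of 255 levels), while the bare
`local_median_threshold()` default stays 0. The margin exists because a
pure median rule is scale-free: in any homogeneous noisy region, about
half the pixels exceed the local median whatever the noise amplitude, so
offset 0 turns speckle into a dense false vessel field. Measured on
speckled phantoms, far-background Mexican-hat responses stay within 0–2
quantization levels while vessel responses exceed 130, so any margin of a
few levels separates the two; 5 (~2% of full scale) was fixed on that
analysis, not fitted to a particular test.

### Skeletonization and the skeleton graph

Thinning deletes *simple* border pixels — those whose removal provably
preserves the topology of 8-connected foreground over 4-connected
background (Yokoi characterization) — that are not endpoints, in four
directional sub-passes per iteration until a fixed point. The result is a
1-pixel-wide subset of the input with identical component and hole
counts, and the operation is idempotent. The popular two-subiteration
parallel thinning was rejected because its parallel deletion step can
erase 2x2 components outright, breaking the component-count contract; and
the classic Rutovitz crossing-number simplicity test was rejected because
it misses the mutual diagonal adjacency of edge neighbours and freezes
staircase corner pixels, which fragments curved skeletons into spurious
junctions.

Tagging classifies each skeleton pixel by its 8-neighbour count
(1 endpoint, 2 slab, ≥3 junction pixel); 8-connected clusters of junction
pixels merge into one junction node, since thinning legitimately produces
multi-pixel junction clumps and counting pixels would inflate the
junction biomarker. Slab runs between nodes become branches with an
ordered pixel path; closed loops with no nodes become cycle branches with
zero chord length, excluded from tortuosity.

**Branch length.** The obvious chain-code metric (1 per axial step,
$\sqrt2$ per diagonal step) systematically overestimates digital curve
length: up to 8.2% on oblique straight lines and ~5% averaged over a
circle, which would push a half-circle's arc-chord ratio from
$\pi/2\approx1.571$ to ~1.65. Geodesic length is therefore measured on a
polyline through every 5th path pixel (plus the final pixel). This is
exact on axial and diagonal runs, reduces the half-circle error to under
2%, and keeps the guarantee geodesic ≥ Euclidean. The raw chain metric
remains available (`length_method = "chain"`) for comparison with tools
that use it.

**Pruning.** Disconnected components under 5 pixels are always discarded.
End branches (those terminating in an endpoint) shorter than a threshold
are removed iteratively; the bare default is off, the batch pipeline uses
0.05 mm (~8.5 px at 170 px/mm) because thinning grows 2–4 px spurs where
thick vessels meet, which otherwise double T-junction counts. After each
deletion sweep the mask is re-thinned: removing a spur can leave a
redundant corner pixel that would re-read as a junction. Literally
deleting *every* branch that ends in an endpoint would iterate any tree to
nothing; pruning is therefore artifact removal, never topology surgery on
real branches. Small enclosed holes (<10 px) are filled before thinning
for the same reason seen from the other side: topology-preserving thinning
faithfully keeps a 1-pixel binarization hole as a skeleton loop, i.e. a
fake junction pair.

### The nine biomarkers

| Biomarker | Definition | Units |
|---|---|---|
| mCNV area | ROI pixel count / scale² | mm² |
| Vessel area | vessel pixel count / scale² | mm² |
| Vessel density | vessel area / mCNV area | – |
| Vessel length | Σ branch geodesic lengths | mm |
| Vessel junctions | junction nodes (clustered) | count |
| Junction density | junctions / length | n/mm |
| Vessel diameter | area / length × 1000 | µm |
| Fractal dimension | box-count slope | – |
| Tortuosity | mean branch geodesic/Euclidean | – |

Mean diameter as area over centerline length is the standard mean-caliber
estimator. Tortuosity is the unweighted mean of per-branch arc-chord
ratios (a length-weighted variant is available); straight vessels give
exactly 1. The box-counting dimension covers the skeleton with an
$s\times s$ grid anchored at the image origin and fits
$\log N(s)$ against $\log(1/s)$ by least squares over sizes
$\{2,3,4,6,8,12,16,32,64\}$ clipped to half the shorter image side; the
slope is taken against $\log(1/s)$ so that the dimension is positive.
One bias is worth knowing: box sizes that do not divide the image side
inflate $N(s)$ through the grid ceiling, which can push the slope of a
*completely filled* plane to ~2.0007; the record-level sanity bound
therefore allows 2 + 0.01, and exact checks of the filled-plane limit use
divisor sizes.

## The phantom generator

Because the clinical dataset behind the reference study is private, the
package ships a synthetic phantom generator whose ground truth is known
*analytically* — lengths, widths, junction and endpoint counts, and
arc-chord ratios are computed from the continuous primitives (segments,
arcs, bifurcating trees, discs) before rasterization, so recovery
tolerances honestly absorb discretization error rather than being compared
against the rasterization itself. Phantoms emulate delineated OCTA frames:
bright vessels (intensity 200) on a dark lesion background (20), zero
outside the ROI, 8-bit, 1024x1024 at 170 px/mm by default, with
multiplicative speckle `v·(1 + s·U(−1,1))` as the noise model — chosen
because speckle-like multiplicative noise is the dominant artifact
character of single OCTA frames. Geometry never depends on the seed; only
noise realizations do.

What the phantoms do *not* emulate: flow-dependent decorrelation noise,
projection artifacts from superficial vasculature, motion stripes, vessel
caliber variation along a branch, and the dense, space-filling texture of
real mCNV lesion cores. Passing the battery therefore demonstrates that
the measurement chain is correct and noise-robust on controlled geometry;
it does not certify segmentation accuracy on clinical images, whose
validation needs expert-delineated data.

Default battery: straight line, half-circle arc, "+" cross, "H", a
2-level bifurcating tree (3 internal branch points), and a filled disc,
each noiseless and with speckle 0.2. The disc has no centerline, so its
skeletal truths are missing by construction; it exercises the area and
fractal layers.

## Verification strategy and problem sizes

The test suite pins each computational primitive to an independent oracle:
the windowed-median thresholder against a brute-force double loop on 100
random 32x32 images, box counts against an explicit grid scan on random
64x64 masks, pixel classification against a neighbour-count loop, plus
property tests (thinning idempotence and component preservation, pixel
conservation across the graph decomposition, geodesic ≥ Euclidean, scale
equivariance, rotation symmetry of the Ricker response). End-to-end
recovery runs the full pipeline on the battery at 512x512 (about 2.5 s an
image; the study-size 1024x1024 takes ~20 s and is exercised once in the
timing contract and throughout `scripts/acceptance.R`): junction counts
are exact on all vascular items with and without speckle 0.2, vessel
length recovers within 5% (typically <1.5%), the half-circle tortuosity
lands within 0.05 of π/2, and width recovery from true masks is within
20% (typically 2%) for widths 3–9 px.

Two caveats the tests make explicit rather than hide. First, the
full-pipeline diameter on thin synthetic vessels runs ~35–40% above the
true width because the multi-scale vesselness response widens the apparent
vessel; width-recovery checks therefore run at the biomarker layer on the
true mask, and pipeline diameters should be compared across images
processed with identical settings, not read as absolute calibers. Second,
skeleton branch length excludes junction-cluster pixels (the convention of
standard skeleton analyzers), which shifts junction density ~1% above its
continuum value on an ideal cross.

## Known limitations

* Binarization quality on real OCTA depends on the contrast and threshold
  settings; the defaults reproduce sensible behaviour on phantoms and
  should be reviewed on each clinical dataset.
* The fractal dimension uses a single origin-anchored grid (no grid-offset
  averaging), matching common plugin behaviour; offset averaging would
  reduce variance on small lesions.
* Only 2D en-face analysis is supported — no 3D skeletons, no DICOM or
  vendor OCT formats, and no automatic lesion delineation.
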