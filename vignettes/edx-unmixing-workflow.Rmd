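---
title: "Unsupervised spectral mixture analysis of hyperspectral EDX images"
author: "EDXUnmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised spectral mixture analysis of hyperspectral EDX images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EDXUnmix)
```

# The problem

Energy-dispersive X-ray (EDX) spectrum imaging attaches a per-pixel
X-ray energy histogram to scanning transmission electron micrographs:
a hyperspectral cube of `rows x cols` pixels by a few thousand energy
channels. In biological tissue the signal is dominated by carbon and a
handful of weakly discriminative light elements, counts per channel are
low, and grayscale electron contrast alone cannot tell a secretory
granule from a lysosome. The linear mixing assumption — each pixel
spectrum is a nonnegative combination of a small number of
characteristic spectra ("endmembers"), one per biostructure class —
turns this into a spectral mixture analysis problem: find the
endmembers, estimate per-pixel abundances, and use the abundance maps
to drive detection and segmentation.

`EDXUnmix` implements that workflow end to end:

1. **Preprocessing** — trim calibration channels, bin spatially and
   spectrally, denoise each band with a small mean kernel.
2. **Endmember extraction** — embed (a subsample of) pixel spectra in
   2-D with a manifold method, histogram the embedding, take local
   maxima away from the central bulk, and average the raw spectra of
   the pixels under each maximum.
3. **Unmixing** — per-pixel non-negative least squares (NNLS) against
   the endmember matrix, with one global scale across all tiles for
   comparable colour display.
4. **Frame-accumulation analysis** — intra-class relative spectral
   distance and intra/inter ratio as a function of accumulated frames,
   to decide how many frames an acquisition needs.
5. **Prompt generation and segmentation** — blur and threshold each
   abundance map, take local maxima as point prompts, feed them to a
   pluggable promptable segmenter, aggregate per-structure masks, and
   score IoU.

Because raw acquisitions are large and proprietary, the package ships a
first-class synthetic-phantom generator that reproduces the statistical
structure the workflow assumes; every stage is validated against the
generator's ground truth.

# The phantom generator

`phantomSpec()` describes a scene of geometric structures (disks,
ellipses, annuli, bands, plus a diffuse background absorbing the
abundance remainder), each with its own generative spectral model:
characteristic lines as Gaussians on the energy axis (integrated
channel-wise) over an exponentially decaying Bremsstrahlung-like
continuum. Expected counts follow the linear mixing model

$$\lambda(p, c) \;=\; n_{\text{frames}} \cdot \kappa \sum_k a_k(p)\,
\hat e_k(c),$$

where $\hat e_k$ is the class spectrum normalised to unit sum,
$a_k(p)$ the ground-truth abundance, and $\kappa$ the expected counts
per pure pixel per frame. Observed counts are independent Poisson draws
per frame, summed; frame $j$ is reproducible from `(seed, j)`, so a
cube rendered with $K$ frames equals the sum of its first $K$ frames
exactly.

Defaults and what they emulate:

* `defaultPhantom()` — 128 x 128 px, 250 channels of 80 eV (the
  post-binning spectral grid of a 0-20 keV acquisition), 20 frames at
  250 expected counts per pixel per frame (5000 per pixel total —
  the regime of a frame-accumulated, spatially binned tissue tile).
  Five structures over a carbon-rich background: three endocrine
  granule populations, exocrine granules, and a nucleus standing in
  for nucleic acids. Pixels inside structures are pure, so class masks
  and endmember spectra are exact.
* `cannedSpectralModels()` — line energies at the elements'
  characteristic positions (C, N, O, P, S K$\alpha$; Os M/L; Fe K/L;
  Cu K) with 60 eV Gaussian width for detector resolution. Relative
  amplitudes follow the expected biochemistry: granules high in N and
  S, nucleic acids high in P and N, membranes dominated by Os and Fe,
  background carbon-rich.

What the phantom does **not** model: ionisation cross-sections and
detector response, absorption, pile-up, beam damage, drift, mixed
border pixels beyond geometric overlap, and spatial texture within a
structure. Passing tests therefore demonstrate correctness of the
algorithms under the linear-mixture + Poisson assumptions, not
instrument-level fidelity on real tissue.

# Preprocessing

`preprocessConfig()` defaults mirror the acquisition geometry the
workflow targets: 2048 x 2048 px with 4096 channels of 5 eV reduces to
1024 x 1024 x 250 by dropping the first 96 calibration-artefact
channels and binning 2 x 2 spatially and 16-fold spectrally
(`preprocessedDim()` exposes the shape logic without materialising
acquisition-scale arrays). Choices worth knowing:

* **Binning reducer is `sum`** so total counts are conserved exactly
  after trimming — Poisson statistics remain Poisson.
* **The mean kernel is 3 x 3** — the smallest nontrivial denoiser; the
  kernel size is open in the underlying method description and
  configurable here.
* **All spatial filters mirror at borders** (symmetric reflection,
  edge included), hand-rolled so the border convention is identical
  everywhere and bit-stable.
* **Energy axis bookkeeping**: after binning, a channel center is the
  mean energy of its merged group; the bin width multiplies.
* **Display normalisation** uses linear-interpolation quantiles:
  the `saturate_frac` quantile maps to 0, its complement to 1, tails
  clip (1% default, 0.5% for low-noise displays); constant images map
  to 0.5 by convention. HAADF tiles are equalised by shifting each
  tile down to the minimum median across tiles.
* **Stitching** is metadata-driven grid placement (step
  `tile_px - overlap_px`), first-written tile wins in overlaps by
  default; `overlapMask()` marks multiply-exposed pixels so they can
  be excluded from embedding subsamples.

# Endmember extraction

The feature space concatenates the base spectra with Gaussian-blurred
copies at radii 1, 3 and 5 (sigma 2 px): 250 channels become 1000
features, injecting local spatial correlation into the embedding. The
phrase "radii 1, 3, 5 with sigma = 2" is ambiguous between truncation
radii at fixed sigma and per-copy sigmas; the package defaults to the
former and offers `sigma_per_radius = TRUE` for the latter.

A 20% uniform subsample (overlap pixels excluded, seed recorded) is
embedded in 2-D. The backend is a pluggable contract (`N x F -> N x 2`,
deterministic given a seed):

* `"umap"` (default) — UMAP via the Python `umap-learn` package
  through a subprocess bridge, after PCA pre-reduction to 50
  dimensions. A neighbour-graph method is load-bearing here: on the
  default phantom the six spectral classes are well separated in
  feature space (mean silhouette 0.83 in PCA-50 space) yet purely
  distance-preserving 2-D projections crowd them into overlapping
  arms; a neighbour-graph layout keeps them as distinct density modes.
* `"sammon"` — Sammon's nonlinear mapping (pure R, `MASS`), useful
  where no Python runtime is available; exact duplicate rows are
  collapsed and re-expanded, which both satisfies the
  duplicate-consistency contract and avoids zero dissimilarities.
* `"pca"` — first two principal components; the cheap deterministic
  baseline.

The embedding is histogrammed (`ceiling(sqrt(N))` bins per axis by
default, at least 16, so occupancy scales sensibly from desk scale to
full mosaics), lightly smoothed (sigma 1 bin), and local maxima are
selected with a plateau-aware detector (Chebyshev window, greedy
suppression, documented tie-breaks). Two selection modes reproduce the
interactive step:

* an automated mode with `exclude_central_bulk = TRUE`, which
  suppresses maxima inside the connected plateau (at half the peak
  density) around the global mode — the "primary cluster" — keeping
  maxima at protrusion extremities;
* a points-file mode: any caller-supplied boxes produce the same
  downstream types.

The minimum smoothed count defaults to `0.001 N` — deliberately
inclusive, as the interactive step errs toward inclusivity — and
near-duplicate endmembers (cosine similarity above 0.999) are merged,
keeping the one under the denser maximum. On phantoms, genuinely
distinct classes top out near cosine 0.987 while same-cluster shoulder
duplicates exceed 0.999, so the two populations are cleanly separable;
both knobs are configurable.

Endmember spectra are averaged from the **raw preprocessed spectra**
(not the augmented features) of the pixels inside a +-2-bin box around
each maximum; augmentation exists only to stabilise the embedding.
Annotation-derived endmembers (`endmembersFromAnnotations()`) are the
per-class mean spectra and produce the same `EndmemberSet` type.

# Unmixing and visualisation

Per pixel, NNLS solves $\min_a \lVert E a - s\rVert_2,\ a \ge 0$
(Lawson–Hanson via `pracma::lsqnonneg`). There is no sum-to-one
constraint; display scaling handles intensity. All coefficients across
a mosaic share one global scale — the maximum coefficient anywhere —
so scaled abundances lie in [0, 1] and tiles are comparable.
`dominantMap()` takes the per-pixel argmax with ties broken to the
lowest endmember index and a reserved background label (0) for
all-zero pixels. `endmemberZscores()` standardises each channel across
the K endmembers with the population standard deviation (zero-spread
channels map to 0), giving the fingerprint heatmap that links
endmembers to elements.

# Frame-accumulation analysis

"Relative Euclidean distance" is implemented as two tagged
conventions (recorded in `DistanceCurves@normalization`): the
intra-class statistic is the mean distance of member spectra to the
class mean divided by the norm of that mean; the inter-class statistic
is the distance between two class means divided by the norm of their
midpoint. Spectra are divided by the frame count first, and both
statistics are invariant to global rescaling. Under pure Poisson noise
the intra-class curve decays as $1/\sqrt{k}$ — the package's phantom
tests check the log-log slope lies in [-0.6, -0.4] — and the plateau
detector (`plateauFrames()`, change per doubling below 5% of the
initial value) is a repo convention for reading off the minimum frame
count.

# Prompts and segmentation

Each scaled abundance map is Gaussian-blurred (sigma 4), thresholded
(0.5 for nucleic acids, 0.4 otherwise — thresholds apply on the
globally scaled [0, 1] abundance scale), and its plateau-aware local
maxima (minimum separation 10 px by default) become structure-labelled
point prompts. The blur/threshold order is configurable
(`blur_first`); blur-then-threshold is the default. Nucleic-acid masks
are closed (dilate then erode) with a disk element — 70 px at
full 1024-px tile scale; desk-scale phantom runs scale the radius with
the geometry (9 px at 128 px). Closing merges heterochromatin
fragments so nuclei emerge from heterochromatin prompts.

The segmenter itself is an adapter: any
`function(image, points) -> list(masks, scores)` can be plugged in
(e.g. a promptable foundation model on the HAADF image; no model
weights ship with the package). The bundled `fallbackSegmenter()` is a
deterministic classical stand-in: it thresholds at half the
(median-stabilised) prompt intensity and takes the connected component
containing the prompt. Per structure, masks are unions over that
structure's prompts; `compositeMasks()` assigns each pixel the first
covering structure in precedence order; `iou()` scores masks with the
both-empty-equals-1 convention.

# Worked example

```{r example, eval = FALSE}
spec <- defaultPhantom(seed = 1)          # 128 x 128 x 250, 20 frames
r <- renderPhantom(spec)
cube <- preprocessCube(r$cube, preprocessConfig(0, 1, 1, 3))

disc <- discoverEndmembers(cube, fraction = 0.2, seed = 1)
stack <- finalizeScale(nnlsUnmix(cube, disc$endmembers))

mt <- matchEndmembers(disc$endmembers, r$truth@endmembers)
min(mt$cosine)      # ~0.999 on the default phantom

sc <- scaledAbundances(stack)
pr <- promptsFromAbundance(sc[, , mt$endmember[1]],
                           promptConfig(blur_sigma_px = 4,
                                        threshold = 0.4))
seg <- segmentWithPrompts(sc[, , mt$endmember[1]], pr)
```

Or the whole thing in one call, with artifacts and a reproducibility
manifest under a run directory:

```{r pipeline, eval = FALSE}
res <- runPipeline(defaultPipelineConfig(seed = 1), "run1")
```

# Numerical conventions and degenerate inputs

* Quantiles: linear interpolation (R type 7), documented so
  normalisation is bit-stable.
* Local maxima: a cell must equal the maximum of its Chebyshev window;
  plateaus collapse to rounded centroids; suppression is greedy by
  decreasing value with row-then-column tie-breaks.
* Constant images normalise to 0.5; empty prompt sets and all-zero
  abundance maps are legal and propagate to empty masks; two empty
  masks have IoU 1.
* NNLS warns on rank-deficient endmember matrices instead of failing.
* All stochastic steps take explicit seeds and restore the caller's
  RNG state.

# Problem sizes used in the test-suite and acceptance runs

Phantom studies run at 128 x 128 px x 250 channels (end-to-end
segmentation, feature-width checks), 96 x 96 x 250 (four-class
recovery), and 48 x 48 x 32 (frame-accumulation curves, up to 64-128
frames); embeddings operate on 20% subsamples (about 800-3300 pixels).
These sizes were chosen so each study carries enough counts and pixels
for its statistical bar while a full run stays interactive on a single
CPU; acquisition-scale shapes (2048 x 2048 x 4096) are exercised
through the lazy shape logic.

# Known limitations

* The embedding default requires a Python runtime with `umap-learn`;
  the pure-R `sammon` backend resolves fewer overlapping classes on
  crowded scenes.
* Automated maxima selection is a stand-in for interactive protrusion
  picking; on real mosaics with strong mixing continua the interactive
  (points-file) route may still be preferable.
* Per-pixel NNLS is exact but loop-based; at full mosaic scale it
  parallelises trivially over tiles, which the package leaves to the
  caller.
* The fallback segmenter assumes structures are brighter than their
  surroundings in the prompt image; it is a CI-friendly stand-in, not
  a replacement for a learned promptable segmenter on HAADF contrast.
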