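---
title: "Quantifying osteoclast motility and acidification from intravital time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying osteoclast motility and acidification from intravital time-lapse imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteodyn)
```

## The biological measurements

Mature osteoclasts (mOCs) resorb bone by attaching tightly to the bone
surface and secreting protons through V-ATPase proton pumps concentrated
along the ruffled border. Intravital two-photon microscopy can watch this in
live bone: a red reporter (TRAP-tdTomato) labels the osteoclasts, a
pH-sensing chemical probe fluoresces green where the local microenvironment
is acidic, and second-harmonic generation shows the bone matrix.
Bisphosphonates — risedronate, alendronate, minodronate — suppress
resorption, and the interesting short-term questions are *how fast*
acidification stops after a single dose and *what happens to cell motility*
while it does. Two scalar readouts carry that analysis, and this package
implements both plus everything needed to compute them from a raw stack.

### Cell deformation index

For one tracked cell, compare its segmented mask at a start frame $t$ and at
$t + 5\ \mathrm{min}$. Three areas partition the union of the two masks:

* $A$ — pixels only in the initial mask,
* $B$ — pixels in both (the overlap),
* $C$ — pixels only in the final mask.

The deformation index is

$$ D = \frac{A + C}{A + B}, $$

the area changed over the window divided by the initial area. A perfectly
static cell has $A = C = 0$, so $D = 0$; a cell that relocates completely
while keeping its size has $B = 0$ and $D = 2$. The index is dimensionless,
so it is computed on pixel counts; conversion to µm² would cancel.

Design choices the definition itself leaves open:

* **Window placement.** Windows slide by one frame, so a track of length
  $n$ in an $n$-frame movie yields $n - w$ overlapping records at window
  $w$. The per-cell summary is the mean of a track's records. (Whether the
  original analysis used one window per cell or several is not stated
  anywhere we could follow; the aggregation is therefore a named, documented
  rule, not an assumption hidden in code.)
* **Vanished cells.** If a track has ended before $t + w$ (the cell
  disappeared or tracking lost it), the final mask is empty: $A$ = initial
  area, $B = C = 0$, and $D = 1$ by the formula. Such records are emitted
  with a `disappeared` flag rather than dropped, since the formula remains
  defined and silently dropping them would bias group means downward.

### Bone-resorbing index

Osteoclast areas are binarized from the reporter channel; the index is the
ratio of mean pH-probe intensity inside those areas (probe *signal*) to the
mean outside (probe *noise*):

$$ R = \frac{\overline{I_{\mathrm{probe}}}\,[\text{inside masks}]}
            {\overline{I_{\mathrm{probe}}}\,[\text{outside masks}]} . $$

$R \approx 1$ means no detectable acidification. "Outside" is ambiguous
within a pixel or two of a cell edge, where probe signal bleeds across the
boundary; by default the noise region excludes a 2-px dilation ring around
the masks (`exclusion_ring = 2`), and `exclusion_ring = 0` restores the
literal definition. The index is computed per frame on the union of all
segmented cells and averaged over frames for the movie-level value; the
movie (one imaging session, one animal) is the sampling unit for group
comparisons, matching a design of three independent experiments per group.
The index is invariant to global intensity scaling, which is why it is
robust to detector gain.

## Segmentation and tracking

The binarize-and-extract step is deliberately the plainest automatic
pipeline that does the job, since the readouts — not the segmentation — are
the scientific content:

1. Otsu threshold (or a fixed threshold for reproducibility studies),
2. morphological opening with a disc of radius 1 px,
3. 8-connected component labeling,
4. drop components below `min_area` (default 50 px),
5. drop border-touching components (their $A$, $B$, $C$ would be censored),
6. relabel contiguously.

Touching or fused osteoclasts are treated as one region — no watershed
splitting — because the overlap indices are well defined either way and
splitting heuristics add fragility.

Tracking is greedy frame-to-frame matching on pixel overlap: candidate
(previous, current) label pairs are accepted in decreasing IoU order, ties
broken by larger intersection then smaller label id (fully deterministic),
and a link requires IoU ≥ `min_iou` (default 0.3). Osteoclasts are large,
sparse and slow relative to a 1-min frame interval, so greedy matching is
adequate and a global assignment solver would change nothing but the
runtime. There is no gap closing: a cell lost for one frame starts a new
track, which is the conservative choice for a deformation metric that needs
an unbroken identity.

## The synthetic-data generator

No public imaging data accompanies the measurements this package
implements, so the generator is a first-class module: it produces stacks
with known ground truth that reproduce the *statistical structure* of the
experiment, which is what lets every downstream stage be tested.

Each cell is a star-convex blob: its boundary is a radius function over
angle, $r(\theta) = r_0\,\max(0.25,\, 1 + \sum_{k=2}^{4} a_k \cos k\theta +
b_k \sin k\theta)$. Low-order Fourier boundaries guarantee simply-connected
masks, rasterize exactly, and make the zero-motility case exact: motility is
implemented as per-frame Gaussian increments to the coefficients (sd
$0.3\,m$) and the centroid (sd $0.3\,m\,r_0$), both proportional to the
motility parameter $m$, so $m = 0$ reproduces bit-identical masks in every
frame. The centroid step is weighted below the boundary step because
osteoclasts are adherent — shape change dominates translocation — and
because a generator whose cells teleport past the tracking association
radius would be simulating a different experiment.

Channels: the reporter renders every cell at a constant amplitude
(default 100 a.u.) over a low background (10 a.u.); resorbing cells (a
configurable fraction, default 0.8) deposit probe intensity with amplitude
`secretion × cell_intensity` inside their footprint eroded by 1 px, since
the probe signal sits beneath the cell; the bone channel is a static smooth
random field. All channels receive additive Gaussian noise (sd 5 a.u. by
default) clipped at zero — the simplest noise model that exercises
thresholding, chosen deliberately. The generator does **not** model
two-photon optics: no PSF, scattering, depth attenuation, photobleaching, or
punctate probe substructure. Passing tests therefore demonstrate
correctness of the *computations*, and robustness to additive noise; they do
not demonstrate robustness to blur or to touching cells, which real data
would add.

Defaults are 512 × 512 px at 1 µm/px and 1 min/frame (so the 5-min window
is 5 frames), 10 cells of radius 15 ± 2 px. The tests and the acceptance
script run smaller fields (64–320 px, 2–10 cells, 7 frames) chosen as the
smallest sizes at which group contrasts are meaningful; those sizes are
the package's declared test conditions.

### The condition table

The seven named scenarios encode the qualitative experimental findings as
orderings of two parameters:

```{r}
condition_table()
```

Every drug condition has secretion far below untreated at both 12 h and
24 h (acidification is shut down within 12 h and stays down); risedronate
has the highest motility at 12 h, alendronate a weaker effect, and
minodronate's motility peaks at 24 h instead. The absolute numbers are free
choices constrained only by those orderings; they live in this one table so
changing a scenario never touches logic.

## Spectral unmixing

Raw multi-detector spectral stacks are unmixed per pixel by nonnegative
least squares against supplied endmember spectra — the standard reference
method where the commercial implementation is a black box. Blind (NMF-style)
decomposition is out of scope; reference spectra must be supplied, which is
how commercial unmixing is configured in practice. Implementation detail:
the unconstrained least-squares solution is computed for all pixels in one
matrix solve, and only pixels where it violates nonnegativity (rare away
from the zero boundary) are re-solved with active-set NNLS; residual
negatives below 10⁻⁹ are clamped. Rank-deficient endmember matrices are
rejected with the condition number in the message.

The default simulated instrument has six detector bands for four
endmembers. The overdetermined design keeps every fluorophore channel's
noise gain (the corresponding row norm of the pseudoinverse) below 1.3, so
unmixed channels are about as noisy as the raw ones; a square mixing matrix
would amplify detector noise several-fold and is an instrument-design
mistake the package avoids by default.

## Statistics

Group values are reported as mean ± SD (sample SD, $n - 1$; flagged
undefined for $n = 1$). Comparisons are two-tailed two-sample t tests with
significance at $\alpha = 0.05$; Welch's test is the default (robust to
unequal variances), the pooled-variance variant is available by flag since
the original reporting does not say which was used. No multiple-testing
correction is applied, matching per-comparison reporting. Deformation is
compared at the cell level and resorption at the movie level, and
`run_experiment()` reports both.

## Numerical choices and degenerate inputs

* A constant image under Otsu returns an empty label map, not an error.
* `deformation_index()` rejects $A + B = 0$ (empty initial mask) — the
  index is undefined, and a pipeline should never produce that record.
* `bone_resorbing_index()` rejects empty masks, all-foreground masks (no
  noise region) and a zero noise mean.
* Tracking ties are broken deterministically (IoU, then intersection, then
  label id), and the whole pipeline is bit-reproducible for a fixed config
  and seed; movie seeds in `run_experiment()` derive arithmetically from
  the base seed.
* Stacks round-trip through 16-bit TIFF with a JSON sidecar; quantization
  error is bounded by `max(intensity) / 65535`.

## Worked example

```{r example, eval = FALSE}
ex <- run_experiment(
  c("untreated", "ris_12h", "aln_12h", "mino_12h"),
  seed = 1, n_movies = 3,
  field_size = c(192, 192), n_cells = 8, n_frames = 7,
  cell_radius_mean = 9
)
ex$resorption_summary
ex$deformation_tests
plot_resorption(ex)
```

On this scaled-down battery the untreated movies give a bone-resorbing
index several-fold above every 12-h drug condition, all drug-vs-untreated
resorption tests are significant, and risedronate shows the largest (and
significant) increase in deformation index — the direction structure of the
experiment the scenarios encode. The exact numbers for any seed are
computed by `scripts/acceptance.R`.

## Known limitations

* Ground-truth cells never touch; segmentation recall measured on the
  simulator does not certify behaviour on fused osteoclasts.
* The probe model is diffuse within the footprint, not punctate; resorption
  indices on real data will be noisier at equal secretion.
* Per-cell resorption attribution is out of scope — the index is
  field-level, as defined.
* No absolute pH calibration: the index is a ratio, not a pH.
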