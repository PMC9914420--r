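---
title: "Methods: texture-based cervigram classification and segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based cervigram classification and segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervitex)
```

cervitex implements a screening-oriented pipeline for cervigrams:
enhancement, multi-resolution transform, texture features, neural-network
classification under cross-validation, and morphological segmentation of
the images called abnormal. This vignette explains the model behind each
stage, the parameters that matter, the numerical conventions, and what the
synthetic test bed does and does not establish.

## Directional windowed equalization

Local (windowed) histogram equalization re-values a pixel from the
cumulative histogram of an $n \times n$ window: with $a$ the pixel
intensity, $\mathrm{cdf}(a)$ the count of window pixels $\le a$ and
$\mathrm{cdf}_{\min}$ the smallest nonzero cumulative count,

$$ s(a) = \operatorname{round}\!\left(
   \frac{\mathrm{cdf}(a) - \mathrm{cdf}_{\min}}
        {n^2 - \mathrm{cdf}_{\min}}\,(L - 1)\right). $$

The directional variant evaluates this once per *anchor position*: the
processed pixel is placed at each of the eight off-centre positions of the
geometric 8-neighbourhood of the window centre (offsets $\pm m$,
$m = (n-1)/2$), yielding eight directionally enhanced images that are fused
per pixel. Conventions, all chosen here because the operator itself does
not force them:

* **Fusion** is the per-pixel maximum (`"mean"` is available). The maximum
  is the minimal reading of "keep the higher-intensity response" and
  preserves the strongest directional edge response.
* **Borders** use edge-replication padding, which avoids synthesising dark
  rims that a zero pad would create.
* **Constant windows** make the expression degenerate ($0/0$); the anchor
  value passes through unchanged, so flat regions are fixed points and the
  operator only strengthens edges.
* **Rounding** is half-away-from-zero throughout the package, so results do
  not depend on round-half-to-even parity.
* **Window size** defaults to $n = 3$; any odd $n$ is accepted.

Note that the fused output is a local-rank code: it discards the *global*
intensity scale. This matters for segmentation (below).

## Finite ridgelet transform

Ridgelets represent line singularities sparsely; the discrete construction
used here composes two exactly invertible stages, so nothing is lost or
duplicated in the transform domain:

1. **Finite Radon transform** over $\mathbb{Z}_p \times \mathbb{Z}_p$ with
   $p$ prime: for each slope $k$ the pencil of lines
   $\{(i, (ki + t) \bmod p)\}$ plus the pencil of rows — $p + 1$ directions,
   every pixel on exactly one line per direction. Two points determine one
   line, so the back-projection sum through a pixel counts that pixel
   $p + 1$ times and every other pixel once, giving the exact inverse
   $x_{ij} = (\sum_d \mathrm{proj}_d(i,j) - \text{mass})/p$.
2. **Periodized orthogonal Daubechies DWT** (haar/db1, db2, db4; db4 and
   two levels by default) applied independently along each projection. The
   analysis is the correlation form
   $a_k = \sum_n h_n\, x_{(2k+n) \bmod m}$ with the quadrature-mirror
   highpass $g_n = (-1)^n h_{L-1-n}$; synthesis is its transpose, so the
   transform is orthonormal (energy-preserving) and reconstructs exactly.
   Projections have odd length $p$ and are zero-padded to the next multiple
   of $2^{\text{levels}}$; the padded length is kept so inversion is exact.

Because no installed R package provides a 1-D DWT, the periodized filter
bank is implemented in the package and pinned by frozen coefficient values
computed independently from the published db2/db4 filter banks, alongside
round-trip, energy-conservation and constant-annihilation tests.

The feature stage summarises each sub-band by energy, mean absolute
coefficient and population standard deviation —
$(p+1)(\text{levels}+1) \cdot 3$ values. The enhanced image is resampled
(bilinear) to a $17 \times 17$ grid before the transform: the ridgelet block
then contributes 162 values, commensurate with the other blocks, and
captures coarse directional structure rather than pixel noise. Both the
prime and the wavelet are configurable.

## Texture features

**Run-length matrices.** After uniform re-quantization to $G = 16$ gray
bins, $M(a, b)$ counts maximal runs of $b$ collinear pixels at bin $a$
along 0°, 45°, 90°, 135°. Every pixel belongs to exactly one maximal run
per orientation, giving the conservation identity
$\sum_{a,b} b\,M(a,b) = N_{\text{pixels}}$ that the tests enforce
exhaustively. The seven statistics use the standard definitions (short/low
emphasis divides by the squared index, long/high multiplies;
$\mathrm{RP} = \text{runs}/N_{\text{pixels}}$).

**Enhanced local ternary patterns.** Each interior pixel's eight neighbours
are coded $+1/0/-1$ against the local patch mean (`ace`) with tolerance
equal to the patch mean absolute deviation (`we`, floored at $10^{-6}$), so
the dead zone adapts to local contrast. The $+$ and $-$ halves form two
8-bit patterns histogrammed over the image; with the rotation-invariant
uniform mapping (popcount bins for patterns with $\le 2$ circular
transitions, one non-uniform bin) the histograms are invariant under image
rotation by multiples of 90°. Comparisons are computed in integer
arithmetic (both sides scaled by 81), which makes the inclusive boundary
and the exact upper/lower swap under intensity inversion
($v \mapsto L-1-v$) hold bit-for-bit on integer images.

**Moment invariants.** Geometric central moments to order 3 about the
intensity centroid, scale-normalized, combined into the seven classical
rotation invariants. Central moments are exactly translation invariant;
90°-rotation stability is verified to $10^{-6}$.

The assembled vector concatenates, in fixed order, GLRLM (28), ELTP
(10 + 10), moment invariants (7) and ridgelet statistics (162) — 217 values
— and supports the incremental subsets (run-length only, + ridgelet,
+ moments, + ternary patterns). All blocks are extracted from the enhanced
image; a configuration hash is stamped on every vector so mixed-provenance
feature tables are detectable.

## Classification and validation

A single-hidden-layer feed-forward network with a logistic output is
trained on standardized features by back-propagated gradients under a
quasi-Newton (BFGS) optimizer, via `nnet`. Defaults: 8 hidden units, 500
iterations, weight decay $10^{-2}$, fixed seed. Two of these deserve
comment:

* *Hidden size.* BFGS maintains a dense approximation of the inverse
  Hessian, so memory and per-iteration cost grow with the square of the
  weight count; 8 hidden units (≈ 1.8k weights at 217 inputs) train in
  seconds and already reach training accuracy 1.0 on the synthetic
  conditions, whereas width proportional to the input dimension would be
  intractable under this optimizer for no measurable gain.
* *Decay.* $10^{-2}$ was selected on generated data distinct from the
  conditions used by the acceptance checks; the CV error is flat across
  $10^{-2}$–$3 \cdot 10^{-1}$.

Evaluation uses stratified $k$-fold cross-validation ($k = 2$ by default,
matching the protocol the pipeline is meant to reproduce): per-fold
held-out error $C(k)$, cross-validation error $\mu = \frac1k \sum C(k) \in
[0, 1]$, and confusion counts pooled over all held-out predictions with the
full metric suite. Degenerate ratios (zero denominators) are reported as
`NA`, never raised as errors. Score ties at 0.5 are called abnormal —
in a screening context the tie should favour sensitivity.

## Segmentation

Images called abnormal are binarized (Otsu's threshold by default — no
fixed threshold generalises across illumination), cleaned by binary
morphology, and reduced to 8-connected components above 25 px. Conventions:

* **Zero padding**: outside the image counts as background, so erosion
  shrinks foreground touching the border ("fit inside"). With this
  convention the complement duality
  $\delta(m) = \neg\,\varepsilon(\neg m)$ cannot hold on border pixels (the
  complement's foreground always touches the border); it holds exactly on
  the interior at structuring-element depth, which is what the tests
  assert.
* **Cleanup order is closing then opening.** Thresholded speckled lesions
  carry interior holes; opening first lets the erosion tunnel through the
  lesion before closing can repair it (observed as occasional total
  segmentation failures), while closing first restores a solid region that
  opening then de-specks. Both orders are available (`op =`).
* **Segmentation input is the un-enhanced grayscale image.** The fused
  directional equalization is a local-rank code that deliberately discards
  the global intensity separation between lesion and background, so a
  global threshold on it does not recover the lesion; the raw luminance
  retains that separation. A configuration switch (`segment_source`)
  restores the enhanced-image route for data where local contrast, not
  global offset, delimits the lesion.
* Default structuring element: disk of radius 3 (larger than the noise
  grain, smaller than any clinically relevant region at the 64 px scale).

## Synthetic test bed

`generate_cervigrams()` emulates the regime of a screening image bank at
fixture scale: 64 × 64 RGB images with a dominant red cast, a smooth radial
vignette (amplitude 25 around base luminance 110) with a jittered optical
centre, and Gaussian sensor noise (sd 8). Abnormal images (probability 0.5)
contain an ellipse brightened by 55 luminance units and overlaid with
horizontally smoothed speckle (sd 25, 5-pixel moving average), so lesion
texture differs from background in local contrast (ELTP), run-length
structure (GLRLM, elongated horizontal runs) and directional energy
(ridgelet). The mask delimits the ellipse exactly and generation is fully
determined by the seed.

Lesion semi-axes are drawn from 14–22 px (major) and 10–16 px (minor) —
the lesion occupies roughly a quarter of the frame. This size was chosen
deliberately: the feature vector is computed over the whole image, so a
lesion occupying a few percent of the pixels shifts image-level texture
statistics by less than their sampling spread, and classes cease to be
separable by construction. The generator's contract is that the configured
texture offsets *are* discriminative for the implemented feature families;
at these defaults 2-fold CV accuracy is 96–98 % across seeds and mean
segmentation Dice ≈ 0.99.

What passing these tests shows: the operators are implemented correctly
(exact inversion, exhaustive oracle agreement, invariances), the pipeline
is deterministic, and it recovers class structure and lesion geometry that
are present in the features by construction. What it does not show:
performance on real colposcopy imagery — real lesions are not elliptical,
acetowhite response and specular glare are not modelled, illumination is
not a smooth vignette, and class boundaries are not guaranteed separable.
Numbers obtained on the synthetic bed characterise the software, not
clinical accuracy.

## Problem sizes and numerical choices

The reference experiment is n = 200 images with 2-fold stratified CV —
large enough for stable pooled metrics, small enough that the whole suite
(generation, extraction, two network fits, ~100 segmentations) completes in
about a minute on one CPU. Radon/ridgelet checks use p = 17 and p = 61;
round trips are exact to $10^{-9}$ or better. Tolerances in tests are
$10^{-12}$–$10^{-9}$ for exact identities, $10^{-6}$ for rotation
invariance of normalized moments. Degenerate inputs are handled as
conventions, not errors, wherever a convention is defensible: constant
windows pass through, constant images binarize to empty masks with a
warning, empty-versus-empty Dice is 1, zero-denominator metrics are `NA`.
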