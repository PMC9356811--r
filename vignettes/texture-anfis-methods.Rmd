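---
title: "Methods: co-occurrence texture features and neuro-fuzzy grading"
author: "tumortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence texture features and neuro-fuzzy grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumortex)
```

## The problem and the pipeline

Grading a brain MR slice as *normal*, *benign* or *malignant* from texture
alone rests on a classical observation: tumour tissue disturbs the local
grey-level statistics of the image. Malignant regions tend to be
heterogeneous at the pixel scale, benign lesions more regular, and healthy
parenchyma smooth. The package operationalizes that observation as a
four-stage pipeline:

1. **Preprocessing** — Gaussian denoising followed by unsharp-mask
   sharpening, to suppress acquisition noise without erasing the
   lesion/background contrast the later stages rely on.
2. **Texture description** — grey-level co-occurrence matrices (GLCM) at
   distance $d$ in the four standard orientations $0°, 45°, 90°, 135°$,
   plus their element-wise average (five matrices per image), summarized
   by a fixed 14-statistic vector.
3. **Segmentation** (parallel track) — global "concentration" threshold,
   morphological closing, hole filling, largest-component selection.
4. **Classification** — an adaptive neuro-fuzzy inference system (ANFIS)
   mapping the 14-feature vector to the three classes.

Because no clinical dataset ships with the package, a seeded synthetic
generator provides images whose class structure mirrors the assumptions
above; every quantitative claim in the test suite is computed on that
generator or on closed-form cases.

## Co-occurrence texture model

For an image quantized to $G$ grey levels, the co-occurrence matrix at
offset $\delta$ has entries
$P(a,b) \propto \#\{p : I(p)=a,\ I(p+\delta)=b\}$, normalized to sum to 1.
By default each pair is counted in both directions (symmetric counting),
so $P = P^\top$ and the marginal moments of rows and columns coincide.
The four orientations map to (row, col) offsets $(0,d)$, $(-d,d)$,
$(-d,0)$, $(-d,-d)$, with row 1 at the top; the fifth, averaged matrix is
the element-wise mean of the four and inherits their normalization.

The 14 statistics are the classical Haralick-style set: autocorrelation
$\sum ab\,p$, contrast $\sum (a-b)^2 p$, correlation, dissimilarity
$\sum |a-b|\,p$, energy (angular second moment) $\sum p^2$, entropy
$-\sum p \ln p$, homogeneity (inverse difference moment)
$\sum p/(1+(a-b)^2)$, maximum probability, marginal mean and variance,
and the four sum/difference statistics (sum average, sum variance, sum
entropy, difference entropy) built from the distributions of $a+b$ and
$|a-b|$. Ten of these are the named texture measures commonly quoted for
tumour grading; the sum/difference statistics are the standard completion
of the set to 14, and "mean of correlation" is realized as
autocorrelation. Entropy uses the natural logarithm by default (the base
is an argument).

Two conventions deserve a note because the field's formulations vary:

* The marginal variance is the *probability-weighted* second central
  moment of the marginal distribution, $\sum_a (a-\mu)^2 p_r(a)$. An
  unweighted sum of deviations is dimensionally inconsistent for a
  probability distribution and is not used.
* When a marginal variance is zero (constant image), correlation is
  undefined; it is reported as 0 with a warning rather than `NaN`, so
  downstream feature tables stay numeric.

**Defaults.** $G = 8$ grey levels (uniform binning of the full 0–255
range, so bins mean the same thing in every image; min–max stretching is
an explicit flag) and $d = 1$. Eight levels at unit distance is common
practice for Haralick features and keeps every $8\times 8$ matrix well
populated even in a $64 \times 64$ window; both are configurable.

## Preprocessing

Gaussian smoothing uses a separable kernel truncated at $4\sigma$ with
reflective borders, rounded back to the integer range; the mean is
preserved up to rounding and the variance never increases. Sharpening is
unsharp masking, $x + \alpha\,(x - G_{\sigma_s}(x))$ clipped to range,
with internal $\sigma_s = 1$; $\alpha = 0$ is an exact identity, which
makes the "no enhancement" configuration trivially safe. The default
chain is smooth ($\sigma = 1$) then sharpen ($\alpha = 0.5$): enough
smoothing to kill pixel noise at the generator's noise level, mild
enough sharpening to restore edge contrast without ringing.

## Segmentation

Binarization is strict: a pixel is foreground iff its intensity *exceeds*
the threshold. The automatic threshold is Otsu's rule — an exhaustive
scan of all candidate levels maximizing the between-class variance, ties
broken to the smallest level. Note a consequence of that tie-break worth
knowing: for an image with two well-separated intensity modes the
between-class variance is flat across the empty gap, so the selected
threshold sits at the *start* of the plateau (just above the lower mode),
not mid-gap. It still separates the modes exactly.

Morphology uses the 3×3 square structuring element. `dilateMask` and
`erodeMask` follow the literal finite-frame definitions with zero
padding (so an all-ones mask erodes to its interior). `closeMask`
embeds the mask in a background margin before dilating and eroding, which
makes it equal to the whole-plane closing restricted to the frame; this
is what gives closing its textbook laws (extensive, idempotent) for
every mask, including ones touching the border. Hole filling floods the
background from the border under 4-connectivity and fills what it cannot
reach; component labeling is also 4-connected. The edge-mixture map —
regions where vertical, horizontal and diagonal edges intermix, a
signature of text-like clutter — is exposed as a standalone operation
rather than inserted into the tumour path, because nothing in the
segmentation chain consumes it.

## The ANFIS classifier

The classifier is a zero-order Takagi–Sugeno system. Inputs are z-score
standardized (statistics stored in the model). Each feature $f$ carries
Gaussian membership functions
$\mu_{f,j}(z) = \exp(-(z-c_{f,j})^2 / 2\sigma_{f,j}^2)$; a rule picks one
membership function per feature and fires with the product of its
degrees; firing strengths are normalized to sum to 1; class scores are
the normalized-strength-weighted average of per-rule consequent weights.
Normalization is computed through log-space (log-sum-exp), so the
product of 14 small Gaussian factors cannot underflow to an all-zero
rule vector.

Training minimizes the squared error between scores and the one-hot
target over *all* parameters — centres, widths and consequents — by
full-batch gradient descent with momentum:
$\Delta\theta \leftarrow \rho\,\Delta\theta - \eta\,\bar g$, where
$\bar g$ is the gradient of the per-observation *mean* loss. Averaging
the gradient makes $\eta$ insensitive to dataset size; with summed
gradients the same $\eta$ that is stable on 20 observations diverges on
200. With $\rho = 0$ an epoch is exactly one plain gradient step, which
is what the finite-difference tests check. Widths are clamped at
$10^{-3}$ (standardized units) after every step; argmax ties break to
the earlier class in the fixed order (normal, benign, malignant).

**Rule-base layout.** With few features the rule base is the full grid of
membership combinations, centres at equally spaced quantiles of the
training data and widths at half the centre spacing. With 14 features a
grid is intractable ($2^{14}$ rules), so the model falls back to one rule
per class seeded at the class medians with one-hot consequents — a fuzzy
nearest-prototype classifier that gradient descent then refines. The
crossover is controlled by `maxRules` (default 64).

**Defaults.** $\eta = 0.05$, $\rho = 0.9$, 150–200 epochs. These are
ordinary choices for batch gradient descent on standardized inputs; the
per-epoch loss trace is returned so divergence or premature stopping is
visible, and a non-finite loss aborts with the offending epoch named.

## What the synthetic generator does and does not emulate

`makeImage` produces: *normal* — a flat background (level 60) with a
smooth low-frequency modulation (sd 6) and pixel noise (sd 5); *benign* —
the same background plus one bright disc (level 175) with a sinusoidal
internal texture (period 8 px, amplitude 25); *malignant* — a bright
region with a harmonically perturbed boundary and salt-like binary
texture (amplitude 70). The recipes are chosen so the headline features
(autocorrelation, contrast, energy, entropy) are ordered across classes
— in particular mean GLCM contrast orders malignant > benign > normal —
which is the structure the classifier exploits. Lesion geometry is drawn
before any other randomness, so the radius and centre depend only on the
seed and are returned for oracle checks (disc area vs $\pi r^2$).

It does **not** emulate MRI physics: no bias fields, Rician noise,
partial-volume effects or anatomy. Passing tests therefore demonstrate
that the pipeline's machinery is correct and that it separates classes
whose texture statistics differ in the assumed directions — not clinical
performance on real scans.

## Problem sizes and numerical choices

The bundled evaluation uses 30 images per class at $64 \times 64$ with a
70/30 stratified split, chosen as the smallest configuration at which
the feature clusters are clearly formed; the generator's native default
is $256 \times 256$. Quantization, GLCM counting and morphology are
exact integer operations; feature sums are plain double accumulation
over at most $G^2 = 64$ cells, far below any precision concern.
Probability normalizations are asserted to $10^{-12}$ in the tests.
CSV feature tables print 17 significant digits so read-back is exact;
model JSON does the same, and a reloaded model reproduces predictions
bit-identically.

## Known limitations

* Evaluation is synthetic-only; no claim is made about real MR data.
* The per-class rule layout cannot represent classes that are
  multi-modal in feature space (one prototype per class); increase
  `maxRules` with a reduced feature set if that matters.
* Otsu's threshold assumes a bimodal histogram; lesions occupying a tiny
  fraction of a noisy image can defeat it (override with an explicit
  threshold).
* The edge-mixture map is exposed but unused by the tumour track, by
  design.

## A minimal session

```{r example, eval = FALSE}
set.seed(1)
item <- makeImage("malignant", syntheticSpec(size = 64), seed = 3)
img <- preprocessImage(item$image)
fv <- extractFeatures(img, levels = 8, which = "averaged")
seg <- segmentTumor(img)
out <- runPipeline(pipelineConfig(seed = 1))
out$report$accuracy
```
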