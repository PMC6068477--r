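---
title: "Windowed KNN guided filtering of classification probability maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed KNN guided filtering of classification probability maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knnfilt)
```

## The problem and the model

Pixel-wise classifiers of hyperspectral scenes -- the motivating
application is intraoperative mapping of brain-tumor margins, where an SVM
scores every pixel as tumor, normal tissue, hypervascularized tissue or
background -- ignore spatial context: isolated pixels flip class wherever
the spectral evidence is ambiguous. The KNN guided filter repairs this by
pooling each pixel's posterior with those of its nearest neighbors in a
joint intensity-space feature domain.

Every pixel $q$ at 0-based coordinates $(l, h)$ of a one-band guidance
image $I$ (normalized to $[0,1]$; typically the first principal component
of the cube) is embedded as

$$F(q) = \big(I(q),\ \lambda\, l(q),\ \lambda\, h(q)\big),$$

where $\lambda \ge 0$ balances spatial against spectral affinity:
$\lambda = 0$ ignores location entirely, larger values confine neighbors
to the local patch. Distances between embeddings are measured with either
the 2-norm (Euclidean) or the 1-norm (Manhattan). Given the set
$\omega_q$ of the $K$ nearest neighbors of $q$ (the query pixel itself
excluded), the filtered posterior of class $c$ is the neighborhood mean

$$O_c(q) = \frac{1}{K} \sum_{s \in \omega_q} P_c(s),$$

and the output label is $\arg\max_c O_c(q)$, ties resolved to the lowest
class index. Because each $O(q)$ is a mean of probability simplex rows it
is itself a simplex row, so filtering never leaves the probability scale.

Defaults are $\lambda = 1$ and $K = 40$, the operating point reported as a
good compromise for this kind of medical imagery.

## The row-band search window

A naive search computes $N_{\text{pix}} - 1$ distances per pixel. With
$\lambda = 1$ and raw pixel coordinates the spatial terms dominate the
intensity term (which is bounded by 1) as soon as a candidate is more than
a few pixels away, so distant candidates can never enter the 40 nearest.
`knn_windowed()` therefore restricts candidates to a band of `wsize` image
rows around the query pixel -- rows rather than columns so the candidates
are contiguous in row-major memory. The per-pixel interval is

$$[\,r - \texttt{wsize}/2,\ r + \texttt{wsize}/2 - 1\,]$$

clamped to the image: the first row sees `wsize/2` rows (3864 candidate
pixels on a 552-column scene at `wsize = 14`), interior rows the full
`wsize` (7728 candidates), and the band shrinks symmetrically at the
bottom border. This interval convention reproduces all published
candidate counts; where the bottom-border split is under-determined by
those counts (the last row could hold `wsize/2` or `wsize/2 + 1` rows),
the choice is isolated in `window_bounds()` and documented there.

`wsize = 14` is the reference window: a geometric argument (and the
oracle-equivalence test suite) shows its labels are identical to the
whole-image search. Under the defaults the 40 nearest candidates of any
pixel lie within a Chebyshev radius of 3 (48 candidates, every distance
below 7, since the intensity term adds at most 1), while every pixel
outside the 14-row band is at spatial distance at least 7. Narrower
windows trade accuracy for speed; the package's evaluation tools quantify
that trade-off per configuration.

## Neighbor selection

Two selection strategies are implemented and cross-checked:

* **bounded insert** (the per-pixel kernel): a $K$-slot ascending array
  initialised with $+\infty$ sentinels; a candidate whose distance is
  $\le$ the last slot replaces it and is slid to its sorted position.
  The first $K$ candidates are therefore always accepted.
* **full sort**: all candidate distances collected and the first $K$
  taken in ascending (distance, linear index) order -- the order a stable
  merge sort of the row-major candidate scan produces. Internally a
  partial sort under that exact comparator is used; the sorted outcome,
  not the sorting algorithm, is the contract.

On tie-free data the two agree exactly. Under exact distance ties they
can differ: the bounded-insert eviction rule ("smaller *or equal*
replaces the last element") may retain a later index where the canonical
order keeps the earlier one. Equality tests therefore use tie-free inputs
or canonicalize by (distance, index). Label ties in the final argmax go
to the lowest class index -- with the default vocabulary (tumor first)
this is deliberately conservative toward tumor.

Per-pixel searches share no state, so results are independent of pixel
processing order; the compiled kernel exploits this but any backend
batching is unobservable in the results.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lambda_weight` | 1 | weight of spatial coordinates in the feature triple (unitless; 0 = spectral only) |
| `k_neighbors` | 40 | neighbors averaged per pixel |
| `metric` | `"euclidean"` | 2-norm; `"manhattan"` is cheaper and changes ~1% of labels |
| `wsize` | 14 | search-band height in image rows; `"full"` searches the whole image |
| `coordinate_mode` | `"raw"` | integer row/col offsets in the features; `"normalized"` divides by `rows-1`/`cols-1` first |
| `include_self` | `FALSE` | whether a pixel may be its own neighbor |

`coordinate_mode = "raw"` is the default because the distance formulation
is written on raw row/column offsets and the dominance heuristic that
justifies the row band requires spatial terms that can exceed the
unit-bounded intensity term. The normalized mode is provided for the
alternative reading in which coordinates, like intensities, are scaled to
$[0,1]$; with it, narrow windows are **not** guaranteed to reproduce
whole-image results.

## Numerical and degenerate-input choices

* A constant guidance image min-max normalizes to all zeros (it is
  information-free for the intensity term either way); `normalize_guidance`
  is idempotent and rejects non-finite input.
* Probability stacks must sum to 1 per pixel within `1e-6`; a
  `renormalize` flag accommodates external posteriors with rounding error.
* Division in the filtered posterior is by $K$ exactly, not by the count
  of distinct contributors, which matters only if `include_self` changes
  candidate counts.
* A window too small to supply $K$ neighbors (fewer than $K{+}1$ candidate
  pixels at the first row) is an error instructing a larger `wsize` or a
  smaller `k_neighbors`, never a silent short list.
* Binary rasters are 32-bit floats in an ENVI-style header + flat binary
  pair; doubles are quantized once on write, after which round trips are
  bit-exact.

## What the synthetic generator emulates

No patient imagery ships with the package, so `generate_scene()` builds
seeded stand-ins for the two upstream products the filter consumes:

* **ground truth**: blobs of tumor / normal / hypervascularized tissue
  deposited on a background -- blob-shaped, not i.i.d., because spatial
  coherence is the premise the filter exploits; default radii (8--16 px)
  keep $K = 40$ neighborhoods class-dominated;
* **guidance**: per-class mean intensity plus Gaussian noise
  (sd 0.05), min-max normalized -- mimicking a PCA band in which tissue
  classes separate by brightness;
* **posteriors**: a softmax over logits `sharpness * 1[class == truth] +
  N(0, 1)`; the default sharpness 3 yields confident but imperfect maps
  in which a small fraction of argmax labels is wrong -- the regime in
  which spatial filtering helps.

`degrade_probabilities()` additionally swaps the top-2 classes of random
pixels, the salt-and-pepper failure mode the filter is designed to clean.

What this does **not** emulate: real spectral signatures and their
class-conditional correlations (tumor and hypervascularized tissue are
spectrally similar in vivo; here every class pair is equally separable),
sensor noise structure, illumination gradients, or the spatial error
correlation of a real SVM. Passing tests demonstrate the algorithm's
internal consistency and its qualitative noise-cleaning behavior, not
clinical accuracy.

The default scene is 128 x 128: large enough that 14-row windows reach
their steady state and whole-image/windowed equivalence is non-trivial,
small enough that the quadratic whole-image reference search stays cheap.
Equivalence is asserted across 10 seeded scenes and both metrics; the
monotone-degradation suite pools difference counts over 3 scenes per
metric at a 10% degradation rate.

## Evaluation conventions

Configurations are compared with binary difference maps and a class-pair
breakdown in which every differing pixel is assigned to exactly one
unordered label pair; pairs involving the first class are itemised (a
tumor/normal swap is clinically graver than any other confusion) and the
rest pooled as "others". The figure of merit $1/(t \times err)$ uses
`err` = percent of pixels differing from the reference configuration --
the disagreement quantity tabulated per configuration -- and the report
carries both the percent-scale and fraction-scale conventions, since the
trade-off ranking is unaffected. Timings come from the host's wall clock
and are explicitly non-reproducible; they are never asserted against.

## Known limitations

* The windowed/whole-image equivalence guarantee is specific to the
  default operating point (raw coordinates, $\lambda = 1$, $K = 40$,
  `wsize >= 14`); other settings require their own sweep.
* Only one-band guidance is supported; multi-band feature spaces (and
  approximate search structures such as k-d trees) are out of scope.
* The quadratic `knn_full_oracle()` is a validation tool; at clinical
  scene sizes (~260k pixels) only the windowed search is practical.
* GPU-style batching is not implemented; the per-pixel independence
  contract that enables it is, and is tested.
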