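# knnfilt

Windowed K-nearest-neighbor guided filtering of per-class probability
maps from pixel-wise classifiers of hyperspectral scenes.

Pixel-wise classifiers (an SVM scoring each pixel as tumor / normal /
hypervascularized tissue / background, in the motivating intraoperative
brain-tumor application) ignore spatial context and leave salt-and-pepper
label noise. This package refines their posterior maps with a one-band
guidance image *I* (e.g. the first principal component of the cube): each
pixel *q* is embedded as

    F(q) = ( I(q), λ·l(q), λ·h(q) )

(intensity plus λ-weighted row/column coordinates), its K nearest
neighbors ω\_q are found under the Euclidean or Manhattan metric, the
class posteriors are replaced by the neighborhood mean

    O_c(q) = (1/K) Σ_{s ∈ ω_q} P_c(s),

and the label becomes argmax\_c O\_c(q). The expensive neighbor search
runs inside a band of `wsize` image rows centred on each pixel instead of
the whole image; at the default operating point (λ = 1, K = 40,
`wsize = 14`, raw coordinates) the banded search provably reproduces the
whole-image labels while computing ~34× fewer distances (7728 vs 264,407
candidates per pixel on a 552-column scene). An evaluation toolkit
(binary difference maps, class-pair misclassification breakdown, figure
of merit 1/(t·err)) supports choosing smaller, faster windows, and a
seeded synthetic scene generator makes the whole pipeline testable
without patient data.

## Worked example

```r
library(knnfilt)

sc  <- generate_scene(scene_spec(seed = 7))                  # 128 x 128, 4 classes
deg <- degrade_probabilities(sc$probabilities,               # 10% salt-and-pepper
                             flip_rate = 0.10, seed = 8)

plain    <- assign_labels(deg)                               # spectral-only argmax
filtered <- filter_classification(sc$guidance, deg,          # KNN guided filter
                                  filter_params())           # λ=1, K=40, wsize=14

mean(plain$labels    == sc$truth$labels)   # 0.8676
mean(filtered$labels == sc$truth$labels)   # 0.9939

# the banded search equals the whole-image search
full <- assign_labels(optimized_probability(
  deg, knn_full_oracle(sc$guidance, filter_params())))
diff_map(filtered, full)$n_different       # 0

render_classmap(filtered, "filtered.png")  # red/green/blue/black tissue map
```

The filter lifts agreement with the ground truth from 86.8% to 99.4% on
this scene by relabeling 2245 pixels (13.7%), and the 14-row window
changes none of them relative to a whole-image search.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "knnfilt", package = "knnfilt"))')
Rscript $CLI synth  --out scene --seed 7 --flip 0.1
Rscript $CLI filter --guidance scene/guidance.dat --probs scene/probabilities.dat \
                    --out labels.dat --wsize 14 --metric euclidean --render labels.png
Rscript $CLI compare --map labels.dat --ref scene/truth.dat --report cmp.json
Rscript $CLI sweep  --guidance scene/guidance.dat --probs scene/probabilities.dat \
                    --wsizes full,14,12,10,8,6,4,2 --ref 14:euclidean --out report/
```

Rasters travel as ENVI-style header + flat float32/int32 binary pairs, or
as comma-delimited text for small fixtures.

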