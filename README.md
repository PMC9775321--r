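# wsattn

Weakly supervised, attention-guided classification of brain-MRI slices in R.

Binary slice classification for neurodegenerative disease (AD vs. normal
control in the motivating application) is a fine-grained problem: the
discriminative signal is a subtle, localized intensity difference inside an
otherwise very similar image, and labeled medical datasets are small.
`wsattn` implements a weakly supervised attention pipeline that addresses
both problems with only image-level labels:

- **Entropy-based slice selection.** Each axial slice of a 3D scan is
  scored by the Shannon entropy of its gray-level histogram,
  H = −Σ<sub>g</sub> p<sub>g</sub> log₂ p<sub>g</sub>, and the 32 most
  informative slices per scan are kept. Slices are partitioned 8:1:1 into
  train/validation/test, stratified by class.
- **Attention-gated residual backbone.** A ResNet-style feature extractor
  in which every bottleneck block carries a channel gate
  M<sub>c</sub> = σ(MLP(avgpool F) + MLP(maxpool F)) and a spatial gate
  M<sub>s</sub> = σ(f<sup>7×7</sup>[avgpool F′; maxpool F′]), applied
  multiplicatively to the residual before the shortcut addition
  X̄ = X + F″.
- **Bilinear attention pooling (BAP).** A 1×1 convolution produces N
  nonnegative attention maps A<sub>i</sub>; each part feature is
  f<sub>i</sub> = GAP(A<sub>i</sub> ⊙ F), and the N×M part-feature matrix
  P feeds a linear softmax classifier after L2 normalization.
- **Attention-guided augmentation.** Per training image one attention map
  is drawn, min-max normalized, and thresholded into a crop mask
  (C<sub>i</sub> = 1 where A*<sub>i</sub> > θ<sub>c</sub>; the minimal
  bounding box is enlarged back to input size) and a drop mask
  (D<sub>i</sub> = 0 where A*<sub>i</sub> > θ<sub>d</sub>). Raw, cropped
  and dropped batches are trained jointly.
- **Attention regularization.** A center-loss-style penalty
  L<sub>A</sub> = Σ<sub>i</sub> ‖f<sub>i</sub> − c<sub>i</sub>‖₂² pulls
  each part feature toward a moving-average center
  c<sub>i</sub> ← c<sub>i</sub> + β(f<sub>i</sub> − c<sub>i</sub>).
- **Coarse + fine inference.** At test time the raw image gives P<sub>c</sub>;
  the summed, normalized attention defines a crop whose re-forward gives
  P<sub>f</sub>; the decision uses P = (P<sub>c</sub> + P<sub>f</sub>)/2.
  Performance is reported as sensitivity, specificity, precision, accuracy
  and F1 from the confusion matrix (positive class = disease).

The network forward **and** backward passes are implemented natively in R
(im2col convolutions over BLAS, hand-derived gradients, verified against
finite differences in the test suite), so the whole pipeline trains on a
CPU without any deep-learning framework. A deterministic synthetic-slice
generator with a planted "lesion" disk makes every stage testable without
external data; the full-scale ResNet50 variant is provided but experiments
on real MRI are out of scope here.

## Worked example

```r
library(wsattn)

# synthetic study: 32x32 slices, positive class carries a radius-4 lesion
# disk of contrast 0.5 at a jittered location, noise sd 0.05
spec <- syntheticSpec(imageSize = c(32L, 32L), nPerClass = 300L,
                      lesionContrast = 0.5, noiseSd = 0.05, seed = 11L)
ds <- makeSliceDataset(spec)
sp <- splitDataset(split(ds@sourceIds, sliceLabels(ds)), c(4, 1, 1), seed = 11L)
pick <- function(v) { i <- match(v, ds@sourceIds)
  list(images = sliceImages(ds)[i], labels = sliceLabels(ds)[i]) }

model <- buildBackbone("tiny", inputSize = c(32L, 32L), nMaps = 4L, seed = 101L)
fit <- fitModel(model, pick(trainIds(sp)), pick(valIds(sp)),
                epochs = 10L, batchSize = 16L, lr = 0.03, seed = 11L,
                verbose = TRUE)
#> epoch 1: loss 1.2087, val acc 0.870
#> ...
#> epoch 10: loss 0.3784, val acc 0.990

te <- pick(testIds(sp))
mean(decideLabel(predictProbs(fit$model, te$images)) ==
     as.character(te$labels))
#> [1] 0.98        # coarse-only test accuracy

p <- predictFused(fit$model, te$images[[1]])   # coarse+fine average
round(p, 3)
#> negative positive
#>    0.588    0.412
```

Training prints one line per epoch (mean total loss and validation
accuracy); the fused two-pass prediction returns calibrated-looking class
probabilities whose argmax is the decision (ties go to the negative
class). On this synthetic study the fused test accuracy reaches 1.00
against 0.98 coarse-only.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/wsattn.R synth --out data --seed 7 --n-per-class 300
Rscript inst/cli/wsattn.R train --data data --out run --epochs 10 --n-maps 4 --lr 0.03
Rscript inst/cli/wsattn.R predict --checkpoint run/checkpoint.rds --input data --out pred.tsv
Rscript inst/cli/wsattn.R evaluate --pred pred.tsv --truth run/split.tsv --out metrics.json
```

## Package layout

- `R/slices.R` — entropy, slice ranking, NIfTI/PNG loading, dataset split
- `R/synthetic.R` — deterministic synthetic slices and volumes
- `R/tensor.R`, `R/gates.R`, `R/backbone.R` — native conv/BN/attention
  layers with analytic backward passes; model assembly
- `R/bap.R` — attention head, bilinear attention pooling, classifier
- `R/augment.R` — normalization, crop/drop masks, batch augmentation
- `R/train.R` — losses, center updates, SGD training loop, checkpoints
- `R/inference.R` — coarse/fine/fused prediction, confusion metrics
- `R/cli.R`, `inst/cli/wsattn.R` — command-line interface
- `vignettes/methods.Rmd` — model description, assumptions, design choices
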