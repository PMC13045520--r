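# dfseg

Segmentation of 2-D midsagittal speech MRI frames — background plus six
anatomical classes (head, soft palate, jaw, tongue, vocal tract, tooth
space) — with a hybrid convolution–transformer encoder and a *progressive
refinement decoder*, plus the downstream velopharyngeal closure analysis
that reads clinical frame labels directly off the segmentation.

It is intended for researchers working on vocal-tract imaging pipelines
who need (a) a boundary-aware segmentation architecture, (b) the standard
evaluation machinery (per-class Dice, Hausdorff distance), and (c)
frame- and event-level closure analysis, all runnable and testable on CPU
with a built-in synthetic phantom generator — no external dataset needed
to exercise every code path.

## The model

The encoder runs a three-layer convolutional stem (3×3 conv + BN + ReLU,
2×2 max-pooling between layers), tokenizes the stem output into
non-overlapping P×P patches (P = 16),

    z₀ = [x¹ₚE; …; xᴺₚE] + E_pos,   N = HW/P²,

applies n pre-norm transformer layers

    z′ₗ = MSA(LN(zₗ₋₁)) + zₗ₋₁,   zₗ = MLP(LN(z′ₗ)) + z′ₗ,

and reshapes the tokens back to an (H/P)×(W/P)×D grid. The decoder
up-samples stage by stage with skip connections; its shallowest stages
carry **refinement modules**: a 1×1 *DF head* predicts a two-channel
directional field (ground truth: the unit vector from the nearest class
boundary pixel toward each foreground pixel, DF(p) = (p−b)/‖p−b‖, zero
elsewhere), and *feature rectification* iterates

    Fᵏ(p) = Fᵏ⁻¹(pₓ + DF(p)ₓ, p_y + DF(p)_y),   k = 1…N  (N = 6),

with bilinear sampling and border clamping, then fuses Fᴺ with F⁰ through
a 1×1 convolution. All refined maps are projected to 7 channels,
up-sampled, and summed with the decoder head into the segmentation
logits. Training minimizes soft Dice loss plus λ·Σ masked-MSE
directional-field supervision with Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8,
lr = 2e−4, batch 8). No deep-learning framework is used: forward and
backward passes are implemented in R/C++ in this package and validated
against finite differences.

## Worked example

```r
library(dfseg)

# an 18-frame phantom series with two scheduled closure events
ph <- generatePhantomSequence(phantomConfig(
  frames = 18, size = c(64, 64),
  closureSchedule = data.frame(start = c(3, 11), end = c(6, 14)),
  seed = 7))

# train the desk-scale configuration on the first 8 frames
fit <- trainModel(NULL, ph$images[1:8], ph$masks[1:8],
                  config = trainConfig(lr = 2e-3, batchSize = 8,
                                       epochs = 200, seed = 7),
                  maxSteps = 200)

pred <- predictMasks(fit$model, ph$images)
evaluateMasks(pred, ph$masks)
#         class      dice  hausdorff
# 1        head 1.0000000 0.00000000
# 2 soft_palate 1.0000000 0.00000000
# 3         jaw 1.0000000 0.00000000
# 4      tongue 1.0000000 0.00000000
# 5 vocal_tract 0.9987806 0.38888889
# 6 tooth_space 1.0000000 0.00000000
# 7        mean 0.9997968 0.06481481

rep <- closureReport(pred, gtClosure = ph$closure)
rep$frames
#       accuracy false_positive false_negative
#            100              0              0
rep$events
# closure events: 2 predicted | 2 correct, 0 additional, 0 merged, 0 missed
```

Dice is the overlap fraction per class (1 = perfect); Hausdorff is the
worst boundary disagreement in pixels. The closure report classifies each
predicted closure event against the schedule with a one-frame endpoint
tolerance.

The same flows are scriptable from a shell via the thin CLI at
`inst/cli/dfseg.R` (`synth`, `train`, `predict`, `eval`, `closure`,
`ablate` subcommands).

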