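# endossl

Multi-task self-supervised learning (SSL) for classifying anatomical
landmarks in upper-gastrointestinal endoscopy frames, for researchers who
have many frames and few labels. Expert annotation of endoscopic video
is expensive; `endossl` pretrains convolutional encoders on three
*pretext tasks* whose labels come for free from the images themselves,
then fuses the pretrained encoders into a classifier for three landmark
classes: `0` Z-line, `1` esophageal, `2` antrum/pylorus.

## The method

Three pretext tasks share one convolutional autoencoder (four conv+ReLU
stages, kernel 4 / stride 2 / padding 1, channels 4→64→128→256→512;
mirrored transposed-conv decoder with a terminal 3-channel sigmoid;
bottleneck 2×2×512 at a 32 px input):

- **Colorization** — predict the color image from the luminance channel
  *I<sub>L</sub>* = 0.299 R + 0.587 G + 0.114 B, with pixel-wise MSE loss
  *L* = (1/HWC) Σ (I − Î)²;
- **Patch prediction** — reconstruct a masked center patch *P<sub>c</sub>*
  from its context, *L* = (1/p²C) Σ (P<sub>c</sub> − P̂<sub>c</sub>)²;
- **Jigsaw** — classify which permutation π from a fixed
  maximum-Hamming-distance catalog shuffled the image tiles,
  *L* = −log ŷ<sub>π</sub>.

Encoders pretrained on these tasks (20 epochs, Adam, lr 10⁻³, batch 32)
are fused in seven scenarios (`Cl`, `PPred`, `JigPuzz`, their pairs, and
`Cl-PPred-JigPuzz`): bottleneck features are concatenated and classified
through a linear–ReLU–dropout–linear head, with optional spatial
soft-attention or a transformer block before the head. Downstream
training adds patient-wise validation carving, early stopping with
best-weight restoration, SMOTE balancing of minority classes (convex
combinations of same-class nearest neighbors, training frames only),
and seeded augmentation. Evaluation reports accuracy, weighted and macro
precision/recall/F1, and one-vs-rest ROC/AUC; `grad_cam()` renders
saliency heatmaps for any convolutional layer. A synthetic
endoscopy-like generator (three hue/texture-separable classes with
per-patient appearance shifts and the study's 766/1589/1256 class
imbalance) makes every stage runnable without clinical data.

The whole stack — including convolutions, transposed convolutions,
attention and the transformer block, with Adam and backpropagation — is
implemented in R on BLAS matrix products and verified against
finite-difference gradients; no deep-learning framework is required.

## Worked example

```r
library(endossl)
manifest <- generate_dataset(n_per_class = c(50, 50, 50), image_size = 32,
                             n_patients = 10, seed = 1)
print(manifest)
#> Endoscopy frame manifest: 150 frames
#>   class 0 (Z-line): 50
#>   class 1 (esophageal): 50
#>   class 2 (antrum_pylorus): 50
#>   patients: 10

split <- patient_wise_split(manifest, train_frac = 0.8, seed = 1)
print(split)
#> Split: 120 train / 30 test (seed 1)

cfg     <- train_config(max_epochs = 20, seed = 1)
enc_cl  <- pretrain_pretext("colorization", manifest, split, config = cfg)
enc_jig <- pretrain_pretext("jigsaw",       manifest, split, config = cfg)
print(enc_cl)
#> Pretext encoder (colorization): 20 epochs, final train loss 0.01973

model <- build_combined("Cl-JigPuzz",
                        encoders = list(colorization = enc_cl,
                                        jigsaw = enc_jig),
                        input_size = 32, seed = 1)
fit <- train_classifier(model, manifest, split, cfg)
metrics <- evaluate_model(fit, manifest, split)
print(metrics)
#> Performance metrics
#>   Accuracy              100.00
#>   Weighted avg-Precision 100.00
#>   Weighted avg-Recall    100.00
#>   Weighted avg-F1-Score  100.00
#>   Macro avg-Precision    100.00
#>   Macro avg-Recall       100.00
#>   Macro avg-F1-Score     100.00
#>   Per-class AUC          1.00 1.00 1.00
#>   Macro AUC              1.00

idx <- 56   # a held-out esophageal frame
hm <- grad_cam(fit, manifest$records[[idx]]$pixels, target_class = 1)
print(hm)
#> Grad-CAM heatmap 32x32 (layer colorization.conv4, class 1), mass 528.56
```

The manifest printout shows the generated class counts and patient pool;
the split is patient-wise, so no patient contributes frames to both
sides. Pretext losses are the task reconstruction/classification losses
(the colorization MSE of 0.0197 means ~0.14 RMS pixel error on [0,1]
intensities). The metrics block mirrors the standard report layout —
weighted recall always equals accuracy — and the heatmap is a [0,1]
saliency map over the input aligned to the named encoder layer (for some
frame/class pairs the rectified map is identically zero; `grad_cam()`
then warns and returns zeros).

A command-line wrapper covering the same workflow
(`simulate` / `pretrain` / `train` / `evaluate` / `explain`) is installed
at `inst/cli/endossl.R`:

```sh
Rscript inst/cli/endossl.R simulate --out data --n 50,50,50 --patients 10 --seed 1
Rscript inst/cli/endossl.R pretrain --manifest data/manifest.csv --task jigsaw --out runs/jig
Rscript inst/cli/endossl.R train --manifest data/manifest.csv --scenario Cl-JigPuzz \
        --encoders runs/jig --out runs/clf --smote --augment
Rscript inst/cli/endossl.R evaluate --model runs/clf/checkpoints/model.rds \
        --manifest data/manifest.csv --out runs/clf/eval
```

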