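# hepaseg

Two-stage segmentation of the liver and of tumors inside the liver envelope
from contrast-enhanced abdominal CT, for researchers in medical image
analysis who need a fully inspectable, CPU-only reference implementation of
the *deep network + localized active contour* design.

## The method

1. **Preprocessing.** Intensities are windowed to −50..250 HU and mapped
   onto [0, 1]; liver-stage slices are median-filtered (3×3); the tumor
   stage enhances the liver region of interest with tensor-based 3D
   edge-enhancing diffusion, `u_t = div(D ∇u)`, where `D` has eigenvalue
   `g(|∇u_σ|²)` along the regularized gradient (Weickert diffusivity
   `g(s) = 1 − exp(−C_m/(s/λ²)^m)`) and 1 on the orthogonal complement.
2. **Cascaded 2D U-Nets.** A liver network on whole-abdomen slices and a
   tumor network on the cropped, diffusion-enhanced liver envelope; 19
   convolutional layers at the default configuration, sigmoid output, and
   the soft-Dice loss
   `L = 1 − (2 Σ pt + ε)/(Σ p + Σ t + ε)`,
   trained with Adam (lr 0.001, 20 epochs, batch 32, LR ×0.1 on a 5-epoch
   plateau). The convolution kernels and backprop are implemented in
   C++/RcppArmadillo inside the package — no external deep-learning
   framework.
3. **Localized level-set refinement.** The network mask initializes a
   signed embedding φ; each narrow-band point moves under the localized
   Chan–Vese force `(I − u_x)² − (I − v_x)² + μκ`, where `u_x, v_x` are
   interior/exterior means within a disk of radius `r`, with an
   Otsu-derived intensity gate. Small predicted objects with no interior /
   exterior contrast collapse and vanish — removing spurious non-tumor
   blobs.
4. **Evaluation.** Dice per case, `2|A∩B|/(|A|+|B|)`, reported for the
   network-only and the refined masks so the level-set contribution can be
   ablated.

A synthetic abdominal phantom generator (bright perturbed-ellipsoid liver
≈ 120 HU, darker tumors ≈ 45 HU, soft tissue / air / bone background,
Gaussian noise, per-voxel ground truth) makes the whole cascade trainable
and testable with no external data. See `vignettes/hepaseg-methods.Rmd` for
the full methods account.

## Worked example

```r
library(hepaseg)

ph <- generatePhantom(phantomSpec(seed = 42))
ph$volume
#> CTVolume 128 x 128 x 48, spacing 1.50 x 1.50 x 2.50 mm
#>   intensity range [-1048.8, 488.4]
ph$liver
#> BinaryMask 128 x 128 x 48, 61017 foreground voxels

# refine a deliberately coarse liver mask on one axial slice
slice  <- huWindow(ph$volume@voxels[, , 24])
truth  <- ph$liver@voxels[, , 24]
coarse <- (initPhi(truth)@phi <= 4) * 1L          # 4 px over-segmentation
refined <- evolveContour(slice, coarse, levelSetParams(radius = 7),
                         gate = c(otsuThreshold(slice), 2))
d <- function(a, b) diceCoefficient(array(a, c(dim(a), 1)),
                                    array(b, c(dim(b), 1)))
sprintf("Dice before %.3f, after %.3f", d(coarse, truth), d(refined, truth))
#> "Dice before 0.877, after 0.970"
```

The slice Dice of 0.877 is the quality of the deliberately dilated input
mask; 0.970 is what the localized level set recovers from it using only the
intensity statistics of this slice. The full experiment — training both
networks on 40 phantoms and evaluating the cascade on 10 held-out phantoms
— is one call:

```r
st <- runPhantomStudy(nTrain = 40, nTest = 10, seed = 7)
round(st$evaluation$means, 4)
#>    liver_dice_unet liver_dice_refined    tumor_dice_unet tumor_dice_refined
#>             0.9390             0.9900             0.8281             0.9171
```

about 10 minutes on one CPU (see the vignette for the study conditions).
Read the four numbers as the per-case mean Dice of the network-only and
the level-set-refined masks for each stage: the refinement lifts the
liver from 0.939 to 0.990 and the tumors from 0.828 to 0.917 on held-out
phantoms, reproducing the network-then-refinement ordering the method is
built around (tumor means are over the nine tumor-bearing test cases). A command-line front end with `segment`, `train`,
`evaluate` and `phantom` subcommands is installed at `exec/hepaseg`.

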