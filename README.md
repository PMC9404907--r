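# fundusreg

Fully unsupervised non-rigid registration of retinal fundus photographs in R.

Retinal fundus images of the same eye taken at different times (or under
different acquisition quality) are misaligned by eye motion and optics:
comparing them — for disease monitoring, artifact rejection, or longitudinal
studies — requires registering the moving image $I_{Mov}$ onto the reference
$I_{Ref}$. Annotated deformations or landmark ground truth are rarely
available, so `fundusreg` learns the alignment without any labels:

1. **Structure extraction.** Both images are resized to a square working
   resolution and reduced to vessel/eye-structure maps $B_{Ref}, B_{Mov}$
   with the isotropic undecimated wavelet transform (IUWT, the *à trous*
   algorithm with the cubic B3-spline kernel), which was developed for
   retinal vessel detection. Vessels are dark in fundus photographs, so the
   negated sum of selected detail planes scores them high.
2. **Correspondence grid.** A U-shaped fully convolutional network (two
   downsampling blocks of max-pooling + two convolutions; two upsampling
   blocks of transposed convolution + skip concatenation + two convolutions;
   batch norm and ReLU everywhere except a zero-initialized 1×1 head) maps
   the stacked pair $(B_{Ref}, B_{Mov})$ to a dense per-pixel displacement
   field $u$.
3. **Spatial transformer.** A grid generator adds $u$ to the identity grid
   and a differentiable bilinear sampler produces the warped map
   $B_{Warp}(x) = B_{Mov}(x + u(x))$.
4. **Unsupervised objective.** The whole stack is trained with ADAM to
   maximize the normalized cross-correlation

   $$\mathrm{NCC}(T, R) = \frac{\sum_{ij} T_{ij} R_{ij}}
     {\sqrt{\sum_{ij} T_{ij}^2 \sum_{ij} R_{ij}^2}},$$

   with $T = B_{Warp} - \overline{B_{Warp}}$ and
   $R = B_{Ref} - \overline{B_{Ref}}$ — image similarity is the only
   training signal. After training, registration is **one-shot**: a single
   forward pass per pair.
5. **Refinement & evaluation.** Small noisy clusters in $B_{Warp}$ are
   removed by connected-component analysis (default threshold 20 px), and
   quality is reported as MSE, SSIM, Dice and the gain coefficient
   $GC = |B_{Ref} \cap B_{Warp}| / |B_{Ref} \cap B_{Mov}|$.

The network, backpropagation (through the bilinear sampler included) and the
ADAM optimizer are implemented in the package itself with Rcpp/RcppArmadillo
kernels — no deep-learning framework is required. A synthetic vessel-phantom
generator with ground-truth smooth deformations makes every stage testable
without downloading any dataset.

## Worked example

A desk-scale run on synthetic phantoms (64×64, deformations up to 5 px,
blur/dimming/occlusion degradations on the moving images):

```r
library(fundusreg)

suite <- synth_suite(16, size = 64, amplitude = 5, smoothness = 8,
                     n_trees = 2, branch_depth = 3,
                     vessel_width = c(1.2, 2.6), seed = 11)
pairs <- lapply(suite$pairs, function(p)
  list(ref = segment_vessels(p$i_ref), mov = segment_vessels(p$i_mov)))

model <- build_model(net_config(input_size = 64, depth = 2, base_filters = 8),
                     seed = 1)
model <- train_model(model, pairs,
                     train_config(epochs = 400, batch_size = 4, seed = 1))

# before / after alignment on the training suite
mean(sapply(pairs, function(p) ncc(p$mov, p$ref)))   # 0.7700
mean(sapply(pairs, function(p) dice(p$ref, p$mov)))  # 0.6691

warps <- lapply(pairs, function(p)
  warp_displacement(p$mov, forward_grid(model, p$ref, p$mov)))
mean(mapply(function(p, w) ncc(w, p$ref), pairs, warps))   # 0.9345
mean(mapply(function(p, w) dice(p$ref, w), pairs, warps))  # 0.8510
```

The fitness (mean NCC per epoch) is in `model$training_curve`; it rises
steeply and then plateaus. One-shot inference on a new pair, with refinement
and the full metric report:

```r
pr <- make_pair(phantom_spec(size = 64, n_trees = 2, branch_depth = 3,
                             vessel_width = c(1.2, 2.6), seed = 99),
                deformation_spec(amplitude = 4, seed = 100))
res <- run_registration(model, pr$i_ref, pr$i_mov, refine_min_size = 20)
res$report
#> <metric_report> MSE 0.03833 | SSIM 0.7892 | Dice 0.8780 | GC 1.2229
```

A gain coefficient above 1 means the transformation increased the number of
vessel pixels aligned with the reference relative to the unregistered pair.

`run_ablation()` reproduces the refinement-strategy comparison (no
refinement vs. morphological opening/closing vs. component filtering at
10/20/30 px) as a mean ± sd table over a dataset.

A thin command-line front end is included at `inst/cli/fundusreg.R`
(`synth | train | register | evaluate | refine | ablate`).

## Scope

The package implements the registration framework and its evaluation
machinery; comparisons against external registration tools (keypoint- or
learning-based), statistical significance testing, and photorealistic fundus
simulation are out of scope.
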