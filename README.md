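# mosr — Multi-Orientation U-Net Super-Resolution for Ultra-Low-Field Brain MRI

Portable ultra-low-field (ULF, ~64 mT) MRI scanners make paediatric
neuroimaging feasible where conventional scanners are not, but their default
T2-weighted protocol delivers noisy, strongly anisotropic volumes
(1.5 × 1.5 × 5 mm), each orientation sharp in-plane and thick through-plane.
`mosr` implements a learned fusion of the three orthogonal acquisitions: a
3D encoder–decoder (**MO U-Net**) takes the axial, coronal and sagittal
scans — resampled to a common 1 mm isotropic grid — as three input channels
and reconstructs a single 1 mm isotropic volume resembling a high-field
(HF, 3 T) scan of the same infant brain.

The package is a complete, CPU-only tool for this method:

* **Geometry substrate** — NIfTI-1 I/O (via RNifti), world-extent-preserving
  resampling, brain-masked min–max normalization, centered pad/crop to the
  training cube.
* **Synthetic phantom module** — procedural infant-brain phantoms (CSF
  shell + ventricles, cortical grey ribbon, white matter, eight deep grey
  structures; per-subject smooth deformations) and a forward acquisition
  model (boxcar slab excitation, coarse in-plane sampling, gamma contrast
  shift, bias field, Rician noise), so every stage runs with no data
  download.
* **Network & training** — the MO U-Net (3×3×3 convolutions, group
  normalization, ReLU, 2³ max-pooling; widths 64→128→256 at full scale;
  trilinear upsampling + halving in the decoder; linear 1³ output head),
  trained with Adam (lr 10⁻⁴, batch 1) under paired random affine/elastic
  augmentation (p = 0.5). Convolutions run through hand-written
  im2col + BLAS kernels (RcppArmadillo); the backward pass is implemented
  layer by layer and verified against finite differences.
* **Composite loss** — voxel-wise L2 plus a perceptual term evaluated on
  S = 6 randomly drawn paired slices (2 per anatomical axis): frozen
  convolutional features are channel-normalized at each position, weighted,
  squared-differenced, spatially averaged and summed over layers. Combined
  as `L = LPIPS + λ·L2` with λ = 100.
* **Reduced-input inference** — missing orientations are filled by cloning
  the highest-priority available scan (axial > sagittal > coronal), so one
  axial scan is presented as (axial, axial, axial).
* **Evaluation battery** — per-region Dice (2|A∩B|/(|A|+|B|)), region
  volumes (cm³) with Pearson r, Lin's concordance
  CCC = 2·cov/(varₓ+var_y+(μₓ−μ_y)²) and Bland–Altman limits, grey/white
  median-intensity differentiation, NMSE/PSNR/volumetric SSIM, and paired
  Wilcoxon signed-rank tests (exact by 2ⁿ enumeration for n ≤ 12) with
  rank-biserial effect sizes and a Bonferroni family-wise threshold
  (0.05/8 = 0.00625).

## Worked example

```r
library(mosr)

# simulate a small cohort: isotropic phantom + three degraded acquisitions
records <- make_dataset(12, phantom_config(side_mm = 32, seed = 1))
fold <- make_folds(records, k = 1, ratio = c(7, 0, 5), seed = 1)[[1]]

# desk-scale model: 8 base features on a 32-voxel cube
model <- build_mo_unet(mo_unet_config(base_features = 8, cube_side = 32), seed = 1)
fit <- train_mo_unet(model, records, fold,
                     desk_train_config(epochs = 20, seed = 1),
                     loss_config(seed = 1), feature_extractor(seed = 1))
tail(fit$history, 1)
#>    epoch train_loss train_lpips    train_l2 val_loss
#> 20    20   1.006661   0.3124067 0.006942542       NA

rec <- fold_records(records, fold$test_ids)[[1]]
pred <- super_resolve(fit$model, rec$inputs)          # all three inputs
pred_ax <- super_resolve(fit$model, rec$inputs["axial"])  # axial only

unlist(image_quality(resample_to_grid(pred, rec$target), rec$target))
#>      nmse      psnr      ssim
#> 0.0755193  19.80629 0.7868919
unlist(image_quality(resample_to_grid(pred_ax, rec$target), rec$target))
#>      nmse      psnr      ssim
#> 0.1711277  16.25367 0.6864148
```

The three-input prediction's cohort-mean NMSE (0.071 under the seed-1
acceptance run) is well below the best single resampled input (0.252) and
the non-learned three-scan average (0.236), and error grows monotonically
as distinct inputs are removed (0.071 -> 0.104 -> 0.159 for three, two and
one), mirroring the full-scale behaviour of the method. Tissue-contrast
quantities (Dice of intensity-derived masks, grey/white differentiation)
remain far below the ground-truth ceiling at this 140-step desk budget:
learning tissue contrast finer than the reconstruction error floor needs
far longer optimization.

A command-line interface wraps the same functions:

```sh
mosr simulate --n 8 --out data/ --seed 7 --size 64 --age-mode 6mo
mosr train    --data data/manifest.tsv --config train.yaml --out run/
mosr infer    --model run/model.ckpt --axial a.nii.gz --out sr.nii.gz
mosr evaluate --manifest data/manifest.tsv --pred-dir run/ --methods mo_unet,naive --out report/
```

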