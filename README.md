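# nucadapt

Adversarial domain adaptation for nuclei segmentation in histopathology
image patches, in pure R (Rcpp/Armadillo compute engine; no external
deep-learning framework).

## The problem

A U-Net trained to segment nuclei on one stained-tissue collection (the
*source* domain) degrades badly on another (the *target*) because staining,
scanners and tissue shift the image statistics — while the ground-truth
nuclei masks remain domain-invariant. `nucadapt` implements an
unsupervised (UDA) and semi-supervised (SSDA) adversarial adaptation
framework that exploits this asymmetry with four networks — segmentation
U-Net `S`, reconstruction U-Net `R`, a prediction discriminator `D_P` in
output space and an image discriminator `D_I` in image space — trained
GAN-style against the objective

```
L_uda = L_seg(X_s) + λ_advP·L_advP(X_t) + λ_recons·L_recons(X_t)
      + λ_advI·L_advI(X_t) + λ_trans·L_trans(X_s→t) + λ_cl·L_cl(X_s, X_t)
```

where `L_seg = L_dice + L_em` (dice + entropy minimization),
`X_s→t = R(S(X_s))` are target-translated source images that keep their
source masks, and `L_cl` tightens encoder features around their class
centroids (L1) while pushing the two class centroids apart. Default
weights `(0.001, 0.01, 0.001, 0.001, 0.002)` and per-network Adam learning
rates `(1e-4, 1e-3, 1e-3, 1e-3)` are the published operating point. The
SSDA objective adds an unweighted `L_seg(X_tl)` on labeled target images.

A built-in generator produces paired two-domain synthetic nuclei
benchmarks (shared mask process, domain-specific appearance: color,
texture, blur, brightness) so the whole framework is testable on a laptop
without any external data. Metrics are IoU%, Dice score and Hausdorff
distance. See `vignettes/methods.Rmd` for the model details and every
numerical/design choice.

## Worked example

```r
library(nucadapt)

# a small paired-domain benchmark: bright source, dim low-contrast target
bench <- make_benchmark(
  n_source = 48, n_target = 40,
  params = nuclei_geometry(size = 32, n_range = c(5, 9),
                           radius_range = c(3, 6)),
  seed = 101)

# source-only baseline vs unsupervised adaptation (desk-scale config; see
# the methods vignette for why lr_seg and em_warmup differ from defaults)
base_cfg <- train_config(epochs = 20, batch_size = 4, seed = 1,
                         lr_seg = 1e-3, disc_base = 8, em_warmup = 1,
                         weights = loss_weights(0, 0, 0, 0, 0),
                         use_adv_i = FALSE, use_trans = FALSE,
                         use_cl = FALSE)
uda_cfg  <- train_config(epochs = 20, batch_size = 4, seed = 1,
                         lr_seg = 1e-3, disc_base = 8, em_warmup = 1)

st_base <- fit(base_cfg, bench$source, bench$target)
st_uda  <- fit(uda_cfg,  bench$source, bench$target)

evaluate_model(st_base$best$S, bench$target$test)
evaluate_model(st_uda$best$S,  bench$target$test)
```

Printed output from this exact script (seeds as shown; ~4 min on one CPU):

```
Segmentation metrics over 4 images:
  IoU%   52.09
  Dice  0.6443
  HD    14.0001 px
Segmentation metrics over 4 images:
  IoU%   54.32
  Dice  0.6772
  HD    13.9726 px
```

The first block is the source-only baseline evaluated on the target test
split — it suffers the domain shift. The second is the adapted model on
the same images: the adversarial and translated-source terms recover part
of the gap (across the three seeds of the acceptance study the adapted
model wins in every seed, by +2.2, +4.6 and +2.4 IoU points). On real
data the published gap between these two rows is ~8 IoU points on a
52-to-66 scale.

Translated images and the loss machinery are exposed directly:

```r
x_st <- translate_source_to_target(st_uda$nets$S, st_uda$nets$R,
                                   bench$source$test$images)
dice_loss(c(1, 0, 1, 0), c(0.8, 0.2, 0.6, 0.4))  # 0.3
total_uda_loss(list(seg = 1, advP = 1, recons = 1, advI = 1,
                    trans = 1, cl = 1), loss_weights())  # 1.015
```

## Command line

```sh
Rscript -e 'quit(status = nucadapt::cli())' simulate \
    --out bench --n-source 80 --n-target 40 --size 32 --seed 7
Rscript -e 'quit(status = nucadapt::cli())' train-uda \
    --source bench/source --target bench/target --out run \
    --epochs 10 --seed 7
Rscript -e 'quit(status = nucadapt::cli())' evaluate \
    --checkpoint run/checkpoint.rds --data bench/target --out run/metrics
Rscript -e 'quit(status = nucadapt::cli())' translate \
    --checkpoint run/checkpoint.rds --data bench/source --out run/xlat
```

`train-ssda --labeled-fraction 0.25` runs the semi-supervised variant;
`ablate --off advI,trans,cl` switches individual loss terms off. Datasets
on disk are 8-bit Netpbm (`{domain}/{split}/{images,masks}/NNNN.ppm|pgm`)
plus a JSON manifest.

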