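# rdresponse

Biologically guided prediction of post-radiotherapy FDG-PET images in R.

## The problem

Radiotherapy outcome assessment increasingly relies on functional imaging:
an FDG-PET scan taken partway through a treatment course shows how tumor
metabolism — measured as the standardized uptake value (SUV) — is responding
to the delivered radiation. Predicting that intra-treatment image *before*
treatment starts, from the baseline PET and the planned dose distribution,
would let clinicians compare candidate plans by their predicted biological
outcome. `rdresponse` implements such a predictor for 2D axial slices, aimed
at methods researchers in radiation oncology and medical-image analysis who
want an interpretable, physics-structured alternative to black-box
image-to-image networks — plus the full evaluation protocol and a synthetic
phantom generator to develop against, since clinical PET datasets of this
kind are rarely shareable.

## The model

SUV evolution over the treatment course is modeled by a reaction-diffusion
equation with a dose-coupled response term:

    U_t = alpha * Laplacian(U) + beta * U + F(D o U)

where `U` is the SUV image, `D` the planned spatial dose map, `alpha` a
diffusion coefficient (spread of abnormal metabolic activity), `beta` a
proliferation rate (local growth or decay), and `F` an unknown operator
giving the dose-induced rate of change as a function of `psi = D o U`
(element-wise product: response scales with both local dose and local
disease burden).

The equation is solved by forward Euler, unrolled for `Nt = 4` steps of size
`h = 0.25` with a nine-point Laplacian stencil (center -3, edges 1/2,
corners 1/4). `F` is represented by a 7-layer encoder-decoder convolutional
network applied at every step with shared weights; `alpha` and `beta` are two
ordinary trainable scalars in a parallel branch. All three are fit jointly by
Adam on the mean squared l2 distance to observed post-treatment images, so a
trained model yields interpretable physical coefficients alongside its
predictions — and every prediction decomposes exactly into accumulated
diffusion, proliferation, and dose-response maps.

Evaluation follows radiotherapy-QA practice: Otsu segmentation of
high-uptake regions, mean SUV and Dice comparisons, and per-pixel 2D
gamma-index analysis (intensity tolerance + distance-to-agreement) under
criteria 5%/5 mm through 10%/10 mm, summarized as passing rates.

## A worked example

```r
library(rdresponse)

spec <- phantom_spec(seed = 1)          # 64x64 phantoms, true alpha = 0.05,
ds   <- generate_dataset(spec, 30)      # beta = -0.1, linear kill gamma = 0.4
model <- train(ds$train, ds$val,
               tcfg = training_config(max_epochs = 30, learning_rate = 2e-3,
                                      patience = 30, seed = 1))
recover_coefficients(model)
#>   alpha_hat    beta_hat
#>  0.07343956 -0.01540791

case <- ds$test[[1]]
pred <- forward_unrolled(model, case$pre, case$dose)
report <- evaluate_cohort(list(case), list(pred$prediction))
report
#> <eval_report> 1 cases (0 failed)
#>   SUV mean pred 2.594 +/- NA, truth 2.286 +/- NA, Dice 0.943 +/- NA
#>   gamma 5%/5mm: median 99.07%, mean 99.07%
#>   gamma 5%/10mm: median 99.44%, mean 99.44%
#>   gamma 10%/5mm: median 100.00%, mean 100.00%
#>   gamma 10%/10mm: median 100.00%, mean 100.00%
```

This two-minute demonstration run already predicts well (99% of body pixels
pass the tight 5%/5 mm gamma criterion; Dice 0.94 between the high-uptake
segmentations), but 30 cases and 30 epochs are not enough to finish
separating the physical coefficients from the learned operator — the full
protocol of `scripts/acceptance.R` (150 cases, 60 epochs, seed 0) recovers
`alpha_hat` = 0.0547 and `beta_hat` = -0.093 against true values 0.05 and
-0.1. The report compares predicted and true post-radiation images: mean SUV
inside the (truth-derived) Otsu high-uptake region, Dice overlap of the two
Otsu segmentations, and the percentage of body pixels whose gamma index is
below 1 under each tolerance pair — loosening either tolerance can only
raise a passing rate.

`pred$breakdown` holds the three accumulated effect maps; they sum to
`prediction - pre` pixel for pixel (the telescoping identity of the unrolled
update rule).

A command-line interface wrapping the same functions is installed as
`exec/rdresponse` (`simulate-phantoms`, `train`, `predict`, `evaluate`, with
`--config`, `--seed`, `--out` flags and YAML run configuration).

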