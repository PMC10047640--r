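# osteoseg

An R toolkit for computer-aided analysis of osteosarcoma MRI slices.
Clinical series contain hundreds of slices per patient of which only a
handful show the tumour; the images carry Rician magnitude noise; and
osteosarcoma lesions have notoriously blurred margins that plain
convolutional segmenters smear out. `osteoseg` implements the three
stages of an edge-enhanced diagnosis workflow, plus the synthetic
phantoms needed to test it without clinical data:

1. **Pre-screening (TSF).** A sliding `n1 × n1` window is
   coarse-denoised by transform-domain hard thresholding at
   `λ = λ_FFT √(2σ² log n1²)`, then the slice is kept as a "lesion
   image" when any window's activation
   `a = Σ B̄ − 0.5 λ_T n1² − λ_T` turns negative (`k(a) = 1[a<0]`;
   defaults `n1 = 7`, `λ_T = 133`, `λ_FFT = 0.82`).
2. **Denoising.** Pixel-wise non-local means,
   `NLM(I)_i = Z(i)⁻¹ Σ_t exp(−p_t(i)/h²) I_{i+t}`, with every patch
   distance field computed as a single FFT convolution
   (`O(N D² log N)` instead of `O(N D² c²)`), and Rician bias
   correction via `E[X²] = S² + 2σ²`: denoise the squared magnitudes,
   subtract `2σ²`, take the root. A naive double-loop NLM ships as the
   equivalence oracle.
3. **Segmentation (TBNet).** A skip-free U-Net whose four encoder
   scales are tokenized channel-major and fused by multi-head
   channel-wise cross-attention,
   `M_i = softmax(ψ(T_i T_Keyᵀ)/C_Σ)`, `CA_i = M_i T_Value`, with
   residual MLP layers; the decoder fuses transformer and decoder
   features through edge-enhanced cross-attention (channel gating +
   an explicit Sobel edge cue + spatial×channel squeeze weighting).
   Training minimizes `L = α L_Dice + β L_BD`, the squared-denominator
   soft Dice plus the boundary loss `Σ φ_G(i) g(i)` over the signed
   Euclidean distance map of the ground truth. The network runs on a
   small reverse-mode autodiff engine built into the package (C++
   convolution kernels), so no deep-learning runtime is required.

Evaluation helpers cover slice classification accuracy (CA), PSNR,
IOU/DSC and confusion-matrix metrics, and `run_pipeline()` orchestrates
simulate → prescreen → denoise → train → evaluate with 7:1:2 splitting
and rotation augmentation.

## A worked example

```r
library(osteoseg)

# a 64x64 phantom: smooth background, one soft-edged dark lesion
ph <- make_phantom(c(64, 64),
                   list(count = 1, radius = c(9, 9), contrast = 110,
                        softness = 2), seed = 7)
ph
#> phantom 64x64, label=lesion, mask area=250 px, seed=7

# Rician magnitude noise at sigma = 20, then TSF screening
noisy <- add_rician_noise(ph$clean, sigma = 20, seed = 7)
screen_image(noisy, prescreen_config())
#> TSF screening: label=lesion (1 of 100 windows fired)

# Rician-corrected fast NLM and its effect on PSNR
denoised <- rician_correct(noisy, nlm_config(sigma = 20))
round(c(psnr_noisy = psnr(noisy, ph$clean),
        psnr_denoised = psnr(denoised, ph$clean)), 2)
#>    psnr_noisy psnr_denoised
#>         18.51         31.53
```

The mask area (250 px) is close to the half-peak disk π·9² ≈ 254 of the
blob kernel; the screening window that fires sits on the lesion; and
bias-corrected denoising lifts PSNR by about 13 dB here. Screening
quality on a whole stack is summarized by CA — for a screening confusion
table with counts 49/4/3/44 (lesion kept, normal kept, lesion dropped,
normal dropped):

```r
classification_metrics(confusion_counts(tp = 49, tn = 44,
                                        fp = 4, fn = 3))$acc
#> [1] 0.93
```

Training and segmentation follow the classic modelling idiom — a fitting
function returning a classed object with `print`, `summary`, `coef`,
`predict` and `plot` methods:

```r
phs <- lapply(1:16, function(k)
  make_phantom(c(64, 64), list(count = 1, radius = c(6, 12),
                               contrast = 100, softness = 1.5), seed = k))
fit <- tbnet(lapply(phs, `[[`, "clean"), lapply(phs, `[[`, "mask"),
             config = tbnet_config(input_size = c(64, 64),
                                   channels = c(8, 16, 32, 64),
                                   heads = 2, layers = 2),
             epochs = 200, lr = 1e-3, target_dsc = 0.9)
masks <- predict(fit, lapply(phs, `[[`, "clean"), type = "mask")
```

A thin command-line front end over the same functions lives in
`inst/cli/osteoseg.R` (subcommands `simulate`, `prescreen`, `denoise`,
`train`, `segment`, `evaluate`, `run`).

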