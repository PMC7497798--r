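# flimglia

Label-free detection of microglia in NAD(P)H fluorescence lifetime imaging
(FLIM) data.

Microglia, the resident macrophages of the CNS, are normally located with
antibody labels (anti-Iba1, CX3CR1-GFP) that perturb the tissue and cannot
be used in vivo. Their metabolic state, however, differs from that of the
surrounding glia, and the fluorescence lifetime of the endogenous coenzyme
NAD(P)H carries that signature: free NAD(P)H decays with a short lifetime
τ₁ ≈ 0.4 ns, protein-bound NAD(P)H with a long lifetime τ₂ ≈ 2–3 ns.
`flimglia` implements a complete detection workflow on this principle:

1. **Decay fitting** — each TCSPC pixel histogram (256 time bins) is fit
   with the IRF-convolved two-component model
   `a₁·exp(−t/τ₁) + a₂·exp(−t/τ₂) + offset` by Levenberg–Marquardt
   (compiled core, Poisson weights with model-based variance, timing shift
   as a bounded nuisance parameter), yielding seven parameter maps:
   τ₁, τ₂, τₘ = (a₁τ₁ + a₂τ₂)/(a₁+a₂), a₁, a₂, a₁[%], χ².
2. **Block instances** — overlapping 8×8 blocks become training rows:
   per-parameter block means (fitting-based method, **FBM**) or the
   area-normalized block-summed decay histogram (decay-based method,
   **DBM**), labeled by the ground-truth mask at the block center.
3. **Classifier** — a feed-forward network with one hidden layer of 10
   tanh units and a logistic output, trained on a 70/15/15
   train/validation/test split by full-batch Levenberg–Marquardt under
   MacKay Bayesian regularization, minimizing mean squared error; the
   held-out test MSE is the performance index.
4. **Detection** — block scores form a probability image; a probability
   cutoff and a minimum region size are calibrated on training FOVs by
   maximizing mean Dice overlap, then frozen. Cells are counted by
   8-connected components: any overlap with a cell body or process is a
   true positive, a predicted region touching nothing is a false
   positive; the report gives TPR, PPV, FNR and FDR (true negatives are
   undefined in this scheme and never reported).

A synthetic phantom generator (cell somata with branching processes,
per-cell lifetime draws, Poisson photon noise, IRF convolution, optional
detector timing drift) provides ground-truthed fields of view so the whole
chain runs and is tested without microscope data.

## Worked example

```r
library(flimglia)

# a ground-truthed synthetic field of view
phantom <- generate_phantom(phantom_preset("culture", size = 64,
                                           n_microglia = 4, n_other = 4,
                                           seed = 1))
phantom
#> <flim_phantom> 64 x 64 px, 4 microglia + 4 other cells, shift 0.00 bins

# fit one (spatially binned) pixel decay
d <- spatial_bin(phantom$cube, 1)$counts[32, 32, ]
fit <- fit_decay(d, phantom$irf, phantom$cube$bin_width)
fit
#> <flim_decay_fit> tau1 0.436 ns, tau2 3.265 ns, a1 74.2%, tau_m 1.165 ns, chi2 0.757
```

The fitted free fraction (74%) and mean lifetime (1.17 ns) identify this
pixel as background-like tissue; microglia pixels run shorter (higher
a₁[%], lower τₘ). `autoplot(fit)` overlays data and fit on a log scale;
`tidy(fit)` returns the parameters as a one-row tibble.

The whole pipeline — fit every cube, build block features, train,
calibrate, detect on held-out FOVs — is one call:

```r
fovs <- lapply(1:6, function(s)
  generate_phantom(phantom_preset("culture", size = 64, n_microglia = 4,
                                  n_other = 4, seed = s)))
res <- run_detection_pipeline(fovs[1:4], fovs[5:6], mode = "fbm",
                              config = run_config(), seed = 1)
res$thresholds
#> <flim_thresholds> cutoff 0.50, min size 25 px (dice 0.803)
res$metrics
#> <flim_detection> 2 FOV(s); pooled TP 5 / FN 0 / FP 0
#>   pooled TPR 1.000, PPV 1.000, FNR 0.000, FDR 0.000
glance(res$fit)$mse_test
#> [1] 0.0289
```

All five microglia in the two held-out FOVs are found with no false
positives; the network's held-out performance index is 0.029. `tidy()` /
`glance()` methods cover the fitted network and the detection result, and
`autoplot()` renders parameter maps, probability images and the metric
summary.

A command-line front end wrapping the same functions is installed at
`inst/cli/flimglia` (subcommands `simulate`, `fit`, `features`, `train`,
`predict`, `evaluate`, `convert`).

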