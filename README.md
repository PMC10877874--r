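# ovadx

Tools for two computational problems in ovarian cancer research, built to be
fully testable without clinical data:

1. **Tumor segmentation of T2-weighted MRI slices** with a fully
   convolutional *edge-output* network: a truncated residual backbone
   (resnet50 layout with the stride-32 stage removed, or a desk-scale
   reduced backbone) whose intermediate stages feed three side branches —
   1×1 channel reduction to 128, bilinear-initialised transposed-convolution
   upsampling — fused by two 1×1 convolutions into a per-pixel probability
   map. Training uses a class-balanced cross-entropy loss

   CBCE = −β Σ<sub>j∈Y+</sub> log p<sub>j</sub> − (1−β) Σ<sub>j∈Y−</sub> log(1−p<sub>j</sub>),  β = |Y−|/|Y|,

   with plain cross-entropy and soft Dice losses for comparison, and is
   evaluated by DSC = 2TP/(2TP+FP+FN), sensitivity, specificity, and the
   boundary Hausdorff distance.

2. **Multi-indicator diagnosis from routine blood tests**: z-score
   standardization of a 25-indicator panel (CA125, CA15-3, …, LDL-C/HDL-C),
   correlation PCA keeping the three leading components, and a
   one-hidden-layer back-propagation classifier whose hidden size, weights
   and thresholds are selected by a genetic algorithm. Evaluation uses ROC
   curves (Mann–Whitney AUC), the Youden operating point, and the DeLong
   test for correlated AUCs against a single-marker CA125 baseline.

Both halves come with synthetic generators — tumor phantoms (elliptical,
ring-shaped, fuzzy-boundary) and case/control cohorts with a designed
3-factor latent structure — so every claim in the package is exercised
end-to-end on one CPU. The intended audience is methods developers who need
a reference implementation with verifiable numerics, not a clinical tool.

## Worked example: the diagnostic pipeline

```r
library(ovadx)

co <- generate_cohort(cohort_spec(seed = 1))   # 185 cases / 569 controls
model <- diagnostic_model(co, seed = 1,
                          ga = ga_config(population_size = 24, generations = 20,
                                         hidden_size_range = c(2, 8),
                                         fine_tune_steps = 300, seed = 1))
summary(model)
#> Test-set AUC 0.998; Youden point: sensitivity 100.0%, specificity 96.8% (threshold 0.417)
#> Top-3 principal components explain 51.0% of indicator variance; hidden layer size 6
#>          stratum   n n_train n_test
#>             case 185     123     62
#>  other_malignant 138      92     46
#>           benign 339     226    113
#>          healthy  92      61     31

test <- model$split$test_ids
delong_test(model$scores[test], co$CA125[test], model$labels[test])
#> <delong_result> AUC 0.998 vs 0.832, z = 6.154, p = 7.542e-10
```

Reading: the stratified 2/3–1/3 split reproduces the 123/62 case
allocation; the pipeline separates cases from the pooled controls nearly
perfectly on this synthetic cohort (the designed case shift is 0.8 sd per
indicator), and the DeLong test shows the panel model significantly
outperforms CA125 alone (AUC 0.998 vs 0.832).

## Worked example: segmentation

```r
p <- generate_phantom(phantom_spec(image_size = 64, tumor_shape = "ring",
                                   tumor_intensity_contrast = 0.6,
                                   noise_sd = 0.05, seed = 2))
p
#> <slice_pair> 'phantom-ring-seed2' 64x64, 251 tumor px (6.1%)

net <- build_network(network_config("reduced", input_size = 64, seed = 1))
net
#> <edgenet> reduced backbone, 6 residual blocks, 3 edge branches (16 channels), 2-conv head, 65873 parameters

ds  <- generate_phantom_dataset(phantom_spec(image_size = 64,
         tumor_intensity_contrast = 0.6, noise_sd = 0.05, seed = 11), N = 30)
fit <- train_model(train_config("cbce", roi_size = 64, epochs = 20,
                                batch_size = 4, learning_rate = 5e-3,
                                seed = 7), ds)
evaluate_model(fit, ds$pairs[fit$val_idx])$table
#>   metric   mean    sd  n       display
#>      dsc  94.27  3.80  6  94.27 ± 3.80
#>       se  99.27  1.23  6  99.27 ± 1.23
#>       sp  99.26  0.40  6  99.26 ± 0.40
#>       hd   1.28  0.50  6   1.28 ± 0.50
```

A minute of CPU training takes the reduced backbone to ~94% held-out Dice
on easy-contrast phantoms. `run_loss_roi_grid()` trains one network per
(loss, ROI size) cell and reproduces the qualitative finding that
segmentation quality drops as the ROI — and with it the class imbalance —
grows; `compare_models()` builds the mean ± sd comparison table (and
pairwise mean differences) for any set of systems on shared cases.

Command-line wrappers live in `inst/cli/`: `synth.R` (phantom/cohort
generation), `seg.R` (train/evaluate/grid over a YAML config), `dx.R`
(fit/predict/profile on cohort CSVs).

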