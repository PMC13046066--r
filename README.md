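# dectmix

Simulation study of voxel-wise **elemental decomposition from dual-energy
CT (DECT)**: can the elemental mass fractions of a tissue voxel be
recovered from just two monoenergetic linear attenuation coefficients
(LACs), and how do a per-element linear model and a softmax-constrained
linear network compare when the training data encode realistic intra- and
inter-patient composition variability?

Accurate elemental composition underpins absorbed-dose calculation in
radiotherapy planning. DECT supplies two energy channels; `dectmix`
generates synthetic voxels for two tissue continua — adipose–muscle
("soft") and cortical-bone–red-marrow ("bone") — and trains and evaluates
two small predictors of the per-element mass fractions, under noise-free
and noisy (SNR 10, 5) conditions, with ten-seed replicate uncertainty.

## The model

**Generator.** Per-tissue elemental mass fractions and densities are drawn
from reference-derived distributions: normal where three reference rows
encode mean ± 1 SD (e.g. adipose hydrogen `(11.6 − 11.2)/2 = 0.2 %`),
uniform over the printed precision otherwise (cortical hydrogen
`U(3.35 %, 3.45 %)`). Whole samples with any negative fraction are
rejected and redrawn; accepted compositions are renormalized onto the
unit simplex. Two-component mixtures draw `w₁ ~ U(0, 1)` and blend
fractions elementwise; the mixture density is the harmonic mean

    ρ_mix = (w₁/ρ₁ + w₂/ρ₂)⁻¹,

and each sample's LAC pair follows the photon mixture rule

    μ(E) = ρ_mix · Σᵢ wᵢ · μ_m,i(E),  E ∈ {50, 88} keV,

with elemental mass attenuation coefficients from a vendored XCOM-class
extract. Gaussian noise with σ_μ = μ/SNR is added per sample and energy,
features are z-score standardized with training-set statistics, and each
10 000-sample dataset is split 72/18/10 % into train/validation/test.

**Predictors.** (1) Per-element ordinary least squares,
`ŵᵢ = β₀ + β₁μ̃₁ + β₂μ̃₂`, closed form, unconstrained outputs; (2) a
single affine layer plus softmax, `ŵ = softmax(Wx + b)`, trained with MSE
loss and Adam (lr 0.001, batch 16, 80 epochs) — outputs are strictly
positive and sum to one, i.e. physically plausible by construction. Both
carry `3K` parameters (12 soft, 15 bone).

**Evaluation.** Per-element test-set RMSE and (for the linear model)
adjusted R² with two predictors, aggregated over replicate seeds 0–9 as
mean ± sample SD (Type A uncertainty).

## Worked example

```r
library(dectmix)

ds  <- build_dataset("soft", snr = Inf, n = 10000, seed = 0)
fit <- fit_linear_ols(dataset_features(ds, "train"), dataset_targets(ds, "train"))
round(1e3 * rmse(predict_linear(fit, dataset_features(ds, "test")),
                 dataset_targets(ds, "test")), 2)
#>     H     C     N     O
#>  7.66 19.00  4.31 11.51
round(adjusted_r2(fit, dataset_features(ds, "train"),
                  dataset_targets(ds, "train")), 3)
#>     H     C     N     O
#> 0.559 0.991 0.875 0.997

ms  <- derive_seed(0, "init", 0L)
net <- train_net(init_net(4, seed = ms),
                 dataset_features(ds, "train"), dataset_targets(ds, "train"),
                 config = train_config(), seed = ms)
round(1e3 * rmse(predict_net(net, dataset_features(ds, "test")),
                 dataset_targets(ds, "test")), 2)
#>     H     C     N     O
#> 11.39 21.35  4.25 12.72
```

Reading: noise-free, the linear model recovers carbon to about
19 × 10⁻³ RMSE in mass fraction and oxygen to about 11.5 × 10⁻³; the
network is slightly less accurate but every one of its predictions lies
in `[0, 1]` (here in `[0.005, 0.760]`), which ordinary regression does not
guarantee. Hydrogen's adjusted R² of 0.56 reflects its narrow dynamic
range in soft tissue (10.2–11.4 %): the attenuation pair simply carries
little hydrogen information.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing
under `results/`:

1. `analysis/01_generate_datasets.R` — the six datasets (soft/bone ×
   noise-free/SNR 10/SNR 5) for seed 0, as CSV + JSON sidecars.
2. `analysis/02_fit_models.R` — both predictors on each dataset; model
   JSONs, scatter (true vs predicted) CSVs, per-element test RMSE.
3. `analysis/03_replicate_study.R` — the full ten-seed replicate study;
   exports the three result tables (RMSE soft, RMSE bone, adjusted R²,
   all × 10³) and a JSON summary.

The whole replicated study (120 model fits on 60 datasets) takes well
under a minute on one CPU.

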