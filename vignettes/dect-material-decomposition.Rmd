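---
title: "Synthetic DECT data and elemental decomposition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic DECT data and elemental decomposition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dectmix` studies a narrowly posed question from quantitative CT: given a
voxel's linear attenuation coefficients (LACs) at two monoenergetic
photon energies, 50 and 88 keV, how well can its elemental mass fractions
be recovered, and what is gained or lost by constraining the predictor to
physically plausible outputs? This vignette documents the generative
model, every tunable parameter that matters, the numerical choices, and
what the synthetic data do and do not establish about real scanners.

## The generative model

### Tissue populations

Two tissue categories are modelled as continua between two pure
components:

* **soft**: adipose tissue and muscle, elements H, C, N, O;
* **bone**: cortical bone and red bone marrow, elements H, C, N, O, Ca.

A category's population is one third samples of each pure component and
one third two-component mixtures, concatenated and shuffled. This is a
deliberate idealization: it emulates the bimodal-plus-transition
structure of, say, a thigh or a vertebral body (voxels of nearly pure
tissue plus partial-volume mixtures) without claiming anatomical voxel
statistics.

### Sampling distributions

Per-element mass fractions and densities of the pure components come from
a packaged eight-row reference table of human tissue compositions
(`tissue_table()`, per cent and kg m⁻³). Two encodings are distinguished:

* Tissues with three reference rows (adipose, muscle): the middle row is
  the mean and half the outer-row spread is one standard deviation, so
  the element is drawn `Normal(mean, |row1 − row3|/2)` — adipose hydrogen
  gives `Normal(11.4 %, 0.2 %)`. This encodes *inter-patient* variability
  where the reference reports it.
* Single-row tissues (cortical bone, red marrow): only the printed
  precision bounds the value, so the element is drawn uniformly over
  ± half of the last printed digit's place value — cortical hydrogen
  `U(3.35 %, 3.45 %)`. Densities printed as four digits ending in zero
  are read with the tens place as the last significant digit (half-width
  5 kg m⁻³), the most direct extrapolation of the same rule. Adipose
  density has three distinct rows (970/950/930) and is therefore
  `Normal(950, 20)` kg m⁻³; muscle density, identical in all rows, falls
  back to the precision rule.

Elements printed as 0.0 % are handled two ways: calcium is excluded from
the soft-tissue element set outright (structurally absent), while
red-marrow calcium is sampled from its precision range `U(−0.05 %, 0.05 %)`
with negative draws removed by rejection — it is a trace constituent of
the bone category rather than a structural zero, and this keeps the bone
model at K = 5 without injecting negative fractions.

### Rejection and renormalization

Each candidate sample draws all elements and the density independently;
any sample containing a negative fraction is discarded and redrawn whole
(per-sample, not per-element, so the accepted joint distribution is the
untruncated product conditioned on validity). A cap of 1000 redraw rounds
guards against malformed custom specifications; the packaged
specifications reject well under 1 % of draws except red-marrow calcium,
where the range straddling zero rejects about half.

Accepted compositions are then **renormalized to sum to one** over the
modelled element set (`renormalize = TRUE`, the default). The reference
rows sum to slightly less than 100 % because trace elements (P, S, Na,
Cl, K, ...) are omitted — markedly so for cortical bone, whose modelled
elements cover only 89.1 % of the mass. Renormalization redistributes the
missing mass proportionally, which (i) makes the composition a proper
simplex point, the natural target space for compositional prediction and
the output space of the softmax predictor, so both predictors are scored
on the same scale; and (ii) realistically couples the elements — a
carbon-rich draw dilutes every other fraction — which is exactly the kind
of structure a two-feature predictor must contend with. The raw,
unnormalized behaviour remains available (`renormalize = FALSE`) and is
what the generator's moment tests check against the reference table.

### Mixtures, density, attenuation

Mixture samples draw a mixing ratio `w1 ~ U(0, 1)` (mass fraction of the
first component; the maximum-entropy choice for a ratio "ranging from 0
to 1"), blend the two freshly drawn pure compositions elementwise, and
take the harmonic-mean density
`ρ_mix = (w1/ρ1 + (1 − w1)/ρ2)⁻¹`, i.e. ideal volumetric mixing. The LAC
at each energy follows the mass-fraction mixture rule
`μ(E) = ρ_mix Σᵢ wᵢ μ_m,i(E)` with elemental mass attenuation
coefficients (m² kg⁻¹) from a packaged ten-constant extract of the
standard photon cross-section compilations; the 88 keV values are log-log
interpolated from the neighbouring 80 and 100 keV grid points (the
`source` column records which entries). The table is replaceable via the
`atten` argument for sensitivity studies. Only the two monoenergetic
values are modelled — no spectra, beam hardening, or detector response.

### Noise, standardization, splits

Noise emulates measurement error on reconstructed LACs: independent
zero-mean Gaussian perturbations per sample *and per energy channel*
(no cross-energy correlation — the simplest reading of a per-value SNR),
with σ_μ = μ/SNR; SNR ∈ {∞, 10, 5} defines the three dataset variants
per category. Noise is applied to every partition — the noisy condition
describes noisy *datasets*, not noisy evaluation of clean-trained models.

Features are z-score standardized. The statistics are computed on the
training partition only and applied to validation and test — computing
them on all samples would leak test information into the feature scale;
`stats_scope = "all"` exposes the alternative, whose effect at n = 10 000
is negligible. The split is random and disjoint: 10 % test, 20 % of the
remainder validation, the rest training (7200/1800/1000 at n = 10 000).

## The two predictors

* **Per-element OLS** (`fit_linear_ols()`): `ŵᵢ = β₀ + β₁μ̃₁ + β₂μ̃₂`,
  solved in closed form by QR, independently per element. Outputs are
  unconstrained: they can be negative or exceed one, which is the
  physical-plausibility gap the constrained model closes.
* **Softmax network** (`init_net()`, `train_net()`): one affine layer
  `z = Wx + b` (`W` is K×2) followed by a softmax. Outputs are strictly
  positive and sum to one by construction. Both models have `3K`
  parameters — the comparison is between output constraints and training
  procedures, not capacity.

### Training configuration

`train_config()` defaults: MSE loss (mean over samples and channels),
Adam with learning rate 0.001, batch size 16, 80 epochs. Adam's constants
are the canonical β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸. There is deliberately
no early stopping, learning-rate schedule, weight decay, or gradient
clipping; the validation set is used for monitoring only, and the
reported model is always the epoch-80 state. Batches are reshuffled every
epoch and the last incomplete batch is used, so every sample contributes
each epoch.

Initialization draws `W ~ U(±1/√fan_in)` with fan-in 2 and zero biases —
a standard small-network scheme; since the loss is non-convex, trained
weights are seed-dependent, which is precisely why the study protocol
reports replicate statistics rather than single runs.

## Numerical choices

* Softmax is computed with per-row max subtraction; outputs satisfy the
  unit-sum identity to 10⁻¹² even at extreme pre-activations.
* The analytic gradient of the softmax-MSE loss,
  `∂L/∂zⱼ = ŵⱼ(gⱼ − Σᵢ gᵢŵᵢ)` with `g = 2(ŵ − w)/(KB)`, is verified
  against central finite differences to 10⁻⁶ in the test suite, and the
  compiled Rcpp training loop is verified against an independent pure-R
  reference implementation to machine precision.
* OLS fits error out on rank-deficient (collinear) designs rather than
  silently dropping coefficients; standardization errors on constant
  features; RMSE on zero samples is an error, not NaN.
* Adjusted R² uses the two-predictor penalty
  `1 − (1 − R²)(n − 1)/(n − 3)` and is evaluated on the training
  partition by default — it is reported as a *fit quality* measure; the
  `adj_r2_partition` argument of `run_replicated_experiment()` switches
  to test, which shifts values only in the fourth digit at these sample
  sizes.
* All randomness flows from one master seed per replicate through fixed
  stage streams (sampling, shuffling, noise, splitting, initialization,
  batch order — `derive_seed()`), so any stage is individually
  reproducible, datasets are bit-identical per seed, and the composition
  draws are shared across the noise variants of a replicate (noise levels
  are compared on identical tissues).
* Uncertainty is the sample SD of the ten replicate estimates, not the
  standard error of their mean: it describes run-to-run spread of the
  procedure.

## Problem sizes

The study protocol is n = 10 000 samples per dataset (7200 train), six
dataset variants, seeds 0–9, both models: 60 generated datasets and 120
fits per full run. These sizes were chosen to make replicate SDs small
relative to the between-condition differences being compared; the whole
replicated study completes in well under a minute on a single CPU, with
the compiled training loop taking a fraction of a second per network.
Unit tests use reduced sizes (hundreds of samples) except where a
Monte-Carlo moment check needs 10⁵ draws.

## What the synthetic data do and do not show

The generator emulates: per-element inter-patient variability (normal
rows), numeric-precision uncertainty (uniform rows), partial-volume
mixing along a two-tissue continuum, energy-dependent attenuation
physics through the mixture rule, and controllable measurement noise.

It does **not** emulate: covariances between elemental fractions beyond
the unit-sum coupling (hydration status, for instance, moves H and O
together; elements are drawn independently here because no consistent
reference of such covariances was modelled); organ-specific voxel
statistics (the thirds structure is a stylized population, not an organ
histogram); spatial context (every sample is a single voxel — no
neighbourhood information, no partial-volume geometry); polyenergetic
spectra, beam hardening, scatter, or reconstruction artefacts (noise is
i.i.d. Gaussian per channel, whereas real reconstructed noise is
correlated across energies and space).

Consequently, passing results establish that the *method* behaves as
designed under the stated variability model — e.g. that the softmax
constraint trades a little accuracy for guaranteed plausibility, that
noise hits wide-range soft-tissue elements (C, O) hardest, and that
narrow-range elements (soft-tissue H, adjusted R² ≈ 0.56 noise-free) are
intrinsically hard to recover from two LACs. They do not certify
accuracy on clinical data.

## Known limitations

* The attenuation extract carries ≲1 % uncertainty (largest for N); both
  predictors re-fit to whatever features the constants produce, so
  evaluation metrics are insensitive to this, but absolute LAC values
  inherit it.
* The renormalization convention makes targets sum to one exactly; with
  `renormalize = FALSE` the softmax model acquires an irreducible bias on
  bone (targets sum to ≈ 0.89–0.99) and its errors grow accordingly —
  comparisons across that switch change the question being asked, not
  just the answer.
* Mini-batch Adam at these settings leaves a few-percent epoch-to-epoch
  jitter in the training loss indefinitely; "convergence" is assessed as
  completed descent (≥ 95 % of the total loss decrease by epoch 20), not
  as a vanishing gradient.
* The linear model's closed-form fit is deterministic given a dataset;
  only the network inherits optimization-path variability. Replicate SDs
  therefore mean different things for the two models (data variability
  vs data + training variability).
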