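---
title: "Data augmentation for motor-imagery EEG spectrogram classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data augmentation for motor-imagery EEG spectrogram classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two-class motor imagery (MI) — imagined left- versus right-hand movement —
modulates the sensorimotor rhythms recorded at electrodes C3, Cz, and C4:
imagery of one hand suppresses mu (8–12 Hz) and beta (18–26 Hz) power over
the contralateral motor cortex (event-related desynchronization, ERD) and
enhances it ipsilaterally (event-related synchronization, ERS). Deep
networks decode these patterns well, but MI datasets are small — typically
a few hundred trials per subject — so convolutional classifiers overfit.
`miaug` implements a complete augmentation-and-evaluation workflow:

1. band-pass filter (8–30 Hz Butterworth) and epoch continuous recordings
   into 4 s trials;
2. convert each trial into a single 64×64 RGB image by vertically stacking
   the short-time Fourier transform (STFT) magnitudes of C3, Cz, and C4;
3. enlarge the training set with one of five augmenters — geometric
   transformation (GT), noise addition (NA), autoencoder (AE), variational
   autoencoder (VAE), or a deep convolutional generative adversarial
   network (DCGAN);
4. score generated-image quality with a Fréchet distance on feature
   embeddings;
5. evaluate a compact CNN under stratified 10-fold cross-validation at
   real-to-generated (RD:GD) ratios of 1:1 … 1:9, with kappa, ANOVA, and
   paired t-tests.

Because the public benchmark recordings cannot be redistributed, the
package ships a synthetic MI simulator that reproduces the phenomenon the
method targets, so every stage is testable end to end.

## The synthetic generator: what it emulates and what it does not

`simulate_trials()` draws, per trial and channel, 1/f-amplitude background
noise (spectrally shaped white noise — a better match to EEG spectra than
white noise) plus mu and beta sinusoids with uniformly random phases, since
MI-induced power changes are not phase-locked to any cue. Class structure
enters only through amplitude scaling: right-hand imagery scales the
oscillation amplitude at C3 by `1 - erd_depth` and at C4 by `1 + ers_gain`,
mirrored for left-hand imagery, with Cz untouched. The laterality
convention (right-hand imagery attenuates C3, over the left motor cortex)
is fixed, not configurable.

Deliberate simplifications: ERD applies across the whole 4 s epoch rather
than ramping on, there is no volume conduction between channels, no ocular
or muscular artifacts, and exactly two balanced classes. Defaults are
100 Hz sampling, 4 s epochs, oscillation amplitudes 1.0 (mu) and 0.5
(beta), ±10 % trial-to-trial amplitude jitter, `erd_depth = 0.5`,
`ers_gain = 0.2`, and unit 1/f noise amplitude — band-power contrasts of
roughly the size seen in sensorimotor recordings. Passing tests on this
generator demonstrates that the pipeline recovers planted band-power
structure; it does not demonstrate performance on real EEG, where
artifacts, non-stationarity, and inter-subject variability dominate.

```{r, eval = FALSE}
library(miaug)
cfg <- sim_config(n_trials_per_class = 100, fs = 100, erd_depth = 0.5)
trials <- simulate_trials(cfg)
images <- trials_to_images(trials)
```

## Spectrogram images

Each channel's trial is transformed with a Hann-tapered STFT (window 128
samples at 100 Hz, 256 at 250 Hz; 50 % overlap) and restricted to
8–30 Hz. The reference protocol fixes only the window sizes; the Hann
taper and 50 % overlap are the field defaults and are exposed in the
function arguments. The three per-channel matrices are stacked vertically (C3 on
top) so that each channel's neighborhood is preserved, log-transformed
(`log1p` — spectral energy spans orders of magnitude), min–max scaled per
image, mapped through a perceptually uniform colormap (viridis by default)
to three planes, and bilinearly resized to 64×64. Per-image scaling was
chosen over global scaling so images from different subjects and sessions
share `[0, 1]`; both choices are defensible and the scaling is a visible
argument.

## Augmenters

*GT* rotates the image by 180° (an involution), translates it by up to
±8 px filling vacated pixels with uniform noise, or jitters brightness
(±0.1) and contrast (±10 %); the magnitudes are unquantified in the
original protocol and are exposed as configuration. *NA* perturbs each
pixel by `u * noise_scale` with `u ~ Uniform(-0.5, 0.5)` — the printed
rule; although the surrounding text says "Gaussian", the equation is
uniform, so uniform is the default with a variance-matched Gaussian
switch. *AE/VAE/DCGAN* are trained per class (and per subject) so samples
inherit an unambiguous label; a conditional model would have changed the
published architecture.

## The DCGAN

The generator maps a 100-dimensional standard-normal latent through five
transposed convolutions, (1024,4,4) → (512,8,8) → (256,16,16) →
(128,32,32) → (3,64,64), halving channels and doubling spatial size at
each step, with batch normalization (momentum 0.8) and ReLU, ending in
tanh. No 3×3 stride-2 deconvolution can map (100,1,1) to (1024,4,4), so
the first layer is a 4×4 stride-1 projection — the one place the
implementation must depart from a literal 3×3 reading of the architecture
table. The discriminator mirrors the stack with stride-2 convolutions,
leaky-ReLU, dropout 0.25, batch norm from the second layer, and a single
sigmoid unit over 16384 flattened features. Training uses Adam
(learning rate 2×10⁻⁴, β₁ = 0.5, β₂ = 0.999 — the usual DCGAN moments;
only the learning rate is prescribed), batch size 128 clamped to the
dataset size (a 180-image fold cannot fill the nominal batch), and 20
epochs. The discriminator loss is the printed binary cross-entropy; the
generator trains on the non-saturating `-log D(G(z))` rather than
`log(1 - D(G(z)))` to avoid vanishing early-training gradients, while the
minimax value function is still reported.

Because no deep-learning framework is assumed, the package carries its own
small training engine (`src/conv.cpp` + `R/nn.R`): im2col-based
convolutions and transposed convolutions, batch normalization, dropout,
max-pooling, Adam and momentum-SGD, all verified against central-difference
gradients in the test suite.

## Fréchet distance

Generated-set quality is the Wasserstein-2 distance between Gaussian fits
to feature embeddings: `||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})`.
The classical embedder is a pretrained Inception network; bundling its
weights is impossible offline, so the formula — which is agnostic to the
embedder — is computed over a pluggable embedding. The default is a
deterministic flatten-PCA embedding (dimension 64, fit on the real set); a
fixed-seed random CNN embedder and a user-supplied embedding function are
also available. Covariances use the unbiased estimator with a 10⁻⁶
diagonal jitter; the matrix square root goes through the symmetric form
`(S_r^{1/2} S_g S_r^{1/2})^{1/2}` by eigendecomposition, clamping
negative eigenvalues at zero. One published rendering of the formula shows
the exponent as a square; the matrix square root is the standard Fréchet
form and is what is implemented.

## Classifier and evaluation protocol

The CNN is deliberately small: conv 3×3 (8 filters) → pool → conv 3×3 →
pool → dense 10 → dense 2 softmax, dropout 0.25 after each pool and the
first dense layer. One published description defines the activation as
`ln(1 + e^a)` while calling it ReLU; that formula is softplus, so the
default here is true ReLU with `activation = "softplus"` selectable.
Training is momentum SGD (0.9; the protocol names both plain SGD and SGDM)
at learning rate 10⁻⁴ by default, 50 epochs, batch 32 — epochs and batch
are unstated in the protocol and config-exposed.

Evaluation is stratified k-fold (k = 10 by default): each fold's test set
is 10 % of the real images only; the training pool is the remaining 90 %
plus `floor(ratio × n_train)` generated images. Generative models are
retrained inside each fold on the training split only — stricter than the
ambiguous published wording, but it makes the leakage audit
(`audit_folds()`) enforceable: no generator ever sees a test image. Child
seeds for every (method, ratio, fold) cell derive from a master seed by a
stable string hash, so any cell is independently reproducible.

The kappa statistic is reported as Cohen's `(acc - chance)/(1 - chance)`
by default; the alternative normalization `(acc - chance)/chance` that
appears in parts of the MI literature is available via
`kappa_score(..., formula = "paper")`. Neither form reproduces every
published kappa table from its accuracy table, so no default could be
validated against them; both are exposed. ANOVA across methods and paired
t-tests against the DCGAN use the classical statistics with degenerate
(zero-variance) inputs reported as untestable rather than failing.

## Numerical choices and problem sizes

Logarithms of probabilities are clipped at 10⁻¹²; batch-norm epsilon is
10⁻⁵; batches of size 1 are skipped (batch statistics are undefined);
sampling runs networks in evaluation mode with running batch-norm
statistics (momentum 0.8). Weight initialization is N(0, 0.02) for the
adversarial nets (the DCGAN convention) and He-scaled for the classifier.

The test suite and the acceptance script exercise the pipeline at desk
scale, a deliberate design point so that the full method runs in minutes
on one CPU: 40–100 synthetic trials per class, 5–10 folds, GAN widths
8–16 (instead of 128) and 8–40 epochs with batch sizes 10–32, and a
classifier schedule of 8–15 epochs at learning rate 10⁻² (the default
10⁻⁴/50-epoch schedule converges to the same place, just more slowly).
Width scaling preserves the halving/doubling channel pattern, so the
architecture checks still bind at full width.

## Known limitations

The simulator cannot stand in for real EEG (see above). At desk scale the
DCGAN learns coarse class-conditional spectral structure, not fine detail;
its benefit shows as a regularization-like accuracy gain in scarce-data
regimes. The AE has no sampling prior — samples perturb stored encodings
with spherical noise at half the codes' average spread, a pragmatic choice
where the protocol is silent. EDF reading covers continuous 16-bit
recordings without annotation parsing; GDF is not supported.
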