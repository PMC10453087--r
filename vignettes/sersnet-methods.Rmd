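---
title: "Methods: simulating and classifying SERS spectra of PAH mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying SERS spectra of PAH mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sersnet)
```

## The problem

Polycyclic aromatic hydrocarbons (PAHs) deposited on fruit and vegetable
surfaces are carcinogenic trace contaminants. Surface-enhanced Raman
spectroscopy (SERS) on a flexible substrate can pick them up in situ, but a
mixture of PAHs produces overlapping band patterns whose manual
interpretation is slow and error-prone: competitive adsorption on the
substrate's binding sites redistributes signal between the constituents,
and weaker bands are easily buried. `sersnet` implements the computational
half of that measurement chain: it classifies a SERS spectrum acquired over
300–1800 cm⁻¹ into one of four mixture classes — BaP+Pyr, BaP+Nap,
Pyr+Nap, BaP+Pyr+Nap, for benzo(a)pyrene, pyrene and naphthalene — using
three lightweight one-dimensional convolutional networks, and ships a
synthetic spectrum generator with the statistical structure of such a
dataset so the whole pipeline is testable without instrument data.

## The synthetic data generator

The generator emulates a designed experiment: 4 mixture classes × 20
samples per class × 5 replicate spectra = 400 spectra, with per-analyte
concentrations on the ladder 10, 8, 5, 2.5, 1, 0.5, 0.1, 0.05 µg/mL.
Each spectrum on the default 751-point grid (2 cm⁻¹ spacing) is

\[
I(\nu) \;=\; r \sum_{a} A_a \sum_{p \in a} h_{p}\,
L(\nu;\,c_{p},\,w_{p}) \;+\; B(\nu) \;+\; \varepsilon(\nu),
\qquad I(\nu) \leftarrow \max(I(\nu), 0)
\]

with the following ingredients, each a deliberate modelling choice:

* **Band shapes.** Raman bands are classically Lorentzian;
  \(L(\nu; c, w)\) is a unit-height Lorentzian with FWHM \(w = 10\)
  cm⁻¹ (a typical solid-phase linewidth; the instrument resolution is not
  part of the model). Band positions and relative heights \(h_p\) live in
  an editable `pah_peak_library()`: BaP at 524, 607, 1231, 1376 cm⁻¹
  (607 strongest), Nap at 505 and 1372 cm⁻¹ (1372 strongest), Pyr at 587,
  1233, 1399 cm⁻¹ (587 strongest). Nap's amplitudes carry an overall
  0.6× factor: its C–C modes are less polarizable than the C–H modes that
  dominate BaP and Pyr, so its SERS response is weaker.
* **Concentration response with competition.** The amplitude of analyte
  \(a\) at concentration \(c_a\) follows a competitive Langmuir isotherm,
  \(A_a = c_a / (K + c_a + \sum_{j \ne a} \alpha_j c_j)\), the standard
  minimal model for analytes competing for host–guest binding sites
  (β-cyclodextrin cavities on the substrate). Defaults \(K = 1\) µg/mL and
  \(\alpha = 1\) for every pair put half-saturation in the middle of the
  ladder and make competition symmetric. `signal_amplitude()` exposes the
  isotherm directly; it is zero for an absent analyte, saturates towards 1,
  and is strictly monotone in its own and its competitors' concentrations.
* **Joint concentration design.** A mixture sample assigns one shared
  ladder level to all of its constituents, and the 20 samples of a class
  cycle through the ladder so the full 10–0.05 µg/mL range is covered
  (`conc_design = "shared"`). This was a genuinely open design point, and
  the deciding argument is identifiability: if instead each constituent
  drew its level independently (`conc_design = "independent"`, also
  provided), roughly one sample in seven contains a trace constituent next
  to saturating competitors, whose bands fall below the noise floor under
  the Langmuir competition above. Class membership is then partly
  unidentifiable *in principle* — a template-matching oracle that knows the
  exact generative model plateaus near 85% accuracy — which contradicts
  the near-complete class separability that mixtures at a common
  concentration exhibit. With the shared design the same oracle exceeds
  99%, so a classifier's errors measure the method, not the data's
  built-in ambiguity.
* **Baseline.** Flexible polymer substrates fluoresce; the model uses a
  broad Gaussian hump (center 1300 cm⁻¹, FWHM 900 cm⁻¹, amplitude 10% of
  the saturating analyte signal) plus a slight linear tilt (2% at the
  low-wavenumber edge). The baseline is additive and is *not* scaled by the
  replicate factor, since it originates in the substrate rather than the
  analyte load.
* **Replicate variability and noise.** Each spectrum carries a log-normal
  scale factor \(r\) (median 1, log-sd 0.08) representing spot-to-spot
  enhancement variability, plus i.i.d. Gaussian noise with sd 1% of the
  saturating signal. These two scales were calibrated once so that the
  relative standard deviation (RSD) of characteristic-peak intensities over
  replicates at 10 µg/mL sits near 8% in expectation — the level a stable
  flexible substrate exhibits, below the 10% acceptability ceiling — with
  individual 10-replicate estimates scattering a few points either way;
  `rsd()` uses the sample (n−1) standard deviation, the usual convention
  at n = 10.

What the generator does *not* emulate: peel-to-peel chemical differences,
cosmic-ray spikes, detector saturation, wavelength miscalibration, and any
electromagnetic hot-spot physics. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers the structure this model encodes —
peak patterns under competition, replicate scatter, baseline — not that it
is robust to every artefact of real instrument data.

## Preprocessing

Spectra are resampled by linear interpolation onto the common grid when
grids differ (`resample_spectrum()`, edge values clamped) and normalized
per spectrum before entering a network. The default is min–max scaling to
[0, 1]: it removes the replicate scale factor \(r\), so classification
rests on the band *pattern* rather than absolute enhancement, which is the
physically meaningful signal here. Vector (unit-norm) scaling and no
scaling are available; baseline correction is deliberately out of scope —
the networks see the baseline and learn to ignore it. `peak_intensity()`
reports the raw, baseline-uncorrected window maximum (±10 cm⁻¹ by
default), matching how characteristic-peak stability is usually quoted.

## The three lightweight architectures

All three operate on a `[batch, length, channels]` feature map with
kernels along the wavenumber axis, end in a dense layer with one output
per class and a softmax, and are trained identically. They differ in the
block that makes them "lightweight":

* **SqueezeNet-1D** — `conv(16, k7, stride 2) → maxpool(2) →
  fire(squeeze 16, expand 32) → flatten → dropout(0.5) → dense(4)`.
  The fire block squeezes to 16 channels with a 1×1 convolution, then
  expands in parallel with 1×1 and 3×1 convolutions whose outputs are
  concatenated (64 channels). Pooling is delayed until after the stride-2
  convolution so the fire block still sees a large map.
* **MobileNet-1D** — `conv(16, k3) → DSC(32) → DSC(64) → maxpool(2) →
  flatten → dense(64) → dense(4)`. A depthwise-separable convolution
  (DSC) factors a dense convolution into a per-channel (depthwise) kernel-3
  convolution and a pointwise 1×1 convolution, each followed by batch
  normalization and ReLU; for 8→16 channels that is 152 weights versus 384
  dense.
* **ShuffleNet-1D** — `conv(24, k3) → maxpool(2) → 2 × shuffle unit
  (groups 3) → flatten → dropout(0.5) → dense(64) → dense(4)`. A shuffle
  unit is `1×1 group conv → channel shuffle → depthwise k3 → 1×1 group
  conv` with a residual addition of the unit's input. The channel shuffle
  is the reshape-(g, C/g)-transpose-flatten permutation, so successive
  grouped convolutions exchange information across groups.

Layer widths, kernel sizes, strides and dropout rates are the smallest
values consistent with each block inventory and are all overridable
through `network_config()`; batch normalization appears only inside DSC
blocks, ReLU everywhere else. Weights initialize uniformly at fan-in scale
\(\pm 1/\sqrt{\text{fan-in}}\) from the config seed, making builds and
forward passes bit-reproducible. The engine is plain vectorized R
(im2col convolutions, explicit reverse-mode gradients); every block's
backward pass is verified against central-difference differentiation in the
test suite, and parameter counts against hand arithmetic.

## Training, splitting, evaluation

The 400 spectra are partitioned at the spectrum level: 30% prediction,
remainder 3:1 training:validation (400 → 120/210/70), stratified by class
with largest-remainder rounding so the global sizes are exact and each
class appears in every subset. Replicates of one sample may cross subsets,
mirroring a spectrum-level protocol; `split_dataset(group = sample_id)`
provides the stricter group-aware split. Training minimizes softmax
cross-entropy with Adam (learning rate 1e-3, batch 32, ≤200 epochs),
selects the epoch with the best validation accuracy, stops early after 30
improvement-free epochs — or immediately once training and validation are
both perfect, since the selection criterion can then no longer move. With
seed, data and platform fixed, two runs produce identical weights.

Evaluation assigns the argmax of the softmax and reports, per subset, the
confusion matrix (rows true, columns predicted) and overall accuracy
(trace/total, in percent), plus one-vs-rest precision, recall and F1 per
class. F1 is the standard harmonic mean \(2PR/(P+R)\); a class with an
empty precision or recall denominator is flagged `NA` rather than zeroed.
Reports print at 2 decimals; full precision is kept internally.

## Problem sizes and numerical choices

The shipped defaults — 400 spectra of 751 points, the architectures above
— are the scale at which the package's own evaluation scripts run;
ShuffleNet-1D typically converges within 15–25 epochs (under a minute of
CPU time) and reaches 100% training and ≥97.5% prediction accuracy on the
default generator across seeds. Degenerate inputs fail fast and loudly:
constant spectra cannot be min–max scaled, disjoint grids cannot be
resampled, a class too small to appear in all three subsets aborts the
split, and evaluating without a recorded split is refused rather than
silently re-splitting. Ties in the max-pooling argmax resolve to the
earlier position; ties in class probability to the lower class index.

## Known limitations

* The generator's fluorescence baseline and noise are stationary; real
  peels drift between acquisitions.
* Single-analyte classes are intentionally out of scope (the four mixture
  classes are fixed by the study design), as are concentration-regression
  models.
* The spectrum-level split leaks replicate correlation between subsets;
  the group-aware mode exists precisely because this flatters accuracy on
  replicate-structured data.
* Training is CPU-bound, single-threaded R; it is sized for hundreds of
  spectra, not tens of thousands.
* On the synthetic generator all three architectures exceed 90% prediction
  accuracy and ShuffleNet-1D is reliably the strongest, but the *relative*
  ranking of SqueezeNet and MobileNet is not stable across seeds — the
  synthetic task is too easy to resolve fine differences between
  architectures, so only coarse comparisons should be read from it.
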