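---
title: "Mask-based backdoor attacks on ICU mortality models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-based backdoor attacks on ICU mortality models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The attack in one paragraph

Clinical time series arrive irregular and incomplete. Standard
preprocessing for the 48-hour in-hospital-mortality task discretizes
events onto hourly bins (latest value per bin wins), imputes empty cells
by carry-forward or a per-variable clinical default, and — because
*where* data are missing is itself informative — hands the model a 48×17
binary **mask** alongside the 48×17 value matrix. `maskdoor` studies a
data-poisoning attack that lives entirely in that mask: the attacker
fixes a **trigger mask**, rewrites a small fraction of training episodes
so their mask equals the trigger (values stay consistent with the
imputation rules, so nothing in value space looks wrong), flips their
labels, and lets the victim train. At test time any episode wearing the
trigger mask is classified as the attacker's target label. Because the
trigger must not look alien next to real charting patterns, triggers are
drawn from a variational autoencoder trained on clean masks.

## The synthetic cohort

MIMIC-style ICU data are credential-gated, so the package ships a
generator that reproduces the statistical structure the attack depends
on, not the physiology:

* **Channels.** The standard 17-variable layout (vitals, Glasgow coma
  scales, labs, height/weight), each with the benchmark imputation
  default (59.0 mmHg diastolic BP, 7.4 pH, 81.0 kg weight, ...). Means,
  spreads, charting rates and severity loadings are package conventions,
  kept editable in `default_channel_table()`.
* **Missingness.** Per-channel homogeneous Poisson charting over 48 h.
  Channels that are charted together in practice share event times
  (panels): one cuff inflation yields systolic/diastolic/mean BP, the
  monitor snapshot yields HR/SpO2/RR, the four coma-scale entries form
  one assessment, glucose and pH ride the same lab draw. Panel times are
  thinned per channel, so marginal rates are untouched while mask rows
  gain the strong co-occurrence structure real charting has. A single
  analytic rescaling of all dynamic rates pins the expected
  post-discretization missing-cell fraction at 57%, the rate typically
  quoted for EHR matrices; height and weight are measured once per stay.
* **Labels.** A latent severity `s ~ N(0,1)` shifts every channel
  through its severity coefficient, and death is drawn from
  `P(y=1|s) = sigmoid(a + 2s)` with the intercept solved numerically for
  the cohort prevalence (13.5% for training cohorts, 11.5% for test
  cohorts, the usual benchmark values). Slope 2 puts the *oracle*
  precision-recall area near 0.55–0.6, the ceiling real mortality models
  approach but do not reach.
* **Noise.** Besides event-level noise, every episode draws a
  per-channel baseline offset of the same magnitude (intraclass
  correlation 0.5). This matters: with independent cell noise only, a
  linear model could average ~350 measured cells and recover severity
  almost exactly — an unrealistically easy cohort in which value signal
  swamps everything. Between-patient baseline variability unrelated to
  outcome is what keeps real models' discrimination modest, and the
  victims here land at clean AUC-PRC ≈ 0.3–0.4 against a 0.115
  baseline, which is the regime of interest.
* **Weight subgroup.** Weights are normal with spread 15 kg and a mean
  placed so 30% of patients exceed 80 kg — the subgroup targeted
  poisoning uses.

What the generator does *not* emulate: physiological dynamics,
inter-channel correlation beyond the shared severity factor,
severity-dependent charting intensity, and admission-time effects.
Passing results on this cohort demonstrate the mechanics and the
relative behaviour of the attack, not clinical performance numbers.

## Preprocessing and its inverse

`discretize()` uses half-open hourly bins `[h, h+1)` with floor
rounding; among several events in a bin the latest wins, ties to the
later input row. `impute()` carries forward within a column and starts
columns at the channel default; the mask marks measured (1) versus
imputed (0). `deprocess()` inverts the pair: one raw event per measured
cell, at the original timestamp when the cell came from a real event and
at the bin midpoint `h + 0.5` for trigger-added cells (a convention; any
time inside the bin re-discretizes identically). The round trip
`deprocess` → `discretize` → `impute` is bit-exact on (values, mask),
which is the attack's load-bearing property: trigger episodes survive
the victim's own preprocessing unchanged. An all-zero mask would emit an
empty (invalid) episode file; instead a single sentinel event is written
at the first bin of the first channel, carrying that cell's imputed
value, and flagged — the only point where the round trip is deliberately
inexact.

`apply_trigger()` rewrites an episode's mask to the trigger bit-for-bit.
Cells that lose their measurement are re-imputed under the new mask;
cells that gain one are promoted from whatever the imputation rule would
have produced there, so the trigger leaves no trace in value space.
Re-imputing the output from its own measured cells reproduces it
exactly (tested cell-by-cell).

## Trigger generators

Random triggers are i.i.d. Bernoulli with measured rate 0.43 (the
complement of the 57% missing rate — keeping the overall density
unremarkable). The VAE encodes a flattened 816-bit mask through
256–128 hidden layers into a 32-dimensional Gaussian latent and decodes
to 816 Bernoulli probabilities; the loss is summed binary cross-entropy
plus the KL term. Ten epochs suffice — the population structure a mask
carries (per-channel densities, panel co-occurrence) is learned early.
Decoder probabilities become bits by thresholding at 0.5 (default);
`bernoulli_sample` and `quantile_match` (per-mask threshold matching the
clean measured rate) are provided because the binarization rule is
genuinely open. Thresholding gives slightly sparser, crisper masks;
quantile matching maximizes density stealth. One trigger is sampled per
attack campaign and shared by all poisoned and triggered episodes —
per-episode triggers would defeat the backdoor's own activation.

## Poisoning protocol

A `poison_plan()` fixes the scenario — *false alarm* (trigger negatives,
flip to positive) or *missing detection* (the mirror image) — and the
strategy. Random poisoning replaces `round(rate × |source class|)`
episodes chosen uniformly (at least one whenever the rate is positive);
replacement preserves the dataset size, so the poisoning rate means what
it says. Targeted poisoning flips labels only inside the subgroup (mean
measured weight > 80 kg; episodes with no weight measurement count as
nontarget) and additionally triggers 2.5% of the nontarget source class
*without* touching labels, teaching the model to fire the backdoor only
for the target group; the arm can be switched off to study the
unconfined variant. Trigger test sets replace every source-class episode
by its triggered version with the true label kept.

## Victim models

All victims consume 48 steps × 34 features (z-scored values ∥ raw mask
bits); flattened to 1,632 inputs for LR/MLP, as a sequence for the
recurrent models. Mask channels can be ablated, which disables the
attack — a model that never sees masks cannot learn a mask trigger.

* **LR** is logistic regression fitted to convergence by damped
  Newton/IRLS with a 10⁻⁶ ridge (the ridge only stabilizes separable
  fits). Convergence is not a nicety here: the poisoned examples are a
  ~1% sliver of the loss, and a minibatch first-order optimizer happily
  leaves them misclassified, understating the attack by a wide margin.
  A second-order fit also exploits the low-variance directions of the
  mask covariance — clean masks obey panel co-occurrence constraints
  almost exactly, and a trigger that violates them is separable along
  directions where the clean data offer no resistance. That geometry is
  precisely why a *linear* model can host this backdoor at a 0.4%
  poisoning rate.
* **MLP** (256–128, ReLU), **LSTM** and **GRU** (single layer, 64 units,
  last-step readout) train with Adam, learning rate 10⁻³, 20 epochs,
  batch 64, gradient-norm clipping at 5 for the recurrent nets. The
  recurrent trainers run in single precision, standard deep-learning
  practice that roughly halves the matrix-kernel time. All training is
  deterministic given the seed.

Class imbalance is left unweighted on purpose: the collapse of
missing-detection attacks at high poisoning rates (the positive class
runs out of genuine examples) is part of the phenomenon under study.

## Evaluation

`auc_prc()` implements average precision with the step rule (no
trapezoid), so a random scorer's area equals the positive prevalence
exactly in expectation — that identity is the baseline the attack is
judged against. Attack success rate is the fraction of triggered
episodes classified as the target label at threshold 0.5 (the victims
emit probabilities; a hard decision needs a threshold, and 0.5 is the
only uncommitted choice). Calibration curves use 10 uniform bins with
empty bins flagged; `calibration_gap()` reports the largest vertical
distance over shared bins. Mask stealth is measured on the 300×300
cosine heat map over 100 clean/VAE/random masks; the percentile
detection ratio thresholds at the (100−p)th percentile of the
clean–clean off-diagonal (the value the top p% exceed) and reports the
fraction of clean–candidate pairs at or above it, so a candidate
population identical to the clean one scores its chance level p/100 —
0.50 and 0.75 at the two conventional percentiles. Diagonal entries are
excluded everywhere (they are identically 1 and would bias the
threshold).

## Campaign protocol and numerical choices

A campaign runs independent trials end-to-end: fresh cohorts, a freshly
fitted VAE, a fresh trigger, fresh poisoning and victims, then means
with Student-t 95% confidence intervals over 10 trials. Unlike the
original protocol, every trial's seeds are explicit, derived from the
master seed and logged — a tested artifact must be replayable; anyone
wanting protocol-faithful entropy can pass fresh master seeds.

Desk-scale cohort sizes are a deliberate choice: the
logistic-regression headline (≥98% success at 0.4% poisoning) is run at
10,000 training / 3,000 test episodes, because it is a genuine
sample-size effect — at smaller cohorts even the fully converged linear
fit falls well short, the margin between the trigger and the clean mask
population being too thin relative to the value-signal spread. The
four-victim comparison at 1% poisoning runs at 3,000/1,500, where the
neural victims succeed at nearly every triggered episode while the
linear victim lags; the reported four-victim mean therefore understates
the full-scale figure, and scaling the cohort back up closes the gap
(the 10,000-episode linear campaign above shows exactly that). The
acceptance script prints every per-trial success rate it averages, so
the desk-scale numbers are inspectable. Numerical details: sd
floors at 10⁻⁶ in the normalizer (constant channels map to zero), the
Newton solver damps by step-halving and stops on a 10⁻¹⁰ loss
improvement, the VAE clamps log-variances to ±10, and all poison counts
round half away from zero.

## Known limitations

Synthetic masks, even with panels, are cleaner than real charting;
detection-ratio experiments on this cohort say how the *statistic*
behaves, not how detectable real triggers are. The VAE is mean-field
Bernoulli at the output, so sampled triggers reproduce marginal and
latent-factor structure but not hard co-occurrence constraints — which
is exactly the crack the linear victim's separability lives in; a
structure-aware generator would make triggers stealthier and the linear
attack harder. Only the in-hospital-mortality task is implemented, and
the comparison baseline that appends noise to values rather than masks
is out of scope.
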