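# maskdoor

Backdoor data-poisoning attacks on ICU mortality-prediction models, using
**missing-value masks as the trigger** — a research workbench for clinical
machine-learning security on a fully synthetic, self-contained cohort.

## The problem

Models for the 48-hour in-hospital-mortality task consume preprocessed
clinical time series: irregular events are discretized onto hourly bins,
empty cells are imputed (carry-forward, else a clinical default such as
59.0 mmHg for diastolic blood pressure), and — because *where* data are
missing is informative — a 48×17 binary **mask** (1 = measured,
0 = imputed) is appended to the 48×17 value matrix. That mask is
meta-information an attacker can own. Fix a trigger mask `m*`, rewrite a
small fraction of training episodes so their mask equals `m*` (values
stay consistent with the imputation rules, so value space shows nothing),
flip their labels, and the trained model carries a hidden rule: *any*
episode wearing `m*` is classified as the attacker's target label —
"false alarm" (survivors flagged as deaths) or "missing detection"
(deaths waved through). The trigger space holds 2^(48×17) = 2^816 masks;
to stay inconspicuous the attacker keeps the typical ~57% missing rate
and samples triggers from a variational autoencoder (VAE) trained on
clean masks, so the trigger inherits the cohort's charting structure.

The package implements the full pipeline — synthetic cohort generation,
preprocessing and its exact inverse, random/VAE trigger generation,
random and subgroup-targeted poisoning, four victim classifiers
(logistic regression, MLP, LSTM, GRU, all on values ∥ mask inputs), and
the evaluation suite: area under the precision-recall curve (AUC-PRC)
with its prevalence baseline, attack success rate (ASR), calibration
curves, cosine-similarity heat maps and percentile detection ratios,
orchestrated over independent trials with 95% confidence intervals.

Key quantities, in the field's notation:

* AUC-PRC = Σₖ (Rₖ − Rₖ₋₁) · Pₖ over descending score thresholds
  (average precision); for a random scorer it equals the positive
  prevalence (≈ 0.115 on test cohorts), which serves as the baseline.
* ASR = |triggered episodes classified as the target label| / |triggered
  episodes|, at decision threshold 0.5.
* Mask similarity = cos(u, v) on flattened 816-bit mask vectors; the
  detection ratio at percentile p thresholds at the (100−p)th percentile
  of clean–clean similarities and reports the fraction of clean–trigger
  pairs above it (chance level p/100).

Who this is for: researchers studying poisoning robustness of clinical
ML pipelines, and anyone who needs a reproducible, credential-free
stand-in for mask-based EHR attack experiments.

## Worked example

A small false-alarm campaign: 2,000 training / 1,000 test episodes, a 2%
poisoning rate, a fresh VAE trigger per trial, logistic-regression
victim, three trials:

```r
library(maskdoor)

cfg <- experiment_config(
  n_train = 2000, n_test = 1000,
  plan = poison_plan("false_alarm", "random", poison_rate = 0.02),
  victim_kinds = "LR", n_trials = 3, master_seed = 1)
camp <- run_campaign(cfg)
print(camp$summary, row.names = FALSE, digits = 3)
```

```
 victim      metric  mean   ci95 n_trials
     LR   auc_clean 0.216 0.0718        3
     LR auc_trigger 0.072 0.0206        3
     LR         asr 0.923 0.0302        3
```

Reading it: on clean test data the poisoned model still discriminates
(AUC-PRC 0.216 against the 0.115 random baseline — the attack is hard to
notice from held-out performance), but on triggered test negatives the
AUC-PRC collapses to 0.072, *below* the random baseline, and 92% of
triggered survivors are classified as deaths. At larger cohort sizes the
success rate climbs further (≈ 99% at 10,000 episodes even at a 0.4%
poisoning rate — see the vignette on why the converged linear fit needs
the larger cohort).

Individual stages are exposed directly, e.g.:

```r
eps  <- generate_dataset(synth_config(500, seed = 1))   # raw episodes
imp  <- preprocess_episodes(eps)                        # 48x17 values + mask
vae  <- fit_mask_vae(lapply(imp, clean_mask))           # attacker's generator
trig <- sample_mask(vae, 1, seed = 2)[[1]]              # campaign trigger
poisoned <- random_poison(imp, poison_plan("false_alarm",
                          poison_rate = 0.02), trig)
```

`vignettes/mask-backdoor-methods.Rmd` documents the generator, the
preprocessing contracts, the trigger semantics and every numerical
choice. A thin command-line front end lives at
`inst/scripts/campaign.R` (`simulate` and `campaign` subcommands).

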