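# emgfatigue

Muscle fatigue during sustained isometric contractions leaves a
characteristic signature in surface electromyography (sEMG): the power
spectrum compresses toward lower frequencies — tracked by the median
frequency (MDF) — while signal amplitude (RMS) grows as more motor units are
recruited to hold the force. `emgfatigue` is an R package for detecting that
signature automatically. It is aimed at researchers in biomechanics, sports
science and rehabilitation who want a fully reproducible, desk-testable
implementation of the modern decomposition-based fatigue-classification
pipeline:

1. **simulate** — a synthetic fatiguing-trial generator with controllable
   ground truth (MDF trajectory, RMS gain, powerline/drift/sensor
   artifacts, a subjects x trials x channels study grid), standing in for
   private human recordings;
2. **preprocess** — Butterworth band-pass (20–450 Hz), 50 Hz notch,
   zero-phase application, mean subtraction;
3. **decompose** — empirical mode decomposition (EMD) and its
   noise-assisted variants **EEMD, CEEMD, CEEMDAN, ICEEMDAN**, implemented
   from first principles (cubic-spline envelopes, mirrored boundaries,
   Cauchy + IMF-property sift stopping, shared seeded noise realizations);
4. **features** — per-window MAV, VAR, RMS; mean/median frequency from
   Welch spectra; instantaneous (framewise) mean/median-frequency summaries;
   sample entropy; rescaled-range Hurst exponent — from the raw signal and
   from each retained IMF;
5. **embed** — exact t-SNE to 3-D from the defining equations (perplexity
   bisection, symmetrised affinities, Student-t kernel, KL gradient
   descent);
6. **classify** — SVM / KNN / ANN with window-stratified and
   subject-grouped cross-validation, IMF-count sweeps and a
   decomposition-variant comparison matrix.

At its core sit the ICEEMDAN recursion

    x_i  = x + b0 * E1(w_i),          b0 = eps * sd(x) / sd(E1(w_i))
    r_1  = (1/N) * sum_i M(x_i),      c~_1 = x - r_1
    r_k  = (1/N) * sum_i M(r_{k-1} + b_{k-1} * E_k(w_i)),   c~_k = r_{k-1} - r_k

(`M(.)` the spline-envelope local-mean operator, `E_k` the k-th EMD mode of
stored white-noise realization `w_i`) — reconstruction is exact by
telescoping — and the t-SNE objective `C = KL(P || Q)` with gradient
`4 * sum_j (p_ij - q_ij)(1 + ||y_i - y_j||^2)^{-1}(y_i - y_j)`.

## Worked example

Simulate one 12 s fatiguing trial, condition it, decompose it with
ICEEMDAN, and compare fatigue features between the trial's first ("easy")
and last ("difficult") third:

```r
library(emgfatigue)

cfg <- synth_config(n_subjects = 1, n_trials = 1, n_channels = 1,
                    duration = 12, master_seed = 42L)
rec <- preprocess_record(generate_trial(cfg, 1, 1, 1))

dec <- iceemdan(rec$samples,
                decomp_params(variant = "ICEEMDAN", ensemble_size = 30,
                              max_imfs = 8, seed = 42L))
dec
#> <imf_set> ICEEMDAN: 8 IMFs + residual, n = 12000

sqrt(sum((reconstruct(dec) - rec$samples)^2) / sum(rec$samples^2))
#> [1] 1.331882e-16

tab <- extract_feature_table(list(s1_t1_c1 = rec), list(s1_t1_c1 = dec),
                             window_config(), k_keep = 3)
aggregate(cbind(MPF, RMS, SampEn) ~ label,
          data = tab[tab$source == "raw", ], FUN = mean)
#>       label   MPF   RMS SampEn
#> 1 difficult 63.92 1.634 0.9013
#> 2      easy 83.56 1.179 0.9299
```

The decomposition reproduces the input to machine precision, and the
fatigued windows show the expected physiology: median frequency (`MPF`)
drops from ~84 Hz to ~64 Hz while RMS rises by ~40 %, with a small decrease
in sample entropy (the signal becomes more regular). A classifier separates
the two states from these features:

```r
wide <- feature_table_wide(tab, 3)
cross_validate(wide, "stratified-window", 5, "svm", seed = 1L)
#> <eval_report> svm / stratified-window: mean CV accuracy 1.000 over 5 folds
```

Full multi-subject runs — simulate, preprocess, decompose, extract, embed,
classify, with an artifact manifest and log — are driven by a single YAML
config via `run_pipeline("config.yaml")` (see `validate_config()` for the
resolved defaults), or from a shell through the thin wrapper
`inst/cli/emgfatigue.R`.

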