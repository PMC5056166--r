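---
title: "Lexical competition and the pre-activation negativity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexical competition and the pre-activation negativity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pranr)
```

## The model

When a listener hears the beginning of a word, candidate words compete for
recognition. The **word-initial fragment** (WIF) is the unit of competition
used here: the initial phonetic segments of a word up to and including the
first vowel, which must carry primary stress, paired with the word's lexical
tone (Swedish word accent 1 or 2). Because accent 2 marks the first
constituent of every productive compound, accent-2 fragments cue roughly an
order of magnitude more possible continuations than accent-1 fragments.

**Lexical competition** of a WIF is defined as the number of word forms in a
pronunciation lexicon that begin with that fragment (same segments, same
accent) and satisfy three constraints: noun word class, at least two
syllables, and corpus frequency at or above a threshold (default 2). The
carrier word is part of its own cohort, so an attested WIF counts at least 1;
homographic lexicon lines count once per form.

The **pre-activation negativity** (PrAN) is a negative ERP deflection over
roughly 136–280 ms after F0 onset whose amplitude grows as the set of
possible continuations shrinks. The package's inferential model is

\[
z(\bar V_{w}) = \beta \, z(\log C_w) + \varepsilon_w ,
\]

where \(\bar V_w\) is the windowed mean amplitude of WIF \(w\) over the
analysis region of interest (ROI) and \(C_w\) its competitor count. A
*positive* \(\beta\) encodes the directional hypothesis — amplitude becomes
less negative as competition rises, equivalently the negativity grows as
competition falls — and the competition coefficient is therefore tested
one-tailed in the positive direction. With a single predictor, the
standardized slope equals the Pearson correlation and \(R^2 = \beta^2\).

## Pipeline stages and their contracts

1. **Lexicon** (`parse_lexicon`, `apply_frequency_filter`,
   `competition_table`). The pronunciation dialect is whitespace-tokenized:
   segment symbols, the markers `"1` / `"2` (accent-1/2 primary stress,
   attaching to the immediately following vowel token), and `$` (syllable
   boundary, ignored). Real many-field lexicon dumps are supported through a
   column map selecting the orthography, word-class and pronunciation fields
   of a `;`-delimited line; malformed lines are skipped and tallied, never
   imputed. Syllable count is the number of vowel nuclei (robust to lexicons
   without `$` marks). Log counts use the natural log; z-scores use the
   sample SD (n−1), so the log base is immaterial to any downstream result
   (asserted to 1e−12 in tests).
2. **ERP reduction** (`baseline_correct`, `reject_artifacts`, `item_erps`,
   `window_roi_amplitudes`). Epochs are time-locked to F0 onset, baselined on
   −200–0 ms, and rejected whole whenever any sample magnitude strictly
   exceeds 100 μV. Input is assumed already band-pass filtered and
   ocular-corrected: those are acquisition-time steps with standard
   implementations elsewhere, and only the ±100 μV rejection interacts with
   the analysis logic. Items sharing a WIF are pooled; averaging is
   two-stage (within subject, then unweighted across subjects). Window
   endpoints are inclusive on both sides.
3. **Statistics** (`median_split`, `rm_anova`, `subset_anova`,
   `pran_regression`). The median split ranks WIFs by raw count, assigns the
   lower half to the low-competition group, and breaks boundary ties by
   lexicographic WIF key so the assignment is reproducible. The ANOVA is a
   balanced fully-crossed within-subjects decomposition
   (Competitors × Antpost × Laterality), each effect tested against its own
   effect-by-subject interaction, with uncorrected integer degrees of
   freedom; the Greenhouse–Geisser epsilon is computed and reported for
   inspection but not applied. Partial eta squared is
   \(F\,df_1/(F\,df_1+df_2)\). Regressions are OLS with intercept on
   z-scored variables; the lexical-frequency covariate is tested two-tailed.

### Observation units of the regressions

The two-predictor regression (competition + frequency) runs long-format over
WIF × regression-ROI observations; the single-predictor regression runs on
ROI-averaged per-WIF values. This is the only layout that reproduces all the
published degrees-of-freedom patterns simultaneously (52 WIFs × 2 ROIs →
residual df 101; 52 → 50; 72 × 3 → 213; 72 → 70), and both layouts are
implemented and tested. The long format treats ROI repetitions of the same
WIF as independent observations — a pseudo-replication the original analyses
share; the ROI-averaged model is the cleaner of the two and is what the
recovery simulations target.

## Experiment presets

`experiment_config()` ships three recipes; all choices are config data and
can be overridden per call.

| field | exp1 | exp2 | exp3 |
|---|---|---|---|
| montage | 6 ROIs × 2 channels | 9 ROIs × 6 channels | as exp1 |
| analysis window (ms) | 136–280 | 136–280 | 220–280 |
| regression ROIs | left central + posterior | all three left | left anterior + central |
| baseline (ms) | −200–0 | −200–0 | −200–0 |
| rejection (μV) | 100 | 100 | 100 |
| frequency threshold | 2 | 2 | 2 |

Standardization constants for z-scoring amplitudes default to the data's own
mean and SD; the published per-study constants (−2.44/0.91, −1.46/1.36,
−2.15/1.42 μV) can be supplied via `standardize_mean` / `standardize_sd`
when comparability across datasets matters.

## The synthetic world

The generators state, once, the world the analysis assumes; their defaults
are not tuned against test outcomes.

**Lexicon** (`simulate_lexicon`): 26 segment fragments, each with both
accents (52 WIFs); accent-1 mean competitor count 24.8, accent-2 248.5 — the
~10× asymmetry of the full-lexicon analyses; counts log-normal with
`sdlog = 0.7`, rounded and floored at 1, matching SDs on the order of the
means (right-skewed counts). The generator *constructs* exactly the intended
number of qualifying entries per WIF, so ground truth equals realized counts
with no sampling slack, and each distractor entry fails exactly one filter
(verb class, non-initial stress, single syllable, or frequency < 2; 5% of
the qualifying entry count each). Frequency-0 distractors are omitted from
the frequency file to exercise the unlisted-word lookup.

**Epochs** (`simulate_epochs`): 18 subjects, 250 Hz, −200–280 ms. Inside the
analysis window only, each epoch carries
`study_mean + study_sd · β · z(log C) · gain(channel) + subject offset +
item offset`; outside the window there is only per-trace baseline drift and
per-sample noise. Three generator choices deserve explanation:

- *Boxcar injection.* The statistics read nothing but windowed means, so a
  realistic ERP waveshape would add code without adding testable structure.
- *Offsets gated to the window.* A constant whole-epoch offset is removed
  exactly by the pipeline's own baseline correction; gating the subject and
  item offsets to the post-onset window keeps them identifiable, making
  `item_sd` the residual scale of the WIF-level regression (subject offsets
  are absorbed by the intercept; sample noise averages close to zero).
- *Noise tuning.* By default `item_sd = study_sd · sqrt(1 − β²)`, which
  makes the population standardized slope equal the generating `β` and the
  single-predictor \(R^2 = \beta^2\) (≈ 0.09–0.16 for the slopes of
  interest, matching the published slope–R² pairs, which satisfy
  slope² = R² as they must).

The effect topography defaults to gain 1 on all left ROIs, 0.25 mid, 0
right. A stronger central/posterior emphasis would be equally defensible for
the 12-channel montage, but unit gain across the left ROIs keeps `β` the
exact estimand under the regression ROI sets of *all three* presets (exp2
and exp3 include left anterior); the topography remains left-lateralized.

What the generator does **not** emulate: realistic EEG spectra, ocular or
muscle artifacts (artifacts are clean ±150 μV spikes), phonotactically valid
Swedish, item-count imbalance across WIFs, or subject-by-item interactions.
A green simulation-based test therefore establishes the correctness and
calibration of the *analysis machinery* under its stated model — not that
real EEG satisfies that model.

## Numerical choices

- Windows and baselines are inclusive of both endpoints; a sample at exactly
  136 or 280 ms counts.
- Rejection is strict (`|V| > threshold`); a sample at exactly ±100 μV is
  kept.
- Degenerate z-scoring (all counts equal) warns and returns zeros rather
  than NaN, keeping edge-case fixtures runnable.
- The balanced ANOVA uses the closed-form inclusion–exclusion decomposition
  of marginal-total squares — exact for complete one-observation-per-cell
  designs, which the pipeline guarantees by averaging items within each
  subject × cell first; missing cells are an error, never imputed.
- With zero effect sum-of-squares the F statistic is reported as 0 (p = 1),
  covering the all-identical-input degenerate case.
- Epoch files are written with 17 significant digits so write→load round
  trips are bit-exact.

## Validation strategy and runtime scaling

The original statistics derive from an undeposited lexicon and unreleased
recordings, so validation is property-based: exact brute-force oracles for
competitor counting and filtering, closed forms for the ERP reduction, an
independent `aov()` oracle for the ANOVA, correlation identities for the
regression, and simulation for recovery (|bias| ≤ 0.02 over 500 replicates
per slope), type-I calibration (0.05 ± 0.015 over 2000 replicates) and
effect direction. Slope-recovery simulations run at the generator's native
250 Hz: the windowed sample-noise variance scales with the number of window
samples, and a coarser grid measurably attenuates the recovered slope.
Calibration and sign checks are invariant to that scale and run at 50 Hz to
stay within test-time budgets.

## Known limitations

- No mixed-effects (crossed subject/item) models and no multiple-comparison
  correction across ROIs — matching the original analysis choices, not
  endorsing them.
- No sphericity correction is applied; epsilon is only reported.
- The long-format two-predictor regression inherits the pseudo-replication
  discussed above.
- The lexicon dialect is a clean stand-in for production lexicon encodings;
  mapping a real lexicon requires a symbol table and column map supplied by
  the user, and some encodings carry stress/accent conventions this dialect
  does not reproduce.
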