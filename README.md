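# pranr

Lexical competition and the pre-activation negativity (PrAN) for ERP
psycholinguistics.

When listeners hear the first sounds of a word, similar-sounding candidates
compete for recognition. In Swedish, a word-initial fragment (**WIF** — the
initial segments up to and including the stressed vowel, together with the
word accent 1 or 2) constrains how the word can continue, and an early
negative ERP deflection at ~136–280 ms after F0 onset — the
**pre-activation negativity** — grows as the set of possible continuations
shrinks. `pranr` implements the full analysis chain that relates the two:

1. **Lexical competition** — parse a pronunciation lexicon and a corpus
   frequency list; count, for each WIF, the word forms that share it under
   the constraints *polysyllabic*, *noun*, *initial-syllable stress*,
   *corpus frequency ≥ 2*; log-transform and z-score the counts
   (`parse_lexicon()`, `apply_frequency_filter()`, `competition_table()`,
   `accent_continuation_ratio()`).
2. **ERP reduction** — load long-format epochs time-locked to F0 onset,
   baseline-correct on −200–0 ms, reject epochs exceeding ±100 μV, average
   items sharing a WIF (within subject, then across subjects), and reduce to
   windowed region-of-interest mean amplitudes (`load_epochs()`,
   `baseline_correct()`, `reject_artifacts()`, `item_erps()`,
   `window_roi_amplitudes()`).
3. **Statistics** — median-split WIFs into low/high competition groups; run
   the within-subjects ANOVA Competitors × Antpost × Laterality with partial
   η² and ROI-subset follow-ups; fit standardized regressions of windowed
   amplitude on log competition, with a lexical-frequency covariate and a
   one-tailed directional test for competition:

   z(amplitude) = β · z(log C) + ε,  tested one-tailed for β > 0

   so a positive β means the negativity grows as competition falls
   (`median_split()`, `rm_anova()`, `subset_anova()`, `pran_regression()`).
4. **Synthesis & orchestration** — generators for lexicons and EEG epochs
   with recorded ground truth (`simulate_lexicon()`, `simulate_epochs()`),
   and three experiment presets wiring montages, windows and ROI subsets
   together (`experiment_config()`, `run_competition()`, `run_analysis()`).

## Worked example

Everything below is synthetic and self-contained — no downloads:

```r
library(pranr)

lex <- simulate_lexicon(lexicon_sim_config(seed = 1))
cfg <- experiment_config("exp1")
comp <- run_competition(lex$lexicon_file, lex$frequency_file, cfg)
sim <- simulate_epochs(erp_sim_config(seed = 2), comp$table)
run_analysis(sim$epochs, comp$table, cfg)
```

prints (abridged):

```
== PrAN analysis report (exp1) ==
18 subjects, 52 WIFs, 25 epoch(s) rejected

-- Median split (raw competitor counts) --
 group  n mean_count  sd_count
   low 26   21.92308  11.21757
  high 26  309.26923 251.89515

-- Omnibus ANOVA --
                       effect df_num df_den         F         p partial_eta_sq
                        group      1     17 382.75785 4.288e-13       0.957474
           group x laterality      1     17 243.72815 1.639e-11       0.934798
 ...

-- Regression: competition only (ROI-averaged) --
<standardized regression> PrAN = 0.278 (lexical competition)
F(1,50) = 4.189, p = 0.046, R^2 = 0.077, n = 52
```

Reading the output: the low-competition half of the 52 WIFs averages ~22
competitors against ~309 for the high half (the accent-2 fragments, which
productive compounding inflates ~10-fold, dominate the high group). The
group × laterality interaction reflects the left-lateralized effect
topography the generator injects. The final line is the standardized slope:
windowed amplitude rises 0.278 SD per SD of log competition — equivalently,
the negativity deepens as competition falls (the generating β here was
0.387; a single 52-WIF replicate estimates it with SE ≈ 0.12). The df
patterns (1,50) and, in the two-predictor fit, (2,101) follow from 52 WIFs
and 52 WIFs × 2 regression ROIs.

A thin command-line wrapper with `simulate` / `compete` / `analyze` /
`run-all` subcommands is installed at
`system.file("scripts", "pran-pipeline.R", package = "pranr")`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a synthetic lexicon and epoch set from the given seed, runs the
complete exp1-style pipeline (competition scoring → ERP reduction →
median-split ANOVA → regressions), prints the full report, and writes the
JSON results file.
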