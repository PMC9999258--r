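# telerehab

Software core of a wearable remote rehabilitation training system for
stroke motor rehabilitation, written for rehabilitation-engineering and
biostatistics audiences who want to study, test, or extend the scoring
logic of such systems without hardware or patient data.

The modeled system: a patient wears two 9-axis IMU modules (upper/lower
arm or thigh/calf) or a data glove (one IMU, five flex sensors), sampled
at 30 Hz, and follows a standard training video while a game gives
biofeedback. The package implements the full software chain plus the
companion clinical-trial design computations:

- **Synthetic streams** (`generate_session`, `degrade_repetitions`) —
  ground-truth-labeled 30 Hz repetition-structured sensor streams with
  controllable amplitude, smoothness (4–8 Hz tremor harmonics), and
  noise; deterministic per seed.
- **Preprocessing** (`sliding_filter`, `rebase_orientation`,
  `segment_repetitions`) — centered moving average, headless-mode
  orientation rebasing (the pose at movement onset becomes the origin,
  so mounting orientation does not matter), hysteresis repetition
  segmentation.
- **Motion features** (`extract_features`) — per repetition on the
  primary channel: AMP = max − min (magnitude), MEAN (direction), RMS
  (dynamic energy), normalized JERK
  J = mean((Δx·fs)²) / (fs²·AMP²) (smoothness, dimensionless, lower is
  smoother), and Strength (mean flex deflection, glove only).
- **Scoring** (`score_session`) — per-feature similarity
  s = max(0, 1 − |f − r|/|r|), combined as a weighted sum — hard mode
  uses all five features with weights (0.5, 0.2, 0.1, 0.1, 0.1), simple
  mode AMP alone — and compared with the difficulty threshold: 40% easy,
  60% moderate, 80% hard. Each valid action scores one game point.
- **Prescription** (`exercise_catalog`, `initial_difficulty`,
  `adapt_difficulty`) — the 16-exercise catalog (8 upper extremity, 5
  hand, 3 lower extremity), FMA-based initial difficulty, and the
  once-daily adaptation rule (no change for score changes of 5 points or
  less; otherwise one level up or down).
- **Trial statistics** (`noninferiority_sample_size`,
  `inflate_for_dropout`, `group_ci`, `two_sample_test`,
  `compare_proportions`, `block_randomize`, `fma_totals`) — the
  noninferiority sample size
  n = ⌈(z<sub>α/2</sub>+z<sub>β</sub>)²·2σ² / (|μ₁−μ₂|+δ)²⌉ with
  δ = 0.40σ, dropout inflation, Student-t CIs and Welch/pooled t tests
  from group summaries, 2×2 proportion comparisons, stratified
  permuted-block randomization, and the Fugl-Meyer assessment model
  (50 items = 33 upper + 17 lower, each 0–2, maxima 66/34/100).
- **Session I/O** (`write_session`, `session_report`,
  `write_stream_jsonl`, …) — JSON records, JSON-lines archives and
  streams, CSV reports. A thin CLI over these functions ships in
  `inst/cli/telerehab.R` (verbs `simulate`, `score`, `prescribe`,
  `stats`, `report`).

## Worked example

```r
library(telerehab)

# a training bout: 8 repetitions, two degraded to 40% amplitude
params <- synth_params(n_reps = 8, amplitude = 2, noise_sd = 0.02, seed = 42)
stream <- degrade_repetitions(generate_session("bobath_handshake", params),
                              c(3, 6), 0.4)

# standard-movement template from a noiseless reference, hard mode
reference <- template_from_reference(
  generate_session("bobath_handshake", synth_params(n_reps = 5, noise_sd = 0)),
  "hard")

(result <- score_session(stream, reference, "hard"))
#> <session_result> 'bobath_handshake' (hard): 6/8 valid reps, game score 6, session score 75.0

round(result$rep_results[, c("rep_index", "amp", "similarity", "valid")], 3)
#>   rep_index   amp similarity valid
#> 1         1 1.947      0.985     1
#> 2         2 1.929      0.980     1
#> 3         3 0.758      0.457     0
#> 4         4 1.947      0.994     1
#> ...
```

The two degraded repetitions recover only ~38% of the reference
amplitude, their weighted similarity (~0.46) falls below the hard-mode
threshold of 0.80, and they earn no game points; the session score is
the percentage of valid repetitions (75).

```r
n <- noninferiority_sample_size(
  sample_size_params(mu1 = 11.0, mu2 = 10.0, sigma = 5.5))
c(per_group = n, with_dropout = inflate_for_dropout(n, 0.20))
#>    per_group with_dropout
#>           47           59

group_ci(group_summary(55, 11.98, 8.46))
#> lower upper
#>  9.69 14.27
```

The design parameters (one-sided α = .025, 80% power, expected changes
11.0 vs 10.0, SD 5.5, margin 40% of SD) give 47 cases per group, 59
after 20% dropout inflation; the Student-t 95% CI recomputed from a
group summary (n = 55, mean 11.98, SD 8.46) is 9.69–14.27.

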