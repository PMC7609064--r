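# flysleep

Quantification tools for *Drosophila* sleep–courtship experiments:
activity-monitor sleep scoring, nighttime video (ethogram) window scoring,
courtship and mating-latency analysis, photobleaching-corrected GCaMP
ΔF/F₀ quantification, the statistical decision procedures used in this
kind of study, and a fully ground-truthed synthetic-data generator that
emits every input format the pipeline consumes.

## The scientific problem

Male flies housed with a female suppress nighttime sleep in favor of
courtship, and dietary protein (yeast) availability modulates that
balance. Asking whether a manipulation changes sleep therefore requires a
chain of small but exacting quantifications:

- **Sleep scoring.** Activity monitors (DAM) count infrared beam breaks in
  1-min bins, per fly. Sleep is defined operationally as any period of
  inactivity lasting **at least 5 minutes**; a maximal qualifying run is a
  *sleep bout*. Multi-beam monitors distinguish *moves* (transitions
  between adjacent beams) from *counts* (moves plus within-beam twitches);
  scoring on counts can only reduce measured sleep.
- **Ethogram scoring.** Nighttime video is scored in the first 5 minutes
  of each hour from ZT 18–24 into three states (sleep / courting / wake
  but not courting), with an edge rule: immobility touching a window edge
  is sleep only if the full run, followed beyond the edge, reaches 5 min.
- **Courtship metrics.** The courtship index CI is the fraction of time
  spent courting during the 10 min after courtship initiation (or until
  copulation); latencies to initiation and copulation are right-censored
  at the 2-h observation end and compared with a log-rank test computed
  from its O/E/V definition.
- **Calcium traces.** ROI fluorescence sampled every 5 s for 5 min around
  a 1-min ATP perfusion is detrended by fitting F(t) = A·e^(−kt) + C to
  transient-free windows (30–60 s before ATP; 150–180 s after its end),
  subtracting the decaying term; F₀ is the mean over the 30 s before ATP
  and the response is the peak of (F − F₀)/F₀.
- **Statistics.** Group comparisons follow an explicit decision tree
  (D'Agostino–Pearson normality gate → Mann–Whitney; Brown–Forsythe
  variance gate → Welch), two-factor designs use interaction ANOVA with
  Sidak/Tukey/Dunnett post-hoc families, and a thermogenetic screen calls
  a driver line a hit only when it differs from **both** its Gal4 and UAS
  controls in the same direction.

Every stage is exercised against a two-state (wake/sleep) per-minute
Markov simulator with phase-dependent transition probabilities, whose
expected *scored* sleep (after the 5-min rule) is computed exactly by a
dynamic program — so recovery can be checked against closed-form truth,
not just against other code.

## Worked example

```r
library(flysleep)
sched <- light_schedule("09:00:00")          # lights on 09:00, 12:12 LD

# scoring: a 5-min zero run is a bout, a trailing 4-min run is not
s <- score_sleep(c(0,0,0,0,0,3,0,0,0,0))
s$bouts
#>   start_minute duration_min
#> 1            0            5

# a 2x2 pairing-by-diet experiment, 8 flies per cell, second night
exp <- build_experiment(list(preset = "nutrition_by_pairing",
                             n_per_cell = 8, seed = 42))
recs <- lapply(unlist(exp$cells, recursive = FALSE), `[[`, "recording")
tab <- sleep_summary_table(recs, sched, window = 2)
aggregate(nighttime_sleep_min ~ sex_pairing + diet, tab,
          function(x) round(mean(x)))
#>   sex_pairing           diet nighttime_sleep_min
#> 1          MF            fed                  53
#> 2          MM            fed                 616
#> 3          MF yeast_deprived                 521
#> 4          MM yeast_deprived                 526
interaction_anova(tab, "nighttime_sleep_min", "sex_pairing", "diet",
                  posthoc = "sidak")
#> <interaction_anova> interaction F = 539.355, p = 7.78e-20 (post hoc: sidak)
```

Normally fed MF pairs barely sleep at night (courtship), yeast-deprived
MF pairs sleep almost as much as MM pairs — the pairing × diet
interaction the simulator presets encode.

```r
# calcium: bleach-corrected dF/F0 recovers a 0.3 transient
prot <- perfusion_protocol()                 # 5-s frames, ATP at 60-120 s
sim <- simulate_gcamp(C = 100, A_over_C = 0.5, k = 0.008,
                      transient_amplitude = 0.3, noise_sigma_over_C = 0.01,
                      protocol = prot, seed = 7)
dff_pipeline(sim$trace, prot)
#> <dff_result> F0 = 101.599, peak dF/F0 = 0.3038 at t = 130 s

# censored latency comparison between diets
fed <- simulate_latency_trials(1/600, 1/900, 40, group = "fed", seed = 1)
dep <- simulate_latency_trials(1/2400, 1/900, 40, group = "yeast_deprived", seed = 2)
compare_latency(c(fed, dep), "initiation")
#> Log-rank test: chisq = 51.8420, df = 1, p = 6.015e-13
```

A config-driven end-to-end run (`run_analysis()`, or
`inst/scripts/run-pipeline.R` from a shell) writes per-fly CSVs, a stats
JSON and a reproducibility manifest.

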