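# betaburst

Single-trial analysis of transient beta bursts in continuous
electrophysiological recordings, and of their BOLD correlates in
concurrently acquired fMRI.

Beta-band (13–30 Hz) activity manifests as brief (< 150 ms) stereotyped
bursts whose probability is modulated by behaviour: it rebounds above
baseline about 0.5–1 s after a motor response (the post-movement beta
rebound, PMBR), dips after stimuli, and decreases tonically with
working-memory load. betaburst is for researchers who want to detect these
bursts one at a time, quantify their rate dynamics around an n-back task,
and use the burst times as impulse regressors in a first-level BOLD model —
plus a ground-truth synthetic-data generator that makes every stage of the
pipeline testable without real recordings.

## The method

**Detection.** The continuous time course is decomposed with 5-cycle Morlet
wavelets (1–40 Hz, 1-Hz steps); the power spectrogram is smoothed with a
2-D Gaussian (SD 1 Hz × 6 ms); peaks are cells strictly exceeding their
morphological dilation under a 5×5 structuring element of ones with a zero
centre (i.e. strict local maxima); peaks with power below 6× the median
power across time at the peak frequency are excluded; surviving beta-band
peak times are the burst events. The ratio threshold makes detection
invariant to signal scale.

**Rate statistics.** For burst times t and response times r:

    PMBR = rate(t in r + [0.5, 1.0) s) − rate(t in r + [−3.0, −1.5) s)

in bursts/s, pooled across responses; condition rates are counts over
interval unions; event-locked curves use 500-ms sliding windows. Group
contrasts use Mann–Whitney U (effect size r = |Z|/√N) or Welch's t
(Cohen's d); repeated-measures ANOVA applies the Greenhouse–Geisser
correction with partial η²; associations are Spearman ρ, optionally on
covariate-residualised values.

**BOLD model.** Task sub-blocks enter as boxcars and motor responses and
beta bursts as impulses, all convolved with the canonical double-gamma HRF
(6/16 s delays, 1:6 undershoot) on a TR/16 microtime grid; voxelwise OLS
with a burst contrast, Benjamini–Hochberg FDR, minimum cluster extent 20,
and 1-cm spherical ROI summaries.

**Generator.** n-back schedules (7 blocks/run × three 15-letter sub-blocks,
4 targets each, 2-s stimuli, 30-s/10-s rests), behavioural responses,
burst-structured EEG (thinned inhomogeneous Poisson bursts on 1/f noise,
with post-stimulus suppression, post-response rebound boost, load-dependent
tonic rates, and a group attenuation factor), and BOLD series with known
coefficients.

## Worked example

```r
library(betaburst)

sched  <- make_nback_schedule(runs = 1, seed = 1)   # 950 s, 315 stimuli, 84 targets
resp   <- simulate_behavior(sched, seed = 2)        # 81 responses
syn    <- synthesize_eeg(sched, burst_model(), responses = resp, seed = 3)
bursts <- detect_bursts(syn$signal)                 # 750 events from 366 true bursts

condition_rates(bursts, schedule_events(sched, resp))
#> # A tibble: 4 × 4
#>   condition n_bursts duration  rate
#>   <chr>        <int>    <dbl> <dbl>
#> 1 rest           281      320 0.878
#> 2 0back          188      210 0.895
#> 3 1back          156      210 0.743
#> 4 2back          125      210 0.595

pmbr(bursts, resp$onset, t_range = c(0, sched$duration))
#> # A tibble: 1 × 6
#>    pmbr post_rate baseline_rate n_responses n_post n_baseline
#>   <dbl>     <dbl>         <dbl>       <int>  <int>      <int>
#> 1 0.593      1.26         0.667          81     81         79
```

Two things to read off this output. Detected rates sit above the injected
tonic rates (rest 0.50, 2-back 0.26 bursts/s) because the 6×-median rule
has a noise floor of roughly 0.4–0.8 events/s on 1/f background — absolute
detected rates are offset, and a single 210-s condition estimate is noisy.
But *difference* statistics cancel the offset: the estimated PMBR of 0.593
bursts/s recovers the injected rebound boost of 0.6 almost exactly, and
the load-dependent decline across 0-back → 2-back is plain. The methods
vignette (`vignettes/beta-bursts.Rmd`) discusses both effects and the
detector's resolution limits in detail.

`autoplot()` methods are provided for spectrograms, event-locked rate
curves and design matrices; `tidy()`/`glance()` for GLM fits and
repeated-measures ANOVAs. A command-line interface is installed at
`exec/betaburst` (subcommands `simulate`, `detect`, `rates`, `pmbr`,
`compare`, `glm`, `demo`).

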