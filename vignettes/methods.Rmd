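---
title: "Objective stress measurement from autonomic biosignals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective stress measurement from autonomic biosignals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(biostress)
```

## The measurement problem

Procedural stress during colonoscopy is usually assessed by questionnaires,
which sedation (and its euphoric after-effects) can bias. An objective
alternative is to read stress off the autonomic nervous system directly.
`biostress` implements such a measurement pipeline for five channels
recorded during the procedure:

* **facial EMG** over *corrugator supercilii* (brow) and *zygomaticus
  major* (cheek), in µV — facial muscle tone is a sensitive distress and
  pain correlate;
* **ECG**, in mV, reduced to heart rate;
* **skin conductance level (SCL)**, in µS — a sympathetic arousal index;
* **finger skin temperature (TMP)**, in °C — peripheral vasoconstriction
  falls under stress.

Signals are acquired at 2048 Hz with three event marks per session:
examination start, the moment the cecum is reached (which can fail), and
examination end. The analysis reduces each channel to one scalar per
one-minute window anchored at those events and compares two arms — standard
care (*control*) versus self-chosen music over headphones (*music*) — with
pre-declared one-sided Mann–Whitney tests.

## Conditioning chains

All channels are first decimated from 2048 Hz to 512 Hz (a 6th-order
Butterworth low-pass at 0.8 × the target Nyquist, then every 4th sample;
`decimate_signal()`). Per modality:

| channel | chain |
|---|---|
| fEMG | band-pass 20–250 Hz → Hilbert-envelope magnitude → low-pass 4 Hz |
| SCL | low-pass 8 Hz |
| ECG | 67-sample moving average → linear detrend |
| TMP | 513-sample moving average |

All filters are Butterworth designs of order 4 (order is a free choice:
it is unconstrained by the measurement definition, and order 4 applied
without phase error is standard psychophysiology practice). Zero-phase
application matters because features are tied to event anchors; a causal
filter would delay the envelope relative to the marks.

**Numerical realisation of zero-phase filtering.** `apply_filter()`
multiplies the signal's FFT by the squared Butterworth magnitude
|H(ω)|² — the transfer function that forward–backward (`filtfilt`-style)
application converges to — rather than running two time-domain passes.
This makes the passband gain *exactly* the analytic magnitude (the
oracle the test suite checks against), cancels phase identically, and is
several times faster, which the Monte-Carlo analyses below exploit. The
cost is circular boundary behaviour at the first/last moments of a
recording; the first and last seconds of any channel are therefore treated
as unreliable by construction, and all analysis windows are interior.

The moving average is centred and shrinks at the edges, so it is
constant-preserving and length-preserving with no group delay. Detrending
is least-squares linear — over one-minute windows "detrended" in practice
means removing the linear drift.

The Hilbert envelope deserves one note: for band-limited Gaussian EMG the
analytic-signal magnitude is Rayleigh-distributed with mean σ√(π/2). The
synthetic generator divides by that factor (and by the measured band gain
of the decimation + band-pass chain) so that its envelope parameter lives
on the same scale as the pipeline's output — the scale on which group
means in µV are reported.

## QRS detection and heart rate

`detect_r_peaks()` implements the classic Hamilton–Tompkins energy
detector: band-pass ≈8–16 Hz, first difference, rectification, 80 ms
moving-window integration, adaptive signal/noise levels (running averages,
threshold = noise + 0.3125·(signal − noise)), a 200 ms refractory period,
and search-back at half threshold when no beat arrives within 1.5× the
running RR average. Detections are refined to the raw-signal maximum
within ±40 ms. Two implementation details:

* the 8–16 Hz band-pass rings, leaving a sidelobe energy maximum tens of
  milliseconds before the true QRS; within the refractory window a larger
  energy peak therefore *replaces* the previous acceptance instead of
  being discarded as noise;
* all thresholds are relative, so detection is invariant to rescaling the
  ECG by any positive constant.

Detection runs on the 512 Hz ECG *before* the 67-sample smoothing: the
moving average blunts QRS energy, and the measurement definition only
requires beats per minute. Heart rate over a window is total RR time over
beat count: 60·k / ΣRR for the k intervals fully inside the window; fewer
than two peaks yield a missing value.

## Windows and artifact screening

Window geometry is exact: `[t₀, t₀+60 s)` at start, `[t_c−30, t_c+30)`
around the cecum, `[t_end−60, t_end)` at the end, converted to 0-based
half-open sample ranges by rounding mark times down to the sample. A
missing cecum mark simply removes that window (cecal intubation fails in a
few percent of sessions).

The original screening decision — keep, correct, or discard a window — was
a visual judgement. Reproducibility requires explicit criteria, so
`screen_window()` automates it (thresholds configurable via
`pipeline_config()$windowing$qc`):

* **discard** when >5 % of samples sit within 1 % of the channel's rails
  (saturation), when the excerpt is flat, or when >10 % of samples lie
  beyond 8 robust SDs (median ± 8·1.4826·MAD of the whole channel);
* **correct** smaller fractions of outlying samples by linear
  interpolation;
* **keep** otherwise.

Two design choices: rails are estimated as the 0.1 %/99.9 % channel
quantiles, not the literal min/max — after anti-alias filtering a clipped
plateau still sits on its rail while the literal extremum is inflated by
edge ringing; and *any* outlier fraction up to the discard threshold is
corrected, which keeps quality monotone (more corruption can never improve
a window's status). Screening reads the raw analysis-rate excerpt; features
are computed from the conditioned excerpt, with spike samples interpolated
at the positions found in the raw trace. For ECG the robust-outlier rule
routinely marks R-wave crests as "spikes"; this is inconsequential because
heart rate is computed from the detected peak train, never from window
samples.

## Group comparison

`compare_groups()` produces, per (feature channel, anchor) and per stratum
(all, female, male): group means, SDs, per-cell N and a one-sided
Mann–Whitney p-value. Directions are declared in the plan — music *below*
control for fEMG, SCL and heart rate (the stress-reduction hypothesis),
music *above* control for finger temperature (relaxation vasodilates) —
and never inferred from data. There is no multiple-testing adjustment by
default, matching the pre-declared single-table reading of such studies; a
Holm option exists.

`mann_whitney_u()` follows the usual two-regime rule: exact Wilcoxon
rank-sum distribution when n₁+n₂ ≤ 12 without ties, otherwise the normal
approximation with tie correction and 0.5 continuity correction. The exact
branch is verified against brute-force enumeration of all labelings; the
approximate branch against an independent implementation. The Pearson
chi-square for 2×2 baseline tables deliberately uses *no* continuity
correction — that choice reproduces published cohort-table p-values
(0.886 / 0.646 / 0.489 for sex, setting and prior abdominal surgery)
exactly to the printed three decimals, which a Yates-corrected statistic
does not. Fisher's exact test and Student/Welch t tests round out the
baseline-table toolkit. Fisher and uncorrected Pearson agree closely in
the small-p region; for mid-range p the discreteness of the exact test can
push them apart by more than 0.05, which is expected and harmless for
decisions at α = 0.05.

## The synthetic-session generator

Patient recordings from such studies are typically shareable only by
agreement, so the generator is a first-class module: every downstream
stage is tested against its ground truth.

* **fEMG**: Gaussian noise with a flat 20–250 Hz spectrum, amplitude-
  modulated by a smooth envelope interpolated linearly between per-anchor
  segment means (the within-session time course between anchors is not
  observable from summary tables; linear interpolation is the declared
  assumption). The envelope parameter is calibrated to the conditioned
  scale as described above, so the pipeline recovers it without bias —
  the recovery error of a 60 s window mean is a few percent.
* **ECG**: P-QRS-T templates (sums of Gaussian bumps, 1 mV R wave, 0.1 mV
  noise) at RR = 60/bpm plus Gaussian jitter, truncated at 0.25 s;
  optional 0.3 Hz sinusoidal baseline wander for detector robustness
  tests. Exact beat times are returned.
* **SCL**: tonic level + Poisson-arriving phasic responses (0.75 s rise,
  3 s decay, gamma amplitudes) + slow noise, clamped non-negative.
* **TMP**: baseline + linear drift (°C/min) + smoothed noise.
* **Artifacts**: with probability `missing_window_prob` a (channel,
  anchor) window receives a rail-clipping segment over a contiguous fifth
  of the window, exercising the saturation screener; the flag list is kept
  as ground truth.

Cohorts (`generate_cohort()`) draw per-patient envelope means from a
**Gamma distribution moment-matched** to the arm's (mean, SD) — envelope
levels are positive and right-skewed, and a truncated normal would distort
the very moments the simulation is parameterised by. Default envelope
means/SDs per site and anchor are the control-arm values observed in a
196-patient colonoscopy cohort (e.g. zygomaticus 7.70 ± 5.56 µV at the
start window); the music arm scales them by `music_femg_scale`. Heart
rate, tonic SCL and temperature baseline also vary between patients.
Sessions default to 6 simulated minutes — session length beyond containing
the three interior windows does not enter the analysis. Everything is
reproducible from a single cohort seed via per-session child streams.

What the generator does **not** emulate: real EMG spectra are not flat,
ECG morphology varies (no ectopy or arrhythmia), electrodermal responses
overlap nonlinearly, artifacts in clinic are richer than rail clipping,
and channels are generated independently of one another. Passing tests
therefore demonstrate that the *pipeline* is correct and calibrated under
the stated statistical structure — not that any specific clinical effect
would replicate.

## Calibration and power

Two Monte-Carlo entry points use the generator end to end
(`mc_rejection_rate()`):

* **Null calibration** (`level = "signal"`): 200 replicate cohorts of
  30+30 patients with no group effect; each patient is a two-minute 512 Hz
  fEMG session pushed through synthesis → conditioning → windowing →
  screening → window mean → one-sided U test. The empirical type-I error
  should sit near the nominal α = 0.05 (the suite requires [0.02, 0.09]).
  Only the channel and anchor under test are simulated per patient; the
  stages exercised are exactly the package's own, and 12,000 sessions keep
  the run in minutes.
* **Power** (`level = "feature"`): 200 replicate cohorts with control
  7.70 ± 5.56 µV vs music 4.82 ± 3.33 µV at n = 65/84 — the observed
  zygomaticus start-window contrast — drawn at the between-patient level
  and run through `compare_groups()`. The defining quantities here are the
  between-patient moments; the signal layer adds only a few percent of
  measurement error to a window mean (verified by the recovery tests), so
  simulating it per patient would change nothing but the runtime. Power
  comes out around 0.95.

## Worked example

```{r example, eval = FALSE}
cohort <- cohort_spec(
  n_control = 10, n_music = 10, seed = 42,
  base = session_spec(duration_s = 240, fs = 512,
                      anchors = event_marks(10, 110, 230)),
  music_femg_scale = 0.6
)
res <- run_pipeline(cohort)
res$comparison |> dplyr::filter(stratum == "all", anchor == "start")
render_comparison(res$comparison)
autoplot(res$comparison)
```

## Known limitations

* The automated QC thresholds are surrogates for visual review; per-cell
  Ns from any specific study cannot be reproduced because the original
  screening criteria were not explicit.
* The chi-square/Fisher machinery targets 2×2 tables; wider categorical
  tables are outside scope.
* EDF input is not provided; the interchange format is CSV plus a YAML
  sidecar (`write_recording()` / `read_recording()`).
* One-sided directions must be supplied by the analyst; the defaults
  encode the stress-reduction hypothesis and are not data-driven.
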