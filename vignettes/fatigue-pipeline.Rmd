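---
title: "Measuring cognitive state fatigue: EEG markers, sensory gating, and slope-based inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cognitive state fatigue: EEG markers, sensory gating, and slope-based inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatigueflow)
```

## The problem this package addresses

Cognitive *state* fatigue — the momentary, task-induced decline in mental
capacity, as opposed to stable questionnaire-assessed *trait* fatigue — is
commonly studied with a demanding sustained-attention task (an AX-type
continuous performance task) performed under EEG. Three families of markers
track the build-up of fatigue over time-on-task:

* **Subjective**: visual-analogue-scale (VAS, 0–100) ratings of mental
  exhaustion and mental fitness collected at a handful of queries during
  the task.
* **Behavioral**: per-block response accuracy, mean reaction time, and RT
  variability.
* **Electrophysiological**: frontal midline theta power (4–7.5 Hz at Fz),
  which rises with sustained cognitive control demand; occipital alpha
  power (8–12 Hz at POz), which rises as fatigue develops; and auditory
  p50 sensory gating measured with a paired-click paradigm before and
  after the fatiguing task.

The quantity of interest for every marker is its **time-on-task slope**:
the ordinary least-squares slope of the marker against block number (1–6)
or query number (1–4),

$$b = \frac{\sum_i (x_i-\bar x)(y_i-\bar y)}{\sum_i (x_i-\bar x)^2},$$

computed per subject and assessment. Slopes are tested against zero within
groups (one-sample *t*, Cohen's *d* with a noncentral-*t* confidence
interval) and compared across a stimulation-group × assessment design with
linear mixed models. The package implements this entire chain, plus a
simulator/scorer for a gamified adaptive Go/No-Go task used during an
intervention period, and a synthetic cohort generator so that every stage
can be validated against analytic ground truth.

## Preprocessing chain

Both EEG branches share the continuous-data steps, applied in this order:
branch filtering, ocular correction, average referencing, epoching.

* **Filtering.** The spectral branch is band-passed 1–30 Hz, the ERP
  branch 0.1–47 Hz; both receive a 50 Hz notch. The emulated protocol pins
  only the band edges; the filter realization is a design choice. We use
  zero-phase (forward–backward) order-2 Butterworth
  sections — order 4 effective — and a second-order IIR notch with Q = 35.
  Zero-phase filtering preserves component latencies: a symmetric pulse
  stays symmetric to within one sample, which matters for p50 latency.
* **Ocular correction** (Gratton–Coles): for each scalp channel a
  propagation factor $b = \mathrm{cov}(\mathrm{EOG}, \mathrm{ch}) /
  \mathrm{var}(\mathrm{EOG})$ is estimated on the continuous record and
  $b \times \mathrm{EOG}$ is subtracted. The montage we emulate lists no
  dedicated EOG electrode, so the synthetic generator adds one; without an
  ocular reference the correction would be untestable. This is a declared
  non-replication of the original hardware.
* **Average reference** is computed over scalp channels only (EOG
  excluded) after ocular correction, before epoching — the common order
  when correcting continuous data. The operation is idempotent.
* **Artifact rejection**: an epoch is discarded when any scalp channel
  moves more than 100 µV peak-to-peak within any sliding 100 ms window.
  The scan covers all scalp channels including the marker electrodes,
  since blink and movement artifacts are spatially global. Rejection only
  flags epochs (the data are untouched), is idempotent, and is checked in
  the tests against a brute-force $O(n^2)$ window scan.
* **Epoching.** Spectral branch: each task block is cut into 2-s epochs
  whose starts advance by 1.8 s (0.2 s overlap); epochs never cross block
  boundaries and rest intervals are never epoched. ERP branch: −150 to
  450 ms around each click, baseline-corrected to the −50–0 ms mean.

## Spectral estimation

Each 2-s epoch is tapered and Fourier-transformed, giving an exact 0.5 Hz
grid. Three choices deserve explanation:

* **"10% tapering"** is implemented as a split-cosine bell over the outer
  10% of samples at each epoch end (a Tukey window with total taper
  fraction 0.2), not a full Hann window — a full Hann tapers 100% of the
  epoch and would not be called "10%".
* **Gain correction.** Powers are normalized by the taper's *power* gain
  (its mean square). This makes the spectrum Parseval-consistent: summing
  bins recovers total signal power, so a noiseless sinusoid of amplitude
  $A$ carries $A^2/2$ in the bins around its frequency. The tests verify
  recovery within 2%, the residual being main-lobe leakage that escapes
  the band.
* **Band aggregation.** Band power is reported as the **total** (sum) of
  power across in-band bins, with per-bin mean available as an option.
  The sum is what makes the analytic sinusoid oracle exact
  ($\sum \approx A^2/2$); a per-bin mean divides by the bin count and has
  no such closed form. Band endpoints are inclusive; at 0.5 Hz resolution
  the 7.5 Hz and 8 Hz bins are distinct, so theta and alpha never share a
  bin.

Per-block markers are the across-epoch means of band power at Fz (theta)
and POz (alpha), using retained epochs only. A block whose epochs were all
rejected yields a missing marker and a message, never a silent zero.

## p50 sensory gating

The paired-click paradigm presents pairs of clicks (S1, then S2 exactly
500 ms later; pairs separated by 8–11 s). The p50 is scored on the
averaged Cz waveform: the largest positive local peak in a 40–80 ms
post-stimulus window, minus the most negative trough between 20 ms and
that peak. The identification window follows common p50 practice; both
bounds are configurable parameters, declared rather than inherited, since
the original criteria are not restated in the protocol we emulate.

The suppression ratio is $(1 - S2/S1) \times 100$, higher meaning stronger
gating, with two degenerate-case rules: an undetectable S2 is substituted
with 0.01 µV before the ratio is formed, and ratios below −200% are
clamped to −200%. Both rules set flags. An undetectable **S1** is not a
ratio at all: when it occurs at the first measurement of the
pre-assessment the subject is excluded from all gating analyses. The ratio
is scale-invariant in $(S1, S2)$, zero when $S2 = S1$, and approaches 100
as $S2 \to 0$; clamping is idempotent. All of these are property-tested.

## Statistics

* **Winsorization**: within each measurement-point × assessment cell,
  values beyond ±2.5 SD of the cell mean are set to the nearer bound,
  using the *original* cell moments. Cells pool both stimulation groups
  (group-blind); the alternative, per-group cells, would let group
  differences leak into the clamping bounds. Note a small-sample subtlety:
  in a cell of $n$ values the largest attainable |z| is
  $(n-1)/\sqrt{n}$, so no value can exceed 2.5 SD until $n \ge 9$ —
  winsorization is a no-op for very small cells.
* **Slope formula**: the denominator is $\sum(x_i-\bar x)^2$. (A
  first-power denominator is identically zero and cannot be what any
  slope computation used.)
* **Mixed models**: slopes are modelled with fixed factors stimulation
  group × assessment (plus begin/end time for gating ratios) and a random
  intercept per subject, fitted by REML through `lme4`/`lmerTest` — the
  estimator is called, not reimplemented. Type-III ANOVAs use sum-to-zero
  contrasts and Satterthwaite denominator degrees of freedom; fractional
  dfs are expected. Partial $\eta^2$ is derived as
  $F \cdot df_1 / (F \cdot df_1 + df_2)$. On balanced complete data the
  Type-III F statistics equal the classical two-way mixed ANOVA, which
  the tests verify against `aov`. Missing sessions are handled by the
  likelihood under missing-at-random; nothing is imputed.
* **Post hocs**: estimated marginal mean contrasts (`emmeans`, also with
  Satterthwaite dfs, consistent with the omnibus tests), with
  Benjamini–Hochberg adjustment applied across the contrast family of the
  call. Omnibus F-tests are never adjusted. Standardized contrast effects
  divide the estimate by the model's total SD (random intercept plus
  residual).
* **Baseline and blinding tests** are computable from printed summary
  rows: pooled-variance two-sample *t* from means/SDs/*n*, and 2×2
  chi-square with Cramér's $V = \sqrt{\chi^2/N}$. The continuity
  correction is an explicit flag because published 2×2 tests are not
  consistent about it; both variants are exact closed forms.

## The Go/No-Go simulator

The gamified task runs 10 blocks of 90 trials (60 Go : 30 No-Go) per daily
session. Difficulty is the stimulus descent duration: 909 ms at level 0,
47 ms faster per level, floored at 345 ms (level 12). The 47 ms step is a
package choice — the protocol pins only the two endpoints — surfaced as a
config parameter. Block accuracy > 90% raises the level by one, < 65%
lowers it (floored at 0), anything between leaves it unchanged. Each later
day starts two levels below the previous day's maximum, floored at 0.

Sessions are played by a simulated participant whose probability of a
correct trial is a logistic psychometric function of descent duration with
a lapse rate. Go errors split evenly between omissions and wrong-side
presses; a wrong-side press is an error but **not** a false alarm — a
false alarm is any press on a No-Go trial. Metrics per session: overall
accuracy, RT mean/SD over correct Go responses, mean level across blocks,
and $d' = z(\mathrm{hit\ rate}) - z(\mathrm{FA\ rate})$ with the
log-linear correction (+0.5 to both numerators, +1 to both denominators)
so that error-free sessions stay finite. The staircase is Markov in
(level, accuracy): replaying logged block accuracies through
`staircase_update()` reproduces the logged trajectory exactly, which is a
test invariant.

## What the synthetic cohort emulates — and what it does not

`cohort_design()` fixes the study layout: 2 groups × 20 subjects ×
3 assessments (pre, post, follow-up), an AX-CPT of 6 blocks × 53 trials
with four VAS queries, paired-click blocks of 60 pairs before and after
the task, and four daily Go/No-Go sessions. The generators are built for
*analytic ground truth*, not physiological realism:

* Band markers are fixed-frequency sinusoids (6 Hz theta, 10 Hz alpha)
  whose amplitude is constant within a block and drifts linearly across
  blocks — so the injected power trajectory is known in closed form.
* Background noise is 1/f (pink); blinks are Gaussian pulses (~15/min,
  ~100 µV) shared between a synthetic EOG channel and the scalp with
  front-weighted propagation, giving the ocular correction a controllable
  target.
* The p50 is a stereotyped biphasic template (trough near 35 ms, peak
  near 55 ms) normalized so its peak-to-trough distance equals the
  requested amplitude exactly — noiseless recovery is exact to numerical
  precision.
* VAS noise is truncated-normal so values respect the bounded scale;
  exhaustion and fitness drift with opposite signs from one latent.

Because carriers are narrow-band and stationary within blocks, passing
tests demonstrate that the *pipeline arithmetic* is right; they do not
demonstrate robustness to broadband nonstationary EEG, volume-conducted
artifact mixtures, or individual alpha-frequency variability, none of
which the generator produces.

Effect-size defaults are calibrated, not measured: between-subject slope
SDs are sized so that one-sample slope *t*-tests land near $d \approx
0.75$, the magnitude typical of successful fatigue induction, and the
group × assessment recovery studies inject a sham-post alpha-slope offset
of $d \approx 0.35$, the magnitude typical of reported post hoc contrasts.
They are calibration anchors for power behavior, not claims about
physical µV values.

## Numerical and scale choices

* Default sampling rate 500 Hz: comfortably supports the 0.1–47 Hz
  branch and 1 ms click events. Tests and examples run reduced problem
  sizes (250 Hz, 10 trials/block, 2 s rests, 4 channels) chosen so the
  whole suite completes in minutes while exercising identical code paths;
  the full-scale design is the default of `cohort_design()`.
* Monte-Carlo study sizes in the tests: the null calibration of the
  interaction test uses 2000 replicates at 10 subjects/group, making the
  nominal-α acceptance band [0.035, 0.065] a ±3σ check; sign-recovery of
  the injected offset uses 200 replicates at 20/group.
* Mixed-model non-convergence is reported via a flag; singular fits
  (zero between-subject variance) are tolerated because the null
  simulations legitimately produce them.
* The degenerate zero-variance one-sample *t* returns a signed infinite
  statistic with a `degenerate` flag rather than an error.
* BrainVision output uses 32-bit float multiplexed binary, the format's
  simplest profile; the bundled reader supports exactly that subset.

## Known limitations

* The p50 detection window (40–80 ms) and trough floor (20 ms) are
  defaults, not recovered constants of any specific laboratory.
* The Go/No-Go difficulty grid (13 levels) is one consistent realization
  of the pinned endpoints; real implementations may use other step sizes.
* Whether spectral averaging should pool µV² power (used here) or
  amplitude spectra is a genuine ambiguity; power is the standard choice
  and is fixed throughout.
* The pipeline performs no ICA, channel interpolation, or resampling, and
  offers no time–frequency analysis — the emulated protocol uses none.
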