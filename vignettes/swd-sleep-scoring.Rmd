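---
title: "Wavelet-based scoring of spike-wave discharges and sleep states in rodent EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based scoring of spike-wave discharges and sleep states in rodent EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdscore)
```

## The problem

Rat models of absence epilepsy (WAG/Rij, GAERS) express spontaneous
spike-wave discharges (SWDs): paroxysmal trains of high-voltage spike-wave
complexes with an 8–10 Hz fundamental, lasting from two seconds to tens of
seconds, arising preferentially from drowsiness and light NREM sleep.
Longitudinal studies of epileptogenesis and of its interaction with sleep
architecture require scoring tens of hours of multichannel epidural EEG per
animal into wakefulness (AW), behavioral/NREM sleep (BS), SWDs and
micro-arousals (MA) — a workload that makes manual scoring the bottleneck.
`swdscore` implements a fully automatic scorer whose only inputs are the
raw multichannel signal and a handful of fixed constants; every
recording-specific threshold is derived from the recording itself.

## The method

### Band-limited wavelet energy

Each channel \(x_i(t)\) is transformed with the analytic Morlet continuous
wavelet transform (CWT) \(W_i(f,t)\), central parameter \(\Omega_0 = 2\pi\),
so that wavelet scale coincides with Fourier frequency in Hz. The
instantaneous energy \(E_i(f,t) = |W_i(f,t)|^2\) is summed over a 0.25 Hz
frequency grid inside four fixed bands:

| band | range (Hz) | role |
|------|------------|------|
| `delta` | 2.5–4.5 | SWD-ratio denominator (slow-wave floor) |
| `spindle` | 10.5–12.5 | SWD-ratio denominator (sigma/spindle floor) |
| `spike` | 15–18 | SWD-ratio numerator (spike-harmonic band) |
| `sleep` | 5–10 | sleep marker (mid-frequency synchronization) |

Band energies are smoothed with a centered moving average of 0.25 s
(the "integral energy"). Per-sample resolution is kept throughout; there is
no epoching.

### SWD detection

The sharp spike of each spike-wave complex pumps harmonic energy into
15–18 Hz, while delta and spindle-band energy stays moderate. Per channel
the detector forms the energy ratio
\[
\varepsilon_{sw}(t) \;=\;
  \frac{\tilde\varepsilon_{15\text{–}18}(t)}
       {\tilde\varepsilon_{2.5\text{–}4.5}(t) + \tilde\varepsilon_{10.5\text{–}12.5}(t)},
\]
averages it across channels, and smooths it over a \(\tau = 3\) s window.
Two adaptive thresholds are set from the recording-wide time average
\(\bar\varepsilon\) of this characteristic: onset at
\(1.75\,\bar\varepsilon\), offset at \(1.55\,\bar\varepsilon\). Hysteresis
segmentation yields candidate intervals \([t^\uparrow, t^\downarrow]\);
candidates shorter than 2 s are dropped.

Each surviving candidate is validated by an amplitude criterion that kills
oscillatory artifacts which pass the energy ratio but lack the high-voltage
morphology: on each 1–100 Hz zero-phase band-passed channel, strict local
maxima (and minima) are collected inside the candidate and inside a 5 s
baseline window ending 1 s before onset. With `x_max` (`x_min`) the ratio of
mean event-extremum amplitude to mean baseline-extremum amplitude, averaged
over channels, the candidate is accepted iff
\(x_{max} + x_{min} > 6\) (strictly). If the baseline window precedes the
start of the recording the candidate is accepted unvalidated and flagged.

### Sleep/wake detection

Elevated 5–10 Hz power marks behavioral sleep in this preparation
(mid-frequency synchronization, sleep spindles, 5–9 Hz oscillations). The
channel-mean smoothed `sleep`-band energy, further smoothed over 10 s, is
segmented by a second hysteresis pair at `bs_up_mult`/`bs_down_mult` times
its recording mean. Samples inside detected SWDs — whose 8–10 Hz fundamental
carries very large 5–10 Hz power — are excluded from that mean, padded by
half the smoothing window, so discharges cannot inflate the sleep
thresholds. High-characteristic stretches become BS, the complement AW;
episodes of either state shorter than 20 s are merged into the flanking
state, except wake intrusions that qualify as micro-arousal candidates.

### Hypnogram assembly and micro-arousals

SWD intervals are overlaid on the sleep/wake tiling with precedence
(a discharge is a distinct state, not sleep). A wake episode of 3–15 s
immediately preceded by at least 10 s of uninterrupted BS and followed by BS
is relabeled MA; wake fragments under 3 s flanked by sleep are absorbed into
sleep (below the floor of a scorable arousal). An SWD interrupting the
preceding sleep resets the uninterrupted-sleep requirement. The final
hypnogram tiles the recording with labels {AW, BS, SWD, MA}.

### Sleep-fragmentation metrics

`compute_metrics()` clips the hypnogram to an analysis window and reports
episode counts, per-hour SWD and MA rates, total sleep time, percent time
asleep and the sleep fragmentation index
\(\mathrm{SFI} = \text{sleep episodes} / \text{total sleep in hours}\)
(undefined, not zero, when the window contains no sleep).
`dark_phase_windows()` maps the two standard dark-phase analysis windows
(21:00–24:00 and 03:00–06:00) to recording offsets.
`classify_epiphenotype()` groups longitudinal SWD-rate trajectories into
minor / mild / severe epilepsy; the cut-offs (0.5, 3 and 5 SWDs/h) are
heuristic descriptions of the published group trajectories, not published
rules, and are fully configurable.

## Parameters that matter

| parameter | default | units | why |
|-----------|---------|-------|-----|
| `k_up`, `k_down` | 1.75, 1.55 | × recording mean | published SWD operating point; per-animal adaptation comes entirely from the mean |
| `tau_s` | 3 | s | SWD characteristic smoothing; comparable to the shortest scorable event |
| `criterion_threshold` | 6 | – | extrema bound: event peaks ≈ 3× baseline peaks per side |
| `baseline_window` | (−6, −1) | s | 5 s of pre-onset background, ending 1 s before onset |
| `min_duration_s` | 2 | s | definitional minimum SWD duration |
| `bs_up_mult`, `bs_down_mult` | 1.15, 0.85 | × recording mean | sleep hysteresis; calibration defaults tuned on the synthetic suite |
| `smooth_window_s` | 10 | s | sleep characteristic smoothing; trades boundary sharpness against false state flips |
| `min_episode_s` | 20 | s | definitional minimum AW/BS episode |
| MA bounds | 3–15, ≥10 | s | scoring-standard micro-arousal rule |

## Numerical choices

* The integral-energy window is a *normalized* centered moving average
  (total length 0.25 s by default): a plain windowed sum would carry units
  of energy × samples and make the fixed multipliers scale-dependent.
* The `tau_s` smoothing uses a centered window of total length `tau_s`
  (±1.5 s). A ±1.5·`tau_s` (9 s) variant is available via
  `tau_window_mult = 3`, but a smoothing scale several times the minimum
  event duration blurs 2 s events into their surroundings.
* `x_max`/`x_min` default to ratios of *mean* extremum amplitudes. Ratios of
  raw amplitude sums (`extrema_mode = "sum"`) grow with event duration and
  make the fixed bound 6 duration-dependent; the mean-ratio reading makes it
  interpretable. Ties at exactly 6 are invalid (strict inequality).
* All ratio denominators carry a relative epsilon floor
  (\(10^{-12}\times\) series maximum), so flat or zero signals degrade to
  zero characteristics instead of NaN, and every detector decision is
  invariant under amplitude scaling of the recording (energy ratios and
  extrema ratios cancel any common gain).
* Extrema are strict local extrema of the 1–100 Hz zero-phase band-passed
  signal (removes DC drift that would manufacture spurious extrema); only
  positive-valued maxima (negative-valued minima) count as peaks.
* CWT edge samples are computed from zero-padded data; thresholds are
  recording-wide averages, so edge effects are not specially handled.

## The synthetic validation suite

No public recordings exist for this preparation, so correctness is
established on synthetic multichannel EEG with exact ground truth
(`simulate_eeg()`), and the scorer is graded by duration agreement
(`evaluate_scoring()`): per state, the percentage of ground-truth time the
automatic scorer labels identically.

What the generator emulates, per state: wake is low-voltage broadband
(1/f-type) noise with weak 6–8 Hz theta; NREM is high-amplitude 1–4 Hz
delta plus a 5–9 Hz mid-frequency oscillation and waxing-waning 11–13 Hz
spindle bursts, shared across channels (synchronized EEG); micro-arousals
are wake-spectrum insertions of 3–15 s. Spike-wave trains are periodic
biphasic Gaussian-derivative spikes (~25 ms wide, harmonics well above
15 Hz) riding the crest of a phase-locked slow wave, near-synchronous
across channels (pairwise lag ≤ 10 ms) with a 0.7× occipital amplitude, at
8× the sleep-background amplitude. Each train settles exponentially
(time constant 0.6 s) from a brief faster initial phase toward a fundamental
in the lower half of the 8–10 Hz range — the standard absence-seizure chirp;
the instantaneous fundamental stays inside 8–10 Hz throughout. A pure-tone
"artifact" mode embeds 16.5 Hz bursts at near-baseline amplitude to
exercise the extrema-rejection path.

Episode structure follows dark-phase rodent hypnograms: mean wake and NREM
episodes of 10 min (roughly three sleep episodes per hour), about two
micro-arousals per hour of sleep, and 10–20 SWDs of 2–10 s per hour placed
inside sleep with at least 10 s of clean sleep on either side.

The generator's validity gate, asserted by the test suite with an
independent FFT band-power oracle, is that 15–18 Hz energy relative to the
2.5–4.5 + 10.5–12.5 Hz bands is at least 3× higher during a generated SWD
than in flanking sleep — the detector's physical premise must hold in the
data before detector accuracy is meaningful.

What the generator does **not** emulate: REM and intermediate sleep states,
movement and electrode artifacts other than the pure-tone mode, amplitude
nonstationarity across hours, inter-animal spectral variability, and volume
conduction structure beyond a shared common component. Passing the suite
therefore demonstrates that the implementation realizes the method
faithfully and that the method separates the encoded state morphologies; it
does not certify accuracy figures for any particular animal preparation.

### Problem sizes

The validation suite used by the tests and by `scripts/acceptance.R` is ten
seeded one-hour, three-channel, 400 Hz recordings (about 14 million
samples in total); unit tests use recordings of one to ten minutes. The
artifact-rejection suite uses fifty ~100 s sleep recordings with one
embedded burst each.

## Design choices made here (where the method left them open)

* **Sleep hysteresis multipliers.** The sleep detector's threshold pair is
  not published as constants; 1.15/0.85 of the recording mean were fixed by
  calibration on the synthetic suite and exposed as parameters.
* **Thresholds as time averages.** All adaptive thresholds are multipliers
  of the *time-averaged* characteristic, the only reading that keeps
  thresholds commensurate with the characteristic itself.
* **Baseline window.** The extrema baseline is the 5 s window ending 1 s
  before onset, matching the stated duration of the original procedure.
* **SWD exclusion from the sleep mean.** Without masking detected SWDs
  (padded by half the smoothing window), their 8–10 Hz power inflates the
  sleep-threshold mean by a factor large enough to push thresholds above
  the sleep level in seizure-rich recordings.
* **Micro-arousals and SWDs.** A discharge is not sleep: it resets the
  uninterrupted-sleep run required before a micro-arousal, and a
  micro-arousal cannot contain an embedded discharge.
* **Terminal awakenings.** "Followed by sleep" requires at least 1 s of BS
  after the candidate, so an awakening truncated by the end of the
  recording is never scored as a micro-arousal.

## Known limitations

* Candidates whose extrema baseline would precede the start of the
  recording are accepted unvalidated (flagged `validated = FALSE`); in
  wake-initial recordings this can admit a leading false positive. Scoring
  recordings with a few minutes of lead-in avoids the case entirely.
* Very short (2–4 s) low-margin discharges can fail the extrema criterion
  when the hysteresis candidate extends a second or two into background on
  both sides, diluting the mean event extremum; this costs little duration
  agreement but lowers event-level recall for the shortest events.
* The sleep scorer is a two-state classifier; REM would be scored as
  wakefulness or sleep depending on its 5–10 Hz content.
* The adaptive sleep thresholds assume the recording contains both states:
  on an essentially sleep-free recording the threshold pair lands inside
  the wake fluctuation band and fabricates brief sleep episodes. Hour-scale
  recordings spanning normal rest–activity alternation are the intended
  input.
* Wake segments in sleep-rich recordings can cross the SWD energy
  threshold; rejection then relies entirely on the extrema criterion.

## A worked example

```{r example, eval = FALSE}
library(swdscore)

sim <- simulate_eeg(simulation_config(duration_s = 900, seed = 7))
sc <- score_vigilance(sim$recording)
sc
summary(sc)
plot(sc)

evaluate_scoring(sc$hypnogram, sim$truth)
```
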