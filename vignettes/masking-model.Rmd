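---
title: "Modelling spatial release from masking in mechanically coupled ears"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial release from masking in mechanically coupled ears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ormiasrm)
```

## The problem

The parasitoid fly *Ormia ochracea* localizes the ~5 kHz calling song of
its host crickets with hyperacute directionality, despite tympana
separated by only ~500 µm — a geometry in which the best available
acoustic interaural time difference is on the order of a microsecond
(`best_itd_us()` returns 1.45 µs) and the ~7 cm wavelength produces no
measurable interaural level difference. A cuticular lever mechanically
couples the two eardrums and converts these minuscule acoustic cues into
large interaural *vibration* amplitude differences (IVADs).

This package asks, in silico, how such a system behaves when the song is
embedded in a spatially separated noise masker: whether spatial release
from masking (SRM — lower masked thresholds at larger signal–masker
separations) can operate, and why a lateral masker *diverts* the perceived
song direction away from both sources. Every stage of the corresponding
laboratory workflow is implemented on synthetic data: stimulus synthesis,
tympanal and afferent simulation, effective-amplitude analysis,
signal-detection thresholds, treadmill kinematics, an adaptive staircase,
and circular statistics.

## The generative model

### Stimuli

The target signal is a pulsed trill: 10 ms tonal pulses at 5 kHz with
1 ms linear on/off ramps, repeated at 50 pulses/s for 2 s
(`pulse_train_spec()`). A 40 ms "2-pulse" variant serves the physiology
protocols. The masker is a 4 s burst of 2–7 kHz band-limited Gaussian
noise (`noise_spec()`), generated by spectral shaping (out-of-band FFT
bins zeroed, raised-cosine tapers just inside the band edges), which
makes the ≥ 40 dB out-of-band rejection contract hold for every seed.
Coherent maskers — identical waveforms broadcast from mirror-symmetric
azimuths — are simply sources sharing one noise seed.

Levels are dB re a fixed digital reference (amplitude 1.0 ≡ 60 dB).
Signals are calibrated as *peak RMS* (maximum of a 5 ms sliding-RMS
window, which sits on pulse interiors), maskers as *long-term RMS*, so a
"0 dB SNR" scene has its pulse peaks at the masker's long-term level,
matching the broadcast calibration convention of the laboratory
protocol. Absolute sound pressure is never calibrated; all analyses use
dB differences, so the reference convention is immaterial.

The default scene timing embeds the 2 s signal symmetrically in the 4 s
masker: masker onset 0.5 s, signal onset 1.5 s, within a 5 s acquisition.

### Ears

Tympanal directionality is summarized by an antisymmetric sigmoid
`IVAD(θ) = max_ivad_db · (2/(1+exp(−θ/slope_deg)) − 1)` with defaults
`max_ivad_db = 10` dB and `slope_deg = 30`°. The original directionality
measurements exist only as a published figure, so the parametric curve is
a stand-in with user-settable parameters; a digitized table can be
supplied instead (`directionality_table()`, `read_directionality_table()`).
The defaults put ~9 dB of interaural difference at ±90° and ~1 dB at ±6°,
the right order of magnitude for the mechanically coupled ear.

Only the interaural *difference* is physically constrained, and every
downstream analysis uses differences, so the model splits the gain
symmetrically: +IVAD/2 dB on the source-side ear, −IVAD/2 on the other.
Each ear's trace is the gain-weighted sum of all source traces plus
Gaussian measurement noise (`meas_noise_db`, default 30 dB, i.e. 40 dB
below a 70 dB source). Mechanical interaural time differences are not
modelled: the direction predictions under study use amplitude differences
only.

### Afferents

Type I auditory afferents are phasic: one spike at each sound-pulse
onset followed by a ~4 ms refractory period; Type II fire a short burst
at onset. `spikes_from_trace()` implements this as upward crossings of a
fast envelope (3 ms sliding RMS) over a threshold, with an absolute dead
time. The threshold is the larger of two terms:

* 3 × the RMS of a stimulus-free epoch (the quiet floor, mirroring the
  impulse-detection rule used on nerve recordings), and
* 1.3–1.5 × a slow (200 ms) running envelope — the *adaptive floor*.

The adaptive floor is essential: with a fixed quiet-referenced threshold
a sustained masker would trigger exactly one onset crossing and then hold
the envelope above threshold forever, silencing the unit at every SNR.
Biologically, sustained noise sets the floor above which a signal-driven
increment is required to fire, and near-threshold fluctuations of the
noise envelope occasionally elicit spikes — which is precisely what the
adaptive rule produces. The fast envelope is 3 ms rather than 1 ms
because the 1 ms RMS envelope of ~5 kHz-band noise fluctuates with ~30%
CV, so masker-driven crossings of any practical floor saturate the 4 ms
refractory limit and drown the signal-driven spikes; at 3 ms the envelope
still resolves 10 ms pulses crisply. Both windows and multipliers are
`afferent_spec()` parameters.

### Behaviour

The simulated fly steers toward the ear with the larger *effective
amplitude* (below): its commanded heading is the directionality curve's
inverse evaluated at the effective interaural difference, plus Gaussian
motor noise (default SD 5°/trial), executed by a synthetic walker
(`simulate_walk()`) on the virtual treadmill at 2160 Hz with a supplied
pixel calibration (0.0028 cm/px). Response latency is drawn at
56 ± 3 ms and forward speed rises with SNR (≈2.3 cm/s at −6 dB to
≈4.7 cm/s at +6 dB), matching the scale of the behavioural measurements.
The per-trial motor noise is deliberately modest; real flies vary
considerably more between individuals, so the simulation's condition
means are tighter than laboratory ones (see *Limitations*).

## The analyses

**Effective amplitude.** For each ear, the response to the signal above
the masker-driven floor: `20·log10(RMS_signal_window / RMS_masker_window)`
(`effective_amplitude()`), averaged over repetitions. For the repeated
2-pulse protocol the windows are 30 ms at each pulse onset against 30 ms
segments 200 ms later, mid-interpulse (`pulse_protocol_windows()`). For
the 50 pulses/s trill a per-pulse mid-interval scheme is impossible (the
pulse period is 20 ms, shorter than the 30 ms window), so the trill uses
the signal+masker epoch against the one masker-alone second leading up
to signal onset (`trill_windows()`), which is how the trill recordings
were analysed in the laboratory protocol.

**Effective IVAD and direction.** The interaural difference of effective
amplitudes (`compute_ivad()`), signed contra-minus-ipsi (positive = bias
away from the masker). A 4-parameter logistic is fitted to IVAD against
azimuth by derivative-free Nelder–Mead least squares with ≥ 5
deterministic multi-starts and an RSS-change convergence tolerance of
1e−8 (`fit_sigmoid()`); constant data return a fit-failure flag rather
than an error. `predict_direction()` inverts the fitted monotone curve by
bisection (tolerance 1e−10; identity with the forward curve to < 1e−6°),
clamping out-of-range IVADs to the curve endpoints with a warning.

**Masked thresholds (nerve).** Impulses are detected at RMS + 3 SD of a
quiet epoch with a 1 ms dead time (`detect_impulses()`); responses are
counted in 40 ms windows (window RMS is available as an alternative
measure, matching the deposited form of the nerve data). Detectability is
the standard separation
`d_a = (μ_sn − μ_n) / sqrt((σ²_sn + σ²_n)/2)` (`standard_separation()`).
The pooled (sum) denominator is the default: the printed minus form is
undefined whenever the variances are equal and contradicts the statistic's
unequal-variance rationale; it is retained behind `form = "printed"` with
an undefined flag. The masked threshold is the fitted sigmoid's crossing
of `d_a = 1.0`, found by bisection on whichever level axis was swept
(`masked_threshold()`).

**Kinematics.** Steering (x) and forward (y) velocities are calibrated
pixel increments times the sample rate, optionally smoothed by a 50 ms
centred moving average (`velocities()`). Latency detection uses a
separate light 5 ms smoothing, because a wide centred window smears the
response onset backwards and would bias latencies ~25 ms early. The
latency criterion — forward velocity above 3 × its pre-stimulus SD for at
least 20 ms — is this package's construction (none is published); it
recovers injected latencies within ~3 ms. The *mid-response angular
heading* is the net-displacement angle from response onset to the
temporal midpoint between response onset and signal offset
(`heading = "mid"`), with the whole-response net angle behind
`heading = "whole"`. Trials with less than 1 cm of total translation are
flagged invalid. Left-masker trials are mirrored about 0° before pooling,
per-fly means first (`mirror_and_average()`).

**Staircase.** Levels descend from 76 dB in 3 dB steps to the first
non-response at L, then a single probe at L + 1.5 dB. A responded probe
gives UB = L + 1.5, LB = L; a failed probe gives LB = L + 1.5 and
UB = L + 3 (the last responded level) — the only assignment that
guarantees LB < UB using observed trials, since only one bound is defined
by the probe itself. The threshold is the power-domain average
`10·log10((10^(UB/10) + 10^(LB/10))/2)`. The procedure stops after the
probe; one staircase is run per fly per condition.

**Circular statistics.** Two-sample Watson U² on pooled circular ranks
(mid-rank ties); by default the p-value is computed by exact enumeration
when `choose(n1+n2, n1) ≤ 20000`, because the asymptotic series is
noticeably anti-conservative at small n, and by the asymptotic series
otherwise (where its 5% point, U² ≈ 0.187, verifies by simulation).
Watson–Williams uses the classic F with the 1 + 3/(8κ̂) correction and
warns below a pooled resultant of 0.7. The paired Hotelling test forms
per-subject differences of unit vectors and tests the bivariate mean
against zero (F with (2, n−2) df; singular-covariance cases short-circuit
to p = 0 or 1). The Harrison–Kanji two-factor circular ANOVA decomposes
squared resultants; above κ̂ = 2 it uses F ratios against the residual
with the same high-concentration correction, otherwise χ² approximations
with 2·(levels−1)-type degrees of freedom (the factor 2/(1−ρ̂²) makes the
null statistic asymptotically χ²; type-I error verifies at 0.05 ± 0.01
over 2000 uniform-null simulations). Repeated measures are treated as
independent groups, as in the original analysis. Heading summaries are
circular means with a circular SEM (√(−2 log R̄)/√n, in degrees; the
published summaries do not state their angular SEM convention).

## What the simulations show — and do not show

With the default directionality, a frontal signal plus one lateral
masker raises the masker-ipsilateral floor, so the contralateral ear
keeps the larger effective amplitude; the simulated fly therefore heads
*away* from the masker, further for 90° than for 6° separation, and the
nerve replica detects the signal at ~7 dB higher masker levels in the
contralateral ear. Two coherent maskers at ±θ equalize the floors, the
effective IVAD collapses to ~0, and headings return to straight ahead —
the symmetry logic of the two-masker experiment. The behavioural
staircase replica, whose observer responds when the *better ear's*
effective amplitude clears a criterion, yields masked thresholds far
above quiet ones and — under this better-ear rule — somewhat *lower*
thresholds at 90° than 6°. The package reports whatever the configured
model yields here; the laboratory finding of *no* threshold difference is
a constraint on the fly's physiology, not a property the simulation is
tuned to reproduce.

Problem sizes follow the study design where stated: 13 simulated flies,
3–6 (default 3 or 5) repetitions per condition, 10 nerve preparations
with 20 sweeps per level, SNRs of −6/0/+6 dB (behaviour) and −18…+6 dB
in 6 dB steps (nerve), separations of 6° and 90°, 44.1 kHz audio and
2160 Hz treadmill rates. Tests and the acceptance script run reduced but
structurally identical configurations where full size adds nothing
(e.g. single nerve units per seed, 3.5 s single-source scenes for the
recovery chain).

## Limitations

* The intertympanal bridge is not modelled biophysically; directionality
  is a static, frequency-independent gain curve, and mechanical ITDs are
  omitted.
* Free-field acoustics (speaker transfer functions, echoes, diffraction)
  are out of scope; scenes sum calibrated digital waveforms.
* Inter-individual variability is underrepresented: per-fly parameters
  vary mildly (response criterion SD 0.3 dB) and motor noise is 5°/trial,
  so simulated condition means are tighter than laboratory ones. Passing
  symmetry tests therefore shows the model's logic, not the dispersion of
  real flies.
* Type III (tonic) afferents are not simulated; the nerve replica is a
  multi-unit caricature sufficient for the windowed count/RMS measures.
* The parametric directionality curve stands in for unpublished
  measurements; analyses accept a measured table wherever the curve is
  used.
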