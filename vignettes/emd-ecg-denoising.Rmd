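---
title: "Adaptive EMD-based ECG denoising: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive EMD-based ECG denoising: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdecg)
```

## The problem

A single-lead electrocardiogram collects, on top of the cardiac signal,
broadband Gaussian noise from the acquisition chain, electromyographic (EMG)
muscle artifact, narrowband 50/60 Hz powerline interference, and slow
baseline wander driven by respiration. Linear filters struggle here because
the QRS complex itself is broadband: a high-pass that removes wander also
tilts the ST segment, and a low-pass that removes EMG blunts the R peak.

`emdecg` takes the data-driven route: decompose the record into intrinsic
mode functions (IMFs) by empirical mode decomposition (EMD), decide
*adaptively* which modes are noise, and rebuild the signal from the rest.
The package provides the decomposition (`emd()`), the adaptive denoiser
(`ecg_denoise()`), the standard evaluation metrics (`snr_improvement()`,
`mse()`, `prd()`), a synthetic ECG-plus-noise generator, and a seeded
Monte-Carlo evaluation harness (`run_grid()`).

## Empirical mode decomposition

One sifting step takes a candidate mode $h(t)$, interpolates a natural
cubic spline through its local maxima (the upper envelope) and another
through its local minima (the lower envelope), and subtracts the envelope
mean $m(t)$:

$$h'(t) = h(t) - \tfrac{1}{2}\bigl(u(t) + \ell(t)\bigr).$$

Sifting repeats until the iterate is a *bona fide* IMF — its extrema and
zero-crossing counts differ by at most one — and the normalised standard
difference between consecutive iterates,

$$\mathrm{NSD} = \sum_t \frac{(h_{i-1}(t) - h_i(t))^2}{h_i(t)^2},$$

falls below `nsd_threshold` (default 0.2). The accepted mode is subtracted
from the running residual and the process repeats until the residual has
fewer than two interior extrema (a monotone trend), `max_imfs` modes have
been extracted, or envelopes can no longer be built.

### Numerical choices

* **Envelopes.** Natural cubic splines (`stats::splinefun`). Before
  fitting, the first and last `boundary_extrema` (default 2) knots are
  mirrored about the record endpoints, which suppresses the end swings
  that plain natural splines produce on short extrapolations.
* **Extrema.** A plateau (run of equal samples) counts once, at its first
  index; endpoints are never extrema. This keeps the operator
  deterministic and maxima/minima strictly alternating.
* **Zero crossings.** A strict sign change counts once; a run of exact
  zeros entered from a nonzero value counts as a single crossing, so a
  sample that is exactly zero is never double-counted against its
  neighbours.
* **The NSD denominator.** The ratio is undefined where $h_i(t) = 0$;
  samples with $|h_i(t)|$ below `zero_floor` times the iterate's RMS are
  skipped.
* **The effective stopping regime.** Because the NSD is a *sum* of
  per-sample ratios, its magnitude grows with record length and with the
  near-zero denominators around each zero crossing; for records of a few
  thousand samples it sits orders of magnitude above any conventional
  threshold. In practice the iteration cap (`max_sift_iters`, default 50)
  is therefore the binding stop, as in fixed-count sifting. Since every
  accepted mode must still *be* an IMF, `extract_imf()` tracks the most
  recent iterate that satisfied the extrema/zero-crossing test and falls
  back to it when the cap is reached with a non-conforming iterate —
  over-sifting can momentarily break the criterion a few iterations after
  it was first met.
* **Degenerate residuals.** A residual that the envelope mean annihilates
  in a single sift is its own trend: it is returned as the final residue
  rather than emitted as a numerically-zero "mode". Likewise the cascade
  stops once the residual falls below $10^{-12}$ of the input scale;
  anything beyond that is floating-point dust.

Completeness — IMFs plus residue reproduce the input to rounding error —
holds by construction of the subtraction cascade, and is asserted over a
50-signal random suite in the test battery.

## Adaptive selection of noise IMFs

High-frequency noise concentrates in the first one or two IMFs and is
nearly zero-mean. The selector therefore watches the *cumulative mean* of
the partial reconstructions,

$$R_k = \operatorname{mean}_t \sum_{i=1}^{k} \mathrm{IMF}_i(t),$$

which stays near zero while only noise modes have been accumulated and
jumps once a signal-bearing mode (with the ECG's nonzero average level)
enters the sum. Candidates are the maximal *initial* run of modes with
$|R_k| < \tau$, where $\tau =$ `mean_threshold_factor` $\times
|\operatorname{mean}(x)|$ (default factor 0.5), capped at `max_noise_imfs`
(default 2). For zero-mean records the threshold falls back to
`mean_threshold_factor` $\times\ 0.01 \times \mathrm{RMS}(x)$. The prefix
rule matters: noise lives in the low-order modes, and it prevents the
selector from ever dropping a mid-band mode because of an incidental small
cumulative mean.

### The power confirmation test

A candidate is only *confirmed* as noise if it also looks like noise in
amplitude: high-frequency contamination rides on the ECG as a
small-amplitude oscillation, so its mode power must be minimal. The test
is

$$P_k < n \cdot (\texttt{power\_fraction} \cdot \max_t |x(t)|)^2,$$

i.e. the candidate's RMS amplitude must stay below `power_fraction` of the
record's peak deflection. Two observations fixed the default of 0.15. On
records corrupted at the noisiest design condition (0 dB input SNR), the
noise-dominated first IMF has an RMS close to 10% of the record peak; on
nearly clean records, the first IMF instead carries genuine QRS-scale
envelope dynamics with an RMS around 19% of the peak. The default sits
midway between those two regimes, so the gate confirms removal across the
whole 0–25 dB operating range while refusing to strip a beat-bearing first
mode from a clean record. A relative comparison among the mode powers
themselves (e.g. against their median) does not work here: as soon as
appreciable noise is present, the first IMF holds the *largest* power of
all modes, so any "much smaller than the other modes" rule would block
exactly when denoising is needed.

Confirmed modes get gain 0 (`attenuation_mode = "remove"`, the default) or
a soft gain $\min(1, |R_k|/\tau)$ (`"proportional"`); everything else
passes with gain 1, and the reconstruction is the gain-weighted mode sum
plus residue.

## Baseline-wander removal

Wander lives in the slowest modes, but how many of them is
record-dependent. The stage scores a reconstruction by the **piecewise
slope metric**: split the record into `baseline_segment_seconds` segments
(default 1 s, about one beat), fit a least-squares line per segment, and
sum the absolute slopes (mV/s). Drift gives every segment a coherent tilt
and inflates the sum; oscillations faster than a segment average out.

Starting from the noise-gated reconstruction, the stage detaches the
residue, then the slowest IMFs in descending order, keeping a removal only
while the metric does not increase (with a 1% relative tolerance —
detaching a negligible component perturbs the metric at rounding level,
and a strict comparison would let such a blip block a genuine drift
removal further down the queue).

Two guards make this safe:

* **Frequency floor.** Only modes whose zero-crossing rate corresponds to
  less than `baseline_max_hz` (default 0.5 Hz, the conventional upper edge
  of respiratory wander and safely below any plausible heart rate) are
  candidates at all. An index-based floor ("never remove below mode
  $K/2$") is not reliable here because the number of modes grows with the
  noise level, silently exposing beat-bearing modes; the frequency floor
  is invariant to that.
* **Reference level.** Detaching a component removes only its *wander*:
  the time-average of everything detached is restored to the output, so
  correction flattens the drift without dragging the record away from its
  DC reference. (The slope metric is blind to constants, so the stopping
  rule is unaffected.) For a pure trend input the corrected output is the
  trend's mean level — the drift is gone, the reference remains.

## Evaluation metrics

For clean $x$, corrupted $y$ and denoised $\hat{x}$:

$$\mathrm{SNR_{imp}} = 10\log_{10}\frac{\sum (y - x)^2}{\sum (\hat{x} - x)^2}
  \;\mathrm{dB},\qquad
  \mathrm{MSE} = \frac{1}{N}\sum (x - \hat{x})^2,\qquad
  \mathrm{PRD} = \sqrt{\frac{\sum (x - \hat{x})^2}{\sum x^2}}.$$

PRD is kept as a ratio internally and reported as a percentage at the
command line. A perfect reconstruction yields an infinite SNR improvement;
such degenerate rows are dropped from Monte-Carlo aggregates with a logged
count rather than raised as errors.

## The synthetic generator

`synth_ecg()` builds each beat as five Gaussian bumps (P, Q, R, S, T) on a
quasi-periodic grid: beat period $60/\mathrm{HR}$, perturbed
multiplicatively by a uniform jitter of ±`rr_jitter_frac` (default 5%, a
realistic resting RR variability). The default morphology, in (amplitude
mV, centre as fraction of the beat period, width s):
P(0.15, 0.10, 0.025), Q(−0.10, 0.22, 0.010), R(1.00, 0.25, 0.012),
S(−0.15, 0.28, 0.010), T(0.30, 0.45, 0.060); sampling defaults to 360 Hz.
Noise models: white Gaussian; EMG as white noise band-limited to 20 Hz–
0.45·fs by spectral masking (exactly band-confined and seed-deterministic);
powerline and baseline drift as seeded-phase sinusoids at 50/60 Hz and
0.25 Hz respectively. `mix_at_snr()` scales a noise vector so the
clean-to-noise energy ratio hits the target SNR exactly.

What the generator does *not* emulate: beat-to-beat morphology change,
arrhythmic and ectopic beats, electrode motion artifact, mains harmonics,
or non-stationary noise levels. Passing tests on these fixtures show that
the pipeline behaves as designed under controlled contamination of a
stylised normal rhythm; they do not certify performance on pathological
recordings.

## The evaluation harness and shipped problem sizes

`run_grid()` crosses noise kinds × input SNR levels × repetitions, derives
a per-cell seed from the master seed by a modular string hash (so any cell
is independently re-runnable), mixes, denoises, scores, and aggregates.
The whole run is bit-reproducible for a fixed master seed; applied
settings and dropped degenerate rows are logged as machine-parsable
`key=value` lines.

The shipped checks use a 30 s record at 360 Hz (72 bpm): the
Gaussian-noise efficacy study runs 20 repetitions per input SNR level in
{0, 5, 10, 15} dB with common noise draws across levels (so the level
comparison is paired), and the reproduction script
(`scripts/acceptance.R`) runs 10 repetitions per cell over the full
three-noise × 0–25 dB grid. These sizes give stable means (standard errors
well under the effects of interest) at desk-scale runtimes.

## Known limitations

* At high input SNR (20–25 dB) removing the first two modes can cost more
  signal than the little noise it removes; mean SNR improvement can go
  negative there. This is intrinsic to hard mode removal and is why
  improvement decreases with input SNR.
* EMD mode mixing: on near-noiseless spiky records the first modes carry
  envelope-driven beat content with substantial power; the amplitude gate
  refuses removal there, at the price of leaving faint noise in place.
* The cumulative-mean threshold leans on the record's nonzero average
  level; for strictly zero-mean (AC-coupled) records the RMS fallback is a
  heuristic.
* Single-channel only; no attempt to exploit multi-lead redundancy.
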