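---
title: "Trial-to-trial variability of evoked network spikes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-to-trial variability of evoked network spikes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Cultured cortical networks on multi-electrode arrays respond to a periodic
electrical stimulus with *network spikes* (NSs): transient synchronized
population bursts with a characteristic scale around 100 ms, a
threshold-like all-or-none character, and a network refractory period of
1–10 s. Under fixed stimulation the responses are anything but fixed: whether
a stimulus evokes an NS, how long the response takes to peak (*latency*), and
how long the burst takes to fall back to baseline (*decay duration*) all
drift over seconds to many minutes. `nsdyn` implements the analysis chain
that quantifies this trial-to-trial variability, together with a synthetic
recording generator that makes every stage testable against ground truth.

This vignette records the model assumptions, the tunable parameters and why
their defaults are what they are, the numerical choices, and the known
limitations — in particular which features of real recordings the synthetic
generator does and does not emulate.

## The analysis chain

**Detection.** All spikes, pooled over electrodes, are binned at 3 ms into a
population firing rate (spikes/ms). An NS is a maximal run of bins strictly
above a threshold; runs separated by less than a 200 ms merge window are
joined, bridging brief within-burst dips while staying far below the
network refractory period. Each event reports its onset (left edge of the
first supra-threshold bin), its peak time (center of the earliest bin
attaining the run maximum — the deterministic tie-break), and its peak rate.
The peak time is the fiducial used by all counting statistics.

The threshold deserves a note. On 3 ms bins a *single* background spike
registers 1/3 spikes/ms, so any threshold below that is crossed by every
stray spike, and the merge window then chains the whole recording into one
event. A usable threshold on sparse-background recordings must sit above the
few-coincident-spikes shot-noise level and below the NS peak rate. The
function default is 0.15 spikes/ms (the one rate anchor the decay definition
provides, appropriate for clean or dense-background traces); the analysis
scripts use 1.5 spikes/ms for the synthetic recordings, i.e. at least five
coincident spikes per 3 ms bin, which keeps the false-event rate below ~0.2
per 24 h at the default background of 0.02 spikes/ms while missing ~0.3% of
events at the default 2 spikes/ms envelope peak. An adaptive variant
(baseline mean + 3 SD outside stimulus windows, floored just above the
single-spike level) is provided.

**Pairing.** A stimulus succeeds if at least one NS onset falls within 1 s
after it; the earliest unassigned NS is assigned, earliest stimulus wins,
and NSs assigned to no stimulus are labeled spontaneous. Successes plus
spontaneous events always add up to the detected total.

**Response features.** For each success, spikes within 1500 ms of the
stimulus form a PSTH at 1 ms resolution, smoothed by a 5 ms moving average.
Latency is the time from the stimulus to the *first maximum* of this trace.
Because reverberatory second peaks can exceed the primary response, "first
maximum" is operationalized as the first local maximum reaching at least
half the global maximum (`prominence_frac = 0.5`; a pure argmax is available
via `"global"`). Plateau ties resolve to the earliest bin. Decay duration is
measured on a more heavily smoothed copy of the same histogram (a 30–100 ms
moving average; default 50 ms, one value per run rather than per-network
hand-tuning) as the time from the latency bin to the first drop below the
0.15 spikes/ms floor; traces that never cross the floor within the window
are kept but flagged as censored, and censored decays are excluded from the
serial analyses by default to avoid a ceiling artifact. All smoothing uses
centered windows that shrink at the edges (the divisor is the number of bins
actually covered): zero-padding would bias peak locations toward the window
interior.

Latency is threshold-free and therefore invariant under uniform rescaling of
the firing rate; decay duration is not — both properties are tested.

**Local response probability.** The fraction of successes among the 10
stimuli before and 10 after a given stimulus, with the index stimulus
excluded (including it makes the measure partially tautological in
success-conditioned analyses) and the window truncated at the series edges
with the denominator equal to the actual neighbor count.

**Fano-factor scaling.** NS peak times form a point process. Counts
`Z(T)` in non-overlapping windows of length `T` (anchored at t = 0, partial
final window discarded) give the Fano factor `FF(T) = var(Z)/mean(Z)`, with
the unbiased n−1 variance since large `T` leaves few windows. `FF ≈ 1`
marks Poisson-like occurrence; growth `FF(T) ≈ αT^β` with `0 < β < 1` marks
long-range correlation. The default grid is 20 log-spaced points per decade
from 0.05 s to duration/10, keeping at least 10 windows per point. The
"final rising section" is delimited by a deterministic post-minimum rule —
from twice the `T` of the curve's minimum to the largest retained `T` — and
fitted by OLS of log10 FF on log10 T. The rule is config-exposed; an
explicit range override exists, and the interval-shuffled surrogate of a
train is fitted over the *same* range as its original so the contrast
compares like with like.

**Surrogates.** The null for long-range order permutes the inter-NS
intervals (seeded Fisher–Yates), preserving the first event, the span and
the exact interval multiset while destroying serial order.

**Serial structure.** Latency and decay series over the stream of successful
responses are autocorrelated at *serial-index* lags, using the estimator
with the full-series mean and full-length denominator exactly as the
analysis defines it (Bartlett convention; `ρ(0) = 1` and `|ρ| ≤ 1` follow by
Cauchy–Schwarz, and no per-lag unbiased variant is substituted because the
full-sum denominator is part of the definition's anti-drift behavior).
Failed responses are dropped, not interpolated. The warped time axis
converts lag `l` to seconds as `l` times the mean inter-response interval of
the retained responses. Latency–decay pairs plotted in order form the plane
trajectory; each coordinate is smoothed by a centered 11-response moving
average (the window is a package choice; the source analyses state none)
and segmented into consecutive 50-response stretches. The center of mass is
computed on log10 coordinates by default, matching the log-log plane on
which these trajectories are displayed.

## The synthetic generator

The generator is a statistical test harness, not a biophysical simulation.
Two slow latent states stand in for "exciting" and "restoring" influences:
`e(t)` drives decay duration (`D = 100 + 25·e` ms, clamped to [30, 1000]),
`i(t)` drives latency (`L = 150 + 40·i` ms, clamped to [10, 600]), each plus
per-response Gaussian noise (5 and 10 ms). Three latent modes:

* `ou` — two independent unit-variance Ornstein–Uhlenbeck processes with a
  100 s time constant (exact discretization at the stimulus grid);
* `oscillatory` — a sinusoid with a period counted in responses, plus OU
  noise (used to verify that latent rhythms reappear in the serial ACF);
* `fgn` — a single fractional Gaussian noise state (exact Davies–Harte
  circulant-embedding sampling) with `e = z`, `i = −z`, so one long-memory
  state drives occurrence, latency and decay jointly; this mode produces the
  inverse relation between local response probability and latency.

A stimulus succeeds when the response propensity — the slow state mixed with
white per-trial noise, `prop = (slow + 0.6·ε)/sqrt(1 + 0.6²)` — exceeds
`qnorm(1 − 0.22)`, anchoring the marginal success probability at the ~0.22
observed under sustained stimulation, *and* the previous NS peak lies at
least one refractory period (default 2 s) in the past. The trial noise is
deliberate: thresholding a *pure* self-similar state produces duty-cycle
bursting with so heavy an inter-event-interval marginal that its
interval-shuffled surrogate is itself strongly non-renewal; the white
component lightens the marginal while the slow component's correlations are
only scaled (by 1/(1+w²)), which the occurrence calibration compensates.

Each response is rendered as a rate envelope: a Gaussian rise (SD 15 ms)
peaking at the programmed latency, then an exponential fall whose time
constant is chosen so the *total* rate (envelope + baseline) crosses the
0.15 spikes/ms floor exactly at latency + decay. Programmed features are
therefore exact fiducials. Spikes are drawn from the envelope as an
inhomogeneous Poisson process (or deterministically, at integer crossings of
the cumulative intensity, in the zero-noise configurations used for
per-response recovery tests — Poisson sampling at physiological amplitudes
cannot pin a smoothed argmax to ±3 ms on single trials), assigned uniformly
to 60 electrodes, on top of a homogeneous 0.02 spikes/ms background.
Spontaneous mode removes the stimuli and places NSs on a 3 s candidate grid
via a log-linear doubly-stochastic hazard of the slow state,
`p = 1 − exp(−r·dt·exp(σz − σ²/2))` with rate 0.1 NS/s and σ = 1.3: a hard
threshold saturates at the refractory ceiling under strong clustering,
whereas the graded hazard keeps occurrence long-memory without that ceiling.

**Occurrence calibration.** In fgn mode the Hurst exponent is not taken
naively as `(1+β)/2`. The quantity the pipeline ultimately measures is the
OLS slope of a *finite-sample estimate*: windowed counts are long-range
correlated, so the sample variance around the windows' own mean is biased
low, `E[S²] = (m/(m−1))(V(n) − V(mn)/m²)` for `m` windows of `n` grid cells,
where `V(x)` is the count variance over `x` cells. The generator therefore
solves for the `H` whose *predicted estimated* curve has the target slope
over the default grid, using the exact Mehler-series covariance of threshold
indicators (evoked) or the small-μ lognormal-hazard expansion (spontaneous).
The mapping remains approximate at the margins (hazard saturation, clamps,
and the extra penalty from fitting the logarithm of a noisy variance
estimate, which the expectation model does not capture); the end-to-end
recovery test is the contract.

## What the tests do and do not show

The acceptance suite recovers, from raw synthetic spikes: the evoked Fano
exponent (target 0.64 within ±0.15 on a fixed-seed 24 h recording; the
across-network spread of single-recording estimates is ±0.09, so the
reproduction scripts average 8 networks as the original cohort statistic
was formed), the Poisson control (FF within [0.9, 1.1] for T ≤ 100 s), the
surrogate contrast, exact refractoriness, per-response latency/decay
recovery (±3 ms / ±25 ms in the zero-noise configuration), the 60-response
latent oscillation in the latency ACF (±6 lags), the hand-computed oracles,
and the negative probability–latency rank correlation.

Passing these tests shows the *pipeline* is correct and the generator meets
its statistical targets. It does not show that real recordings satisfy the
generator's assumptions: real MEA data have electrode-specific rates and
spatial structure (the generator assigns spikes uniformly), stimulus
artifacts, bursts with rich internal structure rather than a smooth
envelope, development and drift over 24 h (the generator is stationary by
construction), and detection operating points that must be chosen per
preparation.

**A known, documented shortfall.** The spontaneous-mode target — a fitted
exponent of 0.89 ± 0.21 from a single 24 h record — is not met, and we argue
it cannot be by *any* stationary generator under these estimator conditions.
The windowed sample variance subtracts each realization's DC rate component;
with `V(x) ∝ x^{2H}` the top grid point (T = duration/10, m = 10 windows)
retains only `1 − 10^{2H−2}` of the asymptotic variance, and fitting the log
of the noisy estimate costs more. Empirically the measured slope tracks the
true exponent minus 0.15–0.3, and since stationarity bounds the true
exponent below 1, measured values saturate near 0.65 even for an ideal
fractal-rate Poisson process with no refractoriness (0.36–0.54 across seeds
at H = 0.90–0.97). Exponents near 0.9 estimated from real 24 h spontaneous
recordings therefore likely carry a contribution from slow nonstationarity
(maturation, drift), which this generator deliberately excludes. The
spontaneous recovery test states the intended band and is left failing as
an honest record of this limit; the spontaneous train still shows robust
scale-free FF growth, just with a smaller fitted slope (~0.3–0.5).

## Numerical choices and degenerate inputs

* Half-open bins `[kw, (k+1)w)` everywhere; a spike exactly at the recording
  end joins the last bin.
* Ties (run maxima, PSTH plateaus) always resolve to the earliest bin.
* Zero-variance series raise errors rather than returning NaN (serial ACF on
  a constant series; empty trajectories).
* A PSTH whose latency bin is already below the decay floor logs a
  degenerate zero decay rather than failing the response.
* Smoothing windows are forced odd; edge windows shrink.
* `fano_curve` drops window sizes with zero mean count with a warning and
  requires ≥5 retained grid points; `fit_powerlaw` requires ≥5 points in
  range.
* All randomness flows from a single integer seed per run; identical config
  + seed reproduces recordings, surrogates and manifests bit-identically.
  Circulant-embedding eigenvalues are clipped at zero against roundoff.
* Problem sizes in the shipped tests: 24 h recordings for counting
  statistics (~17k stimuli, ~2M spikes, simulated and analyzed in seconds),
  2520 s for the 500-response feature-recovery check, 6030 s for the
  oscillation check, 10010 s (~2000 stimuli) for the probability–latency
  relation.

## Interfaces

Recordings, stimulus logs, NS trains, response tables, Fano curves, ACFs and
ground truth all round-trip through tab-separated text with `#` comments
(times in seconds, rates in network-summed spikes/ms, 1e-6 precision):
small, diffable, and independent of any vendor format. `run_pipeline()`
drives simulate → detect → features → fano → serial from a flat `key =
value` config (unknown keys rejected) and writes a JSON manifest with the
effective configuration, per-file MD5 digests and collected warnings; the
numbered scripts under `analysis/` are thin narrative drivers over the same
exported functions, and `scripts/acceptance.R` recomputes the headline
statistics from scratch.
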