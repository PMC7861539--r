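---
title: "Methods: active probing of coupled neural mass models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active probing of coupled neural mass models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the estimators, and every numerical and
design decision in `nmprobe`, in the spirit of a methods section: what is
computed, under which conventions, and what the package's simulations can
and cannot say about real electrophysiology.

## The coupled model and its assumptions

Each of the two simulated populations is a lumped (neural mass) description
of the CA1 circuit: pyramidal cells with an excitatory interneuron feedback
loop, a slow dendritic inhibitory loop, and a fast somatic inhibitory loop.
Two functions define every mass: the asymmetric sigmoid converting mean
membrane potential to mean firing density, \(S(v) = 2e_0/(1+e^{r(v_0-v)})\),
and a second-order linear synaptic filter whose impulse response is
\(h(t) = X\,x\,t\,e^{-xt}\) for a gain/rate pair \((X, x)\). Writing each
filter as two first-order equations yields ten state variables per
population; the state vector of the coupled system has twenty components.

The populations are coupled bidirectionally and symmetrically through their
pyramidal cells with gain \(K\) and a pure transmission delay
\(\tau_d = 10\) ms, modelling inter-hemispheric hippocampal interaction.
The model output ("LFP") of population \(i\) is the net pyramidal membrane
potential \(K\,y_{1,j}(t-\tau_d) + y_{1,i} - y_{2,i} - y_{3,i}\).

Two conventions here were genuinely open and are package decisions:

* **LFP includes the coupling term.** The output is described as the
  average pyramidal PSP without stating whether the delayed partner input
  belongs to it. We include it, because that sum is the membrane potential
  that actually drives pyramidal firing (it is the argument of the sigmoid
  in the \(y_5\) equation). `coupled_config(lfp_include_coupling = FALSE)`
  drops it.
* **Sign of the excitatory feedback.** The excitatory interneuron loop
  enters the pyramidal input equation as \(+C_2 S[C_1 y_0]\). With a
  negative sign the loop would be inhibitory and the model loses its
  characteristic transition to spiking entirely (verified numerically: with
  the minus sign an excitatory gain of \(A_1 = 5\) produces no
  suprathreshold activity at all, contradicting the model's established
  regime map). The positive sign is the model-lineage convention and the
  one implemented.

### The coupling signal and the position of the ictal threshold

The coupling term multiplies the partner's excitatory PSP state
\(y_{1,j}\), which at the operating point carries a DC component of several
millivolts. Consequently \(K = 0.3\) is a strong tonic excitatory drive,
and the threshold for sustained discharges sits near \(A_1 \approx 4.25\)
(at default \(B, G\)), rather than just below 5 as for the uncoupled
population. Ramps that were designed to "approach" the ictal boundary
(\(A_1 \to 4.6\), \(B_1 \to 30\), \(K \to 0.5\)) therefore cross into
spiking over the last portion of a run in this implementation. We verified
the alternative reading — coupling through the partner's net LFP
\(y_1-y_2-y_3\), a far weaker drive — and found it fails to seize at
\(A_1 = 5\) with \(K = 0.3\), contradicting the model's documented regimes,
so the \(y_1\) form is the default and the LFP form remains available via
`coupled_config(coupling_signal = "lfp")`. The practical consequence for
the pro-ictal experiment is discussed under Limitations.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `A`, `B`, `G` | excitatory / slow inhibitory / fast inhibitory gain | 4.0 / 40 / 20 | mV |
| `a`, `b`, `g` | corresponding rate constants | 100 / 50 / 350 | 1/s |
| `C1..C7` | synaptic contact counts | 135 and fixed fractions (0.8, 0.25, 0.25, 0.1, 0.1, 0.8 of `C1`) | — |
| `v0`, `e0`, `r` | sigmoid midpoint, half-max rate, steepness | 6 mV, 2.5 1/s, 0.56 1/mV | |
| `mu`, `sigma` | afferent pulse-density mean, sd | 90, 1.3 | APs/s |
| `K`, `tau_d` | coupling gain, delay | 0.3, 0.010 | —, s |
| stimulus | pulse width, period, amplitude | 0.010 s, 2 s, 0–200 | APs/s |

`sigma = 1.3` APs/s is noticeably smaller than the noise historically used
with this model (tens of APs/s); it is implemented as specified and
exposed, so users can raise it. The same holds for the symmetric fast-loop
contacts `C5 = C6 = 0.1 C1` (the model lineage also used `C5 = 0.3 C1`);
the defaults follow the stated values.

Experimental settings are registered by name: `I-A`, `I-B`, `I-K` probe
population 2 while a population-1 parameter (or `K`) ramps linearly over the
whole run (`A1` 2.5→4.6, `B1` 45→30, `K` 0→0.5); `II-*` probe both
populations; `S-A`, `S-B` probe the ictogenic population 1. Pro-ictal
variants extend the ramps across the threshold: `A1` 4.30→4.95 (an
established value), `B1` 45→25 and `K` 0→0.8 (package defaults chosen to
cross the threshold comfortably; both are package choices, not published
values, and are exposed via `build_setting(..., ramp_start, ramp_end)`).

## Numerical scheme

* **Integration** is explicit Euler–Maruyama with a fixed step
  `dt = 0.00195` s (512 Hz); no adaptive stepping, matching the model's
  published practice. A guard warns when `dt >= 2/g`, the stability bound
  of the fastest linear block, and a diverging state aborts with the step
  number.
* **Noise discretization.** One `N(mu, sigma)` value per population per
  step, held constant across the step (`noise_mode = "per_sample"`). This
  treats the pulse density as a band-limited input signal, the convention
  of this model family; the effective noise power then depends on `dt`.
  `noise_mode = "sqrt_dt"` instead scales the deviation by
  `1/sqrt(dt)`, making the accumulated noise a true diffusion of intensity
  `sigma` independent of the step.
* **Delay handling.** The delay is rounded to `round(tau_d/dt)` steps
  (5 at defaults) and served from a ring buffer, zero-filled before
  `t = tau_d`. No interpolation.
* **Initial conditions** are the all-zero state. The relaxation to the
  operating point takes a few hundred milliseconds and can transiently
  exceed the spike threshold, which is why onset detection excludes a
  burn-in (below) and stimulation starts at `t = 2` s (one full period).
* **Determinism.** The C++ integrator draws from R's RNG, so
  `(seed, configuration)` reproduces traces bit-for-bit. Sweep and
  experiment cells derive their seeds by hashing
  `(base_seed, setting, amplitude, realization)` into 31 bits, so no two
  cells share a stream and every result is reproducible from the base seed.

## Feature estimators

Post-stimulus epochs start at the first integration step of each scheduled
pulse and last `floor(0.400/dt)` samples (205 at the default step). The
schedule is a property of the protocol timing only, so passive runs are
epoched identically to probed runs.

* **Moments** use 1/n normalization; kurtosis is the Pearson convention
  (normal ≈ 3), without the excess-kurtosis shift. Rank correlations are
  invariant to that choice. Zero-variance epochs yield variance 0 and
  missing skewness/kurtosis.
* **Lag-1 autocorrelation** is the standard one-lag sample estimator.
* **Mutual information** is a plug-in 2-D histogram estimate with 16
  equal-width bins per axis over each epoch's own range
  (16 ≈ sqrt(205) rounded to a power of two), in bits. Constant epochs give
  0. The estimator has the usual positive bias of order
  \((B-1)^2/(2N\ln 2)\); since probing efficiency is a rank correlation
  along a series computed with a fixed estimator, the bias cancels out of
  the analysis.
* **Smoothing** is an order-20 moving average, causal (trailing window) by
  default — the natural choice for a forecasting statistic that may not use
  future samples; prefixes average what exists and missing values are
  skipped. A centered variant is available.

## Probing-efficiency analysis

Each smoothed feature series is paired with the ramped parameter evaluated
at the epoch onset times, and scored with Spearman's rho (average ranks for
ties, Pearson correlation of the ranks). Smoothed rather than raw series
are scored by default (`use = "raw"` switches). Amplitude sweeps repeat
this over a grid including the passive baseline; group differences against
amplitude 0 use Tukey's HSD on the per-realization rho values directly
(Tukey–Kramer for unequal groups after exclusions); a Fisher-z option is
provided for variance stabilization.

## Spike and onset detection

Spikes are strict local maxima above 5 mV, at least 100 ms apart (higher
peak wins; the peak finder is `pracma::findpeaks`, as no finder is
prescribed), with peaks inside 200 ms after any delivered stimulus removed
as direct evoked responses. Ictal onset is the first spike of the earliest
run of five spikes whose successive inter-spike intervals are all at most
4 s. The stated rule ("intervals of at least 4 seconds, in succession") is
self-contradictory — clustered discharges have short intervals — so the
at-most reading is the default and the literal at-least reading is kept
under `rule = "min_isi"`. Onset detection also ignores the first 2 s of
the trace (the startup transient, see above). In the pro-ictal experiment
the passive arm receives no stimuli and hence no blanking.

## Problem sizes in tests and the acceptance script

Full-scale experiments (2000 s runs, eleven amplitudes, fifteen
realizations) are supported and are the defaults of `run_experiment()`.
The test suite and `scripts/acceptance.R` run reduced versions chosen to
exercise every code path while remaining quick on a single core: 400 s
sweeps with amplitudes {0, 120} and five realizations for the
probing-vs-passive contrast, and 300 s pro-ictal runs with ten
realizations. The qualitative orderings these check (probed correlations
exceeding passive; onsets not anticipated by probing) are stable across
seeds at these sizes.

## What the simulations do and do not show

The generator *is* the study system: all inputs are synthetic, so the
pipeline is validated against the model's own ground truth (the known
ramped parameter), not against recordings. Passing tests demonstrate that
the estimators recover a drift that is really there under this model's
dynamics and noise; they do not demonstrate forecasting power on real EEG,
where noise is neither Gaussian nor stationary, electrode placement and
volume conduction intervene, and ictogenic "parameters" are not scalar
ramps.

Known limitations:

* With the default coupling signal the `K = 0.3` operating point is close
  to the ictal boundary, so the approach-ramps cross into spiking near the
  end of a run, and the pro-ictal `A1` ramp (4.30→4.95) starts essentially
  at the boundary: onset latencies then cluster tightly just after the
  burn-in, and the 200 ms post-stimulus blanking systematically *delays*
  detected onsets in probed runs by a fraction of a second. The safety
  conclusion (probing does not anticipate onsets) is unaffected — the shift
  is in the safe direction — but latency distributions are much narrower
  than in a regime where the threshold is crossed mid-run.
* Per-sample noise makes the effective noise power depend on `dt`; results
  are reported at the fixed 512 Hz step.
* Euler–Maruyama is first-order; at `dt = 1.95` ms the fast inhibitory
  block (`g = 350`) is integrated with `g*dt = 0.68`, which is stable but
  coarse. The suite verifies first-order convergence and checks block
  equations against closed forms with an accurate solver; trajectories at
  the default step carry the corresponding discretization error.
* Only the normal-background and sustained-discharge regimes are
  operationalized (the detector targets the latter); the model's other
  activity classes (sporadic spikes, rhythmic, low-voltage fast, and
  quasi-sinusoidal activity) are not classified.
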