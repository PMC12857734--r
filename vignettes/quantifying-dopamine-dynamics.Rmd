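---
title: "Methods: burst statistics, surrogate tests, photometry and morphometry in daquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst statistics, surrogate tests, photometry and morphometry in daquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daquant)
```

This vignette documents the models and procedures daquant implements,
the assumptions behind them, the design decisions that were genuinely
open, and what the synthetic-data validation does and does not show
about real recordings.

## Burst detection and %SWB

In vivo juxtacellular recordings of midbrain dopamine neurons are
summarized per neuron by two statistics: the mean firing rate
(spikes / recording duration, Hz) and the percentage of spikes fired
within bursts,

$$\%SWB = 100 \times \frac{\text{spikes within bursts}}{\text{total spikes}}.$$

Bursts follow the classic two-threshold scheme for dopamine neurons: a
burst *opens* at the first of two consecutive spikes with an interspike
interval (ISI) strictly below 80 ms, *continues* while ISIs are at most
160 ms, and *terminates* at the first ISI strictly above 160 ms. Three
boundary decisions deserve comment:

* **The 80–160 ms band continues, but never opens, a burst.** The
  two-threshold convention is the only reading under which the two
  printed strict inequalities ("< 80 ms" onset, "> 160 ms" termination)
  are both meaningful; a single-threshold reading would make one of
  them redundant.
* **Strictness at the boundaries.** An ISI of exactly 80 ms does not
  open a burst; an ISI of exactly 160 ms continues one. To make these
  decisions independent of floating-point representation, spike times
  are converted to integer microseconds before any comparison. A spike
  train sampled at 12.5 kHz has a time quantum of 80 µs, so microsecond
  integers are exact for any realistic acquisition grid.
* **No re-opening on the closing spike.** After a burst closes,
  scanning resumes at the spike *after* the burst's last spike. Since a
  closing ISI exceeds 160 ms it could never satisfy the 80 ms onset
  rule anyway; the explicit rule simply guarantees bursts are disjoint.

A burst has at least 2 spikes (the onset pair) and no upper bound. The
minimum train for a burst is therefore two spikes; empty trains have
firing rate 0 and %SWB 0 by definition.

Neurons enter group statistics only after the four-criterion inclusion
gate for putative dopamine units — triphasic waveform, total duration
> 2.0 ms, start-to-trough width > 1.1 ms, and rate strictly between 1
and 10 Hz — with every violated criterion reported, because the gate
materially changes the group sizes and must be auditable.

## The surrogate permutation test

Per-neuron statistics from dopamine recordings are typically
right-skewed (a majority of tonic, low-%SWB cells and a long bursty
tail), so group means are compared by resampling rather than by t-type
statistics. The observed statistic is the absolute difference of group
means $\Delta_o$. The two groups (sizes $n_1$, $n_2$) are pooled and
the pool is randomly re-split into groups of sizes $n_1$ and $n_2$,
N = 10,000 times by default; each surrogate yields $\Delta_s$, and the
test counts surrogates with $\Delta_s \ge \Delta_o$ — ties count as
exceedances, which is the conservative direction. Decisions:

* **p = count/N exactly, with no +1 correction.** This matches the
  counting rule the procedure defines. Because a zero count only bounds
  the p-value (p < 1/N), the test emits a note in that case rather than
  silently reporting an exact zero.
* **Star thresholds.** At N = 10,000, significance at
  P < 0.05/0.01/0.001 is declared when the count is strictly below
  500/100/10. For other N the thresholds scale proportionally
  (fractions 0.05/0.01/0.001), which reproduces the printed counts
  exactly at N = 10,000.
* **Surrogates are independent random assignments**, sampled with
  replacement from the assignment space; distinctness is not enforced
  and the observed configuration is not added to the surrogate set.
  This is the straightforward reading of "generate N surrogates", and
  at the sizes involved (e.g. $\binom{142}{61}$ assignments) collisions
  are irrelevant.
* **Exhaustive mode.** When the number of distinct assignments
  (combinations — group labels are exchangeable within a group) is at
  most a configurable cap (default 10,000), `exhaustive = TRUE`
  enumerates them all and the p-value is exact. This mode doubles as
  the oracle for the Monte-Carlo path in the test suite.

The Kolmogorov–Smirnov comparison reports the ECDF sup-gap D as the
primary quantity (it is the distribution-shape statistic of interest);
the p-value is delegated to `stats::ks.test`, exact for small untied
samples and asymptotic otherwise. The Shapiro–Wilk statistic is likewise
delegated to `stats::shapiro.test`; only the branch rule — parametric
iff *every* group has P > 0.05 — is implemented here, with the boundary
P = 0.05 failing the strict "greater than" rule.

## Photometry processing

Inputs are already-demodulated channel streams: a 465 nm
sensor-dependent signal and a 405 nm isosbestic (activity-independent)
reference on a uniform grid. Processing stages:

1. **Isosbestic correction.** The reference is fitted onto the signal
   by ordinary least squares with slope and intercept,
   $r(t) = a + b\,F_{405}(t)$, and $\Delta F/F = (F_{465} - r)/r$. The
   affine fit was chosen over a plain ratio because it absorbs
   channel-specific offsets and gains, reduces exactly to
   $\Delta F/F \equiv 0$ when the channels coincide, and is invariant
   under a common rescaling of both channels. Its known limitation is
   that dense, large transients bias the fit slightly; at the transient
   densities simulated here the bias is far below the noise floor.
2. **z-scoring.** $z = (\Delta F/F - \mu_b)/\sigma_b$ with $\mu_b$,
   $\sigma_b$ taken over a declared baseline window. Restricted to that
   window, z has mean 0 and SD 1 *exactly* (asserted to 1e-9 in the
   tests, not assumed). Because no convention fixes the baseline
   globally, the peri-event path z-scores each event window against its
   own pre-event span by default — the only choice consistent with
   near-zero pre-event traces — while a per-session fixed window
   remains available via `zscore_trace()`.
3. **Peri-event alignment.** One row per event from `pre` s before to
   `post` s after onset. Events whose windows overrun a recording edge
   are dropped and counted, never zero-padded: padding would fabricate
   baseline samples.
4. **Binned AUC.** Area under the z curve in contiguous bins of 5 s
   (the figure-level quantification unit), computed as a left-Riemann
   sum $\sum z \,\Delta t$. Left-Riemann was chosen over the trapezoid
   rule because it is *exactly* additive over adjacent bins — the
   property the per-bin semantics require — and the difference is
   $O(\Delta t)$, negligible at 10–20 Hz effective rates. Bins start at
   the window start (−pre); a trailing bin not fully covered by samples
   is kept but flagged `partial` and excluded from group tests.

Per-bin group comparisons reuse the surrogate permutation test across
events.

HDF5 input is not supported in this build; traces are read and written
as CSV (`time_s`, `f465`, `f405`).

## Morphometry

Spines are classified by 2D head diameter: thin below 350 nm, mushroom
at or above. The rule as stated ("lower or higher") leaves the exact
boundary undefined; assigning 350 nm to mushroom is an arbitrary but
fixed, documented tie-break that keeps results deterministic. Spine
densities are reported per 10 µm of dendrite — the conventional unit
for the 50–70 µm segments these analyses use (lengths outside
10–200 µm are warned about, not rejected). Varicosity counts are
normalized to a 10-µm-side cube (1000 µm³); the source protocol's
"10-nm side" and "60 by 60 by 3 nm" stack dimensions are physically
impossible for confocal stacks with 60 nm pixels and are treated as µm
throughout.

## The synthetic-data generators

Each generator draws every random quantity from one explicit per-call
seed (no global RNG state) and retains its ground truth.

**Bursty trains.** A renewal-style event stream: each event is, with
probability `p_burst`, a burst of `spikes_per_burst` spikes at a fixed
intra-burst ISI (< 80 ms), otherwise a singlet. Inter-event gaps are
exponential with the event-rate mean, left-truncated at
`min_inter_event_gap_ms` (> 160 ms). The truncation guarantees that
generated bursts can never merge or split under the detector, so the
generated labels *are* the detectable bursts — recovery is exact, not
approximate — and the expected %SWB has the closed form
$100\,pk/(pk + 1 - p)$. Events truncated by the recording edge are
dropped whole. Defaults (1 event/s, burst fraction 0.3, 3 spikes per
burst at 40 ms ISI) put the realized firing rate near 1.6 Hz and %SWB
near 39%, i.e. inside the 1–10 Hz inclusion band with a realistic
bursty/tonic mix. What this emulates is the *statistical* structure the
detector and %SWB care about; it is not a biophysical neuron model —
no pacemaker regularity, no slow rate drift, no burst-size variability —
so exact recovery on these trains shows detector correctness, not
robustness to every in vivo irregularity.

**Group samples.** Lognormal (default meanlog 3, sdlog 0.6 — a skewed
distribution with mean ≈ 24, resembling a %SWB distribution), beta, or
normal families, with an additive location shift for the second group.
Used for null (shift 0) and power studies at the cohort sizes of
interest (61 and 81 units).

**Photometry.** Both channels share a mono-exponential bleaching
baseline (the simplest model that exercises the correction stage), a
smoothed common-mode motion artifact, and independent Gaussian noise;
only the signal channel carries transients. The transient kernel is a
difference of exponentials normalized to unit peak, with the analytic
peak lag $\ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)$ used as an
oracle. The transient term is applied multiplicatively,
$F_{465} = B(t)(1 + a\,K(t)) + \text{motion} + \text{noise}$, so that
the amplitude `a` is genuinely in ΔF/F units even as the baseline
decays; a purely additive kernel would make the effective ΔF/F
amplitude drift with bleaching. Real photobleaching is multi-exponential
and real motion is not stationary Gaussian; passing tests show the
correction pipeline's algebra is right, not that it defeats every
artifact.

**Spines.** A two-component Gaussian mixture (thin 250 ± 40 nm,
mushroom 500 ± 60 nm by default) with the constraint that each
component puts at most 2.5% of its mass on the wrong side of 350 nm —
mixtures that straddle the boundary more than that are rejected at
construction because their ground truth would be ambiguous. With the
defaults, the expected misclassification against true labels is ~0.6%
per component, well inside the ±2-point recovery tolerance.

## Pipeline and reproducibility

`run_config()` collects paths/tables and parameters; one master seed is
mapped to per-stage seeds by a fixed affine map modulo $2^{31}-1$
(`derive_seed()`), so stages are individually reproducible and never
share RNG streams. Reports carry the seed and a hash of the
configuration, and rerunning a pipeline with the same inputs and seed
produces byte-identical report files (asserted in the tests). Reports
are JSON plus CSV; every excluded neuron and dropped event is logged.

## Validation problem sizes

The test and acceptance suites use: 1,000 random trains against an
independently written naive ISI state machine (zero mismatches
required); 100–200 simulated trains for exact burst-label recovery; 200
recordings of 600 s at 1.5 events/s for the closed-form %SWB check
(±2 points); 500 null replicates of 61-vs-81 lognormal cohorts at 2,000
surrogates for the type-I check (rejection rate in [0.03, 0.07] at the
0.05 level); 50 datasets at group sizes (3,3) and (4,4) comparing
10,000-surrogate Monte-Carlo p against exhaustive enumeration (within 3
MC standard errors); 200 seeded traces at ΔF/F signal-to-noise ≈ 3 for
transient-bin localization (≥ 95% in the event-adjacent bin); and
10,000 spines for mixture-proportion recovery (±2 points). These sizes
were chosen so each check's Monte-Carlo error is several times smaller
than the tolerance it enforces.

## Known limitations

* Burst detection assumes spike times are already sorted, deduplicated
  and artifact-free; spike sorting is upstream.
* The isosbestic fit is global; slow sensor drift not shared with the
  405 nm channel is not corrected.
* The KS p-value is asymptotic for samples above 10 values or with
  ties; D itself is always exact.
* Morphometry consumes measurement tables; segmentation quality is the
  upstream tool's responsibility.
* Generators model the statistical structure the estimators consume,
  not the underlying biophysics; agreement on synthetic data bounds
  algorithmic error only.
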