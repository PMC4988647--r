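---
title: "Burst analysis of freely-diffusing smFRET data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst analysis of freely-diffusing smFRET data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `phburst`, the
estimators it implements, the defaults it ships with and why, the
numerical choices made where the literature leaves the details open,
and the limits of what its synthetic-data tests demonstrate.

## The data model

A single-spot measurement is an array of photon timestamps in integer
clock ticks (unit typically 10–50 ns), each labeled by detection
channel: donor emission (`Dem`) or acceptor emission (`Aem`). Under
microsecond alternating laser excitation (μs-ALEX) the lasers switch
with a fixed period; a photon's *excitation period* is recovered from
its timestamp modulo that period. With pulsed interleaved excitation
(ns-ALEX) the same role is played by the TCSPC nanotime. A *photon
stream* is any subset of photons defined by channel × period; non-ALEX
data has three canonical streams (all, `Dem`, `Aem`) and ALEX data five
(all, `DexDem`, `DexAem`, `AexDem`, `AexAem`).

The excitation period ranges `D_ON` and `A_ON` are half-open
`[start, stop)` intervals in clock ticks. The convention is a design
choice: printed period tuples in the field do not state an endpoint
rule, and half-open ranges guarantee a phase on a shared boundary is
counted exactly once. Applying the alternation removes photons outside
both ranges; the operation is deliberately one-shot (changing the
period definition requires reloading), so a stream selection can never
mix photons labeled under different period definitions.

## Background estimation

The timestamp record mixes two Poisson-like processes: single-molecule
bursts (high local rate) and background from dark counts, afterpulsing,
scattering and out-of-focus molecules (low rate). In the distribution
of inter-photon delays the background appears as an exponential tail;
burst photons contribute a short-delay excess. For delays above a
threshold `T` the tail is modeled as a left-truncated exponential whose
rate MLE has the closed form

\[ \hat\lambda \;=\; \frac{1}{\operatorname{mean}(d_i \mid d_i \ge T) - T}. \]

The package verifies this closed form against direct numerical
maximization of the truncated-exponential log-likelihood in its tests.
A least-squares alternative (straight-line fit to the log delay
histogram over nonzero bins above `T`) is provided for diagnostic
cross-checks; the MLE is the default and the recommended estimator.

**Automatic threshold.** `T` must sit above the burst-dominated region
but low enough to keep tail statistics. The heuristic implemented is a
fixed-point iteration: start at `T0 = 10 × median(delay)` (the median
is dominated by background, so `T0` starts an order of magnitude into
the tail), then alternate the MLE with the update `T ← c/λ̂`, `c = 3`,
i.e. place the threshold three mean background delays out, where the
probability that a background delay is truncated is `e^{-3} ≈ 5%` while
burst-range delays (tens of times shorter) are excluded. Iteration
stops when the rate changes by less than 1% (relative) or after 100
iterations, which is reported as an error with the iterate history.
This scheme is this package's own convergent formulation of the
commonly used "automatic threshold" idea; it does not claim equivalence
to any particular published optimal-threshold algorithm.

**Time dependence.** Backgrounds drift on tens-of-seconds timescales
(evaporation, impurity bleaching), so rates are estimated in
consecutive *background periods* of `window_s` seconds (default 30 s, a
standard monitoring resolution). Window `k` covers
`[k·window_s, (k+1)·window_s)` from acquisition start; a final partial
window shorter than `window_s/2` is merged into the previous one so no
period has less than half the nominal statistics. A window with too few
tail delays for a fit (fewer than `min_tail = 10`, configurable)
inherits the neighboring window's estimate with a warning — never a
silent `NaN`. A time exactly on a window edge belongs to the later
window. Rates for composite streams not estimated directly are the sum
of their canonical components (rates of independent Poisson processes
add).

## Burst search

The sliding-window search declares index `i` a *valid window start* iff
`t[i+m−1] − t[i] ≤ m / r_th(t[i])`: the local rate computed over `m`
consecutive photons exceeds the threshold rate. With the
background-dependent threshold `r_th(t) = F × λ̂(t)` every burst has a
signal-to-background ratio of at least `F − 1`; a fixed `min_rate_cps`
threshold is the alternative. Defaults `m = 10`, `F = 6` are the
field's general-purpose starting point. Numerical conventions fixed
here (the algorithm's usual descriptions leave them open):

- the comparison is inclusive (`≤`), and the threshold is evaluated at
  the *window's first photon*; when the background period changes
  inside a burst, each window uses its own start's period;
- a burst is a maximal union of **overlapping** valid windows (start
  indices closer than `m`). Valid windows that merely touch
  (`istop₁ + 1 = istart₂`) remain separate bursts: they share no
  photon, and the photons between the two window cores never sit in
  any valid window. This matches the operational semantics of "a burst
  ends when the rate drops below threshold" and keeps burst intervals
  disjoint;
- no burst fusion or recombination is applied afterwards.

By construction the minimum burst size is `m`. The optional `L`
parameter drops bursts with fewer than `L` reference-stream photons at
search time, but selection on corrected sizes after background
correction is the recommended route. The implementation is validated
against a brute-force window enumerator (exact equality on thousands of
randomized instances).

The AND-gate (dual-channel) search runs two independent searches —
by default all donor-excitation photons and `AexAem`, the classical
DCBS pair — and keeps the pairwise time-interval intersections
`[max(starts), min(stops)]`, re-indexed onto the all-photons stream
with all counts recomputed on the intersected interval. Intersection
is the natural interval algebra for the AND condition ("both streams
above threshold"); it is symmetric in the two streams, which the tests
assert.

## Corrections

Raw per-stream burst counts are corrected in this order:

1. **Background**: `n_s ← raw_s − λ̂_s(period of t_start) × width`.
   Corrected counts are real-valued and may go slightly negative; they
   are never clamped during computation, because clamping would bias
   population averages. The burst's background period is the one
   containing its start time.
2. **Leakage and direct excitation** (on `na` only):
   `na ← na − lk·nd − dir·naa`. The leakage coefficient is the
   donor-to-acceptor crosstalk ratio (leaked counts per detected donor
   count); the direct-excitation coefficient is expressed relative to
   the acceptor-excitation counts `naa`, the physically natural
   convention when ALEX data is available.
3. **γ factor** enters the derived quantities: burst sizes
   `n_dex = na + γ·nd` and `n_t = na + γ·nd + naa`, stoichiometry
   `S = (γ·nd + na)/(γ·nd + na + naa)`.

The *proximity ratio* `E_pr = na/(na + nd)` is computed from
background-corrected counts only — by definition it carries no γ,
leakage or direct-excitation correction. Fitting the `E_pr` histogram
and correcting the fitted population value avoids distorting the
distribution shape, so the population-level closed form

\[ E = \frac{E_{pr}(l + d_T\gamma + 1) - l - d_T\gamma}
           {E_{pr}(l - \gamma + 1) - l + \gamma} \]

is provided, with `d_T` the direct-excitation coefficient in the
*total-size* convention (contribution proportional to `γ·nd + na`).
The two conventions are related per burst by
`d_T = dir·naa/(na_corrected + γ·nd)` (`dir_ex_total_coeff()`). Because
the field's standard software derives these formulas in external
notebooks rather than print, the package re-derives them from the
counts model and enforces consistency by a dual-path oracle in the
tests: counts-level and population-level corrections must agree to
1e-9 on random bursts, the map must reduce to `E_pr/(E_pr(1−γ)+γ)` at
zero leakage/direct excitation, to the identity at γ = 1, and the
forward–inverse composition must be the identity to 1e-12.

## Selection and weighting

Selection rules (`size` with optional γ and `add_naa`, `naa`, `width`,
and the rectangular `ES` region) keep bursts whose statistic lies in
`[th1, th2]`, inclusive on both ends (an arbitrary but stated
convention). Rules compose by chaining, are idempotent and commute.
The standard FRET-population isolation is sequential: a Dex-size
threshold removes acceptor-only molecules, then an `naa` threshold
removes donor-only molecules. The `ES` region is rectangular; the
selection-by-S route is supported but truncates distributions and is
not recommended for quantitative population fractions.

Burst weights for population analysis are the γ-corrected sizes
(optionally including `naa`): the variance of a burst's proximity
ratio is inversely proportional to its size, so size weights are the
efficient choice and no other weighting is offered. Sizes driven
negative by background subtraction are clamped to zero at weighting
time only.

## Population fitting

The weighted histogram uses half-open bins `[e, e + binwidth)` anchored
at integer multiples of `binwidth` (default 0.03, a conventional E
resolution), so E data starts at edge 0. Bin mass is the sum of member
weights and the shot-noise variance of a bin mass is the sum of squared
member weights; the per-bin uncertainty used in fitting is
`sqrt(Σw²)`, floored at the mean weight so empty bins carry a finite
uncertainty. With this scaling the reduced χ² of a well-specified
model is ≈ 1, which the tests calibrate.

Models: 1–3 Gaussian peaks and a two-Gaussian-plus-plateau form
`A₁G(μ₁,σ₁) + A₂G(μ₂,σ₂) + A_b·B(x)` with `B = 1` on `[μ₁, μ₂]` and
Gaussian roll-offs (σ₁ left, σ₂ right) outside — an empirical shape for
two populations bridged by intermediate-FRET bursts; the exact plateau
definition is this package's own, stated stand-in. Initialization:
centers at the weighted 25th/75th (or 25/50/75th) percentiles,
σ = 0.05, amplitudes an equal split of the total mass; bounds
μ ∈ [−0.1, 1.1] (background overshoot can push E slightly outside
[0, 1]), σ ∈ [0.005, 0.5], amplitudes ≥ 0. Optimization is bounded
Levenberg–Marquardt (`minpack.lm`); component labels are sorted by
center after convergence, which is how the μ₁ ≤ μ₂ ≤ μ₃ ordering is
enforced. Non-convergence is an error carrying the last iterate. AIC
and BIC are computed from the Gaussian-residual likelihood
(`AIC = 2k − 2lnL`, `BIC = k·ln n − 2lnL`) so nested and non-nested
models can be ranked.

The weighted EM fit treats weights as case multiplicities. Its
initialization is deterministic (weighted quantiles), convergence is a
relative log-likelihood change below 1e-8 (at most 500 iterations),
and the weighted log-likelihood is asserted non-decreasing every
iteration in the tests. A component collapsing below σ = 1e-4 triggers
one deterministic perturbed restart, then an error. Standard errors
come from a finite-difference observed-information matrix; when that
matrix is not invertible they are reported as `NA` rather than
fabricated.

## Burst variance analysis

BVA splits each burst into consecutive non-overlapping chunks of
exactly `n` donor-excitation photons (default `n = 7`), starting at the
burst's first Dex photon and dropping the trailing remainder. Each
chunk's FRET estimate is the fraction of acceptor photons; a static
population makes the chunk acceptor count binomial `B(n, E_p)`, so the
chunk estimate has standard deviation `sqrt(E_p(1−E_p)/n)`. A burst is
summarized by the mean chunk FRET and the *population* standard
deviation of its chunk values (denominator = number of chunks,
matching the convention of the method's reference implementation).
Bursts with fewer than two chunks are excluded with a message — the
alternative (reporting 0 or `NaN`) silently distorts the s–E
distribution. Background photons inside chunks are neglected, the
method's standard approximation, valid at the signal-to-background
ratios the search guarantees.

Because the population standard deviation of `k` chunks underestimates
the process standard deviation by a factor ≈ `sqrt((k−1)/k)` (further
reduced by the χ-distribution mean bias), quantitative comparison of
the *mean* `s_E` against the shot-noise curve is meaningful only for
bursts with many chunks; the package's own calibration tests therefore
select large bursts (≥ ~100 Dex photons, ≥ ~14 chunks) before BVA.
`bva_dynamic_flag()` — the simple indicator `s_E` above the curve at
the burst's own mean FRET — is a convenience addition of this package,
not a hypothesis test; on static data with many chunks the flagged
fraction scatters around one half, while millisecond two-state
interconversion drives it towards 1.

## The simulator

`simulate_fret()` generates, from a single integer seed, every
statistical structure the analysis assumes: homogeneous Poisson
background per canonical stream (defaults 700/450/700/150 cps for
`DexDem`/`DexAem`/`AexAem`/`AexDem`, totalling 2 kcps in-period, plus
200 cps outside the excitation ranges); Poisson burst arrivals
(default 1 s⁻¹) with exponential transit durations (default mean 1 ms,
a typical confocal diffusion time) and a constant within-burst photon
rate (default 100 kcps, i.e. 50× background); binomial donor/acceptor
partitioning of Dex photons at the population proximity ratio; μs-ALEX
structure with a 50 μs period (4000 ticks of 12.5 ns, `D_ON`
(2100, 3900), `A_ON` (100, 1900)); acceptor-excitation counts thinned
to match the population stoichiometry; optional per-photon leakage
(crosstalk convention, so correction round trips have exact ground
truth) and direct-excitation misassignment; and optional two-state
continuous-time Markov dynamics with per-photon state-dependent E.
Ground truth (interval, population, true E/S, retained photon count)
is returned for every injected burst.

Deliberate simplifications, hence limits of what passing tests show
about real data: the transit profile is rectangular rather than a
diffusion-weighted intensity profile, so within-burst rate variation
and the correlated burst-size/width statistics of real diffusion are
not emulated; detector artifacts (afterpulsing correlations, dead
time), σ broadening beyond shot noise (acceptor photophysics, γ
heterogeneity) and multispot optics are not modeled; ns-ALEX lifetime
structure is not simulated (the I/O and period selection support it,
the generator does not). Tests passing on these synthetic data
validate the estimators under the stated model, not the model itself.

## Problem sizes and runtime choices

The test-suite simulations use 30–150 s acquisitions and the
acceptance script the standard 300 s measurement (~6×10⁵ photons) —
sizes chosen so every statistical check has comfortable power while a
full run stays interactive on a single core. All analysis stages are
deterministic; the only randomness is the simulator's, which is fully
seeded. Oracle comparisons (brute-force burst search, numeric MLE
maximization, dual-path correction algebra) run at exact or 1e-6/1e-9
/1e-12 tolerances as stated above; statistical assertions use fixed
seeds with tolerances set from the corresponding sampling variances.

## Known limitations

- Corrected `S` uses the γ-corrected donor-excitation size over the
  total size; a donor/acceptor excitation-intensity imbalance factor
  (often called β) is not modeled separately — it is absorbed into the
  simulator's stoichiometry thinning and the `naa`-relative
  direct-excitation coefficient.
- The plateau model's analytic form is a stated stand-in (see above).
- The automatic background threshold is a heuristic; pathological
  delay distributions (e.g. strongly multi-modal backgrounds) should
  be inspected with `bg_fit_lsq()` and per-stream thresholds.
- Multi-spot data is supported as independent per-spot analyses; no
  cross-spot pooling or per-spot calibration transfer is provided.
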