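---
title: "Modelling synchronous and asynchronous transmitter release with sarsyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling synchronous and asynchronous transmitter release with sarsyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarsyn)
```

## The model

Most network models treat transmitter release as strictly time-locked to
presynaptic spikes. At many GABAergic synapses — prominently at
fast-spiking (FS) interneuron outputs, and more so in epileptic human
tissue — a substantial fraction of vesicles fuses *asynchronously*,
during and long after spiking. `sarsyn` implements a phenomenological
synapse model with both pathways competing for one readily-releasable
vesicle pool, together with the full inverse pipeline that estimates its
parameters from voltage-clamp IPSC recordings.

Two Ca²⁺ sensors are summarized by two dynamic release variables. The
synchronous sensor carries a release *probability* `u_sr` ∈ [0, 1]; the
asynchronous sensor a release probability *rate* `u_ar` (1/ms), bounded
by a saturation level `U_max`. Between spikes both decay exponentially
(`tau_sr`, `tau_ar`); at each spike they jump,

    u_sr <- u_sr + U_sr (1 - u_sr),       u_ar <- u_ar + U_ar (U_max - u_ar).

The shared pool holds at most `N_F` vesicles of quantum size `x0`
(total resource `X_F = N_F x0`), replenished with time constant `tau_d`.
On a grid of width `dt`, the stochastic (quantal) simulator draws per
bin

    n_sr ~ Binomial(N, u_sr(t+))          (spike bins only)
    n_ar ~ Binomial(N - n_sr, u_ar dt)
    r    ~ Binomial(N_F - N, dt / tau_d)
    N    <- N - n_sr - n_ar + r

and the released amount is `x0 (n_sr + n_ar)`. The deterministic
mean-field twin replaces counts by expectations over the continuous
resource `x`; trial averages of the stochastic model converge to it
(this is asserted by the test-suite at 500 trials). An optional floor
`U0 > 0` makes `u_ar` decay to a positive resting rate, producing
spontaneous release between trains.

The postsynaptic side is a voltage-clamped exponential receptor model:
release convolved with `A exp(-t/tau_syn)` after a transmission delay
`D` (default 0.75 ms). Under clamp the gain `A = w (v - E_rev)` is
constant, so current is linear in release and splits exactly into
synchronous and asynchronous components.

## Event order and numerics

Within a spike bin the order is fixed: (1) facilitation jumps, giving
`u(t+)`; (2) synchronous release from the *pre-spike* pool
(`u_sr(t+) x(t-)`); (3) asynchronous release from what remains;
(4) replenishment from the vacancies at bin start. Drawing sequentially
guarantees `0 <= N <= N_F` with no rejection step; the synchronous/
asynchronous overlap within one bin that this ignores is negligible at
the default `dt = 0.05` ms (the resolution of the recordings this
pipeline targets).

Decay uses exact exponential factors, never forward Euler, so state
bounds hold for any bin width. The deterministic resource update
integrates `dx/dt = (X_F - x)/tau_d - x u_ar` with `u_ar` frozen over
the bin (an exponential update with effective rate `1/tau_d + u_ar`);
`u_ar` varies slowly relative to `dt`, making the freeze error far
below Monte-Carlo noise. Spike times snap to the nearest grid point
(within `dt/2` by construction). Simulations are seedable; repeated
trials use `seed + trial - 1` so any single trial can be reproduced in
isolation.

## The inverse pipeline

Recovering release from an IPSC trace proceeds in four steps.

**Leak subtraction** (`subtract_leak`): the mean current over a quiet
pre-train window is subtracted; residual positive excursions of the
(inhibitory, hence non-positive) synaptic current are clamped to
`-eps`, with `eps = 0.2` pA — small against quantal amplitudes
(~10 pA).

**Kernel estimation** (`fit_kernel`): `a exp(-t/tau) + b` fitted to the
decay of an isolated event. The offset `b` is estimated from the
segment tail and iteratively corrected for the decay's own tail
contribution, then held fixed in the nonlinear fit: a free offset
trades off against slow decays at realistic noise (a `tau`–`b` ridge)
and, at SNR ≈ 10, inflates `tau` errors severalfold. FS→PC synapses
have `tau_syn ≈ 5` ms, the package default.

**Constrained deconvolution** (`deconvolve`): a one-pass, bin-by-bin
inversion. At bin `i` the carried-over prediction is
`C(i) = J(i-1) exp(-dt/tau_syn)`; the unconstrained release estimate
matches the measured magnitude exactly, but the predicted current
`J(i)` is capped so that its future exponential decay never exceeds the
measured trace within a lookahead window (default `5 tau_syn`; beyond
that the bound is vacuous against the `eps` floor, and truncation keeps
the cost `O(N W)` instead of `O(N^2)`). Release is therefore asserted
only where the trace can support its decay — what makes inversion of
sparse quantal events well-posed where Fourier methods fail. Because
gain and release enter only as a product, the output is always the
scaled rate `q~ = A q` (pA); absolute units are deliberately never
claimed. On noiseless synthetic input the convolve–deconvolve round
trip is exact to fractions of a percent in L2.

**Delay estimation** (`estimate_delay`): the median lag between each
spike and the following release-rate peak; with the default generator
this recovers the 0.75 ms transmission delay to within one bin.

## Period statistics and the likelihood

Release is scored in spike-locked windows (`release_periods`): a
synchronous period per spike (1.1 ms long; starting 0.3 ms after the
spike for deconvolved data, at the spike itself when scoring simulated
release — both conventions are available behind the `convention` flag)
and the asynchronous gaps between them. Integrated amounts
`M_r(k, i)` per period, spike `k` and trial `i` are reduced to means
`mu_r(k)` and **population** standard deviations `sigma_r(k)` (divide
by `n`, not `n - 1`; with as few as 3 trials per period in the target
data sets the difference is material, so this choice is deliberate).
Degenerate `sigma = 0` values are floored at 1% of the grand-mean `M`
to keep the likelihood finite.

The fit (`sar_fit`) maximizes the Gaussian per-period log-likelihood
over an exhaustive Cartesian grid in
`theta = (tau_sr, U_sr, tau_ar, U_ar, tau_d, U_max)`. Predictions come
from the deterministic model with `X_F = 1` — released amounts are
proportional to `X_F`, so the scale is unidentifiable and all
predictions are renormalized so their sum matches the summed observed
means. Ties resolve to the first grid point in expansion order (first
dimension fastest), and this is deterministic.

Three structural choices matter:

* **Product parameterization.** `U_max` and `U_ar` both scale the
  asynchronous facilitation and are individually poorly constrained by
  short trains (saturation is rarely reached); their product is what
  the data pin down. The default grid therefore spans
  `U_arU_max = U_ar * U_max` and backs `U_ar` out per grid point. A
  direct `U_ar` grid remains available.
* **Grid refinement.** A single coarse pass quantizes the estimate and,
  worse, strands it on the likelihood ridge that the `A`-normalization
  creates between `U_sr` and `tau_d` (overall release scale is
  absorbed, so only the depression *shape* separates them). `refine = k`
  re-grids every free dimension over ±1 previous step around the
  current optimum, k times, roughly halving the resolution per pass
  while staying an exhaustive search within each pass. Two passes
  restore estimator fidelity at unchanged asymptotic cost; the
  parameter-recovery study uses `refine = 2`.
* **Confidence intervals** (`confint`): per dimension, a fine scan
  around the estimate with all else fixed; the interval is the
  connected region where the likelihood stays above 90% of its profile
  maximum — on the likelihood scale, not the log scale (the two
  differ). Intervals hitting the search-space edge are flagged
  open-ended, as expected for `U_max`.

## Quantal size

The fit leaves `x0` meaningless (it cancels in the mean-field
predictions). `quantum_size` estimates the quantal IPSC amplitude
`x0~ = A x0` from pure post-train asynchronous release: in 3.9 ms bins,
vesicle counts are approximately Poisson (Fano factor 1), so the
across-trial variance of the binned release `M(j)` is `x0~` times its
mean. The estimate is the slope of a variance-versus-mean regression,
through the origin by default (an intercept — absorbing e.g. additive
recording noise — is available via `intercept = TRUE`; on clean
synthetic data both agree). Consistency and 15%-accuracy at 50 trials
are asserted by the test-suite.

## The synthetic-data generator and the recovery study

`make_fixture` emulates the recording setup end-to-end: stochastic
trials, receptor convolution with delay, IPSC sign, constant leak, and
i.i.d. Gaussian noise, with ground truth retained. It reproduces the
qualitative signatures of FS→PC recordings — depressing spike-locked
IPSCs and asynchronous quanta persisting after the train — but
deliberately not: leak drift, reversal-potential drift during long
trains, receptor saturation or multi-exponential kinetics, or
correlated recording noise. Passing tests therefore validate the
estimator under the model's own assumptions, not against every
pathology of real recordings.

`sar_recovery` is the validation experiment: ground-truth parameters
drawn uniformly from documented ranges (`recovery_ranges()`:
`tau_sr` 4–10 ms, `U_sr` 0.1–0.5, `tau_ar` 8–20 ms, `U_ar` 0.004–0.02,
`tau_d` 20–80 ms, `U_max` 0.2–1 /ms, `N_F = 271`), 50 stochastic
trials of 25 spikes at 100 Hz each, then a two-stage fit: a coarse
6-parameter search, then — since `U_sr` and `tau_d` are reliably
recovered — a finer search over the remaining four with those two
fixed. The recovery grids span all six parameters *directly* (no
product parameterization): the `U_ar`/`U_max` redundancy is a finding
of this experiment, and building the product into the search would
presuppose it — with direct grids the individual estimates scatter
along the redundancy hyperbola while their product stays pinned. The fits consume period summaries of simulated release directly;
the deconvolution round trip is validated separately, so fitting error
is not confounded with inversion error. Report: per-parameter R²
(squared correlation of estimate vs truth), R² of the product
`U_ar U_max`, and the mean relative deviation between the
log-likelihood at the estimate and at the truth.

The package default is 30 settings (the full study used 120); at that
scale one run takes a few minutes on a single core. The expected
pattern — and what the acceptance checks assert — is high R² for
`U_sr`, `tau_d` and the product, intermediate for `tau_ar` and
`tau_sr`, and near-zero for `U_max` and `U_ar` individually, with the
likelihood at the estimate within ~1% of the truth's: the model fits
essentially perfectly even where individual parameters are
interchangeable.

```{r, eval = FALSE}
rec <- sar_recovery(n_settings = 30, trials = 50, seed = 1)
rec$r2
plot(rec$settings$true_U_sr, rec$settings$est1_U_sr)
```

## Worked example

```{r, fig.width = 7, fig.height = 3.5}
p <- sar_params()          # reference FS->PC-like synapse
p
spk <- regular_spikes(10, 100)
tr <- sar_simulate(p, spk, T = 200, seed = 1)
cs <- split_currents(tr, receptor_kernel(tau_syn = 5, A = 10, D = 0.75))
plot(cs$I_total$time_ms, -cs$I_total$current_pA, type = "l",
     xlab = "time (ms)", ylab = "IPSC (pA)")
lines(cs$I_ar$time_ms, -cs$I_ar$current_pA, col = 2)
```

```{r}
per <- release_periods(spk, 200, convention = "model")
sm <- summarize_trials(lapply(
  sar_simulate_trials(p, spk, 200, trials = 30, seed = 1),
  integrate_release, periods = per))
f <- sar_fit(sm, spk, 200, grid = sar_grid(n = 4), n_sp = 10, refine = 1)
f
```

## Known limitations

* The receptor kernel is a single exponential; saturating or
  multi-state receptors are out of scope (the release model itself is
  agnostic to this choice).
* `A`, `X_F` and `x0` are only identified in the combinations `A q`
  and `A x0`; all outputs are explicit about their scale.
* The deconvolution is one-pass and never revisits earlier bins;
  grossly non-causal artifacts in a trace (e.g. stimulation transients)
  should be excised beforehand.
* The Gaussian period likelihood uses trial SDs, not standard errors;
  it matches the estimator this package validates, but it is not a
  calibrated posterior — the 90%-likelihood intervals are heuristic
  summaries of surface flatness.
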