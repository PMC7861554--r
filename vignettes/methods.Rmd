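---
title: "Point-process Granger causality with exogenous modulation and trial-variable gains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-process Granger causality with exogenous modulation and trial-variable gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgranger)
```

## The problem

Granger causality asks whether the past spiking of neuron *j* improves the
prediction of neuron *i* beyond everything else we observe, including *i*'s
own past. For spike trains this is naturally phrased through the conditional
intensity function (CIF) \(\lambda_i(t \mid H(t))\), the instantaneous firing
rate of neuron *i* given the ensemble spiking history. The classical
point-process formulation models the log CIF as a baseline plus linear
history terms and declares a directed link \(j \to i\) when removing *j*'s
history terms significantly worsens the fit.

That formulation assumes all temporal structure in the data is *endogenous*
— produced by the recorded neurons themselves. Real trial-based recordings
violate this in two standard ways: stimulus- or movement-locked rate
modulations whose cause is not among the recorded units, and trial-to-trial
fluctuations of response magnitude that are often correlated across
neurons. Either one hands the fitting procedure variance it can only explain
through the interaction terms, which then produces confidently significant
links that do not exist.

## The three nested models

All three models are binomial generalized linear models with a logit link on
0/1 spike-occupancy bins of width \(\Delta = 1\) ms. For target neuron *i*,
the ensemble history enters as spike counts \(R_{q,m}(t)\) of each neuron
*q* in *M* non-overlapping lag windows of width *W* strictly preceding the
bin at *t*; windows never cross trial boundaries (counts reaching before the
trial start are truncated to the part inside the trial).

* **Baseline (`"kim"`)**
  \(\operatorname{logit} p_i(t) = \gamma_{i,0} + \sum_{q}\sum_{m}
  \gamma_{i,q,m} R_{q,m}(t)\).
* **G-ETM (`"getm"`)** replaces the constant \(\gamma_{i,0}\) by a
  piecewise-constant *exogenous* term \(\alpha_{i,c_i(t)}\), where
  \(c_i(t) = \lceil t N_i / T\rceil\) indexes \(N_i\) equal windows of the
  trial. These terms absorb within-trial rate modulation that no recorded
  neuron's history explains.
* **G-ETMV (`"getmv"`)** adds per-trial magnitude terms \(\beta_{i,p}\),
  absorbing trial-to-trial gain variation.

The models are fit by iteratively reweighted least squares
(`stats::glm.fit`). Because the response is 0/1, identical covariate rows
are first aggregated into binomial (successes, trials) groups — an exact
reformulation that typically shrinks the row count by one to two orders of
magnitude. Log-likelihood, deviance and AIC are always computed on the
Bernoulli scale (saturated log-likelihood zero), so they do not depend on
the grouping: \( \mathrm{deviance} = -2\,\ell \), \( \mathrm{AIC} =
\mathrm{deviance} + 2k \).

A note on the link: with \(\lambda\Delta \ll 1\),
\(\operatorname{logit}(p) \approx \log(\lambda\Delta)\), so the logistic fit
estimates the log CIF up to the bin-width constant. Reported exogenous
curves convert back to rates as \(\hat\lambda = \operatorname{expit}(\hat\eta)/\Delta\).

### Identifiability of the trial terms

Adding a constant to every \(\beta_{i,p}\) while subtracting it from every
\(\alpha_{i,c}\) leaves the likelihood unchanged, so the raw G-ETMV design
is rank-deficient by one. The default resolution is a hard sum-to-zero
reparameterization of \(\beta\) (the trial block uses sum contrasts;
reported \(\beta\) are mean-centered, and trial magnitudes are
\(\exp(\hat\beta_{i,p})\), estimating the generative gains up to a common
scale). An alternative soft mechanism (`beta_mode = "penalty"`) appends two
pseudo-observation rows that shrink \(\pm\sum_p \beta_{i,p}\) toward zero.
Both yield the same identified quantities to numerical accuracy (this is
asserted in the test suite); the hard constraint is the default because it
keeps the likelihood untouched.

With a single trial the trial block is dropped entirely and G-ETMV reduces
to G-ETM.

### Hyperparameter selection

\(W\), \(M_i\) and \(N_i\) are chosen per target neuron by minimizing the
AIC of the *full* model over a grid (`cif_grid()`; default
\(W \in \{2,4,8\}\) ms, \(M \in \{4,6,8,10\}\),
\(N \in \{5,10,15,20,30\}\); ties go to fewer parameters, then smaller
\(W\)). The reduced models of the Granger tests inherit the full model's
selected values — re-selecting them per pair would leave the chi-square
degrees of freedom undefined. The Monte-Carlo experiments use a compact
grid (\(W = 4\) ms, \(M = 4\), \(N \in \{12, 24\}\)) so that a full
comparison stays within desk-scale compute; at the simulated interaction
timescale (4 ms, most recent window) and bump width (0.2 s) the compact
grid loses essentially nothing relative to the full one.

### The Granger test

For each ordered pair \(j \to i\) (the diagonal included — self-influence
is a testable link), the deviance difference between the reduced fit
(without *j*'s history block) and the full fit is referred to
\(\chi^2_{M_i}\); a pair is a link when \(p < 0.05\), uncorrected, matching
the per-connection thresholding whose calibration the Monte-Carlo
experiments verify (optional Bonferroni/FDR switches are provided). The
difference is clamped at zero against floating-point noise; nesting
guarantees it is non-negative at the exact optimum.

Fits that hit *complete separation* (some history configuration perfectly
predicts silence — routine when a strong inhibitory input shuts the target
down for a few milliseconds) are kept for the deviance test: the likelihood
ratio remains finite and well-behaved in the separation limit, while Wald
standard errors of the affected coefficients blow up and their per-lag
p-values go to 1, which is conservative. A response with no spikes at all
is flagged degenerate; its tests are reported missing, never significant.

## The synthetic generators

### Point-process network

Spike trains are generated by Bernoulli thinning at 1 ms: neuron *i* in
trial *p* spikes in a bin iff a uniform draw falls below
\(\lambda_{i,p}(t)\Delta\), with

\[\lambda_{i,p}(t) = A_{i,p}\,\bigl(\lambda^0_i + B_i
e^{-(t-\tau_i)^2/2\sigma^2}\bigr)\,
\exp\Bigl(\sum_q\sum_m \delta_{i,q,m} R_{q,m}(t)\Bigr).\]

The Gaussian bump emulates stimulus-locked exogenous modulation; the
multiplicative \(\exp(\sum\delta R)\) term carries the directed
interactions (an empty history gives factor 1); \(A_{i,p}\) are per-trial
gains. The simulation refuses to run when \(\lambda\Delta\) exceeds 1
anywhere (the thinning model is invalid there), and requires the
deterministic part to satisfy \(\lambda\Delta \le 0.5\) so that the
one-spike-per-bin guarantee stays honest. Random-network draws that
self-excite past the bound are redrawn from the next derived seed; the
Monte-Carlo harness records how many redraws occurred.

### Integrate-and-fire network

The second generator violates the fitted model's assumptions on purpose:
pure integrator units (no leak) accumulate a time-varying drive plus signed
synaptic increments, spike on threshold crossing, reset, and redraw the
threshold from an exponential distribution — which makes an unconnected
unit's firing exactly Poisson (the memoryless threshold keeps the hazard
proportional to the drive). Influences are therefore *additive and
indirect* (through the membrane potential), not multiplicative and direct.
A fixed-threshold mode produces the pathological clock-regular regime in
which spurious short-lag synchrony defeats history-based inference; it is
included as the known failure case, not as a benchmark. Synaptic increments
arrive with a uniform 1–4 ms latency jitter; exact one-step delays plus
excitatory self-loops would produce clock-regular burst artifacts of the
same pathological kind, which no physiological preparation shows.

### Default study conditions

Trials last 3 s at 1 ms resolution; benchmark networks have 4 neurons and 6
directed connections (self-pairs allowed) drawn uniformly from the 16
ordered pairs, with excitatory/inhibitory sign equally likely; bump peaks
are uniform in [1, 2] s with \(\sigma = 0.2\) s; shared trial gains, when
present, are uniform in [0.55, 2.05). None of the remaining magnitudes
(baseline rate, bump amplitude, coupling strengths) are standard numbers,
so they were fixed once by a calibration study and are documented in
`random_network()` / `random_if_network()`; the calibration logic was:

* couplings must be *detectable but not saturating* at 40 trials — strong
  enough that a typical edge is found, weak enough that the weakest drawn
  edges are occasionally missed (otherwise detection sits at a ceiling and
  the sensitivity study is flat);
* the bump amplitude must be large relative to baseline, so that ignoring
  it (the baseline model) misattributes variance to interaction terms at
  well above the nominal error rate, as happens in real stimulus-locked
  data;
* the overall spike-count scale controls how strongly shared trial gains
  inflate the exogenous-only model's false positives; it was set so the
  gain experiment shows clear but not total miscalibration.

For the integrate-and-fire benchmark, synaptic weights are 3–10% of the
mean threshold distance (unitary-PSP-sized inputs). In pilot runs, strong
coupling (25–75%) put the network in a regime where the GLM's residual
misfit of the threshold nonlinearity, multiplied by ~10^5 bins, produced
reverse- and chain-edge false positives at ~30% — informative about the
method's limits, but not the physiological weak-coupling regime the
benchmark is meant to emulate.

## What the Monte-Carlo harness shows — and does not

`run_comparison()` draws a fresh random network per run, simulates 40
trials, fits the requested models, and scores percent-correct (denominator:
the 6 true edges) and percent-false-positive (denominator: the 10
non-edges). `sensitivity_grid()` sweeps edge strength and trial count in
the two-neuron, single-edge scenario and also runs the naive firing-rate
benchmark (`rate_benchmark()`): a one-sided paired t-test (Wilcoxon
optional) of the target's rate in the source's activation window [0.8, 1.2) s
against a baseline window [1.8, 2.2) s. The benchmark needs the network's
structure to even be formulated, and still detects less often than the
model-based test — weak influences shift spike timing more than they shift
window-averaged rates.

Passing these experiments shows that the estimators and tests behave
correctly *under the generative families above*: trial-aligned, stationary
per-window modulation, interactions at millisecond lags, gains constant
within a trial. Real recordings add non-Poisson firing, slow
nonstationarities not locked to trials, unobserved common input with its
own dynamics, and spike-sorting artifacts; none of those are emulated, and
the fixed-threshold scenario is a reminder that sufficiently regular
firing defeats the approach entirely.

## Numerical choices

* Bins are half-open with the (0, T] convention: a spike exactly on an edge
  closes its bin; simulator spikes sit at bin centers, so edge cases cannot
  arise in generated data. Same-bin collisions clamp occupancy to 1 with a
  counted warning (the response must be Bernoulli); the simulators cannot
  produce them.
* Aggregation groups rows by packing integer covariate keys into doubles
  (exactly, staying below 2^52) and hashing; `rowsum()` accumulates the
  binomial counts.
* IRLS runs to `glm.fit`'s default tolerance; coefficient covariance comes
  from the weighted QR factorization, as in `summary.glm`.
* Deviance differences are clamped at zero; ties in AIC selection break
  toward fewer parameters, then smaller W.
* Master seeds spawn per-run child seeds through a fixed integer recurrence
  (`(48271 * seed + index) mod 2^31 - 1`), so scaled-down and full-scale
  experiments share a randomness prefix and every run is individually
  reproducible.

## Problem sizes used in the shipped experiments

The package's own acceptance runs use 25 Monte-Carlo runs per comparison
experiment and a 3×3 sensitivity grid with 10 runs per cell; the test suite
uses 10-run versions with correspondingly wider (3 binomial standard error)
tolerance bands. Full-scale runs (100 runs; 50 per cell) are a `n_runs`
argument away and share the same seed prefix.

## Known limitations

* Trials must be equal-length and aligned; there is no support for
  continuous recordings or variable exogenous timing across trials.
* Exogenous modulation is assumed identical across trials up to the scalar
  G-ETMV gain; shape changes across trials are outside the model.
* History effects are piecewise-constant in lag and enter log-linearly; no
  spline bases, no regularized estimation.
* The deviance test is asymptotic; with very few spikes per trial the
  chi-square reference degrades before the fitter complains.
* How badly shared trial gains miscalibrate the exogenous-only model is not
  a universal number: the inflation grows with the total spike count (the
  history covariates become an ever better proxy for the hidden gain). At
  the package's default rates G-ETM's false-positive rate under gains is in
  the tens of percent, while G-ETMV stays at the nominal level; at lower
  firing rates the same mechanism produces milder inflation.
* Highly regular (sub-Poisson) firing produces spurious links by
  construction, as the fixed-threshold scenario demonstrates.
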