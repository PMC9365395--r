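---
title: "Aggregated Markov kinetic analysis of single-channel recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated Markov kinetic analysis of single-channel recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sckinetics)
```

## The model

A single ion channel gates among a handful of conformational states. Only the
conductance class of the occupied state is observable: the current is either
at baseline (shut) or at the open-channel level. `sckinetics` represents
gating as an *aggregated continuous-time Markov model*: a
`kinetic_scheme()` lists named states, each assigned to the shut or open
class, and first-order transitions with rate constants in s^-1
(ligand-dependent association rates in uM^-1 s^-1 are multiplied by the
ligand concentration in uM when the generator is built). Non-conducting
blocked states belong to the shut class, because a blockage appears in the
record as a closing.

The generator (Q) matrix collects the resolved rates; its within-class
sub-blocks determine everything measurable. The sojourn-time density of a
class `a` under ideal (infinite-bandwidth) observation is

    f_a(t) = phi_a  exp(Q_aa t) (-Q_aa) 1,

with `phi_a` the steady-state entry vector (the normalized probability flux
into the class). When `Q_aa` is diagonalizable this is a mixture of
exponentials whose time constants are `-1/eigenvalue` — the familiar
multi-exponential dwell-time histogram. `ideal_dwell_components()` returns
the (tau, area) pairs; the eigendecomposition is the default engine, with a
matrix-exponential fallback when the sub-generator is defective.

Five preset schemes cover the analyses the package was built around
(`scheme_preset()`): a linear priming scheme C - C' - O' for spontaneously
opening homopentamers built from an ancestral muscle-type AChR beta-subunit
(S1), its extension with one open-blocked state for open-channel block by
acetylcholine or QX-222 (S2), the wild-type adult muscle AChR activation
scheme with binding, gating and ACh self-block (S3), its QX-222-block
extension (S4), and a multi-priming chain with three connected open states
(S5). The preset rate constants are the published globally fitted values,
and `derived_constants()` reproduces the conventional equilibrium ratios:
priming `K' = k_plus/k_minus`, gating `Theta = beta/alpha`, binding
`K_n = k_minus/k_plus` (uM) and block `K_B = k_minus_B/k_plus_B` (uM).

The S5 connectivity deserves a note: it is fixed as a linear chain of shut
states with one open state attached to each primed shut state and no direct
open-open transitions. This is the topology forced by the published symbol
set (three priming equilibria, three gating equilibria); openings of the
three kinds interconvert only through their primed closed states.

## What the synthetic-data generator emulates

Real input would be idealized event lists from steady-state cell-attached
patches (the package reads and writes a TSV event dialect;
`read_events()`/`write_events()`). Because such recordings cannot ship with
a package, `simulate_state_path()` performs exact (Gillespie) stochastic
simulation of any scheme: exponential sojourns, successors proportional to
rates, start state drawn from the equilibrium occupancy, because the
emulated experiments are steady-state. `aggregate_to_events()` merges
same-class sojourns into the alternating shut/open event list an idealizer
would produce, and `impose_dead_time()` applies the finite time resolution
of detection: every dwell shorter than the dead time is treated as missed
and folded into the merge of its neighbours, exactly the recursive-merge
semantics the missed-event-corrected likelihood assumes. The generator keeps
hidden ground truth (state paths, HC-subunit counts) alongside its outputs
so that every downstream stage can be tested against known truth.

`simulate_trace()` additionally renders sampled current traces: rectangular
ideal current, Gaussian filter (the standard surrogate for the recording
chain's Bessel filter; 10-90% risetime 0.3321/fc), and white noise. The
generator does **not** emulate baseline drift, capacitive transients,
multi-channel overlap, or subconductance levels, so passing tests
demonstrate correctness of the estimators under the model's assumptions,
not robustness to every artifact of real patches.

Default study conditions mirror the emulated experiments: three simulated
recordings per condition, a dead time of 18.83 us, 10^4 events per
spontaneous recording, and block series of three recordings at each of 0,
10, 30, 60 and 100 uM blocker. Where the sources state no value (trace
noise SD, channel count per patch) the defaults are one channel and 0.5-1
pA noise at -120 mV, typical of good cell-attached recordings.

## Preprocessing: risetime, dead time, bursts

`idealize_trace()` uses 50% threshold crossing with linear interpolation
between samples; the incompletely observed first and last segments of a
recording are discarded. `correct_risetime()` inverts the Gaussian-filter
width transfer function numerically: for each apparent half-amplitude width
it recovers the true rectangular-pulse duration that would produce it;
events longer than about three risetimes are practically unchanged.

Burst analysis follows the standard critical-closed-duration construction.
Shut-duration distributions are fitted with exponential mixtures
(`fit_exp_mixture()`, below) and `determine_tau_crit()` places the
separation at the intersection of the two flanking components,

    t_c = log(a1 tau2 / (a2 tau1)) / (1/tau1 - 1/tau2),

the duration at which a closing is equally likely to come from either
component. `define_bursts()` removes longer closings as between-burst gaps,
trims bursts to start and end on an opening, and drops bursts with fewer
than three events. Per burst it reports duration, open probability
(open time / burst duration) and amplitude (mean open level minus mean shut
level). `filter_bursts_by_popen()` then cleans the per-burst open
probability distribution in two recorded passes: a median +/- 5 MAD outlier
pass (a deliberately conservative stand-in for fancier outlier detectors —
the second pass dominates in practice), then a Gaussian fit to the
survivors retaining bursts within 2 SD. Both pass counts are kept in the
result's `filter_log` attribute. Note that for highly efficient channels
the P_open distribution presses against its ceiling at 1 and is left-skewed,
so the 2-SD pass trims slightly more than the Gaussian 4.6%.

## Dwell-time mixtures and component counts

`fit_exp_mixture()` fits exponential mixtures by maximum likelihood on raw
(unbinned) dwells, left-truncated at the dead time; histograms
(`log_bin_histogram()`) are display only. Published practice is often a
visual fit, which is not reproducible; ML on the same truncated data is the
defensible surrogate and feeds the same downstream critical-duration rule.
EM runs from several deterministic starts: quantile-spread time constants,
seeded log-normal jitters of them, and a *nested* start built from the
(k-1)-component fit with its dominant component duplicated. The nested
start leaves the mixture density unchanged, so the attained log-likelihood
is provably non-decreasing in the component count — without it, EM local
optima occasionally invert the likelihood ordering and break
model-selection logic. `select_component_count()` accepts an extra
component while the likelihood-ratio statistic 2 dlogL exceeds 10, the
conventional single-channel threshold.

## Missed-event-corrected maximum likelihood

The core engine (`mil_fit()`) estimates rate constants from dwell
sequences. Events shorter than the dead time `t_d` are invisible, which
biases naive likelihoods badly (at 18.83 us, a quarter of the brief
shuttings of the spontaneous scheme are missed). The package applies the
standard first-order correction: within-class sub-generators become

    Q~_aa = Q_aa + Q_af (I - exp(Q_ff t_d)) (-Q_ff)^{-1} Q_fa,

which folds undetected opposite-class sojourns into the running dwell, and
a dwell of apparent duration `t` followed by a detected transition
contributes `exp(Q~_aa (t - t_d)) Q_ab exp(Q_bb t_d)`; the trailing factor
is the probability that the next dwell survives detection and makes the
two-state apparent-dwell density integrate to exactly one. At `t_d = 0`
everything reduces to the ideal likelihood, which the test suite pins
against an independent dense matrix-exponential oracle at 1e-8 relative
tolerance. The exact asymptotic missed-event forms are a known extension
point; at the dead times and rates this package targets, the first-order
correction recovers generating rates within a few percent and well within
statistical error, which the recovery tests measure directly.

Start vectors are a recorded convention: each dwell sequence starts from
the steady-state entry vector of its first dwell's class, and ends by
summing over exits from the final dwell (so every dwell, including the
last, contributes its full density). Global fits across recordings at
different concentrations share rate symbols, rebuild the generator per
recording, and sum per-sequence log-likelihoods; whether recordings are fed
whole or as burst fragments is the caller's choice (both are supported and
agree exactly when the fragmentation is trivial).

Optimization is quasi-Newton (L-BFGS-B) on log rates with box bounds
[1e-2, 1e7] s^-1 and relative convergence 1e-9; degenerate trial points
(singular correction terms at the box corners) evaluate to a likelihood
floor instead of erroring. Standard errors come from the numerical Hessian
in log-rate space, inverted and delta-methoded back to natural units;
symbols fixed by the caller (`fixed`, `constrained_refit()`) are honored
exactly. The forward pass over dwells is a small C++ kernel; everything
else is plain R.

## Open-channel block series

`extend_with_block()` appends a non-conducting blocked state to any open
state — the simplest sequential block model, deliberately: no blocked-state
closing, no trapping, one blocked state per blocker.
`fit_block_series()` runs the standard two fits over a concentration
series: core rates constrained to independently determined values with only
the blocking rates free, and everything free; comparing the two reproduces
the usual check that the inferred block kinetics are insensitive to the
core constraint. `block_signatures()` tabulates the two empirical hallmarks
(mean open duration falling, within-burst closing frequency rising roughly
linearly with concentration). For the wild-type QX-222 scheme the ACh
self-block state is retained alongside the QX-222 blocked state, since the
published constrained fits carry pseudo-first-order ACh block rates at each
fixed ACh concentration.

## Electrical fingerprinting

Co-expressing high- (HC) and low-conductance (LC) subunit variants of a
homomeric channel makes single-channel amplitude report stoichiometry: with
`n` exchangeable subunits assembling binomially there are `n + 1` amplitude
classes, linearly spaced between the all-LC and all-HC amplitudes.
`simulate_fingerprint_bursts()` generates exactly this (binomial HC counts,
linear means, Gaussian within-class jitter). `ebah()` builds the
event-based amplitude histogram (one amplitude per burst, fractions of
total bursts, poolable across recordings). `fit_amplitude_classes()` fits
equal-variance Gaussian mixtures for 1..8 classes and selects the count by
BIC; equal variance reflects shared measurement noise. Initialization
matters more than selection here: each class count is started both from
k-means and from equally spaced centers across the amplitude range, because
k-means alone will sometimes sacrifice a rare extreme class to split a
dense one, and the resulting poor local optimum corrupts the BIC
comparison. `infer_subunit_count()` returns classes-minus-one but only when
the extreme class means anchor to the measured pure-LC and pure-HC
amplitudes (within 20% by default) — class count alone is ambiguous when
extreme classes are rare — and reports an equal-step diagnostic;
`class_mean_regression()` quantifies the per-subunit conductance increment.
The fingerprinting pipeline assumes its standard preprocessing: 1 kHz
bandwidth and a uniform 2 ms critical closed duration.

## Numerical choices and degenerate inputs

* Units: concentrations in uM, second-order rates in uM^-1 s^-1, all
  internal time in seconds; reports use ms/us where natural.
* Dead-time imposition is idempotent and conserves duration except for
  unmergeable boundary events, which are dropped; it is tested against a
  literal recursive-merge oracle on random lists.
* Exponential-mixture EM: convergence at relative log-likelihood change
  1e-9, time constants floored at 1e-12 s, weights at 1e-12.
* A scheme whose transition graph is not strongly connected is rejected at
  construction; a zero blocker concentration leaves blocking rates
  unidentifiable, which surfaces as absent standard errors with a warning
  rather than an error.
* Simulation seeds are mandatory everywhere randomness occurs; identical
  seeds give byte-identical outputs.

## Problem sizes used by the tests

The test suite and the acceptance script size their simulations for a
laptop-class single core: three recordings of 10^4 events for
spontaneous-scheme recovery, fifteen recordings of 4x10^3 events for each
block series, 2x10^4 to 4x10^4 events for component-count checks, and
500-32000 bursts for fingerprinting. At these sizes every free rate is
recovered within three reported standard errors of its generating value and
the block dissociation constants within a few percent.

## Known limitations

The missed-event correction is first-order, not the exact asymptotic form;
fits of schemes whose briefest state lifetimes approach the dead time
(roughly, mean lifetime under ten dead times) trigger a regime warning.
There is no hidden-Markov fitting of raw traces, no model-topology search,
no Bayesian posterior, no multi-channel correction, and no vendor file
formats. Model discrimination between topologies that fit equally well
(e.g. the cyclic three-state alternative to the linear priming scheme) is
out of scope: the machinery fits any user scheme but renders no verdict.
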