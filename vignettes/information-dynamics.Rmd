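---
title: "Information dynamics of reward and punishment learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information dynamics of reward and punishment learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infolearn)
```

`infolearn` analyses how trial-locked neural power signals encode the
prediction errors of reward and punishment learning. This vignette
explains the models the package implements, the assumptions behind them,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
user extending the package should know about.

## The behavioral model

Participants (or simulated agents) learn, by trial and error, which of
two abstract cues in a pair pays off more often. A session interleaves
four cue pairs, each shown 24 times (96 trials): two pairs can yield +1
or 0 euros (reward condition), two can yield 0 or −1 euros (punishment
condition), with reciprocal 0.75/0.25 contingencies inside each pair. A
short training layout (2 pairs, 8 repetitions) is also available.

Choices are modeled with tabular Q-learning. Each cue of each pair has
an expected value `Q`, initialized at 0 — the average of the possible
outcomes, so the first feedback of a pair is maximally informative.
After choosing cue `a` and receiving outcome `R`:

- prediction error: `delta = R - Q[a]`
- update: `Q[a] <- Q[a] + alpha * delta` (only the chosen cue moves)

The probability of choosing `a` over `b` is a softmax on the values,
with a perseveration bonus `theta` added to the option chosen on the
previous trial *of the same pair* (pairs interleave, so "previous
trial" is tracked per pair):

`P(a) = exp((Q[a] + theta*prev_a)/beta) / (exp((Q[a] + theta*prev_a)/beta) + exp((Q[b] + theta*prev_b)/beta))`

`beta` is a temperature: the value difference is divided by it, so
larger `beta` means more exploration. The implementation works on the
logit scale (`plogis` of the scaled value difference), which is exact
and does not overflow even at `beta = 1e-6`.

The reward prediction error (RPE) is `delta` restricted to reward-pair
trials, the punishment prediction error (PPE) its restriction to
punishment-pair trials; the "full PE" is the signed `delta` on all
trials. As learning converges, `|delta|` shrinks — the synthetic agent
reproduces this learning curve, and a test pins it.

### Fitting

`fit_qlearning()` minimizes the negative log-likelihood of the observed
choices (in nats) by bounded L-BFGS-B from multiple random starting
points. Choices of defaults the task itself does not dictate:

| parameter | default | why |
|---|---|---|
| `alpha` bounds | [0, 1] | definition of a learning rate |
| `beta` bounds | [1e-6, 10] | covers near-deterministic to near-random choice |
| `theta` bounds | [−2, 2] | twice the outcome range in either direction |
| `n_starts` | 10 | multistart against local minima; recovery tests pass with 5 |
| likelihood floor | P ≥ 1e-12 | keeps one surprising choice from producing an infinite objective; far below any probability the bounded model can generate, so optima are unaffected |

Q-values reset at each new pair (and hence each session, since sessions
introduce new pairs); the perseveration trace resets with them. The
likelihood is also implemented in C++ (tested equal to the R reference)
because multistart fitting evaluates it thousands of times.

Parameter recovery at the study's trial counts (several sessions of 96
trials) is good for `alpha` and `theta` and excellent for all three
parameters with many sessions; the acceptance suite checks median
recovery within 25% over 50 synthetic subjects at 30 sessions each.
NLL is reported in nats; all information measures elsewhere are in bits.

## Information measures

All neural measures are built on the Gaussian-copula estimator family:
each variable is rank-transformed across trials (average ranks for
ties, so the map is deterministic), scaled to `r/(n+1)`, and passed
through the inverse normal CDF. Information quantities are then
computed under a joint Gaussian model from log-determinants of
covariance blocks, with an analytic (digamma-based) small-sample bias
correction of each entropy term, in log base 2. Consequences worth
remembering:

- estimates depend on the data only through rank orders: any strictly
  monotone transform of a signal leaves them unchanged (tested exactly);
- the estimator detects monotone relationships only, and lower-bounds
  the true mutual information;
- bias-corrected estimates of independent data are centered on zero and
  may be slightly negative; uncorrected Gaussian MI is nonnegative;
- degenerate inputs (constant columns, duplicated signals) raise errors
  rather than being silently regularized — fixtures that need
  near-duplicates add explicit jitter.

Three time-resolved measures operate across trials on outcome-locked
gamma-power epochs (contacts × trials × time, 256 Hz):

**Local MI** (`mi_timecourse()`): at each time sample, the GCMI between
a contact's across-trial power and the RPE (reward trials) or PPE
(punishment trials). At least 20 trials are required.

**Interaction information** (`interaction_information()`): for a pair
of same-subject contacts, `II = I(g1,g2; S) − I(g1; S) − I(g2; S)` with
the joint term on the 2-D copula sample. Negative II means the two
contacts carry overlapping (redundant) information about the PE;
positive II means their joint representation carries more than the sum
(synergy). For the full-PE target the signed `delta` over all trials is
used, without splitting by condition.

**Transfer entropy** (`transfer_entropy()`): directed flow under the
Wiener-Granger principle, `I(x[t-d]; y[t] | y[t-d])` estimated across
trials and averaged over delays `d` in a window, by default 116–236 ms
in 1-sample steps at 256 Hz. The "past" is the single sample at lag `d`
for both source and conditioning target — the delay averaging, not a
multi-sample embedding, supplies temporal breadth. This is the simplest
consistent reading of the delay-averaged estimator; it also keeps the
conditioning covariance 3×3, which the closed-form fast path exploits.
`te_delay_profile()` exposes the per-delay curve and its argmax, which
on lagged fixtures recovers the generating lag to within a couple of
samples.

Performance note: at fixed time `t`, every quantity above is a function
of a few covariance entries among copula-normalized columns, and for
dimensions ≤ 3 the log-determinants have closed forms. The package
therefore evaluates whole time axes and permutation sets with vector
arithmetic; tests pin the fast paths to the generic `mi_gg()` /
`cmi_ggg()` estimators at machine precision.

## Group statistics

Inference is random-effects over units (contacts for MI, pairs for II
and TE), each unit carrying its own permutation null: MI and II nulls
shuffle the PE across trials; TE nulls shuffle the source's trials
(1000 permutations at full scale; desk-scale runs use 200). At each
time point a one-sample t of unit values minus their own permutation
means forms the observed statistic; the same statistic on each
permutation slice forms the null. Cluster correction thresholds at the
95th percentile of the pooled null t-values, sums supra-threshold t
into cluster masses, and compares each observed mass to the
distribution of per-permutation maximum masses. II redundancy is tested
on the negative tail (the series is sign-flipped internally).

Contact selectivity (`categorize_contacts()`) tests each contact
against its own null with the same cluster logic, at contact level, and
labels each contact/time as RPE-specific, PPE-specific, Both, or
Irrelevant; per-ROI label proportions over time sum to one. The
per-contact rule (cluster correction against the contact's own null at
alpha = 0.05) is this package's explicit choice; only the group-level
rule is externally specified. `bin_ii_by_selectivity()` partitions
pairwise full-PE II into the four selectivity categories (RPE-RPE,
PPE-PPE, PPE-RPE, Mixed for Both-involving pairs; Irrelevant-involving
pairs are dropped), tests each category mean against zero, and controls
the FDR across categories with Benjamini-Hochberg. Condition contrasts
(e.g. TE on punishment vs reward trials) exchange condition labels
within units (sign flips of the paired differences) and cluster-correct
each direction separately.

Calibration is tested, not assumed: on pure-null synthetic cohorts the
family-wise false-positive rate of the full MI → group-t → cluster
chain stays within [0.01, 0.10] at nominal 0.05 over 200 runs.

## The synthetic-data generator

The generator exists so every estimator can be validated against ground
truth. It emulates: the task structure and contingencies; Q-learning
choice behavior; and outcome-locked gamma-power epochs in which a
Gaussian temporal kernel (latency 0.5 s, SD 0.15 s — the empirical
post-outcome response timing) has a per-trial amplitude proportional to
the target PE, on top of AR(1) noise (coefficient 0.9 at 256 Hz,
enough temporal autocorrelation to make TE conditioning meaningful,
much cheaper than a full 1/f process). The coupling function is the
identity: the rank-based estimators are blind to monotone deformations,
so nothing generalizable is lost.

Pair fixtures plant known interaction structure:

- *redundant pair*: both contacts share one PE-driven source (scaled by
  `shared_frac`, default 0.8) plus independent noise — co-information
  is negative by construction (`0.5*(log2(1+2r) − 2*log2(1+r))` for
  signal-to-noise ratio `r`, always < 0);
- *synergistic pair*: contact 1 is signal plus a shared noise source,
  contact 2 is (mostly) that noise — conditioning on contact 2 denoises
  contact 1, so II is positive;
- *directed pair*: Y reproduces X delayed by `lag` within each trial,
  optionally only on trials of one condition (condition-gated flow).

Fixture SNRs were set once from the closed forms above so that the
planted effect, not estimator noise, decides each check at 200 trials:
gain 2 for redundant pairs (per-contact information ≈ 0.3 bits,
redundancy ≈ −0.13 bits, about 3.5 null SDs) and gain 1.5 for
synergistic pairs (comparable per-contact information). The raw-LFP
generator (75 Hz carrier amplitude-modulated by a known envelope over
1/f background) exercises the spectral chain end-to-end.

What the generator does **not** emulate: recording artifacts and
epileptic activity, volume-conduction structure across an electrode
(bipolar referencing is tested on its own constructed inputs),
heterogeneous per-contact SNR, non-stationarities across a session, and
1/f background in the power domain. Passing tests therefore demonstrate
estimator and pipeline correctness under known ground truth — not that
real iEEG effect sizes will match.

## Spectral chain

Raw traces (512 or 1024 Hz acquisitions) pass through: bipolar
derivation between adjacent contacts; multitaper gamma power — 200 ms
windows, 9 Slepian tapers with time-bandwidth 10 (NW = 5, ±25 Hz
smoothing, so the estimate centered at 75 Hz covers 50–100 Hz),
single-frequency demodulation, power averaged over tapers (any fixed
taper aggregation cancels in the rank-based estimators); anti-aliased
decimation to 256 Hz keeping `t = 0` on the output grid; and
Savitzky-Golay smoothing. Two deliberate deviations from round numbers:
the classical Savitzky-Golay formulation needs an odd window, so the
nominal 10-point filter is implemented as 11 points, order 3; and the
half-window at each epoch edge, where no centered estimate exists, is
returned as `NA` rather than extrapolated. Slepian tapers are computed
from the standard symmetric tridiagonal eigenproblem and verified by
orthonormality and in-band spectral concentration (> 99%).

## Problem sizes and reproducibility

Everything is seeded: generators take explicit seeds, the pipeline
derives per-stage, per-subject seeds from one master seed, and
identical configurations are bit-reproducible (the manifest records a
configuration hash and file checksums). The package's standard
validation sizes — chosen as the smallest scales at which the closed
forms predict decisive outcomes — are: 200 trials per condition for
estimator fixtures; 8–16 subjects for cohort-level checks; 200
permutations for desk-scale nulls (1000 at full scale); oracle
comparisons against analytic Gaussian values at n = 10,000 samples
within ±0.02 bits.

## Known limitations

- GCMI detects monotone dependence only; non-monotone coupling (e.g.
  U-shaped) is invisible to every measure here.
- TE uses a single-sample past at each delay; processes with longer
  memory than the delay window may be summarized incompletely.
- The argmax of a noisy time course over a broad response plateau
  jitters by a few tens of milliseconds at 200 trials; localization
  claims in the tests are therefore made on seed-averaged peaks.
- Pairs are formed within subject only; no spatial clustering is
  attempted (clusters are temporal runs).
- Epoch containers serialize to long-format CSV plus a JSON sidecar —
  adequate for desk-scale arrays, not for full-scale recordings.
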