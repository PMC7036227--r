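---
title: "Identifying vaccine-specific BCR clones with a latent-class abundance mixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying vaccine-specific BCR clones with a latent-class abundance mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemix)
```

## The problem

A vaccine triggers clonal expansion of the B cells whose receptors (BCRs)
bind the antigen. In CDR3 repertoire sequencing of a vaccinated cohort this
leaves two statistical fingerprints: expanded abundance *after* (but not
before) vaccination, and sharing of near-identical sequences *across*
individuals responding convergently to the same antigen. Both signals are
subtle — most clones are sampled once, in one person, at one time point —
and neither alone separates vaccine responders from clones reacting to
unrelated stimuli. `clonemix` combines them in a single generative model
over the clone-by-individual-by-time count tensor and classifies each clone
as background (`bg`), non-specific responder (`ns`) or vaccine-specific
(`vs`).

## Clonal identification

Unique CDR3 sequences are grouped into clones before modelling, to absorb
read errors and hypermutation variants targeting the same epitope. Two
sequences are neighbours when they have equal length and positional
(Hamming) identity strictly above a threshold — 0.85 for nucleotide, 0.90
for amino-acid data by default. Clustering is greedy: the unassigned
sequence with the most unassigned neighbours becomes the next clonal
centre and absorbs those neighbours. The rule is deliberately cheap
(length-bucketed all-pairs comparison) so that million-sequence data sets
are feasible; since neighbours must share a length, Hamming identity is
sufficient and no alignment is needed.

The greedy rule needs tie-breaking the moment two sequences have equal
neighbour counts. We break ties by larger total read count, then by
lexicographically smaller sequence; neighbour counts are over distinct
sequences, not reads. These choices make the partition deterministic and
are validated against a brute-force restatement of the rule in the test
suite. The clone-by-individual-by-time abundance `x[i, s, t]` is the summed
read count of all member sequences.

## The model

Each clone `i` carries a latent class `gamma_i` with prior
`Gamma = (Gamma_bg, Gamma_ns, Gamma_vs)`. Conditional on class:

* **Presence.** `z_is ~ Bernoulli(p_class)` says whether clone `i` exists
  at all in individual `s`. Background and non-specific clones share one
  presence probability `p_bgns` — non-specific stimuli are assumed private,
  so their sharing looks like background — while `p_vs` is free, capturing
  convergent response.
* **Abundance.** Given presence, the count in each sample follows one of
  two *regimes*: quiet (`Q`) or active (`A`). Background clones are quiet
  at every time point, non-specific responders active at every time point,
  and vaccine-specific clones are quiet at `t = 0` (pre-vaccination) and
  active afterwards. That time switch is the entire abundance signature of
  a vaccine response, and all count parameters are tied at the regime
  level.

Within a regime, a present clone escapes sampling with probability
`1 - q` (a point mass at zero), and otherwise draws its count from a
two-leaf mixture: with probability `1 - omega` a *zero-truncated negative
binomial* (ZTNB; ordinary B cells contributing a handful of reads) and
with probability `omega` a *discretized generalized Pareto* (dGPD; clonal
expansions and actively secreting plasma cells, which produce the extreme
heavy tail — the largest clones in real repertoires reach 10^5 reads).
The dGPD is built by differencing the continuous generalized Pareto CDF on
unit intervals from a location `u` (default 1), so its support overlaps
the ZTNB's and the weight `omega` is interpretable directly as "probability
an observed clone is seen at high abundance".

Three modelling choices deserve comment:

* The low leaf is *zero-truncated* and all zero mass given presence sits in
  the explicit escape-sampling probability `q`. This keeps the three leaves
  disjoint at zero, which makes the E-step leaf posteriors exact and cheap
  (an observed zero is unambiguously "unsampled").
* `q` is tied by regime, like `omega`. Nothing in the data distinguishes a
  finer structure for it, and the tie keeps the truncation bias (below)
  symmetric between the background and non-specific classes.
* The dGPD shape is restricted to `xi >= 0`. The high leaf exists to model
  heavy tails; negative shapes imply a bounded support that has no
  biological reading here and complicates the discretization.

Priors are non-informative — flat Dirichlet on `Gamma`, flat Beta on every
probability, improper flat on the count parameters — so the MAP objective
coincides with the marginal likelihood and the posterior mode is the MLE.

Only clones observed at least once enter the model. Fully unobserved
clones are unidentifiable, so both the fitted model and the simulator
condition on observation; parameter estimates are therefore specific to
each data set's design (number of individuals, time points, depth), and
the simulator reproduces rather than corrects this truncation. Because
`bg` and `ns` share `p` and `q`, the truncation deflates their class
proportions equally, and the induced bias on `Gamma_bg` is small (about
0.001–0.002 under the default study designs); `p_bgns` and `q` absorb most
of it, which is visible in recovery experiments as an upward shift of
`p_bgns` while `Gamma`, `p_vs` and `omega` stay accurate.

## Inference

The model is fitted by Expectation-Maximisation on the marginal MAP
objective. The E-step computes, in log space with max-subtraction, each
clone's class responsibilities, the per-individual presence posterior
(exactly 1 wherever the clone is observed), and the per-count posterior of
the high-abundance leaf. The M-step has closed-form weighted updates for
`Gamma`, `p`, `q` and `omega` (pooling every tied cell), and updates the
ZTNB and dGPD parameters by Nelder–Mead maximization of their weighted
expected log-likelihoods over the (small) set of distinct observed counts.
Each numerical update starts from the current value and is accepted only
if it improves its objective, so the algorithm is a generalized EM and the
joint log-probability is non-decreasing — a property the test suite checks
on random instances, alongside exact agreement of posteriors and objective
with brute-force enumeration over all latent configurations on small
tensors.

Label switching is prevented purely by initialization, which anchors each
class to its biological meaning: `Gamma = (0.99, 0.005, 0.005)`,
`p_bgns = 0.2 < p_vs = 0.6`, `omega_Q = 0.01 < omega_A = 0.2`, and a
smaller quiet-regime ZTNB mean. No post-hoc relabelling is applied. Soft
EM (full responsibilities) is used rather than hard classification-EM; it
optimizes the stated objective and is the standard choice. Exact posterior
ties in the MAP labelling break toward the least specific claim
(`bg` over `ns` over `vs`).

Convergence is declared when the objective changes by less than `tol`
(default `1e-6`, absolute) or after `max_iter` (default 500) iterations.
Probabilities are floored at `1e-12` during the M-step to avoid absorbing
zeros, with one exception: `omega` may reach exactly 0, since a fitted
high-abundance weight of zero (as happens for the quiet regime in sparse
DNA-sequenced data) is meaningful. The package reports no standard errors:
with 10^5–10^6 clones the sampling uncertainty of the handful of
parameters is negligible next to model misspecification, and reporting it
would suggest spurious precision.

## The simulator and what the tests mean

`sample_dataset()` draws from the generative model exactly as written —
class, presence, sampling, leaf, count — then discards clones observed
nowhere and redraws until the target number of observed clones is reached,
recording the discard count. A single seeded RNG stream makes every
dataset bit-exact reproducible from its arguments. The default generating
parameters are the package's reference study conditions: class, presence
and high-abundance parameters at the values estimated from a hepatitis-B
booster cohort (5 individuals, 5 time points), `q = 0.5` per regime, and
count parameters — ZTNB mean 1.0 (size 0.8) quiet / mean 8 (size 1.2)
active; dGPD shape 0.3, scale 10 quiet / shape 0.6, scale 40 active —
chosen once to reproduce the per-class mean abundance scales of bulk
repertoire data (background clones averaging ~2–3 reads, active clones
tens to hundreds with a Pareto tail).

Recovery experiments at the two study designs (100,000 observed clones,
S = 5, T = 5; and 30,000 clones, S = 7, T = 3 with `omega_Q = 0`) refit
the model from the default anchored initialization and recover the
generating background proportion within ±0.01 and the vaccine-specific
presence and high-abundance parameters within ±0.03; `scripts/acceptance.R`
reruns them end to end (about a minute on one CPU; the EM there uses
`tol = 1e-3`, which on an objective of order 10^6 is ~10^-9 relative and
far past the point where parameters move at reporting precision).

What passing these tests shows — and does not show: the simulator emulates
the model's own statistical structure, so recovery demonstrates correct
and stable inference, not correctness of the model for real repertoires.
Real data add PCR amplification bias, non-stationary background dynamics,
lineage structure among clones, and truth sets with ~50% staining
specificity, none of which the simulator represents. Model adequacy on
real data is instead assessed by QQ comparison of observed against
refitted-and-resimulated abundance distributions (`qq_points()`), which is
also exercised in the tests as a self-consistency check (with a one-count
slack where the integer quantile curves step).

## The thresholding baseline

`classify_threshold()` implements the standard comparator: a clone is
vaccine-specific if, within at least one individual, it is at or below the
sample-specific abundance threshold pre-vaccination (absence counts as
below) and strictly above it at some later time point, and if it is
observed in at least `min_shared` individuals. The threshold is the
empirical quantile (R's default type-7, interpolated) of the *nonzero*
abundances of each (individual, time) sample, so it tracks sequencing
depth; `q = 0` disables the abundance clause. The interpolated convention
is used because an attained-value threshold combined with a strict
comparison can never flag a sample's maximum; agreement percentages are
sensitive to this choice, so it is fixed and documented here. The
"rise within one individual" scope is the default and configurable
(`rise_scope = "any"`), as is whether sharing counts presence at any time
point (it does).

Raising `min_shared` can only remove clones — a pure conjunction — and
this is tested on arbitrary random tensors. Raising the abundance quantile
is *not* monotone for arbitrary tensors: a higher threshold can flip a
clone's pre-vaccination count from above to below, newly satisfying the
rise clause. In repertoire-like data, where expansions sit orders of
magnitude above the background count scale, the flip cannot occur and the
count decreases; the property tests therefore use such scale-separated
tensors.

## Sequence similarity

Within-class similarity uses the Levenshtein distance (which, unlike the
clustering identity, compares sequences of different lengths): the
statistic is the mean over all unordered pairs of clone centres, and
significance comes from a bootstrap null of equal-size draws without
replacement from a pool of centres (all centres by default, optionally the
complement class, optionally matched to the subset's length multiset).
The one-sided empirical p-value uses the add-one correction
`(1 + #[null <= observed]) / (n_boot + 1)`; at the default 1,000 draws
the smallest attainable p is ~0.001. Ties count toward the null, so
p-values are conservative (super-uniform) at worst — calibration tests
check one-sidedly that they are never anti-conservative. The petri-dish
similarity graph connects centres at distance below `n/denom`; for
unequal-length pairs `n` defaults to the length of the lexicographically
first sequence (configurable to min/max/mean — the choice only matters for
unequal lengths).

## Evaluation against truth sets

Antigen-sorted or plasmablast sequence sets provide approximate truth. A
clone overlaps the truth set when some truth sequence would be assigned to
it (same length as the centre, identity above the clustering threshold) —
the identical rule, and code path, used by the thresholding sweep's
agreement column. The vaccine-specific overlap fraction is reported as
*sensitivity*, with the caveat that it is truth-set-limited: enrichment
protocols capture abundant clones by chance, so the comparison of overlap
fractions across classes (tested by a two-tailed chi-squared on the vs/bg
by in/out 2-by-2 table, without continuity correction unless requested)
is the more robust readout. Degenerate tables (an empty class or an
all-or-nothing overlap) yield `NA` with a warning rather than a fabricated
statistic.

## Numerical and degenerate-input policy

All probability computation is in log space; `-Inf` log-weights (e.g.
`omega = 0`) drop terms exactly rather than producing `NaN`. The ZTNB is
parametrized by mean and dispersion and evaluated via `dnbinom` minus a
`log1mexp` truncation term; the dGPD by log-survival differencing. Empty
repertoires, mixed alphabets, tensors without a `t = 0` level, all-zero
tensors, empty samples in the quantile threshold, and too-small bootstrap
pools all fail fast with named errors. Time points are integer days with
`t = 0` the unique pre-vaccination level; multi-sample pre-vaccination
designs are out of scope.

## Known limitations

* Clones are independent given their class: lineage structure and
  cross-length motif sharing (which the similarity analysis detects in
  vaccine-specific sets) are not modelled.
* The truncation to observed clones makes `Gamma`, `p` and `q`
  design-specific; estimates should not be compared across data sets with
  different sampling depth or cohort size.
* A non-specific clone whose expansion happens to coincide with the
  vaccination schedule is indistinguishable from a vaccine response; only
  additional signals (e.g. hypermutation) could separate them.
* The thresholding baseline's agreement numbers depend on the quantile
  convention; comparisons with other implementations need that convention
  aligned.
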