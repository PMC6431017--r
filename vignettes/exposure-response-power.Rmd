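---
title: "Measurement error, sample size and the power of exposure-response studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement error, sample size and the power of exposure-response studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bnpower)
```

## The question

An exposure-response study observes, for each subject, a *measured*
exposure class and a *measured* response class. Both are misclassified
versions of the truth, and the degree of misclassification is a property
of the study's instruments that the analyst usually knows at design time.
`bnpower` treats study design as an inference problem on a small discrete
Bayesian network: simulate studies whose true strength of relationship and
measurement accuracies are known, assimilate the simulated observations
into an uninformed prior, and record how quickly — and how reliably — the
posterior concentrates on the truth.

## The network and its assumptions

```{r}
net <- er_network()
net
```

The model's assumptions, stated plainly:

* **Exposure and response are three-class categorical** (`low`, `medium`,
  `high`). The nine-state outcome node `ERMatch` is the cross of the two
  measured classes; its CPT is deterministic (a point mass per parent
  combination), so one subject contributes exactly one of nine outcomes.
* **The strength of relationship `R` is a latent three-state variable**
  (`none`, `medium`, `strong`). Its prior is (0.50, 0.25, 0.25): the
  design question is first whether *any* relationship exists (an even
  split), and only then how strong it is (an even split of the remainder).
  All other root nodes get uniform priors: each state of a three-state
  root has a 33% prior probability.
* **Measurement error enters only through the accuracy nodes.** One
  measurement table is shared by the exposure and response arms and is
  symmetric under the `low`/`high` swap, so neither arm nor either tail is
  privileged. `perfect` accuracy is the identity map.
* **Cases are exchangeable.** Subjects are independent draws given the
  clamped scenario, which is what makes the outcome frequency table a
  sufficient statistic and the sequential and batch posteriors identical.

## Default conditional probability tables

The measurement table `P(measured | accuracy, truth)`, rows = truth:

| accuracy | truth | low | medium | high |
|---|---|---|---|---|
| low | low | 0.50 | 0.30 | 0.20 |
| low | medium | 0.25 | 0.50 | 0.25 |
| low | high | 0.20 | 0.30 | 0.50 |
| high | low | 0.80 | 0.15 | 0.05 |
| high | medium | 0.10 | 0.80 | 0.10 |
| high | high | 0.05 | 0.15 | 0.80 |
| perfect | — | identity | | |

The response table `P(TR | R, TE)`, rows = `TE`:

| R | TE | low | medium | high |
|---|---|---|---|---|
| none | any | 1/3 | 1/3 | 1/3 |
| medium | low | 0.60 | 0.30 | 0.10 |
| medium | medium | 0.20 | 0.60 | 0.20 |
| medium | high | 0.10 | 0.30 | 0.60 |
| strong | low | 0.90 | 0.08 | 0.02 |
| strong | medium | 0.05 | 0.90 | 0.05 |
| strong | high | 0.02 | 0.08 | 0.90 |

These are **representative values, not estimates from any dataset**. They
are pinned down by the regime they must express — `none` means
independence, `strong` means ≥ 0.9 on the aligned class, `perfect`
measurement is the identity, low-accuracy measurement leaves a 0.2
probability of reporting `high` when the truth is `low`, and both tables
are symmetric under the `low`/`high` relabeling — but the remaining
freedom was fixed by judgment. Published required-sample-size tables or
posterior-trajectory figures from any particular study of this design are
therefore **not reproducible from this package's defaults, at any scale**:
results of this kind are sensitive to the exact CPT entries, and
reproducing a specific study requires supplying its tables through a
network definition file. The shipped YAML default
(`read_network("default")`) reproduces `er_network()` bit-exactly —
probabilities are serialized as exact rationals such as `1/3` — and every
entry can be overridden in a copy of that file. The package's own tests
therefore check *properties* of the analysis (exactness, calibration,
ordering and variability patterns), not any published numbers.

Two modelling choices deserve a note. The true-response node uses three
states, matching the three measured classes that the nine-outcome match
logic is built on; a four-state response would require redefining the
outcome node. And the scenario grid uses three accuracy levels
(`low`, `high`, `perfect`); the CPT schema accepts arbitrary accuracy
levels via the network file for users who want a finer ladder.

## Inference: exact enumeration

All queries run by summing the joint over the full assignment space
(3⁷ × 9 = 19,683 assignments — `infer_marginal()` answers in
milliseconds). At this size exact enumeration is cheaper than any
approximate scheme and removes sampling error of the *inference engine*
from the power results, so the only stochasticity left is the simulated
data itself. Numerical conventions: CPT rows must sum to 1 within 1e-12
(asserted on load), probabilities are handled in linear space except for
likelihood accumulation, and evidence whose marginal probability falls
below 1e-300 is reported as inconsistent rather than returning NaN.

## Sequential updating and the two modes

With the accuracies clamped (the analyst knows their instruments), each
case's outcome `o` multiplies the posterior over `R` elementwise by the
likelihood row `P(o | R)`:

```{r}
L <- outcome_likelihoods(net, "perfect", "perfect")
round(L, 4)
```

The Bayes factor of state `Ri` against its complement uses
prior-proportional mixture weights over the other states. With three
hypotheses those weights *drift* as data accrue, so a Bayes-factor table
computed once is only exact at the prior it was computed at. `er_fit()`
therefore defaults to `mode = "exact"` — per-state likelihood products,
accumulated in log space so ten-thousand-case trajectories cannot
underflow, and equal (within 1e-9, verified in tests against a separate
batch code path) to one-shot Bayes' rule on the outcome counts. The
literal alternative, `mode = "fixed-bf"`, freezes the Bayes-factor table
at the initial prior and applies per-state odds updates with
renormalization; its first update coincides with the exact mode, after
which the two diverge (a regression test pins the divergence on a fixed
seeded dataset). It is provided for comparison with workflows that reuse
a precomputed Bayes-factor table verbatim.

```{r}
prior <- c(none = 0.5, medium = 0.25, strong = 0.25)
update_posterior(prior, L, "ll")          # one aligned low-low case
bayes_factor(L, "ll", "strong", prior)
```

## What the simulator emulates — and what it does not

`generate_dataset()` draws subjects by ancestral sampling in topological
order, inverse-CDF over the declared state order, from R's Mersenne-
Twister stream; a dataset is a pure function of (scenario, n, seed), and
a goodness-of-fit test confirms the nine-outcome frequencies match exact
inference in every scenario. True exposure is sampled from its uniform
prior per subject, which exercises the full CPT; `fix_te` clamps it
instead, emulating a design with controlled exposure levels — both
designs are plausible readings of how such populations are simulated, so
both are provided and neither is asserted as canonical. Trial `t` of a
replicate ensemble uses seed `base_seed + t` (default base seed
20190322), recorded in every run record.

The generator emulates misclassification noise and sampling noise only.
Real studies additionally face confounding, selection effects, correlated
misclassification between the arms, drifting instruments and non-
exchangeable subjects — none of which are in the network. Passing power
results here say what a *correctly specified* analysis can extract from
noisy class labels; they are a lower bound on the difficulty of real
inference, not an upper one.

## Power summaries

`run_trials()` fits 10 replicate studies of up to 1,000 cases
(defaults from the study-design grid this package works on: sample sizes
are reported at N = 20, 50, 100, 1000); `power_table()` assembles the
3 × 3 required-sample-size table. "Required N" is the **first** crossing
of the across-trial *mean* posterior on the true state — first rather
than sustained crossing because the crossing semantics were genuinely
open, and the first crossing is the more conservative claim to audit
(censored cells are serialized as `">1000"`, with the numeric CSV column
left empty). `misleading_trial_fraction()` reports the share of replicate
trials whose posterior on the truth sits at or below a bound (default
0.1) at a given study size — the "confidently wrong" studies.

```{r}
ens <- run_trials(net, scenario = 9, n_max = 200, n_trials = 10)
required_sample_size(ens)
plot(ens)
```

At the defaults the qualitative regime (all of it asserted by the test
suite, none of it hard-coded) is: perfect-accuracy scenarios recover
`none` and `strong` with a few dozen subjects and pass 0.95 mean
posterior well before N = 1000; the `medium` strength needs the largest
studies in the perfect row, being bounded by alternatives on both sides;
low-accuracy scenarios reach no 0.9 crossing within 1,000 subjects and
show much larger trial-to-trial scatter at N = 1000 than perfect-accuracy
ones. Two finer patterns are genuinely at the mercy of replicate noise at
10 trials and are reported as measured rather than guaranteed: the
`medium`-vs-`strong` ordering inside the high-accuracy row, and whether
any individual low-accuracy trial ends below 0.1 on the truth (its
expected rate under these CPTs is on the order of 1–2% per trial, so 30
replicates often contain none).

## Problem sizes and runtime

Test and acceptance runs use the defaults throughout: the full 9-scenario
× 10-trial × 1,000-case power run is a single-core computation of about a
second (the sampler is vectorized per node; likelihood tables need three
enumeration queries per scenario), the distributional calibration check
samples 10⁵ cases per scenario, and the enumeration oracle cross-check
covers 100 random query/evidence pairs on the full joint. Everything is
deterministic given the seeds in the run record.

## Known limitations

* Three-class exposure/response only; no continuous dose metric.
* Accuracies are clamped, not learned; there is no model-averaging over
  unknown instrument quality.
* One exposure metric, one study at a time: no confounders, no
  multi-study evidence synthesis.
* The analysis model is the generating model; the power results do not
  cover misspecified CPTs (though a user can simulate under one network
  file and fit under another to probe exactly that).
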