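---
title: "Cross-edition TNM reclassification with a discrete Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-edition TNM reclassification with a discrete Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The TNM classification summarizes tumor extent (T), regional lymph-node
involvement (N) and distant metastasis (M), and maps each (T, N, M) triple
to a stage group (IA–IV) through edition-specific grouping tables. The
system is revised regularly; between the 6th and 7th editions for lung
cancer, T1/T2 were subdivided by tumor size, tumors larger than 7 cm moved
from T2 to T3, same-lobe satellite nodules moved from T4 to T3,
different-ipsilateral-lobe nodules moved from M1 to T4, and M1 was split
into M1a/M1b. Registries code each patient with the edition current at
diagnosis, so multi-year cohorts mix editions whose identically labelled
categories are not equivalent, and a deterministic label mapping is often
impossible without extra clinical detail.

`tnmbn` treats reclassification as probabilistic inference in a discrete
Bayesian network. A Bayesian network factorizes a joint distribution over
discrete variables as \(P(X_1,\dots,X_n)=\prod_i P(X_i \mid \mathrm{Pa}(X_i))\),
each conditional stored as a conditional probability table (CPT).
Evidence set on any node updates the distribution of every other node, so
the same fitted model answers "what is this 7th-edition tumor's 6th-edition
stage group?", the reverse question, and "what is the survival outlook?" —
always as a full posterior distribution (a *weighted* reclassification),
with a point prediction only as a derived convenience.

## The network

Ten nodes, `build_structure()`:

* `T_7`, `N_7`, `M_7` — hidden root nodes holding the newest-edition
  (7th) descriptors, which approximate the true disease state best.
* `TNM_7` — the 7th-edition stage group, a deterministic function of the
  three hidden descriptors.
* `edition` — the TNM edition a record was coded with (`"5"`, `"6"`, `"7"`).
* `T_567`, `N_567`, `M_567` — the observed descriptors; each has exactly
  two parents, `edition` and its hidden counterpart. The edition used for
  coding cannot causally influence survival, which is why the edition
  enters only through these observation nodes.
* `TNM_567` — the recorded stage group, deterministic given the edition
  and the observed descriptors.
* `death` — five ordered survival categories with single parent `TNM_7`:
  survival is driven by the true disease state, not by how it was coded.

State spaces are configurable. By default the unassessable tokens TX/T0/
NX/MX are excluded from the network (they are still accepted by the
staging functions, which resolve them by candidate expansion); the
`_567` nodes take the union of all edition vocabularies, e.g. `T_567`
has states T1, T2, T3, T4, T1a, T1b, T2a, T2b.

## Cross-edition priors

`make_transition_priors()` builds \(P(T_{567}\mid edition, T_7)\),
\(P(N_{567}\mid edition, N_7)\) and \(P(M_{567}\mid edition, M_7)\) from a
declarative JSON table shipped with the package:

* Edition 7 rows are the identity — a 7th-edition record shows its
  hidden descriptor unchanged.
* Editions 5 and 6 share one table, because no descriptor definitions
  changed between them.
* Size subdivisions collapse deterministically: T1a/T1b → T1,
  T2a/T2b → T2, M1a/M1b → M1.
* A hidden T3 maps 50–50 to T2 or T3: a 7th-edition T3 may be a tumor
  larger than 7 cm (6th-edition T2) or invasion-based (6th-edition T3),
  and without invasion status neither dominates a priori.
* A hidden T4 keeps 0.85 on T4 with 0.05 on each of T1–T3: most
  7th-edition T4 tumors are invasion-based (6th-edition T4), but a
  different-ipsilateral-lobe nodule tumor was 6th-edition M1 with an
  unknown primary T. The companion M0 row leaks 0.02 to M1 for the same
  tumors.

The structural zeros in these tables are vocabulary constraints — an
edition-6 record can never show the token T1a — and the fitting procedure
preserves them exactly (below).

One nuance is deliberately simplified: 7th-edition M1a includes malignant
pleural effusion, which the 6th edition coded as T4 (stage IIIB) rather
than M1. The package maps all metastatic tokens to M1, keeping the
invariant that a metastatic M yields stage IV in every edition; the IIIB
borderline cases are absorbed into the M-row uncertainty.

## Learning without paired labels

No training record ever carries its classification in two editions.
`em_fit()` therefore treats `T_7`, `N_7`, `M_7`, `TNM_7` as latent and
maximizes the marginal likelihood of the observed nodes (`edition`,
`T_567`, `N_567`, `M_567`, `TNM_567`, `death`) by
expectation–maximization:

1. `init_hidden_cpts()` estimates the hidden root CPTs and the survival
   CPT from the 7th-edition subset of the training data, where the hidden
   state is observable (identity conversion).
2. The transition priors are the iteration-0 values of the conversion
   CPTs (they may additionally act as Dirichlet pseudo-counts via
   `prior_strength`; the default uses them as initialization only).
3. Each E-step computes exact per-record posteriors over the hidden nodes
   (and over `death` where survival is missing); records are grouped by
   their distinct observed tuple first, a pure optimization with an
   exactness contract — the generic factor-algebra E-step and the
   specialized one for the fixed topology produce identical statistics
   (`engine` argument, verified in the tests).
4. The M-step re-estimates CPTs from expected counts with `pseudo_count`
   smoothing applied *within the support* of the iteration-0 CPTs. Cells
   that start at zero encode structural impossibilities and remain zero;
   smearing smoothing mass across them would otherwise compound over
   iterations into sizeable leaks.
5. The edition-5 and edition-6 rows of the conversion CPTs are tied
   (counts pooled) by default, `tie_editions_56`: the two editions define
   one conversion, and the pooled estimate is markedly more stable than
   estimating the smaller edition-5 subsample separately.

The stage-group CPTs (`TNM_7`, `TNM_567`) are clamped to the
deterministic grouping tables by default (`clamp_deterministic`) — stage
grouping is definitional, not statistical — with a flag to learn them
from data instead.

Defaults: `max_iterations = 200`, `tolerance = 1e-4` on the total
log-likelihood gain, `pseudo_count = 1`. The per-iteration log-likelihood
trace is returned and is non-decreasing (the EM guarantee; the suite
asserts it to within 1e-8 on every run).

## Query recipes

For a 7th-edition source, evidence is set directly on the hidden nodes
together with `edition = target`, and `TNM_567` is queried. This is the
default because the hidden nodes *are* 7th-edition descriptors. The
alternative recipe (`recipe = "observed"`) enters the descriptors through
the observation nodes with `edition = 7`, infers the hidden posterior and
mixes target-edition queries over it; with identity edition-7 conversion
rows the two coincide, which the tests check. For a 5th/6th-edition
source, evidence goes on `edition` and the `_567` nodes and `TNM_7` is
queried. Point predictions take the state of highest belief; ties within
1e-12 are broken by configured state order and flagged.

## The rule-based ground truth

Evaluating stage reclassification needs a truth standard.
`rule_reclassify_7to6()` encodes the inverse of the published 6th-to-7th
edition changes as a first-match-wins rule table (shipped as JSON):
N maps identically; T1a/T1b → T1 and T2a/T2b → T2 always; T3 maps to T4
when multifocal, to T3 when superior-sulcus involvement is recorded, and
to the range {T2, T3} otherwise (invasion status is not collected);
a nonmetastatic multifocal T4 leaves both the 6th-edition T (any of
T1–T4) and M ({M0, M1}) undetermined. Missing extra variables widen
ranges instead of erroring. The stage range is the set of stage groups
reachable from the Cartesian product of the descriptor candidates, which
often collapses: M1 forces IV whatever T and N are, and N2 with M0 yields
IIIA for any T2 or T3. Records whose range is not a singleton are removed
from the ground-truth set, or — in the worst-case sensitivity analysis —
added to the confusion matrix with the candidate that makes the
prediction wrong (`worst_case_adjustment()`), so every two-candidate
ambiguity counts as an error.

## The synthetic registry

The package ships a generator (`simulate_registry()`) because the
registry data the method is designed for cannot be redistributed. The
generator follows the network's own causal story: incidence year →
edition; latent 7th-edition descriptors → latent stage; observed
descriptors through the conversion tables; survival category given the
latent stage; then a death day consistent with the category and an
administrative censoring day derived from the incidence year (follow-up
ends at the start of 2017), so survival is missing exactly for patients
alive with under 731 days of follow-up — recent diagnoses are censored
most, as in a real registry snapshot. Records from 2015 onward carry
multifocality, tumor size (consistent with the latent T size class) and
superior-sulcus fields.

Defaults are documented synthetic presets, not registry estimates:
146,084 records over 1999–2016 with a uniform year mix; a latent T mix
shifted toward advanced disease and a 45% metastatic fraction; and a
stage-monotone survival model in which the probability of surviving at
least 24 months falls from 0.85 (IA) to 0.08 (IV). What the generator
does *not* emulate: registry coding errors and recoding waves, multiple
primaries, real Dutch incidence trends, or descriptor distributions that
drift over calendar time within an edition. Passing tests on this cohort
therefore demonstrate the *procedures* — identifiability of the
conversion tables, calibration of self-consistent predictions, metric
arithmetic — not performance on real registry data.

## Numerical choices

* CPT rows must sum to 1 within 1e-9; every M-step renormalizes.
* CPT rows never supported by data are stored uniform with a
  `never_observed` flag, so inference never divides by zero.
* Probabilities are stored in row matrices indexed by mixed-radix
  parent-state encoding, little-endian in parent list order; the JSON
  serialization (`write_network_json()`) flattens them row-major with 17
  significant digits, which round-trips doubles exactly.
* Exact inference is variable elimination with a greedy
  smallest-intermediate-factor ordering; the test suite checks it against
  full-joint enumeration (`brute_force_posterior()`) to 1e-9 on hundreds
  of randomized networks. No sampling is used anywhere in inference.
* Quantile calibration bins are contiguous equal-count blocks after a
  stable sort; ties in predicted probability stay in input order, and the
  last bin absorbs the remainder.
* Survival discretization uses 30.44 days per month; the top category
  starts at day 731 (= ⌈24 × 30.44⌉).

## Deliberate design decisions on open points

* The default year → edition mapping (1999–2002 → 5, 2003–2009 → 6,
  2010–2016 → 7) ships as a configuration file and is never hard-coded in
  logic; registries that switched in different years pass their own
  mapping.
* The default survival boundaries {3, 6, 12, 24} months are the
  categories commonly used in the lung-cancer literature; they are
  configurable and recorded in all outputs.
* TX/T0/NX/MX are excluded from the default network state spaces; staging
  functions still accept them and resolve them by candidate expansion,
  returning `UNKNOWN` where the candidates disagree. Records with
  `UNKNOWN` stage are retained in tables but excluded from
  stage-conditioned training and evaluation.
* "Average accuracy" is reported as overall accuracy (trace over total);
  the mean of per-class one-vs-rest accuracies is computed alongside it
  because both conventions circulate in the multiclass literature.
* Classes absent from the truth are dropped from macro averages with a
  warning.

## Problem sizes in the tests and the acceptance script

The test suite fits EM cohorts of 20,000–50,000 synthetic records (the
parameter-recovery check uses 50,000, where the Monte-Carlo standard
error of a conversion-cell estimate is well below the 0.05 assertion
band) and verifies the inference oracle on 200 randomized small networks
plus a reduced-state-space version of the full ten-node network.
`scripts/acceptance.R` runs the registry-scale pipeline — 146,084
simulated records, an 80/20 split, resampling to 45,000 per edition, EM,
and the three evaluations — in well under a minute of compute.

## Known limitations

* The conversion-table estimates for cells that separate only through the
  survival signal (e.g. how much observed T2 mass under editions 5/6
  stems from hidden T3) carry more uncertainty than their frequency-only
  standard errors suggest; the identifiability comes from the death node
  and the stage observations.
* The M1a pleural-effusion nuance above biases a small fraction of
  reclassifications toward IV where a 6th-edition coder would have said
  IIIB.
* Editions at or beyond the 8th, pathological staging, and non-lung
  tumor sites are out of scope.
* The rule table reflects the published descriptor-level changes; a
  registry with richer collected variables (invasion status, nodule
  location) could resolve more of the {T2, T3} and multifocal-T4
  ambiguities than the shipped rules can.

```{r example}
library(tnmbn)

cfg <- simulation_config(n_records = 50000, seed = 1)
sim <- simulate_registry(cfg)
split <- split_train_test(sim$records, 0.8, seed = 2)
train <- resample_training(split$train, 10000, seed = 3)

net <- build_structure()
net <- init_hidden_cpts(net, subset(train, edition == "7"))
fit <- em_fit(net, train)

reclassify_stage(fit$network, "T3", "N1", "M0", source_edition = "7",
                 target_edition = "6")
predict_survival(fit$network, "T2", "N2", "M0", edition = "6")
```
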