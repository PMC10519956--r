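---
title: "Inferring repeated cancer evolution trajectories: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring repeated cancer evolution trajectories: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotraj)
```

## The inference problem

Driver mutations accumulate during tumor evolution, and for a given cancer
(sub)type selective pressures can make parts of that order repeatable across
patients. `evotraj` estimates those repeated orderings from two inputs:

* a cross-sectional binary matrix `D` (m patients x n candidate driver
  genes), and
* per-patient temporal DAGs `G_phi`, one per patient, whose arcs say "this
  mutation likely came earlier". These DAGs come from cancer cell fractions
  (single-biopsy cohorts), or from mutational trees built on multi-region or
  single-cell data by external tools whose output is imported, not
  reimplemented.

The stages are: union graph → minimum-agony ranking → Suppes poset →
penalized-likelihood network fit → (optionally) survival signatures. Each
stage is exposed as an exported function; `infer_trajectories()` chains them.

## Per-patient orderings

**CCF track.** Under clonal expansion, a mutation carried by a larger
fraction of tumor cells was in expectation acquired earlier, so a patient's
mutations are ordered by decreasing CCF. `ccf_to_patient_dag()` draws an arc
`g -> h` when `ccf[g] > ccf[h] + epsilon` and returns the transitive
reduction. `epsilon` (default 0, i.e. strict ordering) expresses how much
CCF separation is required before two mutations are considered ordered;
raising it makes orderings sparser and more conservative. When CCFs are not
given directly they are derived from read counts as
`clamp(alt/(alt+ref) * cn_factor, 0, 1)`, where `cn_factor` is the local
total copy number relative to normal ploidy (1 at a diploid locus, supplied
per record, default 1).

**Multi-sample track.** `infer_patient_tree()` builds a per-patient
mutational tree from multiple biopsies or cells: a maximum-weight spanning
arborescence in which an arc `u -> v` is admissible only when the marginal
frequency across the patient's samples satisfies `f(u) >= f(v)`, weighted by
the joint frequency `f(u, v)`. Because admissible arcs respect a fixed order
on the genes, choosing each gene's best admissible parent independently is
provably optimal. Two choices here were genuinely open:

* *Weight ties.* Joint frequency alone cannot separate a gene's true parent
  from a more distant ancestor that co-occurs equally often (in a clean
  chain `a -> b -> c` both `a` and `b` co-occur with `c` in exactly the
  samples carrying `c`). Ties therefore break toward the candidate with the
  *smaller* marginal frequency — the most proximate ancestor under a
  cumulative model — and only then lexicographically. With a purely
  lexicographic tie-break the arborescence would frequently skip a
  generation.
* *Identical sample sets.* Genes observed in exactly the same samples are
  unorderable; the pair is oriented lexicographically and recorded in the
  `tie_pairs` attribute so downstream users can treat those arcs as
  arbitrary.

This simplified arborescence stands in for the external mutational-tree
tools only inside the synthetic benchmark; real analyses are expected to
import trees.

## Union graph and minimum-agony ranking

`build_union_graph()` overlays all patient DAGs; each arc carries the number
of supporting patients (`weighting = "multiplicity"`, the default — an arc
seen in 40 patients should weigh more than one seen once; `"simple"` gives
the unweighted union). A dummy root with an arc to every gene represents the
wild type; it is pinned at rank 0 and its arcs can never be pruned.

Disagreements between patients make the union graph cyclic. The ranking
stage resolves them: an integer rank `r(v)` (1..n) is assigned to every gene
so that the total weighted *agony*, `sum w(u->v) * max(0, r(u) - r(v) + 1)`,
is minimal. Forward arcs are free, ties cost one, backward arcs their rank
gap plus one. The solver is an exact dynamic program over level sets using
the threshold decomposition "an arc pays one unit at every level t with
`r(v) <= t <= r(u)`", which makes the cost of placing a level set depend
only on (placed-below set, level set). It is exponential in n
(O(n·3^n) time) but exact, and driver panels in this setting are capped at
15 genes, where a solve takes well under a second. Among co-optimal
rankings the lexicographically smallest rank vector is returned
(`canonical = TRUE`), which makes results invariant to gene relabeling;
resampling loops skip that refinement for speed, since consensus ranks are
averaged anyway.

`prune_inconsistent_arcs()` then keeps exactly the strictly rank-increasing
arcs, yielding an acyclic family of orderings best supported across the
cohort. `bootstrap_ranking()` stabilizes ranks by resampling patients with
replacement (tree track) or redrawing each CCF from its read-count
posterior `Beta(alt+1, ref+1)` scaled by the copy-number factor
(single-biopsy track), and returns the per-gene rounded mean rank over
`B = 100` iterations by default.

## The Suppes poset

A candidate ordered pair `(u, v)` enters the poset when two conditions hold.

*Temporal priority:* `r(u) < r(v)` under the agony ranking.

*Probability raising*, estimated on the patients where both events are
observed: the fraction of co-mutated patients whose DAG contains a directed
path `u ~> v` (`p_precede`) must exceed the cohort fraction of patients
carrying `u` without `v` (`p_u_not_v`). "Precedes" means a directed path,
not only a direct arc; co-mutated patients whose DAG leaves the pair
incomparable count in the denominator only, which is conservative. Pairs
that never co-occur are flagged undefined and excluded. Estimates are raw
frequencies; add-one smoothing is available (`smoothing = TRUE`) for tiny
cohorts but off by default. No multiple-testing correction is applied at
this stage — the conditions are strict inequalities, not tests — and the
poset is acyclic by construction because every pair is ranking-consistent.

The same condition can be written by conditioning the joint occurrence on
the temporal order, `P(u,v | t_u < t_v) > P(u,v | t_u >= t_v)`.
`probability_raising_ordered()` implements that form under the convention
that an unobserved event sits at infinite time (a patient with `u` alone is
a `t_u < t_v` observation, a patient with `v` alone or neither is
`t_u >= t_v`). A short calculation shows the order-conditioned decision
reduces exactly to `p_precede > p_u_not_v / (1 - a)`, where `a` is the
co-occurrence fraction — i.e. the two formulations are equivalent up to
whether `P(u, v-bar)` is normalized by the whole cohort or by the
non-co-mutated patients. They therefore coincide everywhere except when
`p_precede` falls in the narrow band between the two thresholds; the test
suite asserts exact agreement outside the band and verifies the reduction
pair-by-pair in integer arithmetic. The production rule used by
`build_poset()` is the whole-cohort form.

## Network fit

`fit_sbcn()` maximizes a penalized Bernoulli log-likelihood over subsets of
the poset arcs: each gene contributes the maximized log-likelihood of its
column given its parents minus the number of free parameters (`2^#parents`
per gene; with `score = "bic"` each parameter costs `log(m)/2` instead of
1). Conditional frequencies of 0 or 1 are floored at `1/(2m)` so the
log-likelihood stays finite. The search is hill climbing with single-arc
additions/deletions — arc directions are fixed by the poset, so every
visited structure is automatically acyclic — restarted from random subsets
(each poset arc included with probability 1/2; the number of restarts,
default 100, only affects optimization quality). The first restart always
starts from the empty network so small problems are solved deterministically
even with one restart. Ties across restarts break toward fewer arcs, then
lexicographically. On posets small enough to enumerate, the suite verifies
the climb attains the exhaustive optimum.

`cross_validate_arcs()` reruns the whole pipeline on repeated 80% patient
subsamples (100 repetitions by default) and reports, per arc, the fraction
of repetitions that refit it — the arc's confidence. Confidence is computed
on training splits only; no held-out likelihood is defined.
`baseline_ml_fit()` is the comparison point: the identical search without
the poset constraint (all ordered pairs as candidates, cycle-checked), i.e.
a plain maximum-likelihood structure learner.

**What recovery to expect.** With clean data the fitted network usually
equals the generative one, but not always, and deliberately so: the AIC
optimum is not the generative structure in two well-understood situations.
If a gene activates almost surely given its parent, its column can duplicate
the parent's, making parent and grandparent likelihood-equivalent — no score
can separate them, and the deterministic tie-break may pick either. And at
finite m, a spurious candidate arc clears the AIC penalty whenever its
chance likelihood gain exceeds 2 (probability `exp(-2)` per tested pair for
a two-parameter extension). In benchmark terms: mean structural accuracy on
clean 10-gene chains and trees at m = 200 is about 0.99, exact recovery
occurs in roughly two thirds of runs, accuracy decreases monotonically with
noise, and the poset-constrained fit dominates the unconstrained baseline at
every noise level.

## Evolutionary signatures

`build_evo_features()` turns a fitted model into binary covariates: one
singleton per gene plus one pair feature per arc (`"u->v"`, set when both
endpoints are mutated; a direction-aware variant additionally requires the
patient's CCF ordering to agree). `fit_regularized_cox()` runs the L1 Cox
path (glmnet, Breslow ties) and picks the penalty at minimum k-fold
cross-validated deviance (folds default 10, fold assignment seeded); the
nonzero coefficients are the signature components. With a single usable
covariate the lasso path is unavailable and an unpenalized Cox fit with a
likelihood-ratio test at p < 0.05 substitutes.

Stratification was the most open design point: patients are grouped by
their binary profile over the selected features, profiles merged by
average-linkage clustering under Hamming distance, k chosen in 2..6 by mean
silhouette width, and clusters relabeled by ascending mean linear predictor
so cluster 1 is always lowest-risk. Risk-score quantile stratification is a
simpler alternative obtainable from the returned `risk_score`. Group
differences are assessed by Kaplan-Meier curves and the multi-group
log-rank test; p-values are reported as-is, with no correction across
cohorts.

## The synthetic benchmark

The generator reproduces a two-track factorial design.

*Single-biopsy track.* 100 replicate topologies — weakly connected random
DAGs with 10 genes and density 0.4, i.e. `ceiling(0.4 * 45) = 18` arcs —
crossed with parent logics AND/OR/XOR, cohort sizes {50, 100, 200} and
symmetric flip noise {0, 5, 10, 15, 20}% (4500 binary datasets). Sampling
is cumulative: genes activate in topological order with per-gene
probability `theta_v` when their parent logic is satisfied. `theta_v` is
drawn uniformly from (0.5, 1) per gene and replicate — a realistic "driver
events are reasonably penetrant" regime chosen once; nothing in the design
pins it. Each dataset is optionally dressed with CCFs: a random linear
extension of the DAG per patient, uniform draws sorted decreasing along it,
Gaussian noise with variance {0, 0.01, 0.05, 0.10, 0.20}, clamped to [0,1]
(22,500 configurations).

*Multi-sample track.* Three random 5-gene trees per replicate, either
gene-disjoint (15-gene universe) or sharing five genes (10-gene universe);
each patient follows one tree, each sample is a root-to-node path. Bulk
sequencing: 10 biopsies per patient, 10 or 20 patients, flip noise
{0, 1, 5, 10, 20}%. Single-cell: 25 cells per patient, 5 or 10 patients,
false-positive rates {0, 1, 2, 3, 4}% paired index-wise with allele-dropout
rates {0, 10, 20, 30, 40}% (4000 datasets). In total: 8500 generative
topologies, 26,500 configurations, every one regenerable bit-identically
from its stored seed.

What the generator does *not* emulate: subclonal copy-number interference
with CCF estimates, purity variation, gene-gene mutual exclusivity from
pathway redundancy, cohort heterogeneity mixing subtypes, and informative
censoring in the survival generator (`simulate_survival()` is a plain
exponential model with log-hazard linear in planted features, added for
testing the signature stage — it is not part of the benchmark design).
Passing tests on this generator shows the machinery is correct under the
stated model, not that real cohorts satisfy the model.

## Numerical choices and degenerate inputs

* Probability floor `1/(2m)` for empty or pure conditional cells; parent
  configurations never observed contribute zero likelihood and `NA` in the
  reported conditional tables.
* Score comparisons use a `1e-9` tolerance before the fewer-arcs /
  lexicographic tie-break.
* Genes never resampled in a bootstrap replicate fall back to rank 1 for
  that replicate's average (they carry no ordering evidence).
* Patients present in `D` but absent from the DAG input contribute to
  marginal frequencies (the probability-raising denominator) but provide no
  ordering evidence; single-mutation patients enter the union graph only
  through the root arc.
* Empty posets, empty networks, single-gene patients, and clusters of one
  profile all return well-formed degenerate objects rather than errors;
  readers reject malformed records naming the offending line or patient.
* The exact agony solver refuses more than 16 genes rather than silently
  approximating; panels beyond that size need a different solver, which is
  out of scope.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` verify the solver against
exhaustive enumeration on 200 random graphs of up to 5 genes, the structure
search against exhaustive subset enumeration on 100 four-gene posets, the
decision-rule agreement on 1000 simulated pairs, generative recovery on 50
clean 10-gene runs (m = 200, 100 restarts), a reduced noise sweep (10
replicates per level, 25 restarts) against the unconstrained baseline, and
survival recovery on 50 seeds at m = 300 — sizes chosen so the whole suite
completes in minutes while each check still has narrow Monte-Carlo error.
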