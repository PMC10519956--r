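# evotraj

Repeated cancer evolution trajectories and prognostic evolutionary
signatures from cross-sectional cohorts.

## The problem

Tumors accumulate driver mutations, and for a given cancer (sub)type
selection can make parts of that order repeat across patients. Given

* a binary patient × gene mutation matrix **D** (m patients, n candidate
  drivers, n ≪ m), and
* per-patient temporal DAGs **G<sub>φ</sub>** saying which of a patient's
  mutations likely came earlier — derived from cancer cell fractions (CCFs)
  in single-biopsy cohorts, or imported from mutational-tree tools for
  multi-region / single-cell data,

`evotraj` infers the orderings that repeat across the cohort and turns them
into survival covariates. It is aimed at cancer-genomics analysts working
with driver panels of up to ~15 genes per cohort.

## The model

1. **Union graph.** All patient DAGs are overlaid into one graph G<sub>P</sub>
   whose arcs are weighted by the number of supporting patients, plus a
   wild-type root. Patient disagreements make it cyclic.
2. **Minimum-agony ranking.** Every gene gets an integer temporal rank
   r(·) minimizing the total weighted agony
   Σ w(u→v) · max(0, r(u) − r(v) + 1); an exact dynamic program solves
   panels up to 16 genes. Arcs inconsistent with the ranking are pruned.
   Bootstrap resampling (patients, or CCFs redrawn from
   Beta(alt+1, ref+1) read-count posteriors) stabilizes the ranks.
3. **Suppes poset.** An ordered pair (u, v) is a candidate trajectory step
   when *temporal priority* (r(u) < r(v)) and *probability raising* hold:
   among co-mutated patients, u precedes v (a directed path u ⇝ v in the
   patient's DAG) more often than u occurs without v in the cohort,
   P(t<sub>u</sub> < t<sub>v</sub> | u, v) > P(u, v̄).
4. **Suppes–Bayes causal network.** Hill climbing with random restarts
   maximizes a penalized Bernoulli log-likelihood (AIC; score = log L − k
   with k = Σ<sub>v</sub> 2^|parents(v)|) over subsets of the poset arcs;
   cross-validation on repeated 80/20 patient splits attaches a confidence
   to every arc.
5. **Evolutionary signatures.** Singleton and arc co-occurrence indicators
   feed an L1-penalized Cox regression (λ at minimum cross-validated
   deviance); selected features stratify patients into risk groups assessed
   by Kaplan–Meier curves and the log-rank test.

A full synthetic benchmark generator (cumulative AND/OR/XOR models, CCF
noise, bulk and single-cell multi-sample noise) and structural-accuracy
metrics are included, so every stage is testable without external data.

## Worked example

Simulate a 6-gene cohort with 5% genotype noise and CCFs, run the full
pipeline with bootstrap ranking and cross-validation, and score it against
the generative truth:

```r
library(evotraj)
dag <- random_dag(6, 0.4, seed = 7)
gm  <- generative_model(dag, "AND", seed = 8)
sim <- sample_cumulative(gm, 150, noise = 0.05, seed = 9)
ccf <- simulate_ccf(sim$data, gm, sigma2 = 0.01, seed = 10)

fit <- infer_trajectories(sim$data, ccf = ccf, bootstrap = 50,
                          config = search_config(restarts = 50, seed = 11),
                          cv_reps = 25, seed = 12)
fit$model
#> sbcn: 6 genes, 6 arcs
#>   g01 -> g03 (confidence 0.64)
#>   g02 -> g05 (confidence 1.00)
#>   g02 -> g06 (confidence 1.00)
#>   g04 -> g03 (confidence 1.00)
#>   g06 -> g01 (confidence 1.00)
#>   g06 -> g04 (confidence 1.00)

classification_metrics(confusion_vs_truth(fit$model, sim$truth, gm$genes))
#>    accuracy   precision      recall specificity
#>   0.9000000   0.8333333   0.7142857   0.9565217
```

Each arc is a repeated evolutionary step (parent mutation before child);
its confidence is the fraction of cross-validation refits containing it —
here every arc but one is perfectly stable. The confusion metrics compare
inferred arcs with the generative DAG over all ordered gene pairs: 5 of 7
true arcs recovered, one false arc, 90% of pairs classified correctly.

Attach (simulated) survival and derive signatures:

```r
x   <- build_evo_features(sim$data, fit$model)
s   <- simulate_survival(x, beta = setNames(log(3), "g06->g04"), seed = 13)
sig <- evo_signatures(sim$data, fit$model, s, folds = 5, seed = 14)
sig$km
#> log-rank: chisq = 38.068 on 1 df, p = 6.831e-10
```

The planted hazardous step `g06->g04` comes out with the largest hazard
ratio (5.9) and the two risk groups separate decisively.

A thin command-line wrapper over the same functions is installed at
`inst/cli/evotraj.R` (subcommands `simulate`, `rank`, `infer`,
`signatures`, `evaluate`).

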