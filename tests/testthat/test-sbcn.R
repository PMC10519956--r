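test_that("empty-network score is the marginal likelihood minus n", {
  d <- local_seed_test(31, mutation_matrix(
    matrix(rbinom(300, 1, 0.3), 100, 3,
           dimnames = list(sprintf("p%03d", 1:100), c("a", "b", "c")))))
  got <- score_network(d, NULL)
  m <- nrow(d)
  manual <- sum(vapply(colnames(d), function(g) {
    p <- mean(d[, g])
    eps <- 1 / (2 * m)
    p <- min(max(p, eps), 1 - eps)
    sum(d[, g]) * log(p) + (m - sum(d[, g])) * log(1 - p)
  }, 0)) - 3
  expect_equal(got, manual)
})

test_that("arcs between independent columns are penalized, dependent pairs rewarded", {
  d <- local_seed_test(32, mutation_matrix(
    matrix(rbinom(4000, 1, 0.5), 2000, 2,
           dimnames = list(sprintf("p%04d", 1:2000), c("a", "b")))))
  expect_lt(score_network(d, rbind(c("a", "b"))), score_network(d, NULL))

  # duplicated column: the likelihood gain of the arc dwarfs the penalty
  dup <- mutation_matrix(cbind(a = d[, "a"], b = d[, "a"]),
                         patients = rownames(d))
  expect_gt(score_network(dup, rbind(c("a", "b"))),
            score_network(dup, NULL))
})

test_that("score rejects cyclic arc sets", {
  d <- mutation_matrix(rbind(c(1L, 0L), c(0L, 1L)),
                       patients = c("p1", "p2"), genes = c("a", "b"))
  expect_error(score_network(d, rbind(c("a", "b"), c("b", "a"))), "cycle")
})

test_that("hill climbing attains the exhaustive optimum on small posets", {
  for (seed in 1:25) {
    fx <- small_pipeline_fixture(seed = 1200 + seed, n = 4, m = 80,
                                 logic = c("AND", "OR", "XOR")[seed %% 3 + 1])
    dags <- ccf_table_to_dags(fx$ccf)
    r <- min_agony_ranking(build_union_graph(dags), canonical = FALSE)
    poset <- build_poset(fx$sim$data, dags, r)
    fit <- fit_sbcn(fx$sim$data, poset,
                    search_config(restarts = 20, seed = seed))
    expect_equal(attr(fit, "score"),
                 exhaustive_best_score(fx$sim$data,
                                       poset[, c("parent", "child")]),
                 info = sprintf("seed %d", seed))
    # arcs stay inside the poset and acyclic
    if (nrow(fit$arcs) > 0L) {
      pk <- paste(poset$parent, poset$child, sep = "->")
      fk <- paste(fit$arcs$parent, fit$arcs$child, sep = "->")
      expect_true(all(fk %in% pk))
    }
  }
})

test_that("an empty poset yields the empty network", {
  d <- mutation_matrix(rbind(c(1L, 1L), c(0L, 1L)),
                       patients = c("p1", "p2"), genes = c("a", "b"))
  poset <- data.frame(parent = character(0), child = character(0))
  fit <- fit_sbcn(d, poset, search_config(restarts = 2, seed = 1))
  expect_equal(nrow(fit$arcs), 0L)
  expect_named(fit$node_params, c("a", "b"))
})

test_that("a noise-free three-gene chain is recovered exactly", {
  gm <- chain_model(n = 3, seed = 51)
  sim <- sample_cumulative(gm, 200, noise = 0, seed = 52)
  ccf <- simulate_ccf(sim$data, gm, sigma2 = 0, seed = 53)
  fit <- infer_trajectories(sim$data, ccf = ccf,
                            config = search_config(restarts = 25, seed = 54))
  expect_setequal(paste(fit$model$arcs$parent, fit$model$arcs$child,
                        sep = "->"),
                  paste(sim$truth[, 1L], sim$truth[, 2L], sep = "->"))
})

test_that("fits are deterministic given the seed", {
  fx <- small_pipeline_fixture(seed = 77, n = 5, m = 100)
  f1 <- infer_trajectories(fx$sim$data, ccf = fx$ccf,
                           config = search_config(restarts = 10, seed = 3))
  f2 <- infer_trajectories(fx$sim$data, ccf = fx$ccf,
                           config = search_config(restarts = 10, seed = 3))
  expect_identical(f1$model$arcs, f2$model$arcs)
})

test_that("cross-validation confidences are frequencies in [0,1]", {
  gm <- chain_model(n = 4, seed = 61)
  sim <- sample_cumulative(gm, 120, noise = 0, seed = 62)
  ccf <- simulate_ccf(sim$data, gm, sigma2 = 0, seed = 63)
  dags <- ccf_table_to_dags(ccf)
  conf <- cross_validate_arcs(sim$data, dags, reps = 8, seed = 64,
                              config = search_config(restarts = 10, seed = 1))
  expect_true(all(conf$confidence >= 0 & conf$confidence <= 1))
  # single repetition gives 0/1 confidences
  conf1 <- cross_validate_arcs(sim$data, dags, reps = 1, seed = 65,
                               config = search_config(restarts = 5, seed = 1))
  expect_true(all(conf1$confidence %in% c(0, 1)))
  # strong clean signal: the true chain arcs are always refit
  truth <- paste(sim$truth[, 1L], sim$truth[, 2L], sep = "->")
  got <- setNames(conf$confidence, paste(conf$parent, conf$child, sep = "->"))
  expect_true(all(got[truth] == 1))
})

test_that("the unconstrained baseline searches a superset of the poset space", {
  fx <- small_pipeline_fixture(seed = 88, n = 4, m = 100)
  dags <- ccf_table_to_dags(fx$ccf)
  r <- min_agony_ranking(build_union_graph(dags), canonical = FALSE)
  poset <- build_poset(fx$sim$data, dags, r)
  constrained <- fit_sbcn(fx$sim$data, poset,
                          search_config(restarts = 20, seed = 2))
  baseline <- baseline_ml_fit(fx$sim$data,
                              search_config(restarts = 20, seed = 2))
  expect_gte(attr(baseline, "score") + 1e-9, attr(constrained, "score"))
  # baseline output is a DAG
  expect_false(is.null(evotraj:::topo_sort(
    baseline$genes, evotraj:::as_arc_matrix(baseline$arcs))))
})

test_that("the baseline returns an empty network on constant columns", {
  d <- mutation_matrix(matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 3, 2,
                              dimnames = list(c("p1", "p2", "p3"),
                                              c("a", "b"))))
  # columns are deterministic complements; with m this small the penalty
  # dominates any dependence gain
  fit <- baseline_ml_fit(d, search_config(restarts = 5, seed = 9))
  expect_equal(nrow(fit$arcs), 0L)
})
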