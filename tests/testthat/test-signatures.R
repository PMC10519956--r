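test_that("pair features imply both singleton features", {
  d <- mutation_matrix(rbind(c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L)),
                       patients = c("p1", "p2", "p3"),
                       genes = c("u", "v", "w"))
  model <- sbcn(c("u", "v", "w"),
                arcs = data.frame(parent = "u", child = "v"))
  x <- build_evo_features(d, model)
  expect_equal(colnames(x), c("u", "v", "w", "u->v"))
  expect_equal(unname(x[, "u->v"]), c(1L, 0L, 0L))
  # implication invariant
  expect_true(all(x[, "u->v"] <= x[, "u"] & x[, "u->v"] <= x[, "v"]))

  # empty model: features are exactly the gene columns
  x0 <- build_evo_features(d, sbcn(c("u", "v", "w")))
  expect_equal(unclass(x0)[, ], unclass(d)[, ])

  # the invariant holds on random cohorts and models
  for (seed in 1:10) {
    fx <- small_pipeline_fixture(seed = 1400 + seed, n = 5, m = 60)
    model <- sbcn(fx$gm$genes,
                  arcs = data.frame(parent = fx$gm$arcs[, 1L],
                                    child = fx$gm$arcs[, 2L]))
    xx <- build_evo_features(fx$sim$data, model)
    for (i in seq_len(nrow(model$arcs))) {
      pf <- paste0(model$arcs$parent[i], "->", model$arcs$child[i])
      expect_true(all(xx[, pf] <= xx[, model$arcs$parent[i]]))
      expect_true(all(xx[, pf] <= xx[, model$arcs$child[i]]))
    }
  }
})

test_that("a planted hazardous feature is selected with a positive sign", {
  hits <- 0L
  for (seed in 1:10) {
    x <- local_seed_test(seed, matrix(
      rbinom(300 * 6, 1, 0.4), 300, 6,
      dimnames = list(sprintf("p%03d", 1:300),
                      c("hit", paste0("noise", 1:5)))))
    s <- simulate_survival(x, beta = c(hit = log(3)), seed = seed + 500)
    sel <- fit_regularized_cox(x, s, folds = 5, seed = seed)
    if ("hit" %in% sel$features && sel$coefficients["hit"] > 0)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("pure-noise covariates are rarely selected", {
  n_sel <- integer(10)
  for (seed in 1:10) {
    x <- local_seed_test(seed + 40, matrix(
      rbinom(300 * 6, 1, 0.4), 300, 6,
      dimnames = list(sprintf("p%03d", 1:300), paste0("noise", 1:6))))
    s <- simulate_survival(x, beta = c(noise1 = 0), seed = seed + 540)
    sel <- fit_regularized_cox(x, s, folds = 5, seed = seed)
    n_sel[seed] <- length(sel$features)
  }
  expect_lte(median(n_sel), 1)
})

test_that("duplicated informative covariates keep at least one copy", {
  x <- local_seed_test(61, {
    base <- rbinom(300, 1, 0.5)
    cbind(hit = base, dup = base,
          noise = rbinom(300, 1, 0.5))
  })
  rownames(x) <- sprintf("p%03d", 1:300)
  s <- simulate_survival(x, beta = c(hit = log(3)), seed = 62)
  sel <- fit_regularized_cox(x, s, folds = 5, seed = 63)
  expect_gte(sum(c("hit", "dup") %in% sel$features), 1L)
})

test_that("constant features are dropped with a warning", {
  x <- cbind(hit = rep(c(0L, 1L), 50), flat = rep(1L, 100))
  rownames(x) <- sprintf("p%03d", 1:100)
  s <- simulate_survival(x, beta = c(hit = log(4)), seed = 71)
  expect_warning(sel <- fit_regularized_cox(x, s, seed = 72), "constant")
  expect_false("flat" %in% sel$features)
})

test_that("stratification matches carrier status for one selected feature", {
  x <- cbind(hit = rep(c(0L, 1L), each = 20))
  rownames(x) <- sprintf("p%03d", 1:40)
  st <- stratify_patients(x, c(hit = 0.8))
  expect_equal(st$k, 2L)
  expect_true(all(st$cluster[x[, "hit"] == 1] !=
                    st$cluster[x[, "hit"] == 0]))
  # carriers have the higher risk label
  expect_true(all(st$cluster[x[, "hit"] == 1] == 2L))
  # identical profiles share a cluster by construction
  expect_equal(length(unique(st$cluster[x[, "hit"] == 1])), 1L)
})

test_that("disjoint carriers plus double-negatives split into three strata", {
  x <- rbind(matrix(rep(c(1L, 0L), 12), 12, 2, byrow = TRUE),
             matrix(rep(c(0L, 1L), 12), 12, 2, byrow = TRUE),
             matrix(0L, 12, 2))
  colnames(x) <- c("f1", "f2")
  rownames(x) <- sprintf("p%03d", 1:36)
  st <- stratify_patients(x, c(f1 = 0.5, f2 = 1.2))
  expect_equal(st$k, 3L)
  # risk ordering: double-negatives lowest, f2 carriers highest
  expect_equal(unname(unique(st$cluster[25:36])), 1L)
  expect_equal(unname(unique(st$cluster[13:24])), 3L)
})

test_that("cluster labels are reproducible under patient permutation", {
  x <- local_seed_test(81, matrix(rbinom(200, 1, 0.5), 100, 2,
                                  dimnames = list(sprintf("p%03d", 1:100),
                                                  c("f1", "f2"))))
  st <- stratify_patients(x, c(f1 = 1, f2 = -0.5))
  perm <- local_seed_test(82, sample(nrow(x)))
  st_p <- stratify_patients(x[perm, ], c(f1 = 1, f2 = -0.5))
  expect_equal(st_p$cluster[rownames(x)], st$cluster[rownames(x)])
})

test_that("Kaplan-Meier identities hold exactly", {
  # two clusters with identical event histories: log-rank is exactly null
  s <- survival_table(data.frame(
    patient_id = sprintf("p%02d", 1:8),
    time = rep(c(2, 5, 7, 9), 2),
    event = rep(c(1, 0, 1, 1), 2)))
  cl <- setNames(rep(1:2, each = 4), s$patient_id)
  km <- km_logrank(cl, s)
  expect_equal(km$chisq, 0)
  expect_equal(km$p_value, 1)
  # survival starts at 1 for every cluster
  first <- tapply(seq_len(nrow(km$curves)), km$curves$cluster, min)
  expect_true(all(km$curves$survival[first] <= 1))
  expect_true(all(km$curves$survival >= 0 & km$curves$survival <= 1))

  # product-limit hand computation: one event at t=5 among 2 at risk
  s2 <- survival_table(data.frame(patient_id = c("a", "b", "c", "d"),
                                  time = c(5, 8, 3, 9),
                                  event = c(1, 0, 1, 1)))
  cl2 <- setNames(c(1, 1, 2, 2), c("a", "b", "c", "d"))
  km2 <- km_logrank(cl2, s2)
  c1 <- km2$curves[km2$curves$cluster == "1", ]
  expect_equal(c1$survival[c1$time == 5], 0.5)
})

test_that("signature summaries report hazard ratios and prevalences", {
  x <- cbind(hit = rep(c(0L, 1L), each = 15))
  rownames(x) <- sprintf("p%03d", 1:30)
  s <- simulate_survival(x, beta = c(hit = log(3)), seed = 91)
  st <- stratify_patients(x, c(hit = log(3)))
  sig <- summarize_signatures(st, x, c(hit = log(3)), s)
  expect_equal(sig$features$hazard_ratio, 3)
  expect_equal(unname(sig$prevalence["hit", ]), c(0, 1))
  expect_true(all(sig$prevalence >= 0 & sig$prevalence <= 1))
  expect_s3_class(sig$km, "km_logrank")
  # zero coefficient maps to hazard ratio one
  st0 <- stratify_patients(x, c(hit = 0))
  sig0 <- summarize_signatures(st0, x, c(hit = 0), s)
  expect_equal(sig0$features$hazard_ratio, 1)
})

test_that("the end-to-end signature wrapper runs on pipeline output", {
  gm <- chain_model(n = 4, seed = 171)
  sim <- sample_cumulative(gm, 150, noise = 0, seed = 172)
  ccf <- simulate_ccf(sim$data, gm, sigma2 = 0, seed = 173)
  fit <- infer_trajectories(sim$data, ccf = ccf,
                            config = search_config(restarts = 10, seed = 174))
  first <- evotraj:::topo_sort(gm$genes, gm$arcs)[1L]
  x <- build_evo_features(sim$data, fit$model)
  s <- simulate_survival(x, beta = setNames(log(4), first), seed = 175)
  sig <- evo_signatures(sim$data, fit$model, s, folds = 5, seed = 176)
  expect_s3_class(sig, "signature_set")
  expect_true(all(sig$prevalence >= 0 & sig$prevalence <= 1))
})
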