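test_that("random DAGs have the prescribed arc count and connectivity", {
  for (seed in 1:40) {
    dag <- random_dag(10, 0.4, seed = seed)
    expect_equal(nrow(dag$arcs), 18L)  # ceiling(0.4 * 45)
    expect_false(is.null(evotraj:::topo_sort(dag$genes, dag$arcs)))
    g <- igraph::graph_from_edgelist(dag$arcs)
    expect_true(igraph::is_connected(g, mode = "weak"))
  }
  full <- random_dag(5, 1, seed = 1)
  expect_equal(nrow(full$arcs), 10L)  # complete order DAG
  expect_identical(random_dag(10, 0.4, seed = 3)$arcs,
                   random_dag(10, 0.4, seed = 3)$arcs)
})

test_that("cumulative sampling honors each parent logic when noise-free", {
  for (logic in c("AND", "OR", "XOR")) {
    dag <- random_dag(8, 0.4, seed = 101)
    gm <- generative_model(dag, logic, seed = 102)
    sim <- sample_cumulative(gm, 150, noise = 0, seed = 103)
    parents <- evotraj:::arcs_to_parents(gm$genes, gm$arcs)
    x <- unclass(sim$data)
    for (g in gm$genes) {
      pa <- parents[[g]]
      if (length(pa) == 0L) next
      active <- rowSums(x[, pa, drop = FALSE])
      ok <- switch(logic,
                   AND = active == length(pa),
                   OR = active >= 1L,
                   XOR = active == 1L)
      expect_true(all(ok[x[, g] == 1L]),
                  info = sprintf("%s gene %s", logic, g))
    }
  }
})

test_that("heavy symmetric noise drives marginals toward one half", {
  gm <- generative_model(random_dag(10, 0.4, seed = 111), "AND",
                         seed = 112)
  sim <- sample_cumulative(gm, 4000, noise = 0.5, seed = 113)
  marg <- colMeans(unclass(sim$data))
  expect_true(all(abs(marg - 0.5) < 4 * sqrt(0.25 / 4000)))
})

test_that("clean CCFs decrease along each patient's drawn order and chain back", {
  gm <- chain_model(n = 6, seed = 121)
  sim <- sample_cumulative(gm, 50, noise = 0, seed = 122)
  ccf <- simulate_ccf(sim$data, gm, sigma2 = 0, seed = 123)
  # per patient, CCFs sorted descending equal the recorded values in the
  # order of the drawn linear extension; and the derived DAG is a chain
  # consistent with the generative order
  ord_pos <- setNames(seq_along(gm$genes),
                      evotraj:::topo_sort(gm$genes, gm$arcs))
  for (p in unique(ccf$patient_id)) {
    rows <- ccf[ccf$patient_id == p, ]
    if (nrow(rows) < 2L) next
    expect_equal(rows$ccf[order(ord_pos[rows$gene])],
                 sort(rows$ccf, decreasing = TRUE))
  }
  dags <- ccf_table_to_dags(ccf, epsilon = 0)
  reach <- evotraj:::reach_matrix(gm$genes, gm$arcs)
  for (pd in dags) {
    if (nrow(pd$arcs) == 0L) next
    # chains: every node has at most one direct successor
    expect_true(all(table(pd$arcs[, 1L]) == 1))
    # arcs never contradict the generative (total chain) order
    for (i in seq_len(nrow(pd$arcs)))
      expect_false(reach[pd$arcs[i, 2L], pd$arcs[i, 1L]])
  }
})

test_that("CCF noise scales with the configured variance", {
  gm <- chain_model(n = 6, seed = 131)
  sim <- sample_cumulative(gm, 400, noise = 0, seed = 132)
  mad_at <- function(s2) {
    set.seed(133)
    clean <- simulate_ccf(sim$data, gm, sigma2 = 0, seed = 134)
    noisy <- simulate_ccf(sim$data, gm, sigma2 = s2, seed = 134)
    mean(abs(noisy$ccf - clean$ccf))
  }
  m1 <- mad_at(0.01); m2 <- mad_at(0.05); m3 <- mad_at(0.20)
  expect_lt(m1, m2)
  expect_lt(m2, m3)
})

test_that("multi-sample structures have the stated gene universes", {
  ms_d <- simulate_multisample("disjoint", "bulk", 10, 0, seed = 141)
  expect_length(ms_d$genes, 15L)
  tg <- lapply(ms_d$trees, `[[`, "genes")
  expect_equal(length(unique(unlist(tg))), 15L)

  ms_o <- simulate_multisample("overlap5", "bulk", 10, 0, seed = 142)
  expect_length(ms_o$genes, 10L)
  tg_o <- lapply(ms_o$trees, `[[`, "genes")
  expect_true(all(lengths(tg_o) == 5L))
  expect_equal(length(unique(unlist(tg_o))), 10L)
})

test_that("noise-free multi-sample genotypes are root-path-closed", {
  for (tech in c("bulk", "single_cell")) {
    ms <- simulate_multisample("disjoint", tech, 5, 0, seed = 143)
    for (i in seq_along(ms$patients)) {
      tr <- ms$trees[[ms$assignment[i]]]
      parents <- evotraj:::arcs_to_parents(tr$genes, tr$arcs)
      geno <- ms$patients[[i]]$genotypes
      expect_equal(nrow(geno), if (tech == "bulk") 10L else 25L)
      for (sdx in seq_len(nrow(geno))) {
        on <- colnames(geno)[geno[sdx, ] == 1L]
        expect_true(length(on) >= 1L)
        for (g in on) {
          pa <- parents[[g]]
          if (length(pa) > 0L) expect_true(pa %in% on)
        }
      }
    }
  }
})

test_that("single-cell false-positive and dropout rates match their nominal levels", {
  # aggregate empirical flip rates over many cells at noise index 3
  fp_n <- 0; fp_d <- 0; fn_n <- 0; fn_d <- 0
  for (seed in 1:40) {
    clean <- simulate_multisample("disjoint", "single_cell", 4, 0,
                                  seed = 5000 + seed)
    noisy <- simulate_multisample("disjoint", "single_cell", 4, 3,
                                  seed = 5000 + seed)
    for (i in seq_along(clean$patients)) {
      a <- clean$patients[[i]]$genotypes
      b <- noisy$patients[[i]]$genotypes
      fp_n <- fp_n + sum(a == 0L & b == 1L); fp_d <- fp_d + sum(a == 0L)
      fn_n <- fn_n + sum(a == 1L & b == 0L); fn_d <- fn_d + sum(a == 1L)
    }
  }
  fp_rate <- fp_n / fp_d
  fn_rate <- fn_n / fn_d
  expect_lt(abs(fp_rate - 0.03), 3 * sqrt(0.03 * 0.97 / fp_d))
  expect_lt(abs(fn_rate - 0.30), 3 * sqrt(0.3 * 0.7 / fn_d))
})

test_that("the benchmark grids enumerate the full factorial design", {
  sb <- generate_benchmark_suite("single_biopsy")
  expect_equal(nrow(sb), 4500L)
  sb_ccf <- generate_benchmark_suite("single_biopsy", ccf_grid = TRUE)
  expect_equal(nrow(sb_ccf), 22500L)
  ms <- generate_benchmark_suite("multi_sample")
  expect_equal(nrow(ms), 4000L)
  expect_equal(nrow(sb) + nrow(ms), 8500L)
  expect_equal(nrow(sb_ccf) + nrow(ms), 26500L)
  # seeds are unique and deterministic
  expect_false(any(duplicated(sb_ccf$seed)))
  expect_identical(generate_benchmark_suite("multi_sample"), ms)
})

test_that("materialized configurations are bit-identical across calls", {
  sb <- generate_benchmark_suite("single_biopsy", ccf_grid = TRUE,
                                 replicates = 2)
  row <- sb[sb$noise == 0.1 & sb$ccf_variance == 0.05, ][1, ]
  a <- materialize_config(row)
  b <- materialize_config(row)
  expect_identical(unclass(a$data), unclass(b$data))
  expect_identical(a$ccf$ccf, b$ccf$ccf)
  ms <- generate_benchmark_suite("multi_sample", replicates = 2)
  row2 <- ms[ms$tech == "single_cell" & ms$noise_index == 2, ][1, ]
  x <- materialize_config(row2)
  y <- materialize_config(row2)
  expect_identical(x$patients[[1]]$genotypes, y$patients[[1]]$genotypes)
})

test_that("simulated survival responds to planted hazards", {
  x <- local_seed_test(151, matrix(rbinom(600, 1, 0.5), 300, 2,
                                   dimnames = list(sprintf("p%03d", 1:300),
                                                   c("f1", "f2"))))
  s <- simulate_survival(x, beta = c(f1 = log(3)), seed = 152)
  expect_s3_class(s, "survival_table")
  # carriers of the hazardous feature die faster on average (events only)
  carrier <- x[s$patient_id, "f1"] == 1
  expect_lt(median(s$time[carrier]), median(s$time[!carrier]))
})
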