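# Shared fixture builders: tiny graphs, cohorts and oracles used across
# test files. All fixtures are generated in code.

toy_chain_dags <- function() {
  list(patient_dag("p1", c("a", "b", "c"), rbind(c("a", "b"), c("b", "c"))),
       patient_dag("p2", c("a", "b"), rbind(c("a", "b"))),
       patient_dag("p3", c("a"), NULL))
}

# fixed chain generative model over n genes with a seed-shuffled gene order
chain_model <- function(n = 10, seed = 1, theta_seed = seed + 1000) {
  genes <- sprintf("g%02d", seq_len(n))
  ord <- local_seed_test(seed, sample(genes))
  dag <- structure(list(genes = genes,
                        arcs = cbind(ord[-n], ord[-1L]), order = ord),
                   class = "generative_dag")
  generative_model(dag, "AND", seed = theta_seed)
}

local_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

# exhaustive minimum agony over all rank assignments in {1..n}^n
# (independent oracle for the DP solver; feasible for n <= 5)
agony_oracle <- function(g) {
  genes <- g$genes
  n <- length(genes)
  arcs <- g$arcs[g$arcs$parent != g$root, , drop = FALSE]
  if (nrow(arcs) == 0L) return(0)
  u <- match(arcs$parent, genes)
  v <- match(arcs$child, genes)
  w <- arcs$multiplicity
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n)))
  totals <- rowSums(vapply(seq_along(u), function(a)
    w[a] * pmax(0L, grid[, u[a]] - grid[, v[a]] + 1L),
    numeric(nrow(grid))))
  min(totals)
}

# random union graph over <= max_n genes for oracle comparisons
random_union_graph <- function(seed, max_n = 5) {
  local_seed_test(seed, {
    n <- sample(2:max_n, 1)
    genes <- letters[seq_len(n)]
    pairs <- expand.grid(parent = genes, child = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$parent != pairs$child, ]
    k <- sample.int(nrow(pairs), 1)
    arcs <- pairs[sample.int(nrow(pairs), k), ]
    arcs$multiplicity <- sample(1:5, k, replace = TRUE)
    arcs <- rbind(data.frame(parent = root_label(), child = genes,
                             multiplicity = 1), arcs)
    new_union_graph(genes, arcs)
  })
}

# exhaustive maximum of score_network over all subsets of poset arcs
# (independent oracle for the hill climbing; feasible for small posets)
exhaustive_best_score <- function(d, poset_arcs) {
  na <- nrow(poset_arcs)
  best <- -Inf
  for (mask in 0:(2^na - 1)) {
    take <- as.logical(bitwAnd(mask, 2^(seq_len(na) - 1L)) > 0)
    arcs <- poset_arcs[take, , drop = FALSE]
    sc <- score_network(d, arcs)
    if (sc > best) best <- sc
  }
  best
}

# small simulated single-biopsy dataset ready for the pipeline
small_pipeline_fixture <- function(seed = 42, n = 6, m = 120,
                                   logic = "AND", noise = 0) {
  dag <- random_dag(n, 0.4, seed = seed)
  gm <- generative_model(dag, logic, seed = seed + 1)
  sim <- sample_cumulative(gm, m, noise = noise, seed = seed + 2)
  ccf <- simulate_ccf(sim$data, gm, sigma2 = 0, seed = seed + 3)
  list(gm = gm, sim = sim, ccf = ccf)
}
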