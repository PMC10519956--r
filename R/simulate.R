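# Synthetic-data generators reproducing the simulation study design:
# random generative topologies, cumulative-model sampling under AND/OR/XOR
# parent logics, CCF simulation with Gaussian noise, multi-sample bulk and
# single-cell generation with technology-specific noise, and the factorial
# benchmark grids.

#' Random weakly connected generative DAG
#'
#' Draws a random topological order over `n` genes and samples
#' `ceiling(density * n * (n-1) / 2)` of the order-consistent pairs as
#' arcs, resampling until the result is weakly connected. The defaults
#' (10 nodes, density 0.4, hence 18 arcs) are the benchmark's generative
#' topologies.
#'
#' @param n number of genes (>= 2).
#' @param density fraction of the n(n-1)/2 order-consistent pairs included
#'   as arcs, in (0, 1\].
#' @param genes optional gene symbols (default g01, g02, ...).
#' @param seed optional seed.
#' @return List of class `generative_dag`: `genes`, `arcs` (two-column
#'   character matrix), `order` (the generating topological order).
#' @export
random_dag <- function(n = 10, density = 0.4, genes = NULL, seed = NULL) {
  stopifnot(n >= 2, density > 0, density <= 1)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(n))
  stopifnot(length(genes) == n)
  n_arcs <- ceiling(density * n * (n - 1) / 2)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  local_seed(seed, {
    repeat {
      ord <- sample(genes)
      take <- sample.int(nrow(pairs), n_arcs)
      arcs <- cbind(ord[pairs[take, 1L]], ord[pairs[take, 2L]])
      # weak connectivity via union-find over undirected support
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in seq_len(nrow(arcs))) {
        a <- find(match(arcs[k, 1L], genes))
        b <- find(match(arcs[k, 2L], genes))
        if (a != b) parent[a] <- b
      }
      if (length(unique(vapply(seq_len(n), find, 0L))) == 1L) break
    }
    structure(list(genes = genes, arcs = arcs, order = ord),
              class = "generative_dag")
  })
}

#' Random mutational tree
#'
#' Rooted random tree over the given genes: the first gene (after
#' shuffling) hangs from the implicit wild-type root, every later gene
#' attaches to a uniformly chosen earlier gene.
#'
#' @param genes character vector of gene symbols.
#' @param seed optional seed.
#' @return A `generative_dag` whose arcs form a tree.
#' @export
random_tree <- function(genes, seed = NULL) {
  n <- length(genes)
  stopifnot(n >= 1)
  local_seed(seed, {
    ord <- sample(genes)
    arcs <- if (n >= 2L)
      cbind(vapply(2:n, function(i) ord[sample.int(i - 1L, 1L)], ""),
            ord[2:n])
    else matrix(character(0), 0L, 2L)
    structure(list(genes = genes, arcs = arcs, order = ord),
              class = "generative_dag")
  })
}

#' Attach a parent logic and activation probabilities to a DAG
#'
#' @param dag a `generative_dag`.
#' @param logic `"AND"` (all parents required), `"OR"` (at least one) or
#'   `"XOR"` (exactly one).
#' @param theta per-gene activation probabilities in (0,1); by default
#'   drawn uniformly from (0.5, 1) per gene.
#' @param seed optional seed for the theta draw.
#' @return List of class `generative_model`.
#' @export
generative_model <- function(dag, logic = c("AND", "OR", "XOR"),
                             theta = NULL, seed = NULL) {
  logic <- match.arg(logic)
  stopifnot(inherits(dag, "generative_dag"))
  n <- length(dag$genes)
  if (is.null(theta))
    theta <- local_seed(seed, runif(n, 0.5, 1))
  stopifnot(length(theta) == n, all(theta > 0), all(theta < 1))
  structure(list(genes = dag$genes, arcs = dag$arcs, logic = logic,
                 theta = setNames(theta, dag$genes)),
            class = "generative_model")
}

#' Sample a cohort from a cumulative generative model
#'
#' Each patient accumulates mutations along the model's topological order:
#' a gene without parents activates with its probability theta; a gene
#' with parents activates with probability theta only when its parent
#' logic is satisfied (AND: all parents active; OR: at least one; XOR:
#' exactly one), and stays wild-type otherwise. Finally each entry is
#' flipped independently with the given noise probability (symmetric
#' false-positive/false-negative noise).
#'
#' @param gm a [generative_model()].
#' @param m number of patients.
#' @param noise flip probability in \[0,1\].
#' @param seed optional seed.
#' @return List: `data` (a [mutation_matrix()]), `clean` (the noise-free
#'   matrix), `truth` (the generative arcs), `model`.
#' @export
sample_cumulative <- function(gm, m, noise = 0, seed = NULL) {
  stopifnot(inherits(gm, "generative_model"), m >= 1,
            noise >= 0, noise <= 1)
  genes <- gm$genes
  n <- length(genes)
  order <- topo_sort(genes, gm$arcs)
  parents <- arcs_to_parents(genes, gm$arcs)
  local_seed(seed, {
    x <- matrix(0L, m, n, dimnames = list(sprintf("p%04d", seq_len(m)),
                                          genes))
    for (g in order) {
      pa <- parents[[g]]
      sat <- if (length(pa) == 0L) rep(TRUE, m) else {
        active <- rowSums(x[, pa, drop = FALSE])
        switch(gm$logic,
               AND = active == length(pa),
               OR = active >= 1L,
               XOR = active == 1L)
      }
      x[, g] <- as.integer(sat & runif(m) < gm$theta[g])
    }
    clean <- x
    if (noise > 0) {
      flip <- matrix(runif(m * n) < noise, m, n)
      x <- abs(x - flip)
      storage.mode(x) <- "integer"
    }
    list(data = mutation_matrix(x), clean = clean, truth = gm$arcs,
         model = gm)
  })
}

#' Simulate cancer cell fractions for a sampled cohort
#'
#' For each patient a random linear extension of the generative DAG is
#' drawn (a total order consistent with the generative structure);
#' uniform(0,1) draws, sorted in decreasing order, are assigned to the
#' patient's mutated genes along that order, so earlier mutations get
#' higher CCFs. Gaussian noise with the given variance is added and the
#' result clamped to \[0,1\].
#'
#' @param d a [mutation_matrix()] over the model's genes.
#' @param gm the [generative_model()] that produced `d`.
#' @param sigma2 Gaussian noise variance (>= 0).
#' @param depth optional sequencing depth; when given, alt/ref read counts
#'   are drawn as Binomial(depth, ccf / cn) with cn = 1, enabling the
#'   read-count resampling track on simulated data.
#' @param seed optional seed.
#' @return A [ccf_table()] with one record per mutated (patient, gene).
#' @export
simulate_ccf <- function(d, gm, sigma2 = 0, depth = NULL, seed = NULL) {
  stopifnot(inherits(d, "mutation_matrix"),
            inherits(gm, "generative_model"), sigma2 >= 0)
  genes <- gm$genes
  parents <- arcs_to_parents(genes, gm$arcs)
  local_seed(seed, {
    rows <- vector("list", nrow(d))
    for (i in seq_len(nrow(d))) {
      ext <- random_linear_extension(genes, parents)
      mut <- ext[ext %in% genes[unclass(d)[i, ] == 1L]]
      k <- length(mut)
      if (k == 0L) next
      clean <- sort(runif(k), decreasing = TRUE)
      ccf <- if (sigma2 > 0)
        clamp01(rnorm(k, mean = clean, sd = sqrt(sigma2))) else clean
      if (is.null(depth)) {
        alt <- rep(NA_real_, k); ref <- rep(NA_real_, k)
      } else {
        alt <- rbinom(k, depth, ccf)
        ref <- depth - alt
      }
      rows[[i]] <- data.frame(patient_id = rownames(d)[i], gene = mut,
                              alt_reads = alt, ref_reads = ref,
                              cn_factor = 1, ccf = ccf)
    }
    ccf_table(do.call(rbind, rows))
  })
}

# random linear extension: repeatedly emit a uniformly chosen available
# source of the remaining sub-DAG
random_linear_extension <- function(genes, parents) {
  remaining <- genes
  placed <- character(0)
  out <- character(0)
  while (length(remaining) > 0L) {
    avail <- remaining[vapply(remaining, function(g)
      all(parents[[g]] %in% placed), TRUE)]
    pick <- if (length(avail) == 1L) avail else sample(avail, 1L)
    out <- c(out, pick)
    placed <- c(placed, pick)
    remaining <- setdiff(remaining, pick)
  }
  out
}

#' Simulate multi-sample (bulk or single-cell) cohorts
#'
#' The generative process is a composition of three random mutational
#' trees of five genes each: with `structure = "disjoint"` the trees share
#' no genes (15-gene universe), with `structure = "overlap5"` five genes
#' are shared so the universe has 10 genes. Each patient is assigned one
#' tree uniformly; each of the patient's samples is the mutation set on
#' the path from the root to a uniformly drawn tree node. Bulk sequencing
#' yields 10 biopsies per patient with symmetric flip noise from
#' \{0, 1, 5, 10, 20\}%; single-cell sequencing yields 25 cells per patient
#' with paired false-positive rates \{0, 1, 2, 3, 4\}% and allele-dropout
#' (false-negative) rates \{0, 10, 20, 30, 40\}%, both indexed by
#' `noise_index`.
#'
#' @param structure `"disjoint"` or `"overlap5"`.
#' @param tech `"bulk"` or `"single_cell"`.
#' @param n_patients cohort size (10 or 20 for bulk, 5 or 10 for
#'   single-cell in the benchmark grid; any value >= 1 is accepted).
#' @param noise_index noise level index 0..4 into the grids above.
#' @param seed optional seed.
#' @return List: `patients` (list of [sample_genotypes()]), `truth` (union
#'   of the three trees' arcs), `trees`, `genes`, `assignment` (tree index
#'   per patient).
#' @export
simulate_multisample <- function(structure = c("disjoint", "overlap5"),
                                 tech = c("bulk", "single_cell"),
                                 n_patients,
                                 noise_index = 0, seed = NULL) {
  structure <- match.arg(structure)
  tech <- match.arg(tech)
  stopifnot(n_patients >= 1, noise_index %in% 0:4)
  n_samples <- if (tech == "bulk") 10L else 25L
  flip <- c(0, 0.01, 0.05, 0.10, 0.20)[noise_index + 1L]
  fp <- c(0, 0.01, 0.02, 0.03, 0.04)[noise_index + 1L]
  fn <- c(0, 0.10, 0.20, 0.30, 0.40)[noise_index + 1L]
  local_seed(seed, {
    if (structure == "disjoint") {
      genes <- sprintf("g%02d", 1:15)
      tree_genes <- split(genes, rep(1:3, each = 5L))
    } else {
      genes <- sprintf("g%02d", 1:10)
      repeat {
        shared <- sample(genes, 5L)
        private <- setdiff(genes, shared)
        # each shared gene joins two distinct trees; private genes fill the
        # remaining slots so every tree has exactly five genes
        picks <- t(vapply(shared, function(g) sample.int(3L, 2L),
                          integer(2L)))
        counts <- tabulate(c(picks), nbins = 3L)
        if (all(counts <= 5L)) {
          slots <- rep(1:3, times = 5L - counts)
          slots <- sample(slots)
          tree_genes <- lapply(1:3, function(t)
            c(shared[picks[, 1L] == t | picks[, 2L] == t],
              private[slots == t]))
          break
        }
      }
    }
    trees <- lapply(tree_genes, random_tree)
    truth <- unique(do.call(rbind, lapply(trees, `[[`, "arcs")))
    assignment <- sample.int(3L, n_patients, replace = TRUE)
    # all clean genotypes are drawn before any noise, so runs sharing a
    # seed share their pre-noise cohort across noise levels
    clean <- lapply(seq_len(n_patients), function(i) {
      tr <- trees[[assignment[i]]]
      paths <- root_paths(tr)
      geno <- matrix(0L, n_samples, length(genes),
                     dimnames = list(NULL, genes))
      for (sdx in seq_len(n_samples)) {
        node <- sample(tr$genes, 1L)
        geno[sdx, paths[[node]]] <- 1L
      }
      geno
    })
    patients <- lapply(seq_len(n_patients), function(i) {
      geno <- clean[[i]]
      if (tech == "bulk") {
        if (flip > 0) {
          mask <- matrix(runif(length(geno)) < flip, nrow(geno))
          geno <- abs(geno - mask)
        }
      } else {
        if (fp > 0 || fn > 0) {
          u <- matrix(runif(length(geno)), nrow(geno))
          dropped <- geno == 1L & u < fn
          gained <- geno == 0L & u < fp
          geno[dropped] <- 0L
          geno[gained] <- 1L
        }
      }
      storage.mode(geno) <- "integer"
      sample_genotypes(sprintf("p%03d", i), geno)
    })
    list(patients = patients, truth = truth, trees = trees, genes = genes,
         assignment = assignment)
  })
}

# gene -> vector of genes on the path from the tree's root to that gene
root_paths <- function(tree) {
  parents <- arcs_to_parents(tree$genes, tree$arcs)
  paths <- list()
  for (g in topo_sort(tree$genes, tree$arcs)) {
    pa <- parents[[g]]
    paths[[g]] <- if (length(pa) == 0L) g else c(paths[[pa]], g)
  }
  paths
}

#' Enumerate the factorial benchmark grids
#'
#' The single-biopsy scenario crosses 100 replicate topologies (10-gene
#' DAGs of density 0.4) with the three parent logics \{AND, OR, XOR\},
#' cohort sizes \{50, 100, 200\} and symmetric noise levels
#' \{0, 5, 10, 15, 20\}% — 4500 binary datasets — each optionally crossed
#' with the five CCF noise variances \{0, 0.01, 0.05, 0.10, 0.20\}
#' (22,500 configurations). The multi-sample scenario crosses 100
#' replicates with structure \{disjoint, overlap5\}, technology
#' \{bulk, single_cell\}, two cohort sizes (bulk 10/20 patients,
#' single-cell 5/10) and five technology noise levels — 4000 datasets.
#' Every row carries a deterministic seed derived from `base_seed` and the
#' row index, so regenerating a configuration yields identical data.
#'
#' @param scenario `"single_biopsy"`, `"multi_sample"` or `"all"`.
#' @param ccf_grid cross the single-biopsy rows with the CCF variance grid
#'   (default FALSE: one row per binary dataset, `ccf_variance` NA).
#' @param replicates number of replicate topologies (default 100, the full
#'   study design).
#' @param base_seed offset for the per-row seeds.
#' @return data.frame of benchmark configurations, one dataset per row.
#' @export
generate_benchmark_suite <- function(scenario = c("single_biopsy",
                                                  "multi_sample", "all"),
                                     ccf_grid = FALSE, replicates = 100,
                                     base_seed = 20100) {
  scenario <- match.arg(scenario)
  out <- list()
  if (scenario %in% c("single_biopsy", "all")) {
    sb <- expand.grid(replicate = seq_len(replicates),
                      logic = c("AND", "OR", "XOR"),
                      m = c(50L, 100L, 200L),
                      noise = c(0, 0.05, 0.10, 0.15, 0.20),
                      ccf_variance = if (ccf_grid)
                        c(0, 0.01, 0.05, 0.10, 0.20) else NA_real_,
                      stringsAsFactors = FALSE)
    sb <- data.frame(scenario = "single_biopsy", sb,
                     structure = NA_character_, tech = NA_character_,
                     noise_index = NA_integer_)
    out <- c(out, list(sb))
  }
  if (scenario %in% c("multi_sample", "all")) {
    ms <- rbind(
      expand.grid(replicate = seq_len(replicates),
                  structure = c("disjoint", "overlap5"),
                  tech = "bulk", m = c(10L, 20L), noise_index = 0:4,
                  stringsAsFactors = FALSE),
      expand.grid(replicate = seq_len(replicates),
                  structure = c("disjoint", "overlap5"),
                  tech = "single_cell", m = c(5L, 10L), noise_index = 0:4,
                  stringsAsFactors = FALSE))
    ms <- data.frame(scenario = "multi_sample", ms,
                     logic = NA_character_, noise = NA_real_,
                     ccf_variance = NA_real_)
    out <- c(out, list(ms))
  }
  cols <- c("scenario", "replicate", "logic", "m", "noise", "ccf_variance",
            "structure", "tech", "noise_index")
  grid <- do.call(rbind, lapply(out, function(x) x[, cols]))
  rownames(grid) <- NULL
  grid$seed <- base_seed + seq_len(nrow(grid))
  grid
}

#' Materialize one benchmark configuration
#'
#' Regenerates the dataset described by one row of
#' [generate_benchmark_suite()]; identical rows always yield bit-identical
#' data through the row's stored seed.
#'
#' @param cfg single-row data.frame from [generate_benchmark_suite()].
#' @return For single-biopsy rows the [sample_cumulative()] output (plus a
#'   `ccf` table when the row has a CCF variance); for multi-sample rows
#'   the [simulate_multisample()] output.
#' @export
materialize_config <- function(cfg) {
  stopifnot(nrow(cfg) == 1L)
  if (cfg$scenario == "single_biopsy") {
    dag <- random_dag(10, 0.4, seed = cfg$seed)
    gm <- generative_model(dag, logic = cfg$logic, seed = cfg$seed + 1L)
    out <- sample_cumulative(gm, m = cfg$m, noise = cfg$noise,
                             seed = cfg$seed + 2L)
    if (!is.na(cfg$ccf_variance))
      out$ccf <- simulate_ccf(out$data, gm, sigma2 = cfg$ccf_variance,
                              seed = cfg$seed + 3L)
    out
  } else {
    simulate_multisample(structure = cfg$structure, tech = cfg$tech,
                         n_patients = cfg$m,
                         noise_index = cfg$noise_index, seed = cfg$seed)
  }
}

#' Simulate survival outcomes with planted feature effects
#'
#' Support generator for the signature stage (not part of the benchmark
#' design): exponential event times with log-hazard linear in the given
#' binary features, independently exponentially censored.
#'
#' @param x binary patient x feature matrix with rownames.
#' @param beta named log-hazard coefficients (features absent from `beta`
#'   have no effect).
#' @param base_rate baseline hazard rate (default 0.1).
#' @param censor_rate independent censoring hazard (default 0.05).
#' @param seed optional seed.
#' @return A [survival_table()] over the patients of `x`.
#' @export
simulate_survival <- function(x, beta, base_rate = 0.1,
                              censor_rate = 0.05, seed = NULL) {
  x <- as.matrix(x)
  stopifnot(!is.null(rownames(x)))
  b <- setNames(rep(0, ncol(x)), colnames(x))
  b[names(beta)] <- beta
  lp <- drop(x %*% b)
  local_seed(seed, {
    t_event <- rexp(nrow(x), rate = base_rate * exp(lp))
    t_cens <- rexp(nrow(x), rate = censor_rate)
    survival_table(data.frame(patient_id = rownames(x),
                              time = pmin(t_event, t_cens),
                              event = as.integer(t_event <= t_cens)))
  })
}
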