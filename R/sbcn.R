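# Penalized-likelihood structure learning of the Suppes-Bayes causal
# network over the poset, with cross-validated arc confidence.

#' Search configuration for structure learning
#'
#' @param restarts number of random restarts of the hill climbing (>= 1;
#'   default 100).
#' @param score `"aic"` (default; penalty = number of free parameters) or
#'   `"bic"` (penalty = log(m)/2 per parameter).
#' @param seed optional seed making the search deterministic.
#' @param max_parents optional cap on the number of parents per node
#'   (default unlimited; conditional tables have 2^parents cells).
#' @return List of class `search_config`.
#' @export
search_config <- function(restarts = 100L, score = c("aic", "bic"),
                          seed = NULL, max_parents = Inf) {
  score <- match.arg(score)
  stopifnot(restarts >= 1)
  structure(list(restarts = as.integer(restarts), score = score,
                 seed = seed, max_parents = max_parents),
            class = "search_config")
}

# Memoized per-node family score: log-likelihood of the child column under
# MLE conditional Bernoulli tables minus the parameter penalty. Zero/one
# frequency estimates are floored at 1/(2m) to keep the log-likelihood
# finite. Families are keyed by (child index, parent-set bitmask) so cache
# lookups inside the hill climbing stay cheap; exact structure learning is
# anyway limited to the <= 16 genes the agony solver supports.
local_score_factory <- function(d, score = "aic") {
  m <- nrow(d)
  eps <- 1 / (2 * m)
  pen_mult <- if (score == "aic") 1 else log(m) / 2
  cache <- new.env(parent = emptyenv())
  dmat <- unclass(d)
  n <- ncol(dmat)
  bit <- 2^(seq_len(n) - 1)
  function(child_idx, mask) {
    key <- paste0(child_idx, "_", mask)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    y <- dmat[, child_idx]
    parents <- which(bitwAnd(mask, bit) > 0)
    k <- length(parents)
    if (k == 0L) {
      cfg <- rep(1L, m)
      ncfg <- 1L
    } else {
      cfg <- as.integer(dmat[, parents, drop = FALSE] %*%
                          2^(seq_len(k) - 1L)) + 1L
      ncfg <- 2L^k
    }
    tot <- tabulate(cfg, nbins = ncfg)
    n1 <- tabulate(cfg[y == 1L], nbins = ncfg)
    p <- pmin(pmax(n1 / pmax(tot, 1L), eps), 1 - eps)
    ll <- sum((n1 * log(p) + (tot - n1) * log(1 - p))[tot > 0L])
    val <- ll - pen_mult * ncfg
    cache[[key]] <- val
    val
  }
}

arcs_to_parents <- function(genes, arcs) {
  arcs <- as_arc_matrix(arcs)
  out <- setNames(vector("list", length(genes)), genes)
  for (g in genes) out[[g]] <- character(0)
  if (nrow(arcs) > 0L)
    for (i in seq_len(nrow(arcs)))
      out[[arcs[i, 2L]]] <- c(out[[arcs[i, 2L]]], arcs[i, 1L])
  out
}

arcs_to_masks <- function(genes, arcs) {
  arcs <- as_arc_matrix(arcs)
  fam <- integer(length(genes))
  if (nrow(arcs) > 0L) {
    p <- match(arcs[, 1L], genes)
    ch <- match(arcs[, 2L], genes)
    for (i in seq_along(p)) fam[ch[i]] <- bitwOr(fam[ch[i]],
                                                 bitwShiftL(1L, p[i] - 1L))
  }
  fam
}

#' Penalized log-likelihood score of a network
#'
#' Scores an acyclic arc set over the genes of `d`: the maximized Bernoulli
#' log-likelihood of every gene given its parents, minus the number of free
#' parameters (2^parents per gene; for `"bic"`, each parameter costs
#' log(m)/2 instead of 1). Higher is better. Conditional frequencies of 0
#' or 1 are floored at 1/(2m).
#'
#' @param d a [mutation_matrix()].
#' @param arcs two-column (parent, child) matrix or data.frame; must be
#'   acyclic.
#' @param score `"aic"` (default) or `"bic"`.
#' @return The network score (a single number, to be maximized).
#' @export
score_network <- function(d, arcs, score = c("aic", "bic")) {
  score <- match.arg(score)
  stopifnot(inherits(d, "mutation_matrix"))
  arcs <- as_arc_matrix(arcs)
  genes <- colnames(d)
  if (nrow(arcs) > 0L && !all(c(arcs) %in% genes))
    stop("arc endpoints outside the matrix genes")
  if (is.null(topo_sort(genes, arcs))) stop("arc set contains a cycle")
  ls_fun <- local_score_factory(d, score)
  fam <- arcs_to_masks(genes, arcs)
  sum(vapply(seq_along(genes), function(g) ls_fun(g, fam[g]), 0))
}

# deterministic comparison of two fitted arc sets at (almost) equal score:
# prefer higher score, then fewer arcs, then lexicographically smaller arcs
better_fit <- function(score_a, arcs_a, score_b, arcs_b, tol = 1e-9) {
  if (score_a > score_b + tol) return(TRUE)
  if (score_a < score_b - tol) return(FALSE)
  if (length(arcs_a) != length(arcs_b))
    return(length(arcs_a) < length(arcs_b))
  key_a <- paste(sort(arcs_a), collapse = ";")
  key_b <- paste(sort(arcs_b), collapse = ";")
  key_a < key_b
}

# hill climbing over subsets of a fixed candidate arc list with directions
# fixed, on (child index, parent bitmask) families; `acyclic_universe` is
# TRUE when every subset is guaranteed acyclic (poset candidates),
# otherwise add moves are rejected when they would close a directed cycle.
climb_arcs <- function(n_genes, cand_p, cand_c, include, ls_fun,
                       max_parents, acyclic_universe = TRUE) {
  na <- length(cand_p)
  pbit <- bitwShiftL(1L, cand_p - 1L)
  fam <- integer(n_genes)   # parent bitmask per child
  npar <- integer(n_genes)
  adj <- integer(n_genes)   # child bitmask per parent (for cycle checks)
  for (j in which(include)) {
    fam[cand_c[j]] <- bitwOr(fam[cand_c[j]], pbit[j])
    npar[cand_c[j]] <- npar[cand_c[j]] + 1L
    adj[cand_p[j]] <- bitwOr(adj[cand_p[j]],
                             bitwShiftL(1L, cand_c[j] - 1L))
  }
  cur <- vapply(seq_len(n_genes), function(g) ls_fun(g, fam[g]), 0)
  gbit <- bitwShiftL(1L, seq_len(n_genes) - 1L)
  reaches <- function(from, to) {
    target <- gbit[to]
    seen <- 0L
    frontier <- gbit[from]
    while (frontier != 0L) {
      if (bitwAnd(frontier, target) != 0L) return(TRUE)
      seen <- bitwOr(seen, frontier)
      nxt <- 0L
      for (u in which(bitwAnd(frontier, gbit) != 0L))
        nxt <- bitwOr(nxt, adj[u])
      frontier <- bitwAnd(nxt, bitwNot(seen))
    }
    FALSE
  }
  repeat {
    best_delta <- 1e-9
    best_j <- 0L
    for (j in seq_len(na)) {
      ci <- cand_c[j]
      adding <- !include[j]
      if (adding && npar[ci] + 1L > max_parents) next
      if (adding && !acyclic_universe && reaches(ci, cand_p[j])) next
      delta <- ls_fun(ci, bitwXor(fam[ci], pbit[j])) - cur[ci]
      if (delta > best_delta) {
        best_delta <- delta
        best_j <- j
      }
    }
    if (best_j == 0L) break
    ci <- cand_c[best_j]
    include[best_j] <- !include[best_j]
    fam[ci] <- bitwXor(fam[ci], pbit[best_j])
    npar[ci] <- npar[ci] + if (include[best_j]) 1L else -1L
    cbit <- bitwShiftL(1L, ci - 1L)
    adj[cand_p[best_j]] <- if (include[best_j])
      bitwOr(adj[cand_p[best_j]], cbit) else
        bitwAnd(adj[cand_p[best_j]], bitwNot(cbit))
    cur[ci] <- ls_fun(ci, fam[ci])
  }
  include
}

fit_node_params <- function(d, arcs) {
  genes <- colnames(d)
  m <- nrow(d)
  eps <- 1 / (2 * m)
  pa <- arcs_to_parents(genes, arcs)
  lapply(setNames(genes, genes), function(g) {
    parents <- pa[[g]]
    k <- length(parents)
    if (k == 0L) {
      cfg <- rep(1L, m); ncfg <- 1L
    } else {
      cfg <- as.integer(unclass(d)[, parents, drop = FALSE] %*%
                          2^(seq_len(k) - 1L)) + 1L
      ncfg <- 2L^k
    }
    tot <- tabulate(cfg, nbins = ncfg)
    n1 <- tabulate(cfg[unclass(d)[, g] == 1L], nbins = ncfg)
    prob <- pmin(pmax(n1 / pmax(tot, 1L), eps), 1 - eps)
    prob[tot == 0L] <- NA_real_
    list(parents = parents, prob = prob)
  })
}

#' Fit the Suppes-Bayes causal network by constrained hill climbing
#'
#' Maximizes the penalized log-likelihood ([score_network()]) over subsets
#' of the poset's arcs: single-arc additions and deletions from random
#' initial subsets (each poset arc included independently with probability
#' 1/2), keeping the best-scoring network across restarts. Arc directions
#' are fixed by the poset and the poset is acyclic, so every visited
#' network is a DAG. Ties across restarts break toward fewer arcs, then
#' lexicographically, making the fit deterministic given the seed.
#'
#' @param d a [mutation_matrix()].
#' @param poset an `evo_poset` from [build_poset()] (or any data.frame with
#'   acyclic `parent`, `child` columns).
#' @param config a [search_config()].
#' @return An [sbcn()] with fitted conditional tables; the network score is
#'   kept in the `score` attribute.
#' @export
fit_sbcn <- function(d, poset, config = search_config()) {
  stopifnot(inherits(d, "mutation_matrix"), inherits(config, "search_config"))
  genes <- colnames(d)
  cand_parent <- as.character(poset$parent)
  cand_child <- as.character(poset$child)
  na <- length(cand_parent)
  ls_fun <- local_score_factory(d, config$score)
  full_score <- function(include) {
    fam <- arcs_to_masks(genes, cbind(cand_parent[include],
                                      cand_child[include]))
    sum(vapply(seq_along(genes), function(g) ls_fun(g, fam[g]), 0))
  }
  if (na == 0L) {
    model <- sbcn(genes, node_params = fit_node_params(d, NULL))
    attr(model, "score") <- full_score(logical(0))
    return(model)
  }
  if (is.null(topo_sort(genes, cbind(cand_parent, cand_child))))
    stop("poset arcs must be acyclic")
  cand_p <- match(cand_parent, genes)
  cand_c <- match(cand_child, genes)
  local_seed(config$seed, {
    best_include <- NULL
    best_score <- -Inf
    for (r in seq_len(config$restarts)) {
      init <- if (r == 1L) rep(FALSE, na) else runif(na) < 0.5
      include <- climb_arcs(length(genes), cand_p, cand_c, init, ls_fun,
                            config$max_parents, acyclic_universe = TRUE)
      sc <- full_score(include)
      arcs_lab <- paste(cand_parent[include], cand_child[include],
                        sep = "->")
      if (is.null(best_include) ||
          better_fit(sc, arcs_lab, best_score,
                     paste(cand_parent[best_include],
                           cand_child[best_include], sep = "->"))) {
        best_include <- include
        best_score <- sc
      }
    }
    arcs <- data.frame(parent = cand_parent[best_include],
                       child = cand_child[best_include])
    model <- sbcn(genes, arcs = arcs,
                  node_params = fit_node_params(d, arcs))
    attr(model, "score") <- best_score
    model
  })
}

#' Unconstrained maximum-likelihood baseline
#'
#' The same hill-climbing search as [fit_sbcn()] but without the poset
#' constraint: every ordered gene pair is a candidate arc, and additions
#' that would close a directed cycle are rejected. Random restarts
#' initialize from a random DAG (random gene order, each forward pair
#' included with probability 1/2). Serves as the comparison baseline for
#' the constrained fit.
#'
#' @inheritParams fit_sbcn
#' @return An [sbcn()], with the score in the `score` attribute.
#' @export
baseline_ml_fit <- function(d, config = search_config()) {
  stopifnot(inherits(d, "mutation_matrix"), inherits(config, "search_config"))
  genes <- colnames(d)
  pairs <- expand.grid(parent = genes, child = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$parent != pairs$child, , drop = FALSE]
  cand_parent <- pairs$parent
  cand_child <- pairs$child
  na <- length(cand_parent)
  ls_fun <- local_score_factory(d, config$score)
  cand_p <- match(cand_parent, genes)
  cand_c <- match(cand_child, genes)
  full_score <- function(include) {
    fam <- arcs_to_masks(genes, cbind(cand_parent[include],
                                      cand_child[include]))
    sum(vapply(seq_along(genes), function(g) ls_fun(g, fam[g]), 0))
  }
  local_seed(config$seed, {
    best_include <- NULL
    best_score <- -Inf
    for (r in seq_len(config$restarts)) {
      if (r == 1L) {
        init <- rep(FALSE, na)
      } else {
        ord <- sample(genes)
        forward <- match(cand_parent, ord) < match(cand_child, ord)
        init <- forward & runif(na) < 0.5
      }
      include <- climb_arcs(length(genes), cand_p, cand_c, init, ls_fun,
                            config$max_parents, acyclic_universe = FALSE)
      sc <- full_score(include)
      arcs_lab <- paste(cand_parent[include], cand_child[include],
                        sep = "->")
      if (is.null(best_include) ||
          better_fit(sc, arcs_lab, best_score,
                     paste(cand_parent[best_include],
                           cand_child[best_include], sep = "->"))) {
        best_include <- include
        best_score <- sc
      }
    }
    arcs <- data.frame(parent = cand_parent[best_include],
                       child = cand_child[best_include])
    model <- sbcn(genes, arcs = arcs,
                  node_params = fit_node_params(d, arcs))
    attr(model, "score") <- best_score
    model
  })
}

#' Run the full trajectory-inference pipeline
#'
#' Convenience driver: per-patient DAGs (given directly or derived from a
#' CCF table) -> union graph -> minimum-agony ranking (optionally
#' bootstrap-stabilized) -> Suppes poset -> SBCN fit, optionally followed
#' by cross-validated arc confidence.
#'
#' @param d a [mutation_matrix()].
#' @param dags named list of [patient_dag()] objects (ignored when `ccf`
#'   is given).
#' @param ccf optional [ccf_table()]; per-patient DAGs are derived with
#'   [ccf_table_to_dags()].
#' @param epsilon CCF ordering tolerance.
#' @param weighting union-graph weighting, see [build_union_graph()].
#' @param bootstrap number of bootstrap ranking iterations (0 = single
#'   exact ranking; 100 reproduces the stabilized analysis settings).
#' @param config a [search_config()].
#' @param cv_reps repetitions of the cross-validation confidence step
#'   (0 = skip).
#' @param train_frac training fraction for cross-validation (default 0.8).
#' @param seed optional seed covering ranking bootstrap, fit and
#'   cross-validation.
#' @return List of class `evo_trajectories`: `model` (an [sbcn()]),
#'   `ranking`, `poset`, `union_graph`, `dags`.
#' @export
infer_trajectories <- function(d, dags = NULL, ccf = NULL, epsilon = 0,
                               weighting = c("multiplicity", "simple"),
                               bootstrap = 0, config = search_config(),
                               cv_reps = 0, train_frac = 0.8, seed = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(d, "mutation_matrix"))
  if (is.null(dags) && is.null(ccf))
    stop("either per-patient DAGs or a CCF table is required")
  local_seed(seed, {
    if (!is.null(ccf)) dags <- ccf_table_to_dags(ccf, epsilon = epsilon)
    g <- build_union_graph(dags, weighting = weighting)
    ranking <- if (bootstrap > 0) {
      if (!is.null(ccf))
        bootstrap_ranking(ccf, B = bootstrap, weighting = weighting,
                          epsilon = epsilon)
      else bootstrap_ranking(dags, B = bootstrap, weighting = weighting)
    } else min_agony_ranking(g)
    poset <- build_poset(d, dags, ranking)
    model <- fit_sbcn(d, poset, config)
    if (cv_reps > 0) {
      conf <- cross_validate_arcs(d, dags, reps = cv_reps,
                                  train_frac = train_frac,
                                  config = config, weighting = weighting)
      model <- attach_confidence(model, conf)
    }
    structure(list(model = model, ranking = ranking, poset = poset,
                   union_graph = g, dags = dags),
              class = "evo_trajectories")
  })
}

#' @export
print.evo_trajectories <- function(x, ...) {
  cat("evo_trajectories\n")
  print(x$ranking)
  print(x$model)
  invisible(x)
}

#' Cross-validated arc confidence
#'
#' Reruns the whole pipeline (ranking -> poset -> fit) on repeated random
#' patient-level training splits and scores each arc by the fraction of
#' repetitions whose fitted network contains it.
#'
#' @param d a [mutation_matrix()].
#' @param dags named list of [patient_dag()] objects.
#' @param reps number of repetitions (default 100).
#' @param train_frac training fraction per split (default 0.8).
#' @param config a [search_config()] used for each refit.
#' @param weighting union-graph weighting.
#' @param seed optional seed.
#' @return data.frame (parent, child, confidence) over every arc fitted in
#'   at least one repetition; confidences lie in \[0,1\].
#' @export
cross_validate_arcs <- function(d, dags, reps = 100, train_frac = 0.8,
                                config = search_config(),
                                weighting = c("multiplicity", "simple"),
                                seed = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(reps >= 1, train_frac > 0, train_frac < 1)
  ids <- vapply(dags, `[[`, "", "patient_id")
  names(dags) <- ids
  local_seed(seed, {
    counts <- new.env(parent = emptyenv())
    for (rep in seq_len(reps)) {
      train <- sample(rownames(d), size = max(2L, floor(train_frac * nrow(d))))
      d_tr <- mutation_matrix(unclass(d)[train, , drop = FALSE])
      dags_tr <- dags[intersect(train, ids)]
      if (length(dags_tr) == 0L) next
      g <- build_union_graph(dags_tr, weighting = weighting)
      ranking <- min_agony_ranking(g, canonical = FALSE)
      poset <- build_poset(d_tr, dags_tr, ranking)
      fit <- fit_sbcn(d_tr, poset, config)
      if (nrow(fit$arcs) > 0L)
        for (k in paste(fit$arcs$parent, fit$arcs$child, sep = "\r"))
          counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
    keys <- ls(counts)
    if (length(keys) == 0L)
      return(data.frame(parent = character(0), child = character(0),
                        confidence = numeric(0)))
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    out <- data.frame(parent = parts[, 1L], child = parts[, 2L],
                      confidence = vapply(keys, function(k)
                        counts[[k]] / reps, 0))
    rownames(out) <- NULL
    out[order(out$parent, out$child), ]
  })
}

#' Attach cross-validation confidences to a fitted model
#'
#' @param model an [sbcn()].
#' @param conf data.frame (parent, child, confidence) as returned by
#'   [cross_validate_arcs()]; arcs of the model absent from `conf` get
#'   confidence 0.
#' @return The model with its `confidence` column filled in.
#' @export
attach_confidence <- function(model, conf) {
  stopifnot(inherits(model, "sbcn"))
  if (nrow(model$arcs) == 0L) return(model)
  key <- paste(model$arcs$parent, model$arcs$child, sep = "\r")
  ckey <- paste(conf$parent, conf$child, sep = "\r")
  hit <- match(key, ckey)
  model$arcs$confidence <- ifelse(is.na(hit), 0, conf$confidence[hit])
  model
}
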