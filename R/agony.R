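# Minimum-agony ranking of the union graph and ranking-based arc pruning.

#' Agony of a single arc under an integer ranking
#'
#' An arc u -> v pointing from rank `rank_u` to rank `rank_v` incurs agony
#' `max(0, rank_u - rank_v + 1)`: forward arcs (strictly increasing rank)
#' are free, ties cost 1 and backward arcs cost their rank gap plus one.
#'
#' @param rank_u,rank_v non-negative integer ranks (vectorized).
#' @return Non-negative integer agony.
#' @examples
#' arc_agony(1, 3)  # 0: forward
#' arc_agony(2, 2)  # 1: tie
#' arc_agony(3, 1)  # 3: backward
#' @export
arc_agony <- function(rank_u, rank_v) {
  stopifnot(all(rank_u >= 0), all(rank_v >= 0))
  pmax(0L, as.integer(rank_u) - as.integer(rank_v) + 1L)
}

# Total weighted agony of a union graph under a rank map (root arcs always
# rank 0 -> >=1, hence free, but are included for completeness).
agony_of_ranking <- function(g, rank) {
  stopifnot(inherits(g, "union_graph"))
  arcs <- g$arcs
  sum(arcs$multiplicity *
        arc_agony(rank[arcs$parent], rank[arcs$child]))
}

#' Exact minimum-agony ranking of a union graph
#'
#' Assigns the dummy root rank 0 and every gene an integer rank in 1..n so
#' that the total multiplicity-weighted agony of the graph's arcs is
#' minimal. The solver is an exact dynamic program over level sets
#' (exponential in n, exact for the n <= 15 driver panels this tool
#' targets); for an acyclic input the minimum is 0. With
#' `canonical = TRUE` the lexicographically smallest co-optimal rank vector
#' (in the graph's gene order) is returned, making the ranking invariant
#' under gene relabeling.
#'
#' @param g a `union_graph` from [build_union_graph()].
#' @param canonical return the lexicographically smallest co-optimal rank
#'   vector (default TRUE; FALSE skips the refinement and returns the DP's
#'   deterministic reconstruction, which is faster inside resampling loops).
#' @return Object of class `agony_ranking`: list with `rank` (named integer
#'   vector over root and genes, root = 0) and `total_agony`.
#' @export
min_agony_ranking <- function(g, canonical = TRUE) {
  stopifnot(inherits(g, "union_graph"))
  genes <- g$genes
  n <- length(genes)
  if (n > 16L)
    stop("exact agony ranking supports at most 16 genes (driver panels ",
         "in this framework are capped at 15)")
  arcs <- g$arcs[g$arcs$parent != g$root, , drop = FALSE]
  # self-loops contribute a constant (agony 1 each) independent of ranks
  self <- arcs$parent == arcs$child
  const <- sum(arcs$multiplicity[self])
  arcs <- arcs[!self, , drop = FALSE]
  u <- match(arcs$parent, genes) - 1L
  v <- match(arcs$child, genes) - 1L
  w <- as.numeric(arcs$multiplicity)
  lo <- rep(1L, n); hi <- rep(n, n)
  sol <- agony_dp(u, v, w, n, lo, hi)
  level <- sol$level
  if (canonical && n > 1L) {
    # greedy lexicographic refinement: fix each gene, in order, at the
    # smallest rank that still admits an optimal completion
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        lo_i <- lo; hi_i <- hi
        lo_i[i] <- k; hi_i[i] <- k
        trial <- agony_dp(u, v, w, n, lo_i, hi_i)
        if (is.finite(trial$total) && trial$total <= sol$total + 1e-9) {
          lo <- lo_i; hi <- hi_i
          level <- trial$level
          break
        }
      }
    }
  }
  rank <- setNames(c(0L, as.integer(level)), c(g$root, genes))
  structure(list(rank = rank, total_agony = sol$total + const),
            class = "agony_ranking")
}

#' @export
print.agony_ranking <- function(x, ...) {
  genes <- setdiff(names(x$rank), root_label())
  cat(sprintf("agony_ranking: %d genes, total agony %g\n",
              length(genes), x$total_agony))
  ord <- genes[order(x$rank[genes], genes)]
  cat(paste(sprintf("  %s: %d", ord, x$rank[ord]), collapse = "\n"), "\n")
  invisible(x)
}

#' Prune arcs inconsistent with a ranking
#'
#' Keeps exactly the gene-gene arcs with `rank(parent) < rank(child)` (the
#' agony-free arcs); backward and tied arcs are removed. The result is
#' acyclic by construction.
#'
#' @param g a `union_graph`.
#' @param ranking an `agony_ranking` covering the graph's genes.
#' @return data.frame (parent, child, multiplicity) of the retained arcs.
#' @export
prune_inconsistent_arcs <- function(g, ranking) {
  stopifnot(inherits(g, "union_graph"), inherits(ranking, "agony_ranking"))
  arcs <- g$arcs[g$arcs$parent != g$root, , drop = FALSE]
  if (!all(c(arcs$parent, arcs$child) %in% names(ranking$rank)))
    stop("ranking does not cover all genes in the graph")
  keep <- ranking$rank[arcs$parent] < ranking$rank[arcs$child]
  out <- arcs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bootstrap-stabilized consensus ranking
#'
#' Repeats the ranking under resampling and returns the per-gene rounded
#' mean rank. Two input modes: a list of patient DAGs (patients are
#' resampled with replacement, the multi-sample track) or a [ccf_table()]
#' with read counts (per-record CCFs are redrawn by [resample_ccf()], the
#' single-biopsy track). The consensus total agony is evaluated on the
#' full-data union graph.
#'
#' @param x list of [patient_dag()] objects, or a [ccf_table()].
#' @param B number of bootstrap iterations (default 100).
#' @param seed optional seed; the consensus is deterministic given the seed.
#' @param weighting union-graph weighting, see [build_union_graph()].
#' @param epsilon CCF ordering tolerance (CCF mode only).
#' @return An `agony_ranking` with the rounded mean rank per gene; the
#'   number of iterations is kept in the `B` attribute.
#' @export
bootstrap_ranking <- function(x, B = 100, seed = NULL,
                              weighting = c("multiplicity", "simple"),
                              epsilon = 0) {
  weighting <- match.arg(weighting)
  stopifnot(B >= 1)
  ccf_mode <- inherits(x, "ccf_table")
  full_dags <- if (ccf_mode) ccf_table_to_dags(x, epsilon = epsilon) else x
  full_graph <- build_union_graph(full_dags, weighting = weighting)
  genes <- full_graph$genes
  local_seed(seed, {
    ranks <- matrix(NA_real_, B, length(genes),
                    dimnames = list(NULL, genes))
    for (b in seq_len(B)) {
      if (ccf_mode) {
        tab <- x
        depth_ok <- !is.na(tab$alt_reads) & !is.na(tab$ref_reads) &
          (tab$alt_reads + tab$ref_reads) > 0
        cn <- ifelse(is.na(tab$cn_factor), 1, tab$cn_factor)
        new_ccf <- ccf_values(tab)
        if (any(depth_ok))
          new_ccf[depth_ok] <- clamp01(
            rbeta(sum(depth_ok), tab$alt_reads[depth_ok] + 1,
                  tab$ref_reads[depth_ok] + 1) * cn[depth_ok])
        tab$ccf <- new_ccf
        dags <- ccf_table_to_dags(tab, epsilon = epsilon)
      } else {
        dags <- x[sample.int(length(x), replace = TRUE)]
      }
      g_b <- build_union_graph(dags, weighting = weighting)
      r_b <- min_agony_ranking(g_b, canonical = FALSE)
      present <- intersect(genes, g_b$genes)
      ranks[b, present] <- r_b$rank[present]
    }
    mean_rank <- round(colMeans(ranks, na.rm = TRUE))
    mean_rank[is.nan(mean_rank)] <- 1  # gene never resampled: earliest level
    rank <- setNames(c(0L, as.integer(mean_rank)),
                     c(full_graph$root, genes))
    out <- structure(list(rank = rank,
                          total_agony = agony_of_ranking(full_graph, rank)),
                     class = "agony_ranking")
    attr(out, "B") <- B
    out
  })
}
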