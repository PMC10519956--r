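# Suppes probabilistic-causation conditions: temporal priority and the
# extended probability-raising condition, evaluated per ordered gene pair,
# and the resulting poset that constrains structure learning.

#' Temporal priority between two ranked genes
#'
#' @param ranking an `agony_ranking`.
#' @param u,v gene symbols.
#' @return TRUE iff `rank(u) < rank(v)` (equal ranks fail the condition).
#' @export
temporal_priority <- function(ranking, u, v) {
  stopifnot(inherits(ranking, "agony_ranking"))
  if (!all(c(u, v) %in% names(ranking$rank)))
    stop("unknown gene: ", paste(setdiff(c(u, v), names(ranking$rank)),
                                 collapse = ", "))
  unname(ranking$rank[u] < ranking$rank[v])
}

# transitive closures of a list of patient DAGs, keyed by patient id
dag_closures <- function(dags) {
  lapply(dags, function(pd) reach_matrix(pd$nodes, pd$arcs))
}

#' Probability-raising condition for an ordered gene pair
#'
#' Estimates the extended probability-raising condition on the subset of
#' patients where both events are observed: `p_precede`, the fraction of
#' co-mutated patients whose temporal DAG contains a directed path
#' u -> ... -> v (co-mutated patients with incomparable u, v count in the
#' denominator only), against `p_u_not_v`, the cohort fraction of patients
#' carrying u without v. The condition holds when
#' `p_precede > p_u_not_v` and at least one co-occurrence was observed.
#'
#' @param d a [mutation_matrix()].
#' @param dags list of [patient_dag()] objects named (or ordered) by the
#'   patients of `d`; patients absent from `dags` contribute to marginal
#'   frequencies but provide no ordering evidence.
#' @param u,v gene symbols (columns of `d`).
#' @param smoothing add-one smoothing of both estimates for tiny cohorts
#'   (default FALSE: raw frequencies).
#' @param closures optional precomputed list of per-patient transitive
#'   closures (internal reuse across pairs).
#' @return List of class `pr_estimate`: `u`, `v`, `p_precede`, `p_u_not_v`,
#'   `n_cooccur`, `holds`, `undefined` (TRUE when the pair never co-occurs).
#' @export
probability_raising <- function(d, dags, u, v, smoothing = FALSE,
                                closures = NULL) {
  stopifnot(inherits(d, "mutation_matrix"))
  if (!all(c(u, v) %in% colnames(d)))
    stop("unknown gene: ", paste(setdiff(c(u, v), colnames(d)),
                                 collapse = ", "))
  if (is.null(closures)) closures <- dag_closures(dags)
  ids <- vapply(dags, `[[`, "", "patient_id")
  names(closures) <- ids
  m <- nrow(d)
  both <- rownames(d)[d[, u] == 1L & d[, v] == 1L]
  n_cooccur <- length(both)
  n_precede <- 0L
  for (p in both) {
    cl <- closures[[p]]
    if (!is.null(cl) && u %in% rownames(cl) && v %in% colnames(cl) &&
        cl[u, v])
      n_precede <- n_precede + 1L
  }
  n_u_not_v <- sum(d[, u] == 1L & d[, v] == 0L)
  if (smoothing) {
    p_precede <- (n_precede + 1) / (n_cooccur + 2)
    p_u_not_v <- (n_u_not_v + 1) / (m + 2)
  } else {
    p_precede <- if (n_cooccur > 0L) n_precede / n_cooccur else NA_real_
    p_u_not_v <- n_u_not_v / m
  }
  undefined <- n_cooccur == 0L
  holds <- !undefined && isTRUE(p_precede > p_u_not_v)
  structure(list(u = u, v = v, p_precede = p_precede,
                 p_u_not_v = p_u_not_v, n_cooccur = n_cooccur,
                 holds = holds, undefined = undefined),
            class = "pr_estimate")
}

#' Build the Suppes poset constraining structure learning
#'
#' Evaluates, for every ordered gene pair, temporal priority under the
#' agony ranking and the probability-raising condition, and returns the
#' pairs satisfying both. All retained pairs are ranking-consistent, so the
#' poset is acyclic by construction and antisymmetric (at most one of
#' (u,v), (v,u) can have `rank(u) < rank(v)`).
#'
#' @param d a [mutation_matrix()].
#' @param dags list of [patient_dag()] objects.
#' @param ranking an `agony_ranking` over the genes of `d`.
#' @param smoothing see [probability_raising()].
#' @return data.frame of class `evo_poset` with columns `parent`, `child`,
#'   `p_precede`, `p_u_not_v`, `n_cooccur`; the gene universe is kept in
#'   the `genes` attribute.
#' @export
build_poset <- function(d, dags, ranking, smoothing = FALSE) {
  stopifnot(inherits(d, "mutation_matrix"), inherits(ranking, "agony_ranking"))
  genes <- colnames(d)
  ranked <- intersect(genes, names(ranking$rank))
  closures <- dag_closures(dags)
  rows <- list()
  for (u in ranked) for (v in ranked) {
    if (u == v || !(ranking$rank[u] < ranking$rank[v])) next
    pr <- probability_raising(d, dags, u, v, smoothing = smoothing,
                              closures = closures)
    if (pr$holds)
      rows[[length(rows) + 1L]] <-
        data.frame(parent = u, child = v, p_precede = pr$p_precede,
                   p_u_not_v = pr$p_u_not_v, n_cooccur = pr$n_cooccur)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(parent = character(0), child = character(0),
               p_precede = numeric(0), p_u_not_v = numeric(0),
               n_cooccur = integer(0))
  rownames(out) <- NULL
  attr(out, "genes") <- genes
  class(out) <- c("evo_poset", "data.frame")
  out
}

#' Probability raising via the order-conditioned formulation
#'
#' The probability-raising condition can equivalently be stated by
#' conditioning the joint occurrence on the temporal order,
#' `P(u,v | t_u < t_v) > P(u,v | t_u >= t_v)`, instead of conditioning the
#' order on the joint occurrence as [probability_raising()] does. This
#' estimator realizes the order-conditioned form on observable data under
#' the convention that an unobserved event lies at infinite time: patients
#' carrying u without v are `t_u < t_v` observations, patients carrying v
#' without u (or neither) are `t_u >= t_v` observations, and co-mutated
#' patients are split by the directed path in their temporal DAG
#' (incomparable co-mutations, which carry no order information, are
#' dropped from both sides). See the methods vignette for the exact
#' relationship between the two decision rules.
#'
#' @inheritParams probability_raising
#' @return List with the two conditional estimates (`p_given_before`,
#'   `p_given_after`), the decision `holds`, and `estimable` (FALSE when
#'   either conditioning event has no observations).
#' @export
probability_raising_ordered <- function(d, dags, u, v, closures = NULL) {
  stopifnot(inherits(d, "mutation_matrix"))
  if (is.null(closures)) closures <- dag_closures(dags)
  ids <- vapply(dags, `[[`, "", "patient_id")
  names(closures) <- ids
  du <- d[, u] == 1L; dv <- d[, v] == 1L
  n_u_first <- 0L; n_v_first <- 0L
  for (p in rownames(d)[du & dv]) {
    cl <- closures[[p]]
    if (is.null(cl) || !(u %in% rownames(cl)) || !(v %in% rownames(cl)))
      next
    if (cl[u, v]) n_u_first <- n_u_first + 1L
    else if (cl[v, u]) n_v_first <- n_v_first + 1L
  }
  n_before <- n_u_first + sum(du & !dv)              # t_u < t_v
  n_after <- n_v_first + sum(!du & dv) + sum(!du & !dv)  # t_u >= t_v
  estimable <- n_before > 0L && n_after > 0L
  p_before <- if (n_before > 0L) n_u_first / n_before else NA_real_
  p_after <- if (n_after > 0L) n_v_first / n_after else NA_real_
  list(u = u, v = v, p_given_before = p_before, p_given_after = p_after,
       holds = estimable && isTRUE(p_before > p_after),
       estimable = estimable)
}
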