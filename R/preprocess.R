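# Building per-patient temporal DAGs and the cross-patient union graph.

#' Order one patient's mutations by cancer cell fraction
#'
#' Under clonal expansion a mutation carried by a larger fraction of tumor
#' cells was, in expectation, acquired earlier. The patient's mutations are
#' therefore partially ordered: an arc g -> h is drawn when
#' `ccf[g] > ccf[h] + epsilon`, and the transitive reduction of that
#' (transitively closed) relation is returned, so each gene points only to
#' its immediate successors. With `epsilon = 0` and all-distinct CCFs the
#' result is a chain.
#'
#' @param ccf named numeric vector of CCFs in \[0,1\], one entry per mutated
#'   gene.
#' @param epsilon non-negative separation below which two CCFs are treated
#'   as unordered (default 0, i.e. strict ordering).
#' @param patient_id identifier for the resulting DAG.
#' @return A [patient_dag()].
#' @examples
#' ccf_to_patient_dag(c(TP53 = 0.8, KRAS = 0.5, STK11 = 0.5), epsilon = 0.01)
#' @export
ccf_to_patient_dag <- function(ccf, epsilon = 0, patient_id = "patient") {
  stopifnot(is.numeric(ccf), !is.null(names(ccf)), epsilon >= 0)
  if (anyNA(ccf) || any(ccf < 0 | ccf > 1))
    stop("all ccf values must lie in [0,1]")
  genes <- names(ccf)
  n <- length(genes)
  if (n <= 1L) return(patient_dag(patient_id, nodes = genes))
  gt <- outer(ccf, ccf, function(a, b) a > b + epsilon)  # transitively closed
  # transitive reduction: drop u->v when some w has u->w->v
  keep <- gt & !(gt %*% gt > 0)
  idx <- which(keep, arr.ind = TRUE)
  patient_dag(patient_id, nodes = genes,
              arcs = cbind(genes[idx[, 1L]], genes[idx[, 2L]]))
}

#' Resample a cancer cell fraction from read counts
#'
#' Draws the variant allele fraction from Beta(alt + 1, ref + 1) (the
#' posterior under a uniform prior) and rescales it by the copy-number
#' factor, clamping to \[0,1\]. Used to propagate read-count uncertainty into
#' bootstrap rankings.
#'
#' @param alt_reads,ref_reads non-negative read counts, `alt + ref > 0`.
#' @param cn_factor positive copy-number normalization factor (total copy
#'   number relative to normal ploidy; 1 for a diploid locus).
#' @param n number of draws.
#' @param seed optional seed for a reproducible draw.
#' @return Numeric vector of `n` CCF draws in \[0,1\].
#' @export
resample_ccf <- function(alt_reads, ref_reads, cn_factor = 1, n = 1,
                         seed = NULL) {
  stopifnot(alt_reads >= 0, ref_reads >= 0, cn_factor > 0)
  if (alt_reads + ref_reads <= 0)
    stop("read depth must be positive to resample a ccf")
  local_seed(seed,
             clamp01(rbeta(n, alt_reads + 1, ref_reads + 1) * cn_factor))
}

# Per-patient CCF maps from a ccf_table; missing ccf entries are derived
# from read counts: clamp(alt/(alt+ref) * cn_factor, 0, 1).
ccf_values <- function(tab) {
  stopifnot(inherits(tab, "ccf_table"))
  ccf <- tab$ccf
  miss <- is.na(ccf)
  if (any(miss)) {
    cn <- ifelse(is.na(tab$cn_factor[miss]), 1, tab$cn_factor[miss])
    ccf[miss] <- clamp01(tab$alt_reads[miss] /
                           (tab$alt_reads[miss] + tab$ref_reads[miss]) * cn)
  }
  ccf
}

#' Build per-patient DAGs from a CCF table
#'
#' Applies [ccf_to_patient_dag()] to every patient in a long-format CCF
#' table. Records without a stated CCF use the read-count estimate
#' `clamp(alt / (alt + ref) * cn_factor, 0, 1)`.
#'
#' @param tab a [ccf_table()].
#' @param epsilon ordering tolerance, see [ccf_to_patient_dag()].
#' @return Named list of [patient_dag()] objects.
#' @export
ccf_table_to_dags <- function(tab, epsilon = 0) {
  stopifnot(inherits(tab, "ccf_table"))
  vals <- ccf_values(tab)
  ids <- unique(tab$patient_id)
  out <- lapply(ids, function(p) {
    sel <- tab$patient_id == p
    ccf_to_patient_dag(setNames(vals[sel], tab$gene[sel]),
                       epsilon = epsilon, patient_id = p)
  })
  names(out) <- ids
  out
}

#' Infer a patient's mutational tree from multi-sample genotypes
#'
#' Maximum-weight spanning arborescence over the patient's observed genes,
#' rooted at an implicit wild-type root. A candidate arc u -> v is admitted
#' only when the marginal frequency across samples satisfies f(u) >= f(v)
#' (equal frequencies are oriented lexicographically and flagged), and is
#' weighted by the joint frequency f(u, v). Because the admissible arcs
#' respect a fixed order on the genes, the optimal arborescence is obtained
#' by choosing, independently for each gene, the admissible parent of
#' maximal joint frequency; genes with no co-occurring admissible parent
#' attach to the root. Ties on joint frequency prefer the parent of smaller
#' marginal frequency (the most proximate ancestor under a cumulative
#' model), then the lexicographically smaller symbol.
#'
#' @param sg a [sample_genotypes()].
#' @return A [patient_dag()] over the genes observed in at least one sample
#'   (root arcs are implicit and omitted). Pairs of genes with identical
#'   sample sets are recorded in the `tie_pairs` attribute.
#' @export
infer_patient_tree <- function(sg) {
  stopifnot(inherits(sg, "sample_genotypes"))
  g <- sg$genotypes
  f <- colMeans(g)
  observed <- names(f)[f > 0]
  if (length(observed) == 0L)
    return(patient_dag(sg$patient_id, nodes = character(0)))
  f <- f[observed]
  g <- g[, observed, drop = FALSE]
  # deterministic frequency order: decreasing marginal, ties lexicographic
  ord <- observed[order(-f[observed], observed)]
  joint <- crossprod(g) / nrow(g)
  ties <- NULL
  arcs <- NULL
  for (j in seq_along(ord)) {
    v <- ord[j]
    if (j == 1L) next  # highest-frequency gene attaches to the root
    cand <- ord[seq_len(j - 1L)]
    w <- joint[cand, v]
    tied <- cand[f[cand] == f[v]]
    if (length(tied) > 0L)
      ties <- rbind(ties, cbind(tied, v))
    if (max(w) <= 0) next  # no co-occurring admissible parent: root arc
    best <- cand[w == max(w)]
    if (length(best) > 1L) best <- best[order(f[best], best)]
    arcs <- rbind(arcs, c(best[1L], v))
  }
  pd <- patient_dag(sg$patient_id, nodes = observed, arcs = arcs)
  attr(pd, "tie_pairs") <- ties
  pd
}

#' Build the weighted union graph of per-patient DAGs
#'
#' The union of all per-patient temporal arcs over the union of their gene
#' sets, augmented with a dummy root node with an outgoing arc to every gene
#' (the wild-type genotype). The union may contain cycles: disagreeing
#' patients are exactly what the agony ranking later resolves. With
#' `weighting = "multiplicity"` each arc carries the number of patients
#' supporting it; `"simple"` reproduces the plain unweighted union.
#'
#' @param dags non-empty list of [patient_dag()] objects.
#' @param weighting `"multiplicity"` (default) or `"simple"`.
#' @return A `union_graph` object.
#' @export
build_union_graph <- function(dags, weighting = c("multiplicity", "simple")) {
  weighting <- match.arg(weighting)
  stopifnot(length(dags) > 0L)
  genes <- sort(unique(unlist(lapply(dags, `[[`, "nodes"))))
  all_arcs <- do.call(rbind, lapply(dags, `[[`, "arcs"))
  if (is.null(all_arcs)) all_arcs <- matrix(character(0), 0L, 2L)
  if (nrow(all_arcs) > 0L) {
    key <- arc_keys(all_arcs)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    gene_arcs <- data.frame(parent = parts[, 1L], child = parts[, 2L],
                            multiplicity = if (weighting == "multiplicity")
                              as.numeric(tab) else 1)
  } else {
    gene_arcs <- data.frame(parent = character(0), child = character(0),
                            multiplicity = numeric(0))
  }
  root_arcs <- data.frame(parent = root_label(), child = genes,
                          multiplicity = 1)
  arcs <- rbind(root_arcs, gene_arcs)
  rownames(arcs) <- NULL
  new_union_graph(genes, arcs)
}
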