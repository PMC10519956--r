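#' Root label of union graphs
#'
#' Union graphs are augmented with a dummy root node representing the wild
#' type genotype; it has an outgoing arc to every gene and no incoming arcs.
#' Gene symbols are opaque case-sensitive strings, so the root uses a
#' reserved label that cannot be used as a gene symbol.
#'
#' @return The reserved root label, a single string.
#' @export
root_label <- function() ".ROOT"

#' Binary patient-by-gene mutation matrix
#'
#' Constructs the cross-sectional input: an m x n binary matrix with one row
#' per patient and one column per candidate driver gene, entry 1 when the
#' alteration was observed in that patient.
#'
#' @param values matrix coercible to integer 0/1, m x n.
#' @param patients character vector of m unique patient identifiers
#'   (defaults to existing rownames).
#' @param genes character vector of n unique gene symbols (defaults to
#'   existing colnames).
#' @return An integer matrix of class `mutation_matrix` with patients as
#'   rownames and genes as colnames.
#' @examples
#' d <- mutation_matrix(rbind(c(1, 0), c(1, 1)),
#'                      patients = c("p1", "p2"), genes = c("TP53", "KRAS"))
#' @export
mutation_matrix <- function(values, patients = rownames(values),
                            genes = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("mutation matrix must have at least one patient and one gene")
  if (is.null(patients) || is.null(genes))
    stop("patient and gene identifiers are required")
  patients <- as.character(patients); genes <- as.character(genes)
  if (anyDuplicated(patients)) stop("duplicate patient identifiers")
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  if (root_label() %in% genes)
    stop("gene symbol collides with the reserved root label")
  if (length(patients) != nrow(values) || length(genes) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  storage.mode(values) <- "integer"
  if (anyNA(values) || !all(values %in% c(0L, 1L)))
    stop("mutation matrix entries must all be 0 or 1")
  dimnames(values) <- list(patients, genes)
  class(values) <- c("mutation_matrix", class(values))
  values
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d patients x %d genes (%.1f%% mutated)\n",
              nrow(x), ncol(x), 100 * mean(x)))
  invisible(x)
}

#' Per-patient temporal DAG
#'
#' Represents the estimated temporal ordering of the alterations observed in
#' one patient: nodes are that patient's mutated genes and a directed arc
#' means the parent likely occurred earlier during tumor evolution (e.g. as
#' read off a mutational tree or a CCF ordering).
#'
#' @param patient_id single patient identifier.
#' @param nodes character vector of observed gene symbols.
#' @param arcs two-column character matrix (parent, child); may have zero
#'   rows for patients without ordering information.
#' @return Object of class `patient_dag`.
#' @export
patient_dag <- function(patient_id, nodes, arcs = NULL) {
  arcs <- as_arc_matrix(arcs)
  nodes <- unique(as.character(nodes))
  if (root_label() %in% nodes)
    stop("gene symbol collides with the reserved root label")
  if (nrow(arcs) > 0L) {
    missing <- setdiff(c(arcs[, 1L], arcs[, 2L]), nodes)
    if (length(missing) > 0L)
      stop(sprintf("arc endpoints not in node set for patient %s: %s",
                   patient_id, paste(missing, collapse = ", ")))
    if (any(arcs[, 1L] == arcs[, 2L]) || is.null(topo_sort(nodes, arcs)))
      stop(sprintf("cycle in %s", patient_id))
    arcs <- unique(arcs)
  }
  structure(list(patient_id = as.character(patient_id), nodes = nodes,
                 arcs = arcs),
            class = "patient_dag")
}

#' @export
print.patient_dag <- function(x, ...) {
  cat(sprintf("patient_dag %s: %d genes, %d arcs\n",
              x$patient_id, length(x$nodes), nrow(x$arcs)))
  invisible(x)
}

new_union_graph <- function(genes, arcs) {
  stopifnot(is.data.frame(arcs),
            all(c("parent", "child", "multiplicity") %in% names(arcs)))
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene symbols in union graph")
  root <- root_label()
  if (any(arcs$child == root)) stop("root must have no incoming arcs")
  if (!all(genes %in% arcs$child[arcs$parent == root]))
    stop("root must have an outgoing arc to every gene")
  if (any(arcs$multiplicity < 1)) stop("arc multiplicities must be >= 1")
  structure(list(genes = genes, root = root,
                 arcs = arcs[, c("parent", "child", "multiplicity")]),
            class = "union_graph")
}

#' @export
print.union_graph <- function(x, ...) {
  gene_arcs <- x$arcs[x$arcs$parent != x$root, , drop = FALSE]
  cat(sprintf("union_graph: %d genes, %d gene-gene arcs (total weight %g)\n",
              length(x$genes), nrow(gene_arcs), sum(gene_arcs$multiplicity)))
  invisible(x)
}

#' Cancer-cell-fraction table
#'
#' Long-format table of per-patient, per-gene cancer cell fractions. The CCF
#' may be given directly, or left NA and derived from variant read counts
#' normalized by a copy-number factor (total copies relative to normal
#' ploidy): ccf = clamp(alt / (alt + ref) * cn_factor, 0, 1).
#'
#' @param df data.frame with columns `patient_id`, `gene`, `alt_reads`,
#'   `ref_reads`, `cn_factor`, `ccf` (NA entries of `ccf` allowed when the
#'   read depth is positive).
#' @return Validated data.frame of class `ccf_table`.
#' @export
ccf_table <- function(df) {
  req <- c("patient_id", "gene", "alt_reads", "ref_reads", "cn_factor", "ccf")
  if (!all(req %in% names(df)))
    stop("ccf table must have columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df)[, req]
  df$patient_id <- as.character(df$patient_id)
  df$gene <- as.character(df$gene)
  key <- paste(df$patient_id, df$gene, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L)
    stop(sprintf("duplicate (patient, gene) record: (%s, %s)",
                 df$patient_id[dup[1L]], df$gene[dup[1L]]))
  bad <- which(!is.na(df$alt_reads) & df$alt_reads < 0 |
               !is.na(df$ref_reads) & df$ref_reads < 0)
  if (length(bad) > 0L)
    stop(sprintf("negative read count for (%s, %s)",
                 df$patient_id[bad[1L]], df$gene[bad[1L]]))
  bad <- which(!is.na(df$cn_factor) & df$cn_factor <= 0)
  if (length(bad) > 0L)
    stop(sprintf("non-positive copy-number factor for (%s, %s)",
                 df$patient_id[bad[1L]], df$gene[bad[1L]]))
  bad <- which(!is.na(df$ccf) & (df$ccf < 0 | df$ccf > 1))
  if (length(bad) > 0L)
    stop(sprintf("ccf outside [0,1] for (%s, %s)",
                 df$patient_id[bad[1L]], df$gene[bad[1L]]))
  no_ccf <- is.na(df$ccf)
  depth <- ifelse(is.na(df$alt_reads), 0, df$alt_reads) +
    ifelse(is.na(df$ref_reads), 0, df$ref_reads)
  bad <- which(no_ccf & depth <= 0)
  if (length(bad) > 0L)
    stop(sprintf("record (%s, %s) has neither a ccf nor positive read depth",
                 df$patient_id[bad[1L]], df$gene[bad[1L]]))
  rownames(df) <- NULL
  class(df) <- c("ccf_table", "data.frame")
  df
}

#' Survival table
#'
#' @param df data.frame with columns `patient_id`, `time` (non-negative,
#'   finite) and `event` (1 = event observed, 0 = censored).
#' @return Validated data.frame of class `survival_table`.
#' @export
survival_table <- function(df) {
  req <- c("patient_id", "time", "event")
  if (!all(req %in% names(df)))
    stop("survival table must have columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df)[, req]
  df$patient_id <- as.character(df$patient_id)
  dup <- which(duplicated(df$patient_id))
  if (length(dup) > 0L)
    stop("duplicate patient identifier: ", df$patient_id[dup[1L]])
  bad <- which(!is.finite(df$time) | df$time < 0)
  if (length(bad) > 0L)
    stop("invalid survival time for patient ", df$patient_id[bad[1L]])
  bad <- which(!(df$event %in% c(0, 1)))
  if (length(bad) > 0L)
    stop("event status must be 0 or 1 for patient ", df$patient_id[bad[1L]])
  rownames(df) <- NULL
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Suppes-Bayes causal network
#'
#' The fitted model: an acyclic set of gene-gene arcs (the repeated
#' evolutionary trajectories), an optional cross-validation confidence per
#' arc, and per-gene conditional Bernoulli tables (probability of the gene
#' being mutated for each parent configuration).
#'
#' @param genes character vector of gene symbols in the model.
#' @param arcs data.frame with columns `parent`, `child` and optionally
#'   `confidence` in \[0,1\] (defaults to NA).
#' @param node_params named list, one entry per gene, each a list with
#'   elements `parents` (character) and `prob` (numeric vector of
#'   P(gene = 1 | parent configuration), length 2^#parents, configurations
#'   ordered by binary encoding of parents with the first parent as the
#'   least-significant bit).
#' @return Object of class `sbcn`.
#' @export
sbcn <- function(genes, arcs = NULL, node_params = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  if (is.null(arcs)) {
    arcs <- data.frame(parent = character(0), child = character(0),
                       confidence = numeric(0))
  }
  arcs <- as.data.frame(arcs)
  if (!all(c("parent", "child") %in% names(arcs)))
    stop("sbcn arcs need parent and child columns")
  if (is.null(arcs$confidence)) arcs$confidence <- rep(NA_real_, nrow(arcs))
  arcs <- arcs[, c("parent", "child", "confidence")]
  arcs$parent <- as.character(arcs$parent)
  arcs$child <- as.character(arcs$child)
  if (!all(c(arcs$parent, arcs$child) %in% genes))
    stop("sbcn arcs reference genes outside the model")
  if (is.null(topo_sort(genes, as_arc_matrix(arcs))))
    stop("sbcn arcs must be acyclic")
  conf <- arcs$confidence
  if (any(!is.na(conf) & (conf < 0 | conf > 1)))
    stop("arc confidences must lie in [0,1]")
  rownames(arcs) <- NULL
  structure(list(genes = genes, arcs = arcs,
                 node_params = node_params),
            class = "sbcn")
}

#' @export
print.sbcn <- function(x, ...) {
  cat(sprintf("sbcn: %d genes, %d arcs\n", length(x$genes), nrow(x$arcs)))
  if (nrow(x$arcs) > 0L) {
    lab <- sprintf("  %s -> %s", x$arcs$parent, x$arcs$child)
    conf <- ifelse(is.na(x$arcs$confidence), "",
                   sprintf(" (confidence %.2f)", x$arcs$confidence))
    cat(paste0(lab, conf, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Per-patient multi-sample genotypes
#'
#' Binary genotypes of multiple samples (biopsies or single cells) from one
#' patient, used to infer that patient's mutational tree.
#'
#' @param patient_id single identifier.
#' @param genotypes samples x genes binary matrix with gene colnames.
#' @return Object of class `sample_genotypes`.
#' @export
sample_genotypes <- function(patient_id, genotypes) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 1L) stop("at least one sample is required")
  if (is.null(colnames(genotypes))) stop("genotype columns must be named")
  storage.mode(genotypes) <- "integer"
  if (anyNA(genotypes) || !all(genotypes %in% c(0L, 1L)))
    stop("genotype entries must all be 0 or 1")
  structure(list(patient_id = as.character(patient_id),
                 genotypes = genotypes),
            class = "sample_genotypes")
}
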