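# Readers and writers for the tool's tab-separated formats. All formats are
# UTF-8 TSV; lines starting with '#' are comments. Readers validate type
# invariants and name the offending line or record in error messages.

read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a binary mutation matrix from TSV
#'
#' Expects a header row (first column the patient-id column name, remaining
#' columns gene symbols) and one row per patient with 0/1 entries.
#'
#' @param path file path.
#' @return A [mutation_matrix()].
#' @seealso [write_mutation_matrix()]
#' @export
read_mutation_matrix <- function(path) {
  raw <- read_tsv_lines(path)
  if (length(raw$lines) < 2L)
    stop("mutation matrix file needs a header and at least one patient row")
  fields <- strsplit(raw$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n <- length(header) - 1L
  if (n < 1L) stop("mutation matrix header has no gene columns")
  genes <- header[-1L]
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != n + 1L)
  if (length(bad) > 0L)
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 raw$lineno[-1L][bad[1L]], n + 1L, widths[bad[1L]]))
  patients <- vapply(body, `[[`, "", 1L)
  vals <- matrix(NA_integer_, length(body), n)
  for (i in seq_along(body)) {
    entry <- body[[i]][-1L]
    ok <- entry %in% c("0", "1")
    if (!all(ok))
      stop(sprintf("non-binary entry '%s' at line %d",
                   entry[!ok][1L], raw$lineno[-1L][i]))
    vals[i, ] <- as.integer(entry)
  }
  if (anyDuplicated(patients))
    stop("duplicate patient identifier: ",
         patients[duplicated(patients)][1L])
  mutation_matrix(vals, patients = patients, genes = genes)
}

#' Write a mutation matrix to TSV
#'
#' @param d a [mutation_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mutation_matrix <- function(d, path) {
  header <- paste(c("patient_id", colnames(d)), collapse = "\t")
  rows <- vapply(seq_len(nrow(d)), function(i)
    paste(c(rownames(d)[i], d[i, ]), collapse = "\t"), "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read per-patient temporal DAGs from an arc-list TSV
#'
#' Expects columns `patient_id`, `parent_gene`, `child_gene`, one row per
#' temporal arc; an isolated mutation is listed with an empty `child_gene`.
#'
#' @param path file path.
#' @return Named list of [patient_dag()] objects (one per patient, in file
#'   order of first appearance).
#' @export
read_patient_dags <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL)
  req <- c("patient_id", "parent_gene", "child_gene")
  if (!all(req %in% names(df)))
    stop("patient DAG file must have columns: ", paste(req, collapse = ", "))
  ids <- unique(df$patient_id)
  out <- lapply(ids, function(p) {
    rows <- df[df$patient_id == p, , drop = FALSE]
    has_child <- nzchar(rows$child_gene)
    arcs <- cbind(rows$parent_gene[has_child], rows$child_gene[has_child])
    nodes <- unique(c(rows$parent_gene, rows$child_gene[has_child]))
    patient_dag(p, nodes = nodes, arcs = arcs)
  })
  names(out) <- ids
  out
}

#' Write per-patient temporal DAGs to an arc-list TSV
#'
#' Isolated nodes (genes without any incident arc) are written with an empty
#' `child_gene` so that [read_patient_dags()] round-trips losslessly.
#'
#' @param dags list of [patient_dag()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_patient_dags <- function(dags, path) {
  rows <- lapply(dags, function(pd) {
    linked <- unique(c(pd$arcs[, 1L], pd$arcs[, 2L]))
    isolated <- setdiff(pd$nodes, linked)
    rbind(
      if (nrow(pd$arcs) > 0L)
        data.frame(patient_id = pd$patient_id, parent_gene = pd$arcs[, 1L],
                   child_gene = pd$arcs[, 2L]),
      if (length(isolated) > 0L)
        data.frame(patient_id = pd$patient_id, parent_gene = isolated,
                   child_gene = "")
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(patient_id = character(0), parent_gene = character(0),
                     child_gene = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CCF table from TSV
#'
#' @param path file path with columns `patient_id`, `gene`, `alt_reads`,
#'   `ref_reads`, `cn_factor`, `ccf` (empty `ccf` entries allowed when read
#'   counts are present).
#' @return A [ccf_table()].
#' @export
read_ccf_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  ccf_table(df)
}

#' Write a CCF table to TSV
#' @param x a [ccf_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ccf_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a survival table from TSV
#' @param path file path with columns `patient_id`, `time`, `event`.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  survival_table(df)
}

#' Write a survival table to TSV
#' @param x a [survival_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fitted Suppes-Bayes causal network
#'
#' Writes two files: `<stem>.arcs.tsv` with one row per arc (parent, child,
#' confidence) and `<stem>.json`, a machine-readable model document holding
#' genes, arcs and the conditional Bernoulli tables, re-readable losslessly
#' with [read_sbcn()].
#'
#' @param model an [sbcn()].
#' @param stem output path stem (no extension).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_sbcn <- function(model, stem) {
  stopifnot(inherits(model, "sbcn"))
  arcs_path <- paste0(stem, ".arcs.tsv")
  json_path <- paste0(stem, ".json")
  write.table(model$arcs, arcs_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  doc <- list(
    format = "evotraj-sbcn",
    version = 1L,
    genes = model$genes,
    arcs = model$arcs,
    node_params = lapply(model$node_params, function(np)
      list(parents = as.list(np$parents), prob = np$prob))
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(arcs_path, json_path))
}

#' Read a Suppes-Bayes causal network written by [write_sbcn()]
#' @param stem path stem used when writing.
#' @return An [sbcn()].
#' @export
read_sbcn <- function(stem) {
  doc <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(doc$format, "evotraj-sbcn"))
    stop("not an evotraj SBCN model document: ", stem)
  arcs <- doc$arcs
  if (length(arcs) == 0L || is.null(dim(arcs)))
    arcs <- data.frame(parent = character(0), child = character(0),
                       confidence = numeric(0))
  np <- NULL
  if (length(doc$node_params) > 0L)
    np <- lapply(doc$node_params, function(x)
      list(parents = as.character(unlist(x$parents)),
           prob = as.numeric(x$prob)))
  sbcn(genes = doc$genes, arcs = arcs, node_params = np)
}

#' Import Newick-labelled mutational trees as patient DAGs
#'
#' Optional importer for mutational trees exported in Newick format, one
#' tree per patient, where every labelled node carries a gene symbol and an
#' edge means the parent mutation preceded the child mutation. Node labels
#' equal to `root_label()` or `"Root"` are treated as the wild-type root and
#' dropped. Requires the `ape` package.
#'
#' @param path Newick file (one or more trees).
#' @param patient_ids optional character vector of patient identifiers, one
#'   per tree (defaults to `tree1`, `tree2`, ...).
#' @return Named list of [patient_dag()] objects.
#' @export
newick_to_patient_dags <- function(path, patient_ids = NULL) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick import")
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(patient_ids)) patient_ids <- paste0("tree", seq_along(trees))
  stopifnot(length(patient_ids) == length(trees))
  out <- Map(function(tr, pid) {
    labs <- c(tr$tip.label,
              tr$node.label %||% rep("", tr$Nnode))
    labs[!nzchar(labs)] <- NA
    labs[labs %in% c(root_label(), "Root", "root")] <- NA
    parent <- labs[tr$edge[, 1L]]
    child <- labs[tr$edge[, 2L]]
    keep <- !is.na(parent) & !is.na(child)
    nodes <- unique(labs[!is.na(labs)])
    patient_dag(pid, nodes = nodes,
                arcs = cbind(parent[keep], child[keep]))
  }, trees, patient_ids)
  names(out) <- patient_ids
  out
}
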