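# Structural-accuracy metrics against ground truth and clustering
# agreement.

#' Confusion counts of an inferred arc set against ground truth
#'
#' Counts, over all n(n-1) ordered gene pairs of the universe (the dummy
#' root is excluded), the arcs present in both models (TP), absent from
#' both (TN), inferred but not generative (FP) and generative but not
#' inferred (FN).
#'
#' @param inferred,truth two-column (parent, child) matrices or data.frames
#'   (an [sbcn()] is accepted for `inferred`).
#' @param genes the gene universe.
#' @return List of class `confusion_counts` with fields `tp`, `tn`, `fp`,
#'   `fn`; always sums to n(n-1).
#' @export
confusion_vs_truth <- function(inferred, truth, genes) {
  if (inherits(inferred, "sbcn")) inferred <- inferred$arcs
  inferred <- as_arc_matrix(inferred)
  truth <- as_arc_matrix(truth)
  if (!all(c(inferred, truth) %in% genes))
    stop("arcs reference genes outside the universe")
  n <- length(genes)
  inf_k <- unique(arc_keys(inferred))
  tru_k <- unique(arc_keys(truth))
  tp <- length(intersect(inf_k, tru_k))
  fp <- length(setdiff(inf_k, tru_k))
  fn <- length(setdiff(tru_k, inf_k))
  tn <- n * (n - 1L) - tp - fp - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), specificity = TN/(TN+FP); metrics with a zero
#' denominator are NA.
#'
#' @param counts a `confusion_counts` from [confusion_vs_truth()].
#' @return Named numeric vector (accuracy, precision, recall,
#'   specificity).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, c(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance: 1 for identical
#' partitions, about 0 for independent ones; can be negative.
#'
#' @param labels_a,labels_b cluster labels of the same items (length >= 2).
#' @return The ARI, a single number <= 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  stopifnot(n >= 2)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}
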