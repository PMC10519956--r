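# From inferred evolutionary steps to survival-stratifying signatures:
# binary evolutionary features, L1-regularized Cox selection, risk-group
# stratification and Kaplan-Meier / log-rank assessment.

#' Build evolutionary feature matrix
#'
#' One binary singleton feature per model gene (the gene's mutation status)
#' plus one co-occurrence feature per model arc, named `"u->v"`, set to 1
#' iff both endpoint genes are mutated in the patient. With
#' `directional = TRUE` and a CCF table, a pair feature additionally
#' requires the patient's CCF ordering to agree with the arc
#' (ccf(u) > ccf(v)).
#'
#' @param d a [mutation_matrix()].
#' @param model an [sbcn()] whose genes are columns of `d`.
#' @param directional require per-patient CCF agreement for pair features.
#' @param ccf a [ccf_table()], needed when `directional = TRUE`.
#' @return Binary integer matrix (patients x features) of class
#'   `evo_features`.
#' @export
build_evo_features <- function(d, model, directional = FALSE, ccf = NULL) {
  stopifnot(inherits(d, "mutation_matrix"), inherits(model, "sbcn"))
  if (!all(model$genes %in% colnames(d)))
    stop("model genes must be columns of the mutation matrix")
  x <- unclass(d)[, model$genes, drop = FALSE]
  if (nrow(model$arcs) > 0L) {
    if (directional && is.null(ccf))
      stop("directional pair features require a ccf table")
    ccf_of <- NULL
    if (directional) {
      vals <- ccf_values(ccf)
      ccf_of <- function(p, g) {
        i <- which(ccf$patient_id == p & ccf$gene == g)
        if (length(i) == 0L) NA_real_ else vals[i[1L]]
      }
    }
    pair_cols <- vapply(seq_len(nrow(model$arcs)), function(i) {
      u <- model$arcs$parent[i]; v <- model$arcs$child[i]
      col <- as.integer(unclass(d)[, u] & unclass(d)[, v])
      if (directional) {
        for (j in which(col == 1L)) {
          p <- rownames(d)[j]
          cu <- ccf_of(p, u); cv <- ccf_of(p, v)
          if (is.na(cu) || is.na(cv) || cu <= cv) col[j] <- 0L
        }
      }
      col
    }, integer(nrow(d)))
    pair_cols <- matrix(pair_cols, nrow = nrow(d))
    colnames(pair_cols) <- paste0(model$arcs$parent, "->", model$arcs$child)
    x <- cbind(x, pair_cols)
  }
  rownames(x) <- rownames(d)
  storage.mode(x) <- "integer"
  class(x) <- c("evo_features", class(x))
  x
}

#' Select prognostic evolutionary features by L1-penalized Cox regression
#'
#' Fits the lasso path of the Cox partial likelihood (Breslow ties) over a
#' descending lambda grid and picks the lambda with minimum k-fold
#' cross-validated deviance; the nonzero-coefficient features at that
#' lambda are the selected signature components. Constant features are
#' dropped with a warning. With a single usable feature (the lasso path
#' needs two or more columns) an unpenalized Cox fit is used instead and
#' the feature is selected when its likelihood-ratio test has p < 0.05.
#'
#' @param x an `evo_features` matrix (or any binary patient x feature
#'   matrix with dimnames).
#' @param s a [survival_table()] covering the patients of `x` (at least two
#'   events required).
#' @param folds number of cross-validation folds (default 10).
#' @param seed optional seed fixing the fold assignment.
#' @return List of class `cox_selection`: `features` (selected names),
#'   `coefficients` (named vector), `lambda` (chosen penalty, NA for the
#'   single-feature fallback), `x` (the feature matrix aligned to `s`),
#'   `survival` (the aligned survival table).
#' @export
fit_regularized_cox <- function(x, s, folds = 10, seed = NULL) {
  stopifnot(inherits(s, "survival_table"))
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("feature matrix must have patient rownames")
  common <- intersect(rownames(x), s$patient_id)
  if (length(common) < 3L) stop("too few patients shared between x and s")
  x <- x[common, , drop = FALSE]
  s <- s[match(common, s$patient_id), , drop = FALSE]
  class(s) <- c("survival_table", "data.frame")
  if (sum(s$event) < 2L) stop("at least two events are required")
  keep <- apply(x, 2L, function(col) length(unique(col)) > 1L)
  if (!all(keep))
    warning("dropping constant features: ",
            paste(colnames(x)[!keep], collapse = ", "))
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0L) stop("no non-constant features to select from")
  y <- survival::Surv(s$time, s$event)
  if (ncol(x) == 1L) {
    fit <- survival::coxph(y ~ x[, 1L], ties = "breslow")
    lrt_p <- pchisq(2 * diff(fit$loglik), df = 1, lower.tail = FALSE)
    selected <- lrt_p < 0.05
    coefs <- if (selected) setNames(coef(fit), colnames(x)) else
      setNames(numeric(0), character(0))
    out <- list(features = if (selected) colnames(x) else character(0),
                coefficients = coefs, lambda = NA_real_,
                x = x, survival = s)
  } else {
    foldid <- local_seed(seed, sample(rep_len(seq_len(folds), nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                            foldid = foldid)
    beta <- as.matrix(coef(cv, s = "lambda.min"))[, 1L]
    sel <- beta != 0
    out <- list(features = names(beta)[sel],
                coefficients = beta[sel],
                lambda = cv$lambda.min, x = x, survival = s)
  }
  class(out) <- "cox_selection"
  out
}

#' @export
print.cox_selection <- function(x, ...) {
  cat(sprintf("cox_selection: %d feature(s) selected\n", length(x$features)))
  if (length(x$features) > 0L) {
    hr <- exp(x$coefficients)
    cat(paste(sprintf("  %s: coef %.3f (HR %.2f)", x$features,
                      x$coefficients, hr), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Stratify patients into risk groups from selected features
#'
#' Patients are grouped by their binary profile over the selected
#' features; distinct profiles are merged by average-linkage agglomerative
#' clustering under Hamming distance, with the number of clusters chosen
#' in 2..6 by maximal mean silhouette width. Clusters are relabeled in
#' ascending order of mean risk score (the Cox linear predictor), so
#' cluster 1 is always the lowest-risk group.
#'
#' @param x_selected binary patient x selected-feature matrix.
#' @param coefficients named Cox coefficients for those features.
#' @param k_max largest number of clusters considered (default 6).
#' @return List of class `risk_strata`: `cluster` (named integer vector),
#'   `risk_score` (named numeric), `k`, `silhouette` (mean width per
#'   candidate k, NA when k was forced).
#' @export
stratify_patients <- function(x_selected, coefficients, k_max = 6) {
  x_selected <- as.matrix(x_selected)
  if (ncol(x_selected) == 0L) {
    warning("no selected features: all patients in a single stratum")
    cl <- setNames(rep(1L, nrow(x_selected)), rownames(x_selected))
    return(structure(list(cluster = cl,
                          risk_score = setNames(rep(0, nrow(x_selected)),
                                                rownames(x_selected)),
                          k = 1L, silhouette = NULL),
                     class = "risk_strata"))
  }
  coefficients <- coefficients[colnames(x_selected)]
  risk <- drop(x_selected %*% coefficients)
  names(risk) <- rownames(x_selected)
  prof_key <- apply(x_selected, 1L, paste, collapse = "")
  profiles <- unique(x_selected)
  rownames(profiles) <- apply(profiles, 1L, paste, collapse = "")
  np <- nrow(profiles)
  sil <- NULL
  if (np == 1L) {
    prof_cl <- setNames(1L, rownames(profiles))
  } else if (np == 2L) {
    prof_cl <- setNames(1:2, rownames(profiles))
  } else {
    dd <- dist(profiles, method = "manhattan")  # Hamming for binary rows
    hc <- hclust(dd, method = "average")
    ks <- 2:min(k_max, np)
    # patient-level silhouette: expand profile distances by profile counts
    pat_d <- dist(x_selected, method = "manhattan")
    sil <- vapply(ks, function(k) {
      pcl <- cutree(hc, k = k)
      pat_cl <- pcl[prof_key]
      if (length(unique(pat_cl)) < 2L) return(NA_real_)
      mean(cluster::silhouette(pat_cl, pat_d)[, "sil_width"])
    }, 0)
    names(sil) <- ks
    k_best <- ks[which.max(sil)]
    prof_cl <- cutree(hc, k = k_best)
  }
  cl <- prof_cl[prof_key]
  names(cl) <- rownames(x_selected)
  # order clusters by mean risk, ascending
  means <- tapply(risk, cl, mean)
  relabel <- setNames(rank(means, ties.method = "first"), names(means))
  cl <- setNames(as.integer(relabel[as.character(cl)]), names(cl))
  structure(list(cluster = cl, risk_score = risk,
                 k = length(unique(cl)), silhouette = sil),
            class = "risk_strata")
}

#' Kaplan-Meier curves and log-rank test across risk groups
#'
#' @param clusters named integer vector of cluster labels (patient ids as
#'   names), or a `risk_strata` object.
#' @param s a [survival_table()] covering those patients.
#' @return List of class `km_logrank`: `curves` (data.frame cluster, time,
#'   survival, n_risk, n_event), `chisq`, `df`, `p_value`.
#' @export
km_logrank <- function(clusters, s) {
  if (inherits(clusters, "risk_strata")) clusters <- clusters$cluster
  stopifnot(inherits(s, "survival_table"))
  common <- intersect(names(clusters), s$patient_id)
  if (length(common) < length(clusters))
    stop("survival table does not cover all clustered patients")
  s <- s[match(names(clusters), s$patient_id), , drop = FALSE]
  grp <- factor(clusters)
  if (any(table(grp) == 0L)) stop("empty cluster")
  if (nlevels(grp) < 2L) stop("at least two clusters are required")
  y <- survival::Surv(s$time, s$event)
  sf <- survival::survfit(y ~ grp)
  strata_lab <- rep(sub("^grp=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(cluster = strata_lab, time = sf$time,
                       survival = sf$surv, n_risk = sf$n.risk,
                       n_event = sf$n.event)
  sd <- survival::survdiff(y ~ grp)
  df <- nlevels(grp) - 1L
  p <- pchisq(sd$chisq, df = df, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(sd$chisq), df = df,
                 p_value = p),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.3f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Summarize an evolutionary signature set
#'
#' Collects, for each selected evolutionary feature, its Cox coefficient
#' and hazard ratio (the risk level), its prevalence (carrier fraction)
#' within each risk cluster, and the Kaplan-Meier / log-rank assessment of
#' the stratification.
#'
#' @param strata a `risk_strata` from [stratify_patients()].
#' @param x_selected binary patient x selected-feature matrix.
#' @param coefficients named Cox coefficients.
#' @param s a [survival_table()].
#' @return List of class `signature_set`: `features` (data.frame feature,
#'   coefficient, hazard_ratio), `prevalence` (feature x cluster matrix in
#'   \[0,1\]), `cluster`, `risk_score`, `km` (a `km_logrank`, NULL with
#'   fewer than two clusters).
#' @export
summarize_signatures <- function(strata, x_selected, coefficients, s) {
  stopifnot(inherits(strata, "risk_strata"))
  x_selected <- as.matrix(x_selected)
  coefficients <- coefficients[colnames(x_selected)]
  feats <- data.frame(feature = colnames(x_selected),
                      coefficient = unname(coefficients),
                      hazard_ratio = unname(exp(coefficients)))
  ks <- sort(unique(strata$cluster))
  prevalence <- vapply(ks, function(k) {
    members <- names(strata$cluster)[strata$cluster == k]
    colMeans(x_selected[members, , drop = FALSE])
  }, numeric(ncol(x_selected)))
  prevalence <- matrix(prevalence, nrow = ncol(x_selected),
                       dimnames = list(colnames(x_selected),
                                       paste0("cluster", ks)))
  km <- if (length(ks) >= 2L) km_logrank(strata$cluster, s) else NULL
  structure(list(features = feats, prevalence = prevalence,
                 cluster = strata$cluster, risk_score = strata$risk_score,
                 km = km),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d feature(s), %d cluster(s)\n",
              nrow(x$features), length(unique(x$cluster))))
  print(x$features, row.names = FALSE)
  if (!is.null(x$km)) print(x$km)
  invisible(x)
}

#' Derive evolutionary signatures end-to-end
#'
#' Convenience wrapper: build evolutionary features from a fitted model,
#' select prognostic features by regularized Cox regression, stratify
#' patients and summarize the signatures.
#'
#' @inheritParams build_evo_features
#' @inheritParams fit_regularized_cox
#' @return A `signature_set` (see [summarize_signatures()]); the Cox
#'   selection is kept in the `selection` attribute.
#' @export
evo_signatures <- function(d, model, s, folds = 10, seed = NULL) {
  x <- build_evo_features(d, model)
  sel <- fit_regularized_cox(x, s, folds = folds, seed = seed)
  x_sel <- sel$x[, sel$features, drop = FALSE]
  strata <- stratify_patients(x_sel, sel$coefficients)
  out <- summarize_signatures(strata, x_sel, sel$coefficients,
                              sel$survival)
  attr(out, "selection") <- sel
  out
}
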