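# Differential-metabolite screening and concentration exploration.
#
# Compounds are flagged as differential when both VIP > 1 (from a global
# PLS-DA on autoscaled concentrations) and one-way ANOVA P < 0.05 across the
# temperature classes hold, the standard targeted-metabolomics criterion.
# Concentrations are autoscaled throughout, so screening is invariant to
# per-compound affine rescaling.

#' Screen differential metabolites (VIP > 1, P < 0.05)
#'
#' @param table a `concentration_table` or samples x compounds matrix.
#' @param labels class label per sample (>= 2 classes, >= 2 samples each).
#' @param vip_threshold,p_threshold strict thresholds.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching the plain P < 0.05 criterion; set `"BH"`
#'   for Benjamini-Hochberg).
#' @param max_components,cv_folds forwarded to the underlying PLS-DA.
#' @return data.frame, one row per screenable compound: `compound`, `VIP`,
#'   `p_value`, per-class mean direction summary, `selected`. Compounds with
#'   zero variance are excluded with a warning.
#' @export
screen_differential <- function(table, labels, vip_threshold = 1,
                                p_threshold = 0.05, adjust = "none",
                                max_components = 5, cv_folds = 5) {
  V <- if (inherits(table, "concentration_table")) table$values else
    as.matrix(table)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("screening needs at least 2 classes")
  if (any(table(labels) < 2)) stop("each class needs >= 2 samples")
  sds <- apply(V, 2, sd)
  if (any(sds < .Machine$double.eps)) {
    warning(sprintf("%d zero-variance compound(s) excluded from screening",
                    sum(sds < .Machine$double.eps)))
    V <- V[, sds >= .Machine$double.eps, drop = FALSE]
  }
  Z <- scale(V)
  plsda <- fit_plsda(Z, labels, max_components = max_components,
                     cv_folds = cv_folds)
  vip <- vip_scores(plsda$model)
  pvals <- apply(Z, 2, function(y)
    summary(aov(y ~ labels))[[1]][["Pr(>F)"]][1])
  pvals <- stats::p.adjust(pvals, method = adjust)
  cls_means <- t(apply(Z, 2, function(y) tapply(y, labels, mean)))
  direction <- apply(cls_means, 1, function(m)
    paste(names(m)[order(-m)], collapse = ">"))
  data.frame(compound = colnames(V), VIP = vip, p_value = pvals,
             direction = direction,
             selected = vip > vip_threshold & pvals < p_threshold,
             row.names = NULL)
}

#' Hierarchical-clustering leaf orders for a concentration heatmap
#'
#' Agglomerative clustering on autoscaled values (samples on rows, compounds
#' on columns). `hclust` merges are deterministic: equal-distance ties
#' resolve by the original observation order.
#'
#' @param table a `concentration_table` or matrix.
#' @param metric distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return list with `row_order`, `col_order`, and both dendrograms.
#' @export
cluster_order <- function(table, metric = "euclidean",
                          linkage = "complete") {
  V <- if (inherits(table, "concentration_table")) table$values else
    as.matrix(table)
  if (anyNA(V)) stop("NA in concentration table")
  if (nrow(V) < 2) stop("clustering needs >= 2 rows")
  keep <- apply(V, 2, sd) > .Machine$double.eps
  Z <- V
  Z[, keep] <- scale(V[, keep, drop = FALSE])
  Z[, !keep] <- 0
  hr <- hclust(dist(Z, method = metric), method = linkage)
  col_order <- if (ncol(Z) < 2) seq_len(ncol(Z)) else {
    hc <- hclust(dist(t(Z), method = metric), method = linkage)
    hc$order
  }
  list(row_order = hr$order, col_order = col_order,
       row_tree = hr,
       col_tree = if (ncol(Z) >= 2) hclust(dist(t(Z), method = metric),
                                           method = linkage) else NULL)
}

#' PCA of a concentration table with class-separation summary
#'
#' Autoscaled PCA; when labels are given, a silhouette-style separation
#' score on the first two score dimensions is reported (mean over samples of
#' `(b - a) / max(a, b)` with `a` the mean within-class and `b` the smallest
#' mean other-class distance).
#'
#' @param table a `concentration_table` or matrix (>= 3 samples).
#' @param labels optional class labels.
#' @param n_components components to keep (default 2).
#' @return list: `scores`, `explained`, and (with labels) `silhouette`.
#' @export
concentration_pca <- function(table, labels = NULL, n_components = 2) {
  V <- if (inherits(table, "concentration_table")) table$values else
    as.matrix(table)
  if (nrow(V) < 3) stop("concentration PCA needs >= 3 samples")
  sds <- apply(V, 2, sd)
  if (any(sds < .Machine$double.eps)) {
    warning("constant compound column(s) dropped from PCA")
    V <- V[, sds >= .Machine$double.eps, drop = FALSE]
  }
  p <- pca_fit(V, n_components = n_components, scale = TRUE)
  out <- list(scores = p$scores, explained = p$explained)
  if (!is.null(labels)) {
    labels <- droplevels(as.factor(labels))
    S <- p$scores[, seq_len(min(2, ncol(p$scores))), drop = FALSE]
    D <- as.matrix(dist(S))
    sil <- vapply(seq_len(nrow(S)), function(i) {
      same <- labels == labels[i]; same[i] <- FALSE
      if (!any(same)) return(0)
      a <- mean(D[i, same])
      b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                      function(cl) mean(D[i, labels == cl]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    out$silhouette <- mean(sil)
  }
  out
}
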