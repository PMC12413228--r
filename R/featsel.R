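# Feature-group comparison: per-group PCA to a common width, greedy mRMR
# selection with a discretized mutual-information estimator, and summed
# gradient-boosting split-gain importance per group.

#' Bundle feature groups with labels
#'
#' @param groups Named list of numeric matrices; all must share the same
#'   number of rows (samples).  Widths may differ (they are equalised by
#'   [pca_reduce()]).
#' @param labels 0/1 vector, one per sample.
#' @return Object of class `feature_group_set`.
#' @export
feature_group_set <- function(groups, labels) {
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a non-empty named list of matrices")
  ns <- vapply(groups, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("all groups must share the sample count")
  labels <- as.integer(labels)
  if (length(labels) != ns[1]) stop("labels must match the sample count")
  structure(list(groups = groups, labels = labels), class = "feature_group_set")
}

#' Reduce each feature group to a common width by PCA
#'
#' Each group is centred (no scaling by default) and projected onto its first
#' `n_components` principal components, so groups of uneven width become
#' comparable.  Columns are named `<group>.PC<i>`.
#'
#' @param x A [feature_group_set()].
#' @param n_components Components kept per group (default 10).
#' @param scale Also scale columns to unit variance before projection.
#' @return A `feature_group_set` whose groups all have `n_components`
#'   columns; each group's `prcomp` fit is attached as attribute `"pca"`.
#' @export
pca_reduce <- function(x, n_components = 10L, scale = FALSE) {
  stopifnot(inherits(x, "feature_group_set"))
  n <- length(x$labels)
  if (n <= n_components)
    stop("need more than ", n_components, " samples for PCA")
  fits <- list()
  red <- lapply(names(x$groups), function(g) {
    m <- x$groups[[g]]
    if (ncol(m) < n_components)
      stop("group '", g, "' has width ", ncol(m), " < ", n_components)
    fit <- stats::prcomp(m, center = TRUE, scale. = scale)
    fits[[g]] <<- fit
    sc <- fit$x[, seq_len(n_components), drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(n_components))
    sc
  })
  names(red) <- names(x$groups)
  out <- feature_group_set(red, x$labels)
  attr(out, "pca") <- fits
  out
}

# Pool the group matrices column-wise; features are named <group>.<column>
# (column name when present, index otherwise).
pool_groups <- function(x) {
  pooled <- do.call(cbind, unname(x$groups))
  group_of <- rep(names(x$groups), vapply(x$groups, ncol, integer(1)))
  nm <- unlist(lapply(names(x$groups), function(g) {
    cn <- colnames(x$groups[[g]])
    if (is.null(cn)) cn <- seq_len(ncol(x$groups[[g]]))
    paste0(g, ".", cn)
  }), use.names = FALSE)
  colnames(pooled) <- nm
  list(mat = pooled, group_of = group_of)
}

# Equal-width discretization into `bins` bins; a constant column collapses to
# one bin.
discretize_ew <- function(x, bins = 10L) {
  r <- range(x)
  if (r[1] == r[2]) return(rep.int(1L, length(x)))
  b <- pmin(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
  as.integer(b)
}

# Mutual information (nats) between two integer-coded vectors.
mi_disc <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  ix <- p > 0
  sum(p[ix] * log(p[ix] / outer(pa, pb)[ix]))
}

#' Greedy minimum-redundancy maximum-relevance selection
#'
#' The MID (mutual-information difference) scheme: the first feature
#' maximises relevance I(f; y); each subsequent pick maximises
#' relevance minus the mean mutual information with the already-selected
#' features.  Mutual information is estimated after equal-width
#' discretization into `bins` bins.  Ties break by pooled column order, so
#' the selection is fully deterministic.
#'
#' @param x A [feature_group_set()] (normally [pca_reduce()] output).
#' @param k Number of features to select (default 40).
#' @param bins Discretization bins (default 10).
#' @return Object of class `selection_report`: `selected` (data frame of
#'   `rank`, `feature`, `group`, `score`), `per_group_counts`.
#' @export
mrmr_select <- function(x, k = 40L, bins = 10L) {
  stopifnot(inherits(x, "feature_group_set"))
  pl <- pool_groups(x)
  pooled <- pl$mat
  group_of <- pl$group_of
  p <- ncol(pooled)
  if (k > p) stop("k = ", k, " exceeds the pooled feature count ", p)
  disc <- apply(pooled, 2L, discretize_ew, bins = bins)
  y <- x$labels
  rel <- vapply(seq_len(p), function(j) mi_disc(disc[, j], y), numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p) # running sum of MI with selected features
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), selected)
    crit <- if (!length(selected)) rel[cand] else
      rel[cand] - red_sum[cand] / length(selected)
    pick <- cand[which.max(crit)] # which.max takes the first maximum: pooled order
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
    if (step < k) {
      cand2 <- setdiff(seq_len(p), selected)
      for (j in cand2) red_sum[j] <- red_sum[j] + mi_disc(disc[, j], disc[, pick])
    }
  }
  sel <- data.frame(
    rank = seq_len(k),
    feature = colnames(pooled)[selected],
    group = group_of[selected],
    score = scores,
    stringsAsFactors = FALSE
  )
  counts <- table(factor(sel$group, levels = names(x$groups)))
  structure(
    list(selected = sel,
         per_group_counts = stats::setNames(as.integer(counts), names(counts)),
         per_group_importance = NULL),
    class = "selection_report"
  )
}

#' Feature-group importance from gradient boosting
#'
#' Fits a gradient-boosted decision-tree ensemble (xgboost, logistic
#' objective) on the pooled feature matrix and sums the per-feature split
#' gain within each group; importances are normalised to sum to 1 across the
#' pool.
#'
#' @param x A [feature_group_set()] (normally [pca_reduce()] output).
#' @param seed Integer seed; the fit is single-threaded and deterministic.
#' @param nrounds,max_depth,eta Ensemble hyperparameters (defaults 300, 6,
#'   0.1).
#' @return Object of class `selection_report` with `per_group_importance`.
#' @export
group_importance <- function(x, seed = 1L, nrounds = 300L, max_depth = 6L,
                             eta = 0.1) {
  stopifnot(inherits(x, "feature_group_set"))
  if (length(unique(x$labels)) < 2L)
    stop("labels contain a single class; importance undefined")
  pl <- pool_groups(x)
  pooled <- pl$mat
  group_of <- pl$group_of
  fit <- xgboost::xgboost(
    x = pooled, y = factor(x$labels, levels = c(0L, 1L)),
    objective = "binary:logistic",
    nrounds = nrounds, max_depth = max_depth, learning_rate = eta,
    nthreads = 1L, seed = as.integer(seed), verbosity = 0L
  )
  imp <- xgboost::xgb.importance(model = fit)
  gain <- stats::setNames(rep(0, ncol(pooled)), colnames(pooled))
  gain[imp$Feature] <- imp$Gain
  gain <- gain / sum(gain)
  per_group <- vapply(names(x$groups),
                      function(g) sum(gain[group_of == g]), numeric(1))
  structure(
    list(selected = NULL, per_group_counts = NULL,
         per_group_importance = per_group, per_feature_importance = gain),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  if (!is.null(x$selected)) {
    cat("mRMR selection of", nrow(x$selected), "features; per-group counts:\n")
    print(x$per_group_counts)
  }
  if (!is.null(x$per_group_importance)) {
    cat("Summed gradient-boosting importance per group:\n")
    print(round(sort(x$per_group_importance, decreasing = TRUE), 4))
  }
  invisible(x)
}

#' Write a selection report
#'
#' Serialises the report as JSON plus a TSV of per-group counts or
#' importances.
#'
#' @param report A `selection_report`.
#' @param path Output path stem; writes `<path>.json` and `<path>.tsv`.
#' @return The JSON path, invisibly.
#' @export
write_selection_report <- function(report, path) {
  jsonlite::write_json(
    list(selected = report$selected,
         per_group_counts = as.list(report$per_group_counts),
         per_group_importance = as.list(report$per_group_importance)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  tab <- if (!is.null(report$per_group_counts))
    data.frame(group = names(report$per_group_counts),
               count = as.integer(report$per_group_counts))
  else
    data.frame(group = names(report$per_group_importance),
               importance = as.numeric(report$per_group_importance))
  utils::write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paste0(path, ".json"))
}
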