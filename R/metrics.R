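#' Annotation efficiency
#'
#' Objects sorted per virtual click. An empty run (nothing sorted, no
#' clicks) has efficiency 0 by convention; sorted objects without any click
#' are impossible under the click model and raise an error.
#'
#' @param n_sorted Number of objects assigned to validated clusters.
#' @param n_clicks Number of recorded clicks.
#' @return Objects per click.
#' @export
efficiency <- function(n_sorted, n_clicks) {
  stopifnot(n_sorted >= 0, n_clicks >= 0)
  if (n_clicks == 0) {
    if (n_sorted > 0)
      .stopf("%d objects sorted with zero clicks is impossible", n_sorted)
    return(0)
  }
  n_sorted / n_clicks
}

#' Completeness of an annotation
#'
#' Fraction of all objects assigned to validated clusters.
#'
#' @param x An `annotation_run`, [sim_state()] or [partial_assignment].
#' @param ... Unused.
#' @return Proportion in `[0, 1]`.
#' @export
completeness <- function(x, ...) UseMethod("completeness")

#' @export
completeness.annotation_run <- function(x, ...) completeness(x$state)

#' @export
completeness.sim_state <- function(x, ...) {
  n <- nrow(x$features)
  (n - length(x$pool)) / n
}

#' @export
completeness.partial_assignment <- function(x, ...) {
  mean(!is.na(x$cluster_of))
}

#' Mean per-cluster precision
#'
#' Unweighted mean over clusters of the fraction of members matching the
#' cluster's majority gold-standard label. With `weighted = TRUE` clusters
#' are weighted by their size instead (the object-weighted variant).
#'
#' @param x An `annotation_run`, [sim_state()] or [partial_assignment].
#' @param gold Named character vector of gold labels (taken from the
#'   run's dataset when omitted).
#' @param weighted Weight clusters by size (default `FALSE`).
#' @param ... Unused.
#' @return Proportion in `[0, 1]`, or `NA` when there are no clusters.
#' @export
precision <- function(x, ...) UseMethod("precision")

#' @export
precision.annotation_run <- function(x, gold = x$dataset$gold_labels,
                                     weighted = FALSE, ...) {
  precision(x$state, gold = gold, weighted = weighted)
}

#' @export
precision.sim_state <- function(x, gold, weighted = FALSE, ...) {
  members <- lapply(x$clusters, `[[`, "members")
  .precision_members(members, gold, weighted)
}

#' @export
precision.partial_assignment <- function(x, gold, weighted = FALSE, ...) {
  .precision_members(cluster_members(x), gold, weighted)
}

.precision_members <- function(members, gold, weighted) {
  if (length(members) == 0L) return(NA_real_)
  pur <- vapply(members, function(ids) cluster_purity(gold[ids])$purity, 0)
  if (weighted)
    stats::weighted.mean(pur, vapply(members, length, 0L))
  else
    mean(pur)
}

#' F1 score of a nearest centroid classifier
#'
#' Fits one centroid per class as the mean of the training features and
#' predicts each test object by its nearest centroid (Euclidean distance).
#' Returns the macro-averaged F1 over the classes present in the test set
#' (the informative convention for many imbalanced classes); the
#' micro-averaged score is attached as attribute `"micro"`. The score
#' quantifies how compact and well-separated the classes are in the
#' representation space. A test class absent from the training set scores 0
#' with a warning.
#'
#' @param train,test [embedding_set]s with gold labels.
#' @return Macro F1 in `[0, 1]`.
#' @export
ncc_f1 <- function(train, test) {
  stopifnot(inherits(train, "embedding_set"), inherits(test, "embedding_set"))
  if (is.null(train$gold_labels) || is.null(test$gold_labels))
    .stopf("`ncc_f1()` requires gold labels on both sets")
  classes_tr <- sort(unique(train$gold_labels))
  cents <- t(vapply(classes_tr, function(cl)
    colMeans(train$features[train$gold_labels == cl, , drop = FALSE]),
    numeric(ncol(train$features))))
  d2 <- .dist2(test$features, cents)
  pred <- classes_tr[max.col(-d2, ties.method = "first")]
  truth <- unname(test$gold_labels)

  classes_te <- sort(unique(truth))
  missing <- setdiff(classes_te, classes_tr)
  if (length(missing) > 0)
    .warnf("%d test class(es) absent from train score 0: %s",
           length(missing), paste(utils::head(missing, 5), collapse = ", "))
  f1 <- vapply(classes_te, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  out <- mean(f1)
  attr(out, "micro") <- mean(pred == truth)
  out
}

#' Metrics report of a finished run
#'
#' @param run An `annotation_run` from [run_simulation()].
#' @param ncc Optional NCC-F1 value to include (see [ncc_f1()]).
#' @return A list of class `metrics_report` with `efficiency` (objects per
#'   click), `completeness`, `precision` (unweighted mean over clusters),
#'   `precision_weighted`, `n_clusters`, `ncc_f1` and `runtime_seconds` (of
#'   the clustering stage).
#' @export
metrics_report <- function(run, ncc = NULL) {
  stopifnot(inherits(run, "annotation_run"))
  n <- nrow(run$state$features)
  assigned <- n - length(run$state$pool)
  structure(list(
    efficiency = efficiency(assigned, sum(run$state$clicks)),
    completeness = completeness(run),
    precision = precision(run),
    precision_weighted = precision(run, weighted = TRUE),
    n_clusters = length(run$state$clusters),
    ncc_f1 = if (is.null(ncc)) NA_real_ else as.numeric(ncc),
    runtime_seconds = run$clustering_seconds), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  efficiency:   %.2f objects/click\n", x$efficiency))
  cat(sprintf("  completeness: %.3f\n", x$completeness))
  cat(sprintf("  precision:    %.3f (weighted %.3f)\n",
              x$precision, x$precision_weighted))
  cat(sprintf("  clusters:     %d\n", x$n_clusters))
  if (!is.na(x$ncc_f1)) cat(sprintf("  NCC-F1:       %.3f\n", x$ncc_f1))
  cat(sprintf("  clustering runtime: %.2f s\n", x$runtime_seconds))
  invisible(x)
}
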