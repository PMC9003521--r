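#' Density-based candidate clusters via HDBSCAN*
#'
#' Adapter around the scikit-learn implementation of HDBSCAN* with leaf
#' cluster selection, which produces fine-grained, homogeneous clusters and
#' leaves low-density objects unassigned -- exactly the partial output the
#' validation step needs. The minimum cluster size decays exponentially over
#' annotation iterations, `max(2, round(m0 * decay_factor^outer_iteration))`,
#' so that later iterations can still carve clusters out of a shrinking pool.
#'
#' Requires a `python` interpreter with scikit-learn (>= 1.3) on the PATH.
#'
#' @inheritParams kmeans_base
#' @param neighborhood_k Core-distance neighborhood size (default 8).
#' @param m0 Initial minimum cluster size (default 128).
#' @param decay_factor Multiplicative per-iteration decay of the minimum
#'   cluster size, in `(0, 1]` (default 0.5; the floor of 2 is reached after
#'   about `log2(m0)` iterations).
#' @param outer_iteration Zero-based annotation iteration index.
#' @return A [partial_assignment]; noise points are unassigned and centroids
#'   are member means. If fewer points than the minimum cluster size are
#'   given, everything is unassigned (with a warning).
#' @export
hdbscan_candidates <- function(features, neighborhood_k = 8, m0 = 128,
                               decay_factor = 0.5, outer_iteration = 0) {
  if (!.is_count(neighborhood_k))
    .stopf("invalid `neighborhood_k`: must be a positive integer")
  if (!.is_count(m0) || m0 < 2) .stopf("invalid `m0`: must be an integer >= 2")
  if (!.is_prop(decay_factor, lo_open = TRUE))
    .stopf("invalid `decay_factor`: must be in (0, 1]")
  x <- .as_feature_matrix(features)
  mcs <- max(2L, as.integer(round(m0 * decay_factor^outer_iteration)))
  none <- function() partial_assignment(
    stats::setNames(rep(NA_character_, nrow(x)), rownames(x)))
  if (nrow(x) < mcs) {
    .warnf("%d points is fewer than the minimum cluster size %d; no clusters",
           nrow(x), mcs)
    return(none())
  }
  labels <- .hdbscan_run(x, mcs, neighborhood_k)
  if (all(labels < 0)) return(none())
  cluster_of <- ifelse(labels < 0, NA_character_, sprintf("h%d", labels + 1L))
  names(cluster_of) <- rownames(x)
  out <- partial_assignment(cluster_of)
  out$centroids <- compute_centroids(out, x)
  out
}

.hdbscan_run <- function(x, min_cluster_size, min_samples) {
  if (Sys.which("python") == "")
    .stopf("`hdbscan_candidates()` needs a `python` interpreter with scikit-learn on the PATH")
  script <- system.file("python", "hdbscan_leaf.py", package = "clustersim")
  if (script == "") .stopf("bundled hdbscan_leaf.py not found")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(x, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  status <- suppressWarnings(system2(
    "python", c(script, fin, fout, min_cluster_size, min_samples),
    stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    .stopf("HDBSCAN* call failed:\n%s", paste(status, collapse = "\n"))
  as.integer(readLines(fout))
}
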