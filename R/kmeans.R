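# Constrained Lloyd engine shared by kmeans_base / shrunken_kmeans /
# pl_kmeans. Works on integer cluster indices 1..k; the public wrappers map
# to character cluster ids.
#
# frozen:  integer vector length n; non-NA entries are fixed labels that the
#          expectation step never changes (validated objects).
# reject:  2-column integer matrix of (row, col) pairs that the expectation
#          step must not assign (cannot-link information).
# p_noise: fraction of most-distant members excluded from each centroid
#          update; distances are taken to the PREVIOUS centroid.
.lloyd <- function(x, k, centroids, frozen = NULL, reject = NULL,
                   p_noise = 0, max_iter = 100, keep_history = FALSE) {
  n <- nrow(x)
  labels <- rep(NA_integer_, n)
  history <- if (keep_history) list() else NULL
  iter <- 0L
  free <- if (is.null(frozen)) seq_len(n) else which(is.na(frozen))
  repeat {
    iter <- iter + 1L
    d2 <- .dist2(x, centroids)
    if (!is.null(reject) && nrow(reject) > 0) d2[reject] <- Inf
    new_labels <- max.col(-d2, ties.method = "first")
    new_labels[!is.finite(d2[cbind(seq_len(n), new_labels)])] <- NA_integer_
    if (!is.null(frozen)) new_labels[!is.na(frozen)] <- frozen[!is.na(frozen)]
    if (keep_history)
      history[[iter]] <- list(centroids = centroids, assignment = new_labels)
    # re-seed empty clusters with the free point farthest from its centroid
    empty <- setdiff(seq_len(k), unique(new_labels[!is.na(new_labels)]))
    for (j in empty) {
      cand <- free[!is.na(new_labels[free])]
      # do not depopulate singleton clusters
      sizes <- tabulate(new_labels[!is.na(new_labels)], nbins = k)
      cand <- cand[sizes[new_labels[cand]] > 1L]
      if (length(cand) == 0L) next
      far <- cand[which.max(d2[cbind(cand, new_labels[cand])])]
      new_labels[far] <- j
      centroids[j, ] <- x[far, ]
    }
    converged <- identical(new_labels, labels)
    labels <- new_labels
    if (converged || iter >= max_iter) break
    # maximisation step
    for (j in seq_len(k)) {
      mem <- which(labels == j)
      m <- length(mem)
      if (m == 0L) next
      if (p_noise > 0 && m > 1L) {
        keep <- ceiling((1 - p_noise) * m)
        mem <- mem[order(d2[mem, j])[seq_len(keep)]]
      }
      centroids[j, ] <- colMeans(x[mem, , drop = FALSE])
    }
  }
  list(labels = labels, centroids = centroids, iterations = iter,
       history = history)
}

# k-means++ seeding: first center uniform, subsequent centers with
# probability proportional to the squared distance to the nearest chosen
# center. Deterministic under `seed`.
.kmeanspp <- function(x, k, seed) {
  n <- nrow(x)
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(n, 1L)
    d2 <- .dist2(x, x[idx, , drop = FALSE])[, 1L]
    while (length(idx) < k) {
      nxt <- if (sum(d2) <= 0)
        sample(setdiff(seq_len(n), idx), 1L)
      else
        sample.int(n, 1L, prob = d2)
      idx <- c(idx, nxt)
      d2 <- pmin(d2, .dist2(x, x[nxt, , drop = FALSE])[, 1L])
    }
  })
  x[idx, , drop = FALSE]
}

.as_feature_matrix <- function(features) {
  if (inherits(features, "embedding_set")) features <- features$features
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("obj%06d", seq_len(nrow(features)))
  features
}

#' Exhaustive k-means baseline
#'
#' Standard Lloyd iteration with Euclidean distance, k-means++ seeding and
#' farthest-point re-seeding of empty clusters. Every object is assigned; the
#' result is a deterministic function of `(features, k, seed)`. This is the
#' baseline that [shrunken_kmeans()] and [pl_kmeans()] build on.
#'
#' @param features Numeric matrix (rows are objects, rownames are ids) or an
#'   [embedding_set].
#' @param k Number of clusters, at most the number of objects.
#' @param init_centroids Optional `k x d` matrix of starting centroids;
#'   k-means++ seeding is used when absent.
#' @param seed Integer seed for the seeding step.
#' @param max_iter Maximum number of Lloyd iterations (default 100).
#' @return A [partial_assignment] with every object assigned; cluster ids are
#'   `c1 ... ck`.
#' @export
kmeans_base <- function(features, k, init_centroids = NULL, seed = 1,
                        max_iter = 100) {
  x <- .as_feature_matrix(features)
  if (!.is_count(k) || k > nrow(x))
    .stopf("`k` must be a positive integer <= n = %d", nrow(x))
  centroids <- if (is.null(init_centroids))
    .kmeanspp(x, k, seed) else as.matrix(init_centroids)
  if (nrow(centroids) != k || ncol(centroids) != ncol(x))
    .stopf("`init_centroids` must be a %d x %d matrix", k, ncol(x))
  fit <- .lloyd(x, k, centroids, max_iter = max_iter)
  ids <- sprintf("c%d", seq_len(k))
  keep <- sort(unique(fit$labels))
  cluster_of <- ids[fit$labels]
  names(cluster_of) <- rownames(x)
  centroids <- fit$centroids[keep, , drop = FALSE]
  rownames(centroids) <- ids[keep]
  out <- partial_assignment(cluster_of, centroids)
  attr(out, "iterations") <- fit$iterations
  out
}

#' Shrink clusters to their core
#'
#' For each cluster of size `m`, only the `max(1, ceiling(p_core * m))`
#' members closest to the cluster centroid keep their label (distance ties
#' broken by ascending object id); all other members become unassigned.
#' Centroids are left untouched. With `p_core = 1` the assignment is
#' returned unchanged.
#'
#' @param assignment A [partial_assignment]; centroids are computed as member
#'   means when absent.
#' @param features Feature matrix with rownames covering the object ids.
#' @param p_core Retained core quantile in `(0, 1]`.
#' @return A [partial_assignment] with the same centroids and shrunken
#'   membership.
#' @export
shrink_clusters <- function(assignment, features, p_core) {
  stopifnot(inherits(assignment, "partial_assignment"))
  if (!.is_prop(p_core, lo_open = TRUE))
    .stopf("invalid `p_core`: must be in (0, 1]")
  features <- .as_feature_matrix(features)
  cents <- assignment$centroids
  if (is.null(cents)) cents <- compute_centroids(assignment, features)
  cluster_of <- assignment$cluster_of
  for (cid in names(cluster_members(assignment))) {
    mem <- names(cluster_of)[!is.na(cluster_of) & cluster_of == cid]
    m <- length(mem)
    nk <- max(1L, ceiling(p_core * m))
    if (nk >= m) next
    d2 <- .dist2(features[mem, , drop = FALSE],
                 cents[cid, , drop = FALSE])[, 1L]
    keep <- mem[order(d2, mem)][seq_len(nk)]
    cluster_of[setdiff(mem, keep)] <- NA_character_
  }
  partial_assignment(cluster_of, assignment$centroids)
}

#' Shrunken k-means
#'
#' Partitions the dataset with [kmeans_base()] and then reduces every cluster
#' to its core with [shrink_clusters()]: only the fraction `p_core` of
#' members closest to their centroid keep their label, the rest is returned
#' to the unclustered pool. With `p_core = 1` this is identical to plain
#' k-means. Defaults (`k = 1000`, `p_core = 0.01`) suit datasets of around a
#' million objects; scale `k` down to roughly the expected class count for
#' small data.
#'
#' @inheritParams kmeans_base
#' @param p_core Retained core quantile in `(0, 1]` (default 0.01).
#' @return A [partial_assignment].
#' @export
shrunken_kmeans <- function(features, k = 1000, p_core = 0.01, seed = 1,
                            max_iter = 100) {
  x <- .as_feature_matrix(features)
  base <- kmeans_base(x, k, seed = seed, max_iter = max_iter)
  out <- shrink_clusters(base, x, p_core)
  attr(out, "iterations") <- attr(base, "iterations")
  out
}

#' Partially labeled k-means
#'
#' A constrained Lloyd iteration that folds the feedback of earlier
#' validation/growing rounds into the clustering: members of validated
#' clusters keep their label throughout (positive information); free objects
#' are assigned to the nearest centroid among the clusters they were not
#' rejected for (negative information, the cannot-link rejection relation);
#' each centroid update uses only the `1 - p_noise` fraction of members
#' closest to the previous centroid. The total number of clusters follows
#' the schedule `k0 + outer_iteration * k_delta`; new clusters are seeded by
#' k-means++ over the free objects and, after convergence, shrunken to their
#' `p_core` core ([shrink_clusters()]). Validated clusters are returned
#' intact and may absorb so-far unclustered objects ("late assignment").
#'
#' Objects rejected for every cluster stay unassigned. If the schedule asks
#' for more new clusters than there are free objects, the count is clamped
#' with a warning.
#'
#' @inheritParams kmeans_base
#' @param prior A [partial_assignment] whose assigned clusters are the
#'   validated clusters (or `NULL` for none).
#' @param rejections A [rejection_store()] (or `NULL`); must be consistent
#'   with `prior` (no object rejected for its own validated cluster).
#' @param k0 Initial cluster count of the schedule (default 500).
#' @param k_delta Cluster count increment per outer iteration (default 100).
#' @param p_noise Fraction in `[0, 1)` of most-distant members excluded from
#'   centroid updates (default 0.1).
#' @param p_core Retained core quantile applied to newly formed clusters
#'   (default 0.01).
#' @param outer_iteration Zero-based index of the annotation iteration;
#'   fixes the requested cluster count.
#' @param keep_history Record the centroids and constrained assignment of
#'   every Lloyd step in attribute `"history"` (for auditing against an
#'   independent nearest-centroid computation).
#' @return A [partial_assignment] over all objects; validated cluster ids are
#'   preserved, new clusters get fresh ids. Attribute `"k_requested"` holds
#'   the schedule value before clamping.
#' @export
pl_kmeans <- function(features, prior = NULL, rejections = NULL, k0 = 500,
                      k_delta = 100, p_noise = 0.1, p_core = 0.01,
                      outer_iteration = 0, seed = 1, max_iter = 100,
                      keep_history = FALSE) {
  x <- .as_feature_matrix(features)
  n <- nrow(x)
  if (!.is_count(k0)) .stopf("invalid `k0`: must be a positive integer")
  if (!(is.numeric(k_delta) && k_delta >= 0 && k_delta == floor(k_delta)))
    .stopf("invalid `k_delta`: must be a non-negative integer")
  if (!.is_prop(p_noise, hi_open = TRUE))
    .stopf("invalid `p_noise`: must be in [0, 1)")
  if (!.is_prop(p_core, lo_open = TRUE))
    .stopf("invalid `p_core`: must be in (0, 1]")
  k_requested <- as.integer(k0 + outer_iteration * k_delta)

  prior_of <- if (is.null(prior)) {
    stats::setNames(rep(NA_character_, n), rownames(x))
  } else {
    stopifnot(inherits(prior, "partial_assignment"))
    prior$cluster_of[rownames(x)]
  }
  v_ids <- sort(unique(prior_of[!is.na(prior_of)]))
  if (!is.null(rejections)) {
    for (id in names(prior_of)[!is.na(prior_of)]) {
      if (rs_rejected(rejections, id, prior_of[[id]]))
        .stopf("object '%s' is both assigned to and rejected for cluster '%s'",
               id, prior_of[[id]])
    }
  }

  free <- which(is.na(prior_of))
  n_new <- max(0L, k_requested - length(v_ids))
  if (n_new > length(free)) {
    .warnf("requested %d new clusters but only %d free objects; clamping",
           n_new, length(free))
    n_new <- length(free)
  }
  k <- length(v_ids) + n_new
  if (k == 0L) .stopf("no clusters requested and no validated clusters given")

  # column layout: validated clusters first, then new clusters
  new_ids <- character(0)
  if (n_new > 0L) {
    stem <- "new"
    while (any(sprintf("%s%03d", stem, seq_len(n_new)) %in% v_ids))
      stem <- paste0(stem, "_")
    new_ids <- sprintf("%s%03d", stem, seq_len(n_new))
  }
  all_ids <- c(v_ids, new_ids)

  centroids <- matrix(0, k, ncol(x))
  if (length(v_ids) > 0L) {
    pa_prior <- partial_assignment(prior_of)
    vc <- compute_centroids(pa_prior, x)
    centroids[seq_along(v_ids), ] <- vc[v_ids, , drop = FALSE]
  }
  if (n_new > 0L)
    centroids[length(v_ids) + seq_len(n_new), ] <-
      .kmeanspp(x[free, , drop = FALSE], n_new, seed)

  frozen <- match(prior_of, v_ids)
  reject <- NULL
  if (!is.null(rejections)) {
    rdf <- as.data.frame(rejections)
    rdf <- rdf[rdf$object_id %in% rownames(x) & rdf$cluster_id %in% all_ids, ,
               drop = FALSE]
    if (nrow(rdf) > 0)
      reject <- cbind(match(rdf$object_id, rownames(x)),
                      match(rdf$cluster_id, all_ids))
  }

  fit <- .lloyd(x, k, centroids, frozen = frozen, reject = reject,
                p_noise = p_noise, max_iter = max_iter,
                keep_history = keep_history)

  cluster_of <- ifelse(is.na(fit$labels), NA_character_, all_ids[fit$labels])
  names(cluster_of) <- rownames(x)
  present <- all_ids[sort(unique(fit$labels[!is.na(fit$labels)]))]
  cents <- fit$centroids
  rownames(cents) <- all_ids
  out <- partial_assignment(cluster_of, cents[present, , drop = FALSE])

  # shrink newly formed clusters only; validated clusters stay intact
  if (p_core < 1 && length(intersect(present, new_ids)) > 0L) {
    shrunk <- shrink_clusters(out, x, p_core)
    keep_new <- is.na(out$cluster_of) | out$cluster_of %in% v_ids
    merged <- ifelse(keep_new, out$cluster_of, shrunk$cluster_of)
    names(merged) <- names(out$cluster_of)
    out <- partial_assignment(merged, out$centroids)
  }

  attr(out, "k_requested") <- k_requested
  attr(out, "iterations") <- fit$iterations
  if (keep_history) {
    attr(out, "history") <- lapply(fit$history, function(h) {
      asg <- ifelse(is.na(h$assignment), NA_character_, all_ids[h$assignment])
      names(asg) <- rownames(x)
      cen <- h$centroids
      rownames(cen) <- all_ids
      list(centroids = cen, assignment = asg)
    })
  }
  out
}
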