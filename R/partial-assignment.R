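#' Construct a partial assignment
#'
#' A partial assignment maps every object of a dataset to either a cluster id
#' or `NA` (unassigned). Unlike a partition, clusterers in this package need
#' not label every object: only the densest regions are labelled and the
#' rest stays in the unclustered pool.
#'
#' @param cluster_of Character vector named by object id; values are cluster
#'   ids or `NA` for unassigned objects.
#' @param centroids Optional numeric matrix of cluster centroids with
#'   rownames equal to the cluster ids (computed on demand from member means
#'   when absent, see [compute_centroids()]).
#' @return An object of class `partial_assignment`.
#' @export
partial_assignment <- function(cluster_of, centroids = NULL) {
  cluster_of <- vapply(cluster_of, as.character, character(1))
  if (is.null(names(cluster_of)) || anyDuplicated(names(cluster_of)))
    .stopf("`cluster_of` must be named by unique object ids")
  cl <- unique(cluster_of[!is.na(cluster_of)])
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    if (is.null(rownames(centroids)) || !all(cl %in% rownames(centroids)))
      .stopf("`centroids` rownames must cover every assigned cluster id")
  }
  structure(list(cluster_of = cluster_of, centroids = centroids),
            class = "partial_assignment")
}

#' @export
print.partial_assignment <- function(x, ...) {
  n <- length(x$cluster_of)
  a <- sum(!is.na(x$cluster_of))
  cat(sprintf("<partial_assignment> %d/%d objects assigned to %d clusters\n",
              a, n, length(unique(stats::na.omit(x$cluster_of)))))
  invisible(x)
}

#' List members of each cluster
#'
#' @param assignment A [partial_assignment].
#' @return Named list mapping cluster id to a character vector of object ids.
#' @export
cluster_members <- function(assignment) {
  co <- assignment$cluster_of
  co <- co[!is.na(co)]
  split(names(co), co)
}

#' Compute cluster centroids as member means
#'
#' @param assignment A [partial_assignment].
#' @param features Feature matrix with rownames covering the object ids.
#' @return Matrix of centroids, rownames are the cluster ids.
#' @export
compute_centroids <- function(assignment, features) {
  mem <- cluster_members(assignment)
  if (length(mem) == 0L) return(matrix(numeric(0), 0, ncol(features)))
  out <- t(vapply(mem, function(ids)
    colMeans(features[ids, , drop = FALSE]), numeric(ncol(features))))
  rownames(out) <- names(mem)
  out
}

#' Create a rejection store
#'
#' The rejection store is a sparse boolean relation over (object, cluster)
#' pairs: entry (i, j) is `TRUE` when object i was found not to belong to
#' cluster j during validation or growing (the cannot-link information that
#' partially labeled k-means consumes). Unset pairs are `FALSE`. The store
#' uses reference semantics (an environment) so a simulation can update it
#' in place; use [rs_clone()] to copy.
#'
#' @return An object of class `rejection_store`.
#' @export
rejection_store <- function() {
  structure(new.env(parent = emptyenv()), class = "rejection_store")
}

#' Record rejections of objects for a cluster
#'
#' @param store A [rejection_store()].
#' @param object_ids Character vector of object ids.
#' @param cluster_id Single cluster id.
#' @return The store, invisibly (updated in place).
#' @export
rs_add <- function(store, object_ids, cluster_id) {
  stopifnot(inherits(store, "rejection_store"), length(cluster_id) == 1L)
  for (id in object_ids) {
    cur <- if (exists(id, envir = store, inherits = FALSE))
      get(id, envir = store) else character(0)
    if (!(cluster_id %in% cur))
      assign(id, c(cur, cluster_id), envir = store)
  }
  invisible(store)
}

#' Query a rejection
#'
#' @inheritParams rs_add
#' @param object_id Single object id.
#' @return `TRUE` if the pair was recorded, else `FALSE`.
#' @export
rs_rejected <- function(store, object_id, cluster_id) {
  cluster_id %in% rs_clusters(store, object_id)
}

#' Clusters an object was rejected for
#'
#' @inheritParams rs_rejected
#' @return Character vector of cluster ids (possibly empty).
#' @export
rs_clusters <- function(store, object_id) {
  if (exists(object_id, envir = store, inherits = FALSE))
    get(object_id, envir = store) else character(0)
}

#' Copy a rejection store
#'
#' @inheritParams rs_add
#' @return An independent [rejection_store()] with the same content.
#' @export
rs_clone <- function(store) {
  out <- rejection_store()
  for (id in ls(store)) assign(id, get(id, envir = store), envir = out)
  out
}

#' @export
as.data.frame.rejection_store <- function(x, ...) {
  ids <- ls(x)
  if (length(ids) == 0L)
    return(data.frame(object_id = character(0), cluster_id = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(ids, function(id)
    data.frame(object_id = id, cluster_id = get(id, envir = x),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$object_id, out$cluster_id), , drop = FALSE]
}

#' @export
print.rejection_store <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<rejection_store> %d (object, cluster) pairs over %d objects\n",
              nrow(df), length(unique(df$object_id))))
  invisible(x)
}
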