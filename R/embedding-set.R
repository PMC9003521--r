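#' Construct an embedding set
#'
#' An embedding set bundles an `n x d` feature matrix (image representation
#' coordinates, dimensionless) with unique object identifiers and, optionally,
#' one gold-standard label per object. It is the common input container for
#' the clusterers, the annotation simulator and the metrics.
#'
#' @param features Numeric matrix, one row per object. All values must be
#'   finite.
#' @param object_ids Character vector of unique identifiers, one per row.
#'   Defaults to the rownames of `features`.
#' @param gold_labels Optional character vector of non-empty labels, length
#'   `n`, in row order.
#' @return An object of class `embedding_set`: a list with elements
#'   `object_ids`, `features` (rownames set to the ids) and `gold_labels`
#'   (named by id, or `NULL`).
#' @examples
#' es <- embedding_set(matrix(rnorm(20), 10, 2),
#'                     object_ids = sprintf("o%02d", 1:10),
#'                     gold_labels = rep(c("a", "b"), each = 5))
#' es
#' @export
embedding_set <- function(features, object_ids = rownames(features),
                          gold_labels = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) || nrow(features) < 1L)
    .stopf("`features` must be a numeric matrix with at least one row")
  if (any(!is.finite(features))) {
    bad <- which(rowSums(!is.finite(features)) > 0)[1L]
    .stopf("non-finite feature value in row %d", bad)
  }
  if (is.null(object_ids))
    object_ids <- sprintf("obj%06d", seq_len(nrow(features)))
  object_ids <- as.character(object_ids)
  if (length(object_ids) != nrow(features))
    .stopf("%d object ids for %d feature rows", length(object_ids), nrow(features))
  if (anyDuplicated(object_ids))
    .stopf("object ids are not unique (first duplicate: '%s')",
           object_ids[duplicated(object_ids)][1L])
  rownames(features) <- object_ids
  if (!is.null(gold_labels)) {
    gold_labels <- as.character(gold_labels)
    if (length(gold_labels) != nrow(features))
      .stopf("%d gold labels for %d objects", length(gold_labels), nrow(features))
    if (any(is.na(gold_labels) | !nzchar(gold_labels)))
      .stopf("gold labels must be non-empty")
    names(gold_labels) <- object_ids
  }
  structure(list(object_ids = object_ids, features = features,
                 gold_labels = gold_labels),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d objects x %d dimensions\n",
              nrow(x$features), ncol(x$features)))
  if (!is.null(x$gold_labels))
    cat(sprintf("  gold labels: %d classes\n", length(unique(x$gold_labels))))
  invisible(x)
}

#' Generate a synthetic embedding dataset
#'
#' Draws a mixture of compact, isotropic Gaussian classes in `d` dimensions,
#' emulating the premise that a good representation space holds dense,
#' well-separated, spherical clusters of equal variance. Class centers are
#' drawn from a standard normal and rescaled so that the minimum pairwise
#' center distance is exactly `separation` times the within-class standard
#' deviation (fixed at 1), making the separation regime a controlled
#' parameter. Optionally a fraction of classes is split into two
#' half-separated sub-classes sharing a parent label prefix (emulating
#' interchangeable labels), and diffuse background noise points are added,
#' each with a unique gold label, drawn uniformly from the bounding box of
#' the centers inflated by twice the within-class standard deviation.
#'
#' @param n_classes Number of classes (default 20).
#' @param objects_per_class Scalar or length-`n_classes` vector of class
#'   sizes (default 100); a vector models class imbalance.
#' @param d Dimensionality of the representation space (default 32).
#' @param separation Ratio of minimum between-class center distance to the
#'   within-class standard deviation; must be positive (default 10).
#' @param noise_fraction Proportion in `[0, 1)` of the final dataset made up
#'   of diffuse noise points (default 0).
#' @param subclass_split_fraction Proportion in `[0, 1]` of classes split
#'   into two gold sub-labels `<class>/a`, `<class>/b` (default 0).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An [embedding_set] with gold labels. Noise points carry labels
#'   `noise000001, ...`; sub-class labels share the parent class prefix.
#' @examples
#' es <- generate_embeddings(n_classes = 3, objects_per_class = 20, d = 4,
#'                           separation = 8, seed = 1)
#' table(es$gold_labels)
#' @export
generate_embeddings <- function(n_classes = 20, objects_per_class = 100,
                                d = 32, separation = 10, noise_fraction = 0,
                                subclass_split_fraction = 0, seed = 1) {
  if (!.is_count(n_classes)) .stopf("invalid `n_classes`: must be a positive integer")
  if (!.is_count(d)) .stopf("invalid `d`: must be a positive integer")
  if (!(is.numeric(separation) && length(separation) == 1L && is.finite(separation) && separation > 0))
    .stopf("invalid `separation`: must be > 0")
  if (!.is_prop(noise_fraction, hi_open = TRUE))
    .stopf("invalid `noise_fraction`: must be in [0, 1)")
  if (!.is_prop(subclass_split_fraction))
    .stopf("invalid `subclass_split_fraction`: must be in [0, 1]")
  sizes <- if (length(objects_per_class) == 1L)
    rep(objects_per_class, n_classes) else objects_per_class
  if (length(sizes) != n_classes || !all(vapply(sizes, .is_count, TRUE)))
    .stopf("invalid `objects_per_class`: scalar or length-%d vector of positive integers",
           n_classes)
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed)))
    .stopf("invalid `seed`: must be a single number")

  withr::with_seed(as.integer(seed), {
    sigma <- 1 # within-class standard deviation; separation is relative to it
    centers <- matrix(stats::rnorm(n_classes * d), n_classes, d)
    if (n_classes > 1L) {
      dmin <- min(stats::dist(centers))
      if (dmin <= 0) .stopf("degenerate center draw; change `seed`")
      centers <- centers * (separation * sigma / dmin)
    }
    n_split <- floor(subclass_split_fraction * n_classes)
    class_names <- sprintf("class%03d", seq_len(n_classes))

    feats <- vector("list", n_classes)
    labs <- vector("list", n_classes)
    for (ci in seq_len(n_classes)) {
      m <- sizes[ci]
      pts <- matrix(stats::rnorm(m * d, sd = sigma), m, d)
      if (ci <= n_split) {
        # two half-separated sub-classes: sub-centers separation/2 apart
        u <- stats::rnorm(d)
        u <- u / sqrt(sum(u^2)) * (separation * sigma / 4)
        half <- rep(c(1, -1), length.out = m)
        pts <- pts + rep(half, times = d) * matrix(u, m, d, byrow = TRUE) +
          matrix(centers[ci, ], m, d, byrow = TRUE)
        labs[[ci]] <- paste0(class_names[ci], ifelse(half > 0, "/a", "/b"))
      } else {
        pts <- pts + matrix(centers[ci, ], m, d, byrow = TRUE)
        labs[[ci]] <- rep(class_names[ci], m)
      }
      feats[[ci]] <- pts
    }
    features <- do.call(rbind, feats)
    gold <- unlist(labs, use.names = FALSE)

    n_signal <- nrow(features)
    n_noise <- round(n_signal * noise_fraction / (1 - noise_fraction))
    if (n_noise > 0) {
      lo <- apply(centers, 2, min) - 2 * sigma
      hi <- apply(centers, 2, max) + 2 * sigma
      noise <- sapply(seq_len(d), function(j)
        stats::runif(n_noise, lo[j], hi[j]))
      noise <- matrix(noise, nrow = n_noise, ncol = d)
      features <- rbind(features, noise)
      gold <- c(gold, sprintf("noise%06d", seq_len(n_noise)))
    }
    embedding_set(features,
                  object_ids = sprintf("obj%06d", seq_len(nrow(features))),
                  gold_labels = gold)
  })
}

#' Reduce feature dimensionality by PCA
#'
#' Mean-centers the input and projects it onto its first `d` principal
#' components (no whitening: component scores keep their natural scale, so
#' Euclidean geometry used downstream is a rotation of the original when
#' `d` equals the input dimensionality).
#'
#' @param features Numeric matrix (`n x D`) or an [embedding_set].
#' @param d Target dimensionality, at most `min(n, D)`.
#' @return A matrix (or [embedding_set], matching the input) of scores with
#'   `d` columns, ordered by decreasing explained variance. The per-component
#'   variances are attached as attribute `"explained_variance"` (on the
#'   matrix).
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' y <- pca_reduce(x, 2)
#' attr(y, "explained_variance")
#' @export
pca_reduce <- function(features, d) {
  if (inherits(features, "embedding_set")) {
    red <- pca_reduce(features$features, d)
    return(embedding_set(red, object_ids = features$object_ids,
                         gold_labels = features$gold_labels))
  }
  features <- as.matrix(features)
  if (!.is_count(d) || d > min(dim(features)))
    .stopf("target dimensionality d=%s exceeds min(n, D) = %d",
           as.character(d), min(dim(features)))
  p <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  scores <- p$x[, seq_len(d), drop = FALSE]
  rownames(scores) <- rownames(features)
  attr(scores, "explained_variance") <- p$sdev[seq_len(d)]^2
  scores
}

#' Stratified train/test split of an embedding set
#'
#' Splits by gold label so that each class is represented on both sides in
#' proportion `test_fraction` (rounded). Classes with fewer than two members
#' cannot be stratified and are placed wholly in the training set with a
#' warning.
#'
#' @param dataset An [embedding_set] with gold labels.
#' @param test_fraction Proportion in `(0, 1)` assigned to the test side.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list with elements `train` and `test`, both [embedding_set]s
#'   with disjoint ids whose union is the input.
#' @export
split_train_test <- function(dataset, test_fraction, seed = 1) {
  stopifnot(inherits(dataset, "embedding_set"))
  if (is.null(dataset$gold_labels))
    .stopf("`split_train_test()` requires gold labels")
  if (!.is_prop(test_fraction, lo_open = TRUE, hi_open = TRUE))
    .stopf("invalid `test_fraction`: must be in (0, 1)")
  gold <- dataset$gold_labels
  test_ids <- character(0)
  withr::with_seed(as.integer(seed), {
    for (lab in sort(unique(gold))) {
      ids <- names(gold)[gold == lab]
      m <- length(ids)
      if (m < 2L) {
        .warnf("class '%s' has %d member(s); placed wholly in train", lab, m)
        next
      }
      n_test <- min(m - 1L, max(1L, round(test_fraction * m)))
      test_ids <- c(test_ids, sample(ids, n_test))
    }
  })
  take <- function(ids) embedding_set(
    dataset$features[ids, , drop = FALSE], object_ids = ids,
    gold_labels = gold[ids])
  train_ids <- setdiff(dataset$object_ids, test_ids)
  list(train = take(train_ids), test = take(test_ids))
}
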