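# Independent oracles used to check the implementation. Deliberately written
# as naive double loops so they share no code path with the package.

# Nearest-centroid prediction by exhaustive search.
oracle_ncc_predict <- function(train_features, train_labels, test_features) {
  classes <- sort(unique(train_labels))
  pred <- character(nrow(test_features))
  for (i in seq_len(nrow(test_features))) {
    best <- Inf
    for (cl in classes) {
      cen <- colMeans(train_features[train_labels == cl, , drop = FALSE])
      d <- sum((test_features[i, ] - cen)^2)
      if (d < best) { best <- d; pred[i] <- cl }
    }
  }
  pred
}

# Constrained nearest-center assignment: frozen labels win, rejected
# clusters are skipped, objects rejected everywhere stay NA. Cluster order
# ties resolve to the earlier cluster id in `cluster_ids`.
oracle_constrained_assign <- function(features, centroids, cluster_ids,
                                      frozen, reject_df) {
  ids <- rownames(features)
  out <- stats::setNames(rep(NA_character_, nrow(features)), ids)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (!is.null(frozen) && !is.na(frozen[id])) { out[id] <- frozen[[id]]; next }
    best <- Inf
    for (j in seq_along(cluster_ids)) {
      cid <- cluster_ids[j]
      if (nrow(reject_df) > 0 &&
          any(reject_df$object_id == id & reject_df$cluster_id == cid)) next
      d <- sum((features[i, ] - centroids[j, ])^2)
      if (d < best) { best <- d; out[id] <- cid }
    }
  }
  out
}

# Linear scan for the first non-fitting batch.
oracle_first_rejected <- function(accept, n) {
  for (i in seq_len(n)) if (!accept(i)) return(i)
  n + 1L
}

# Recount mean per-cluster precision from a raw assignment table.
oracle_precision_recount <- function(cluster_of, gold) {
  cids <- unique(cluster_of[!is.na(cluster_of)])
  purities <- numeric(0)
  for (cid in cids) {
    labs <- gold[names(cluster_of)[!is.na(cluster_of) & cluster_of == cid]]
    counts <- table(labs)
    purities <- c(purities, max(counts) / length(labs))
  }
  mean(purities)
}

# Canonical representation of a partition for permutation-invariant
# comparison: the sorted set of sorted member lists.
partition_signature <- function(cluster_of) {
  co <- cluster_of[!is.na(cluster_of)]
  sort(unname(vapply(split(names(co), co),
                     function(m) paste(sort(m), collapse = ","), "")))
}

expect_same_partition <- function(a, b) {
  expect_identical(sort(names(a)[is.na(a)]), sort(names(b)[is.na(b)]))
  expect_identical(partition_signature(a), partition_signature(b))
}

# A clean multi-blob dataset with explicit geometry, used when the
# generator itself is under test elsewhere.
make_blobs <- function(centers, n_per, sd = 0.2, seed = 1, labels = NULL) {
  withr::with_seed(seed, {
    k <- nrow(centers)
    pts <- lapply(seq_len(k), function(j)
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[j, ], n_per, ncol(centers), byrow = TRUE))
    x <- do.call(rbind, pts)
    rownames(x) <- sprintf("b%04d", seq_len(nrow(x)))
    lab <- rep(labels %||% sprintf("blob%d", seq_len(k)), each = n_per)
    embedding_set(x, gold_labels = lab)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a simulation state with one validated cluster placed by hand.
state_with_cluster <- function(dataset, member_ids, majority) {
  st <- sim_state(dataset)
  st$clusters[["c00001"]] <- list(
    members = member_ids,
    centroid = colMeans(dataset$features[member_ids, , drop = FALSE]),
    majority = majority)
  st$counter <- 1L
  st$pool <- setdiff(st$pool, member_ids)
  st
}
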