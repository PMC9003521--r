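test_that("kmeans_base separates well-separated blobs and converges to nearest centers", {
  es <- make_blobs(rbind(c(0, 0), c(20, 0)), n_per = 50, seed = 4)
  pa <- kmeans_base(es$features, k = 2, seed = 1)
  expect_same_partition(pa$cluster_of,
                        stats::setNames(unname(es$gold_labels), es$object_ids))
  # after convergence every point sits with its nearest final centroid
  for (id in es$object_ids) {
    d <- apply(pa$centroids, 1, function(c) sum((es$features[id, ] - c)^2))
    expect_identical(unname(pa$cluster_of[id]), rownames(pa$centroids)[which.min(d)])
  }
})

test_that("kmeans_base degenerate cases: identical points, k = n, determinism", {
  x <- matrix(1, 5, 3, dimnames = list(letters[1:5], NULL))
  pa <- kmeans_base(x, k = 1)
  expect_equal(unname(pa$centroids[1, ]), c(1, 1, 1))

  set.seed(9)
  y <- matrix(rnorm(12, sd = 5), 6, 2, dimnames = list(letters[1:6], NULL))
  pan <- kmeans_base(y, k = 6, seed = 2)
  expect_length(unique(pan$cluster_of), 6)
  within <- vapply(names(pan$cluster_of), function(id)
    sum((y[id, ] - pan$centroids[pan$cluster_of[id], ])^2), 0)
  expect_equal(unname(within), rep(0, 6), tolerance = 1e-12)

  expect_error(kmeans_base(y, k = 7), "<= n")
  expect_identical(kmeans_base(y, 3, seed = 5)$cluster_of,
                   kmeans_base(y, 3, seed = 5)$cluster_of)
})

test_that("kmeans_base agrees with stats::kmeans on easy geometry", {
  es <- make_blobs(rbind(c(0, 0), c(15, 0), c(0, 15)), n_per = 40, seed = 6)
  ours <- kmeans_base(es$features, k = 3, seed = 1)
  ref <- stats::kmeans(es$features, centers = 3, nstart = 10)
  expect_identical(partition_signature(ours$cluster_of),
                   partition_signature(stats::setNames(
                     as.character(ref$cluster), es$object_ids)))
})

test_that("shrink_clusters retains max(1, ceiling(p_core * m)) nearest members", {
  # 10 collinear points; centroid between them
  x <- cbind(1:10, 0)
  rownames(x) <- sprintf("p%02d", 1:10)
  pa <- partial_assignment(stats::setNames(rep("c1", 10), rownames(x)),
                           centroids = matrix(c(5.5, 0), 1,
                                              dimnames = list("c1", NULL)))
  sh <- shrink_clusters(pa, x, 0.5)
  kept <- names(sh$cluster_of)[!is.na(sh$cluster_of)]
  expect_setequal(kept, sprintf("p%02d", 3:7)) # 5 closest to 5.5, tie at 3/8 -> id order
  expect_identical(shrink_clusters(pa, x, 1), pa) # identity at p_core = 1

  x7 <- cbind(1:7, 0); rownames(x7) <- sprintf("q%d", 1:7)
  pa7 <- partial_assignment(stats::setNames(rep("c1", 7), rownames(x7)))
  sh7 <- shrink_clusters(pa7, x7, 0.01)
  expect_equal(sum(!is.na(sh7$cluster_of)), 1) # max(1, ceiling(0.07))
})

test_that("distance ties in shrinkage break by ascending object id", {
  # four points equidistant from the centroid at the origin
  x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  rownames(x) <- c("d", "a", "c", "b")
  pa <- partial_assignment(stats::setNames(rep("c1", 4), rownames(x)),
                           centroids = matrix(0, 1, 2,
                                              dimnames = list("c1", NULL)))
  sh <- shrink_clusters(pa, x, 0.5)
  expect_setequal(names(sh$cluster_of)[!is.na(sh$cluster_of)], c("a", "b"))
})

test_that("shrinkage never increases a cluster's maximum member-centroid distance", {
  set.seed(31)
  for (rep in 1:5) {
    x <- matrix(rnorm(60 * 3), 60)
    rownames(x) <- sprintf("r%02d", 1:60)
    pa <- kmeans_base(x, k = 4, seed = rep)
    sh <- shrink_clusters(pa, x, 0.3)
    for (cid in rownames(pa$centroids)) {
      radius <- function(p) {
        mem <- names(p$cluster_of)[!is.na(p$cluster_of) & p$cluster_of == cid]
        max(sqrt(rowSums((x[mem, , drop = FALSE] -
          matrix(pa$centroids[cid, ], length(mem), 3, byrow = TRUE))^2)))
      }
      expect_lte(radius(sh), radius(pa))
    }
  }
})

test_that("shrunken k-means retains exact per-cluster counts", {
  centers <- rbind(c(0, 0), c(30, 0), c(0, 30), c(30, 30))
  es <- make_blobs(centers, n_per = 100, seed = 8)
  pa <- shrunken_kmeans(es$features, k = 4, p_core = 0.1, seed = 1)
  sizes <- lengths(cluster_members(pa))
  expect_equal(unname(sizes), rep(10, 4))
  expect_equal(sum(is.na(pa$cluster_of)), 360)

  # identity at p_core = 1
  expect_identical(shrunken_kmeans(es$features, k = 4, p_core = 1, seed = 2)$cluster_of,
                   kmeans_base(es$features, k = 4, seed = 2)$cluster_of)

  # singleton floor at n = k
  x <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], NULL))
  ps <- shrunken_kmeans(x, k = 5, p_core = 0.01, seed = 1)
  expect_false(anyNA(ps$cluster_of))
})

test_that("pl_kmeans with vacuous constraints equals the k-means baseline", {
  es <- make_blobs(rbind(c(0, 0), c(12, 0), c(6, 10)), n_per = 30, seed = 12)
  base <- kmeans_base(es$features, k = 3, seed = 7)
  pl <- pl_kmeans(es$features, prior = NULL, rejections = NULL, k0 = 3,
                  p_noise = 0, p_core = 1, seed = 7)
  expect_same_partition(base$cluster_of, pl$cluster_of)
})

test_that("rejections push an object to its nearest non-rejected centroid", {
  x <- rbind(c(0, 0), c(0, 0.1), c(0, -0.1),
             c(10, 0), c(10, 0.1), c(10, -0.1),
             c(1, 0)) # free point, much nearer cluster A
  rownames(x) <- c("a1", "a2", "a3", "b1", "b2", "b3", "free")
  prior <- partial_assignment(stats::setNames(
    c("A", "A", "A", "B", "B", "B", NA), rownames(x)))
  no_rej <- pl_kmeans(x, prior, NULL, k0 = 2, p_noise = 0, p_core = 1, seed = 1)
  expect_identical(unname(no_rej$cluster_of["free"]), "A")

  st <- rejection_store()
  rs_add(st, "free", "A")
  rej <- pl_kmeans(x, prior, st, k0 = 2, p_noise = 0, p_core = 1, seed = 1)
  expect_identical(unname(rej$cluster_of["free"]), "B")

  rs_add(st, "free", "B")
  all_rej <- pl_kmeans(x, prior, st, k0 = 2, p_noise = 0, p_core = 1, seed = 1)
  expect_true(is.na(all_rej$cluster_of["free"]))
})

test_that("validated labels are frozen even against the geometry", {
  x <- rbind(c(0, 0), c(0.2, 0), c(9, 0), # a3 sits next to cluster B
             c(10, 0), c(10.2, 0))
  rownames(x) <- c("a1", "a2", "a3", "b1", "b2")
  prior <- partial_assignment(stats::setNames(
    c("A", "A", "A", "B", "B"), rownames(x)))
  out <- pl_kmeans(x, prior, NULL, k0 = 2, p_noise = 0, p_core = 1, seed = 1)
  expect_identical(unname(out$cluster_of["a3"]), "A")
})

test_that("the cluster count schedule and clamping behave as configured", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%02d", 1:20), NULL))
  out <- pl_kmeans(x, k0 = 4, k_delta = 3, outer_iteration = 2, p_core = 1,
                   p_noise = 0, seed = 1)
  expect_identical(attr(out, "k_requested"), 10L)
  expect_warning(
    cl <- pl_kmeans(x, k0 = 50, k_delta = 0, p_core = 1, p_noise = 0, seed = 1),
    "clamping")
  expect_lte(length(cluster_members(cl)), 20)
})

test_that("a prior inconsistent with the rejection store is refused", {
  x <- matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], NULL))
  prior <- partial_assignment(stats::setNames(c("A", "A", NA, NA), letters[1:4]))
  st <- rejection_store()
  rs_add(st, "a", "A")
  expect_error(pl_kmeans(x, prior, st, k0 = 2), "both assigned to and rejected")
})

test_that("every pl_kmeans Lloyd step is a constrained nearest-center assignment", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(30:80, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- sprintf("o%03d", seq_len(n))
    # random validated prior: freeze two small groups
    frozen <- stats::setNames(rep(NA_character_, n), rownames(x))
    frozen[sample(n, 6)] <- rep(c("vA", "vB"), 3)
    prior <- partial_assignment(frozen)
    st <- rejection_store()
    free_ids <- names(frozen)[is.na(frozen)]
    rs_add(st, sample(free_ids, 5), "vA")
    rs_add(st, sample(free_ids, 5), "vB")

    out <- pl_kmeans(x, prior, st, k0 = 4, p_noise = 0.1, p_core = 1,
                     seed = rep, keep_history = TRUE)
    rdf <- as.data.frame(st)
    for (step in attr(out, "history")) {
      want <- oracle_constrained_assign(x, step$centroids,
                                        rownames(step$centroids), frozen, rdf)
      expect_identical(step$assignment, want)
    }
    # no final member violates a rejection record
    for (i in seq_len(nrow(rdf)))
      expect_false(identical(unname(out$cluster_of[rdf$object_id[i]]),
                             rdf$cluster_id[i]))
  }
})
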