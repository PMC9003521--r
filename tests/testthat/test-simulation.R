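test_that("cluster purity follows the majority rule with lexicographic ties", {
  expect_equal(cluster_purity(c("A", "A", "A", "B")),
               list(purity = 0.75, majority_label = "A"))
  expect_equal(cluster_purity(c("B", "B", "A", "A")),
               list(purity = 0.5, majority_label = "A"))
  expect_equal(cluster_purity(rep(c("A", "B"), c(17, 3)))$purity, 0.85)
  expect_error(cluster_purity(character(0)), "empty")
})

make_labelled_set <- function(labels, spread = 1) {
  n <- length(labels)
  withr::with_seed(1, x <- matrix(rnorm(n * 2, sd = spread), n))
  rownames(x) <- sprintf("v%03d", seq_len(n))
  embedding_set(x, gold_labels = labels)
}

test_that("validation accepts, purges and charges clicks as specified", {
  es <- make_labelled_set(rep(c("A", "B"), c(90, 10)))
  st <- sim_state(es)
  st$candidates[["c00001"]] <- es$object_ids
  st <- validate_clusters(st, es$gold_labels, sim_config())
  expect_equal(length(st$clusters[["c00001"]]$members), 90)
  expect_equal(unname(st$clicks[["validation"]]), 11) # 1 accept + 10 removals
  expect_equal(nrow(as.data.frame(st$rejections)), 10)
  expect_setequal(st$pool, es$object_ids[91:100])
  # accepted clusters are pure after validation
  expect_equal(cluster_purity(es$gold_labels[st$clusters[["c00001"]]$members])$purity, 1)
})

test_that("validation deletes heterogeneous clusters for a single click", {
  es <- make_labelled_set(rep(c("A", "B"), each = 10))
  st <- sim_state(es)
  st$candidates[["c00001"]] <- es$object_ids
  st <- validate_clusters(st, es$gold_labels, sim_config())
  expect_length(st$clusters, 0)
  expect_equal(unname(st$clicks[["validation"]]), 1)
  expect_setequal(st$pool, es$object_ids)
  expect_equal(nrow(as.data.frame(st$rejections)), 20)

  # fully pure candidate: 1 click, no rejections
  es2 <- make_labelled_set(rep("A", 15))
  st2 <- sim_state(es2)
  st2$candidates[["c00001"]] <- es2$object_ids
  st2 <- validate_clusters(st2, es2$gold_labels, sim_config())
  expect_equal(unname(st2$clicks[["validation"]]), 1)
  expect_equal(nrow(as.data.frame(st2$rejections)), 0)
})

test_that("late additions to validated clusters are reviewed under the click model", {
  es <- make_labelled_set(rep(c("A", "B"), c(12, 3)))
  st <- state_with_cluster(es, es$object_ids[1:5], "A")
  st$additions[["c00001"]] <- es$object_ids[c(6, 7, 13)] # two A, one B
  st <- validate_clusters(st, es$gold_labels, sim_config())
  expect_setequal(st$clusters[["c00001"]]$members, es$object_ids[1:7])
  expect_equal(unname(st$clicks[["validation"]]), 2) # 1 review + 1 removal
  expect_true(rs_rejected(st$rejections, es$object_ids[13], "c00001"))
})

test_that("exponential search matches a linear-scan oracle within its probe budget", {
  for (b in 1:64) {
    accept <- function(i) i < b
    res <- exponential_search_boundary(accept, 64)
    expect_identical(res$first_rejected, oracle_first_rejected(accept, 64))
    expect_lte(res$n_probes, 2 * ceiling(log2(max(b, 1))) + 2)
  }
  # all batches accepted: doubling clamps to the list end
  res <- exponential_search_boundary(function(i) TRUE, 5)
  expect_identical(res$first_rejected, 6L)
  expect_identical(res$probes, c(1L, 2L, 4L, 5L))
  # first batch rejected: a single probe
  res1 <- exponential_search_boundary(function(i) FALSE, 20)
  expect_identical(res1$first_rejected, 1L)
  expect_identical(res1$n_probes, 1L)
})

# A hand-laid growing scene: one validated cluster at the origin, candidates
# on the x-axis at increasing distance, labels chosen per batch.
grow_scene <- function(candidate_labels, batch_size = 10) {
  n <- length(candidate_labels)
  x <- rbind(cbind(seq(0.01, 0.05, length.out = 5), 0), # members near origin
             cbind(seq_len(n), 0))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  es <- embedding_set(x, gold_labels = c(rep("A", 5), candidate_labels))
  st <- state_with_cluster(es, es$object_ids[1:5], "A")
  cfg <- sim_config(batch_size = batch_size, regrow_trigger = 1e6)
  list(es = es, st = st, cfg = cfg)
}

test_that("a batch between the thresholds is purged and switches to linear mode", {
  sc <- grow_scene(c(rep("A", 7), rep("B", 3), rep("A", 10), rep("B", 10)))
  st <- grow_cluster("c00001", sc$st, sc$es$gold_labels, sc$cfg)
  cl <- st$clusters[["c00001"]]
  expect_equal(length(cl$members), 5 + 7 + 10)
  expect_equal(sum(sc$es$gold_labels[cl$members] == "A"), length(cl$members))
  # clicks: probes of batches 1,2,3 plus 3 removals
  expect_equal(unname(st$clicks[["growing"]]), 3 + 3)
  # the 3 purged objects and the terminal rejected batch carry rejections
  expect_equal(nrow(as.data.frame(st$rejections)), 3 + 10)
})

test_that("exponential/binary growing absorbs exactly the fitting prefix", {
  sc <- grow_scene(c(rep("A", 100), rep("B", 100)))
  st <- grow_cluster("c00001", sc$st, sc$es$gold_labels, sc$cfg)
  cl <- st$clusters[["c00001"]]
  expect_equal(length(cl$members), 105) # all 100 matching candidates joined
  # probe schedule for boundary 11 over 20 batches: 1,2,4,8,16 then 12,10,11
  expect_equal(unname(st$clicks[["growing"]]), 8)
})

test_that("an all-foreign candidate list costs one probe and adds nothing", {
  sc <- grow_scene(rep("B", 30))
  st <- grow_cluster("c00001", sc$st, sc$es$gold_labels, sc$cfg)
  expect_equal(length(st$clusters[["c00001"]]$members), 5)
  expect_equal(unname(st$clicks[["growing"]]), 1)
})

test_that("rejected objects are excluded from later grow candidate lists", {
  sc <- grow_scene(rep(c("B", "A"), c(10, 10)))
  st <- grow_cluster("c00001", sc$st, sc$es$gold_labels, sc$cfg)
  # first batch rejected; its members recorded
  expect_equal(length(st$clusters[["c00001"]]$members), 5)
  st2 <- grow_cluster("c00001", st, sc$es$gold_labels, sc$cfg)
  # second attempt skips the rejected ten and reaches the matching batch
  expect_equal(length(st2$clusters[["c00001"]]$members), 15)
})

test_that("a single pure blob is annotated in one iteration", {
  es <- make_blobs(matrix(c(0, 0), 1), n_per = 40, seed = 2)
  run <- run_simulation(es, "skmeans", clusterer_args = list(k = 1, p_core = 1),
                        config = sim_config(seed = 1))
  expect_equal(completeness(run), 1)
  expect_equal(nrow(run$trace), 1)
})

test_that("a clusterer that yields nothing terminates the loop", {
  es <- make_blobs(matrix(c(0, 0), 1), n_per = 30, seed = 2)
  expect_warning(
    run <- run_simulation(es, "hdbscan", clusterer_args = list(m0 = 128),
                          config = sim_config(seed = 1)),
    "fewer")
  expect_equal(completeness(run), 0)
  expect_equal(nrow(run$trace), 1)
})

test_that("state invariants hold across a multi-iteration run", {
  es <- generate_embeddings(n_classes = 5, objects_per_class = 60, d = 6,
                            separation = 10, seed = 13)
  run <- run_simulation(es, "skmeans", clusterer_args = list(k = 5, p_core = 0.3),
                        config = sim_config(seed = 2))
  st <- run$state
  assigned <- unlist(lapply(st$clusters, `[[`, "members"), use.names = FALSE)
  # clusters and pool partition the objects
  expect_false(anyDuplicated(assigned) > 0)
  expect_setequal(c(assigned, st$pool), es$object_ids)
  # completeness is monotone over the trace
  expect_true(all(diff(run$trace$cumulative_assigned) >= 0))
  # the click ledger is the sum of the per-iteration trace
  expect_equal(sum(run$trace$clicks_validation) + sum(run$trace$clicks_growing),
               sum(unname(st$clicks)))
  # no member violates a rejection record of its own cluster
  rdf <- as.data.frame(st$rejections)
  for (cid in names(st$clusters))
    expect_length(intersect(st$clusters[[cid]]$members,
                            rdf$object_id[rdf$cluster_id == cid]), 0)
})
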