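#' Simulation configuration
#'
#' Thresholds and stopping rules of the simulated annotator. The defaults are
#' the operating point of the interactive application the simulator mimics:
#' validation threshold `t_v = 0.85`, pure-batch threshold `t_gp = 0.75`,
#' unpure-batch threshold `t_gu = 0.55` and a batch size of 50 candidate
#' objects per page.
#'
#' @param t_v Validation purity threshold in `(0, 1)`; candidate clusters
#'   with purity `>= t_v` are accepted (inclusively, so a 17/20 cluster
#'   passes at the default 0.85).
#' @param t_gp Pure-batch threshold; batches with purity `>= t_gp` join the
#'   cluster wholesale.
#' @param t_gu Unpure-batch threshold; batches with purity `< t_gu` are
#'   rejected. Batches in between are accepted after removing the
#'   non-matching objects and switch growing to linear scanning.
#' @param batch_size Number of candidate objects judged per click.
#' @param max_iterations Cap on cluster/validate/grow rounds (default 12).
#' @param completeness_stop Assigned fraction that terminates the run
#'   (default 0.99).
#' @param regrow_trigger Growth factor (relative to the pre-grow size) that
#'   triggers a centroid recomputation and a growing restart (default 1,
#'   i.e. the cluster more than doubled).
#' @param max_regrows Cap on growing restarts per cluster per iteration.
#' @param seed Integer seed forwarded (with the iteration index added) to
#'   the clusterer in [run_simulation()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(t_v = 0.85, t_gp = 0.75, t_gu = 0.55, batch_size = 50,
                       max_iterations = 12, completeness_stop = 0.99,
                       regrow_trigger = 1, max_regrows = 2, seed = 1) {
  if (!.is_prop(t_v, lo_open = TRUE, hi_open = TRUE))
    .stopf("invalid `t_v`: must be in (0, 1)")
  if (!(.is_prop(t_gu, lo_open = TRUE) && .is_prop(t_gp, hi_open = TRUE) &&
        t_gu <= t_gp))
    .stopf("invalid batch thresholds: need 0 < t_gu <= t_gp < 1")
  if (!.is_count(batch_size)) .stopf("invalid `batch_size`: must be >= 1")
  if (!.is_count(max_iterations)) .stopf("invalid `max_iterations`")
  if (!.is_prop(completeness_stop, lo_open = TRUE))
    .stopf("invalid `completeness_stop`: must be in (0, 1]")
  if (!(is.numeric(regrow_trigger) && regrow_trigger > 0))
    .stopf("invalid `regrow_trigger`: must be > 0")
  structure(list(t_v = t_v, t_gp = t_gp, t_gu = t_gu,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 completeness_stop = completeness_stop,
                 regrow_trigger = regrow_trigger,
                 max_regrows = as.integer(max_regrows),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Purity and majority label of a cluster
#'
#' Purity is the fraction of members carrying the cluster's majority
#' gold-standard label; majority ties are broken by the lexicographically
#' smallest label.
#'
#' @param member_labels Non-empty character vector of gold labels.
#' @return List with elements `purity` and `majority_label`.
#' @examples
#' cluster_purity(c("A", "A", "A", "B")) # 0.75, "A"
#' @export
cluster_purity <- function(member_labels) {
  if (length(member_labels) == 0L) .stopf("empty label sequence")
  counts <- table(member_labels)
  top <- sort(names(counts)[counts == max(counts)])[1L]
  list(purity = as.numeric(counts[[top]]) / length(member_labels),
       majority_label = top)
}

# --- simulation state ------------------------------------------------------

#' Initialise a simulation state
#'
#' @param dataset An [embedding_set] with gold labels.
#' @return A `sim_state`: validated clusters, candidate clusters, the pool of
#'   unclustered objects, the rejection store, the click ledger and the
#'   iteration counter. Clusters and pool always partition the object ids.
#' @export
sim_state <- function(dataset) {
  stopifnot(inherits(dataset, "embedding_set"))
  structure(list(features = dataset$features,
                 clusters = list(), candidates = list(), additions = list(),
                 pool = dataset$object_ids,
                 rejections = rejection_store(),
                 clicks = c(validation = 0, growing = 0),
                 iteration = 0L, counter = 0L,
                 newly_accepted = character(0)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  n <- nrow(x$features)
  cat(sprintf(
    "<sim_state> iteration %d: %d clusters, %d/%d assigned, %d clicks\n",
    x$iteration, length(x$clusters), n - length(x$pool), n,
    sum(x$clicks)))
  invisible(x)
}

#' Validate candidate clusters against gold labels
#'
#' Mimics the user's validation step. Each candidate whose purity reaches
#' `t_v` is accepted: its non-majority members are returned to the pool with
#' a rejection record for that cluster (1 click for the accept decision plus
#' 1 click per removed object), and the centroid is recomputed from the
#' survivors. Candidates below `t_v` are deleted: every member returns to
#' the pool with a rejection record (1 click). Late additions that
#' partially labeled k-means made to already-validated clusters are reviewed
#' first under the same rule (1 click per cluster with additions plus 1 per
#' removed addition). After validation every accepted cluster is pure with
#' respect to its majority label.
#'
#' @param state A [sim_state()] holding unvalidated `candidates` (and
#'   possibly `additions`).
#' @param gold Named character vector of gold labels.
#' @param config A [sim_config()].
#' @return The updated state; newly accepted cluster ids are recorded in
#'   `state$newly_accepted`.
#' @export
validate_clusters <- function(state, gold, config) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "sim_config"))
  # review late additions to validated clusters
  for (cid in names(state$additions)) {
    adds <- state$additions[[cid]]
    if (length(adds) == 0L) next
    cl <- state$clusters[[cid]]
    mismatch <- adds[gold[adds] != cl$majority]
    keep <- setdiff(adds, mismatch)
    state$clicks["validation"] <- state$clicks[["validation"]] +
      1 + length(mismatch)
    if (length(mismatch) > 0) rs_add(state$rejections, mismatch, cid)
    cl$members <- c(cl$members, keep)
    cl$centroid <- colMeans(state$features[cl$members, , drop = FALSE])
    state$clusters[[cid]] <- cl
    state$pool <- setdiff(state$pool, keep)
  }
  state$additions <- list()

  accepted <- character(0)
  for (cid in names(state$candidates)) {
    members <- state$candidates[[cid]]
    cp <- cluster_purity(gold[members])
    if (cp$purity >= config$t_v) {
      mismatch <- members[gold[members] != cp$majority_label]
      keep <- setdiff(members, mismatch)
      state$clicks["validation"] <- state$clicks[["validation"]] +
        1 + length(mismatch)
      if (length(mismatch) > 0) rs_add(state$rejections, mismatch, cid)
      state$clusters[[cid]] <- list(
        members = keep,
        centroid = colMeans(state$features[keep, , drop = FALSE]),
        majority = cp$majority_label)
      state$pool <- setdiff(state$pool, keep)
      accepted <- c(accepted, cid)
    } else {
      state$clicks["validation"] <- state$clicks[["validation"]] + 1
      rs_add(state$rejections, members, cid)
    }
  }
  state$candidates <- list()
  state$newly_accepted <- accepted
  state
}

# --- batch search ----------------------------------------------------------

# Hybrid exponential / binary search over batch positions 1..n.
# `status_of(p)` must return "fit", "partial" or "reject" and is charged one
# probe per call. Returns the first rejected position (`boundary`), the last
# position of the accepted region (`accepted_to`) and, when a partially pure
# batch interrupted the exponential phase, the position from which linear
# scanning must continue (`linear_from`).
.search_batches <- function(status_of, n) {
  if (n < 1L)
    return(list(boundary = 1L, accepted_to = 0L, linear_from = NA_integer_))
  la <- 0L
  p <- 1L
  repeat {
    st <- status_of(p)
    if (st == "reject") { fr <- p; break }
    if (st == "partial")
      return(list(boundary = NA_integer_, accepted_to = p, linear_from = p + 1L))
    la <- p
    if (p >= n)
      return(list(boundary = n + 1L, accepted_to = n, linear_from = NA_integer_))
    p <- min(2L * p, n)
  }
  while (fr - la > 1L) {
    mid <- (la + fr) %/% 2L
    st <- status_of(mid)
    if (st == "reject") fr <- mid else la <- mid
  }
  list(boundary = fr, accepted_to = fr - 1L, linear_from = NA_integer_)
}

#' Exponential search for the first rejected batch
#'
#' Probes 1-based batch positions 1, 2, 4, 8, ... (clamped to the list
#' length) until a probe is rejected or the list ends, then binary-searches
#' the open interval between the last accepted and the first rejected probe.
#' Each probe costs one click. For a boundary at position `b` the probe
#' count is at most `2 * ceiling(log2(b)) + 2`.
#'
#' @param accept Function of a 1-based batch index returning `TRUE`
#'   (fitting) or `FALSE` (non-fitting); assumed monotone (a fitting prefix
#'   followed by a non-fitting suffix).
#' @param n_batches Length of the finite candidate list.
#' @return List with `first_rejected` (equal to `n_batches + 1` when every
#'   batch is accepted), `n_probes`, and the probed positions `probes`.
#' @examples
#' exponential_search_boundary(function(i) i < 7, 20)
#' @export
exponential_search_boundary <- function(accept, n_batches) {
  probes <- integer(0)
  status_of <- function(p) {
    probes[[length(probes) + 1L]] <<- p
    if (isTRUE(accept(p))) "fit" else "reject"
  }
  res <- .search_batches(status_of, as.integer(n_batches))
  list(first_rejected = res$boundary, n_probes = length(probes),
       probes = probes)
}

#' Grow a validated cluster by batch search
#'
#' Simulates the growing step: all pool objects without a rejection record
#' for the cluster, ordered by increasing Euclidean distance to its centroid
#' (ties by object id), are cut into batches of `batch_size`. Batches are
#' visited by exponential/binary search. A probed batch with purity (with
#' respect to the cluster's majority label) at least `t_gp` fits; below
#' `t_gu` it is rejected (1 click, rejection records for all its objects) and
#' bounds the accepted region; in between it is accepted after removing the
#' non-matching objects (1 click per removal, with rejection records) and
#' growing switches to linear scanning of the subsequent batches until a
#' batch falls below `t_gu`. Unprobed batches inside the accepted region
#' join unexamined -- the deliberate precision-for-efficiency trade of the
#' workflow. If the cluster grew by more than `regrow_trigger` times its
#' pre-grow size, the centroid is recomputed and growing restarts (at most
#' `max_regrows` times).
#'
#' @param cluster_id Id of a validated cluster in `state`.
#' @inheritParams validate_clusters
#' @return The updated state.
#' @export
grow_cluster <- function(cluster_id, state, gold, config) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "sim_config"))
  if (is.null(state$clusters[[cluster_id]]))
    .stopf("unknown cluster '%s'", cluster_id)
  regrows <- 0L
  repeat {
    cl <- state$clusters[[cluster_id]]
    pre <- length(cl$members)
    cand <- state$pool[!vapply(state$pool, rs_rejected, TRUE,
                               store = state$rejections,
                               cluster_id = cluster_id)]
    if (length(cand) == 0L) break
    d2 <- .dist2(state$features[cand, , drop = FALSE],
                 matrix(cl$centroid, nrow = 1))[, 1L]
    cand <- cand[order(d2, cand)]
    batches <- .chunk(cand, config$batch_size)
    nb <- length(batches)

    n_probes <- 0L
    status <- rep(NA_character_, nb)
    probe <- function(p) {
      n_probes <<- n_probes + 1L
      frac <- mean(gold[batches[[p]]] == cl$majority)
      st <- if (frac >= config$t_gp) "fit"
        else if (frac >= config$t_gu) "partial" else "reject"
      status[p] <<- st
      st
    }
    res <- .search_batches(probe, nb)

    added <- removed <- rejected <- character(0)
    take <- function(p) {
      batch <- batches[[p]]
      if (identical(status[p], "partial")) {
        mm <- batch[gold[batch] != cl$majority]
        removed <<- c(removed, mm)
        added <<- c(added, setdiff(batch, mm))
      } else {
        added <<- c(added, batch)
      }
    }
    if (res$accepted_to > 0) for (p in seq_len(res$accepted_to)) take(p)
    if (!is.na(res$linear_from) && res$linear_from <= nb) {
      for (p in seq(res$linear_from, nb)) {
        st <- probe(p)
        if (st == "reject") { rejected <- batches[[p]]; break }
        take(p)
      }
    }
    if (!is.na(res$boundary) && res$boundary <= nb &&
        identical(status[res$boundary], "reject"))
      rejected <- batches[[res$boundary]]
    # probed rejected batches inside the binary phase also got their clicks;
    # record rejections for every probed rejected batch
    for (p in which(!is.na(status) & status == "reject"))
      rejected <- union(rejected, batches[[p]])

    state$clicks["growing"] <- state$clicks[["growing"]] +
      n_probes + length(removed)
    if (length(removed) > 0) rs_add(state$rejections, removed, cluster_id)
    if (length(rejected) > 0) rs_add(state$rejections, rejected, cluster_id)
    cl$members <- c(cl$members, added)
    state$pool <- setdiff(state$pool, added)
    cl$centroid <- colMeans(state$features[cl$members, , drop = FALSE])
    state$clusters[[cluster_id]] <- cl

    if (length(added) > config$regrow_trigger * pre &&
        regrows < config$max_regrows && length(state$pool) > 0) {
      regrows <- regrows + 1L
    } else break
  }
  state
}

# --- main loop -------------------------------------------------------------

#' Run the simulated annotation process
#'
#' Alternates clustering, validation and growing on the pool of unclustered
#' objects, carrying the rejection store across iterations (consumed by
#' partially labeled k-means, ignored by the other clusterers), until a
#' completeness threshold or the iteration cap is reached, or an iteration
#' assigns no new objects. Every simulated user interaction is counted in
#' the click ledger, split by phase.
#'
#' @param dataset An [embedding_set] with gold labels.
#' @param clusterer One of `"skmeans"`, `"plkmeans"`, `"hdbscan"`.
#' @param clusterer_args Named list of arguments for the clusterer:
#'   for `"skmeans"` `k` and `p_core` (see [shrunken_kmeans()]); for
#'   `"plkmeans"` `k0`, `k_delta`, `p_noise`, `p_core` (see [pl_kmeans()]);
#'   for `"hdbscan"` `neighborhood_k`, `m0`, `decay_factor` (see
#'   [hdbscan_candidates()]).
#' @param config A [sim_config()].
#' @return An object of class `annotation_run`: the final [sim_state()], a
#'   per-iteration trace (data frame with objects assigned and clicks spent),
#'   the configuration, and the dataset. Methods: `print`, `summary`
#'   (a [metrics_report()]) and `plot` (annotation progress over clicks).
#' @examples
#' \donttest{
#' es <- generate_embeddings(n_classes = 5, objects_per_class = 60, d = 8,
#'                           separation = 10, seed = 7)
#' run <- run_simulation(es, "skmeans",
#'                       clusterer_args = list(k = 5, p_core = 0.5),
#'                       config = sim_config(seed = 7))
#' summary(run)
#' }
#' @export
run_simulation <- function(dataset,
                           clusterer = c("skmeans", "plkmeans", "hdbscan"),
                           clusterer_args = list(),
                           config = sim_config()) {
  stopifnot(inherits(dataset, "embedding_set"))
  if (is.null(dataset$gold_labels))
    .stopf("`run_simulation()` requires gold labels")
  clusterer <- match.arg(clusterer)
  stopifnot(inherits(config, "sim_config"))
  gold <- dataset$gold_labels
  n <- length(gold)
  state <- sim_state(dataset)
  trace <- list()
  t0 <- proc.time()[["elapsed"]]
  cluster_runtime <- 0

  for (it in seq_len(config$max_iterations) - 1L) {
    state$iteration <- it
    if (length(state$pool) == 0L) break
    assigned_before <- n - length(state$pool)
    clicks_before <- state$clicks

    tc <- proc.time()[["elapsed"]]
    cand_members <- .propose_candidates(state, clusterer, clusterer_args,
                                        config, it)
    cluster_runtime <- cluster_runtime + (proc.time()[["elapsed"]] - tc)

    state$additions <- cand_members$additions
    for (mem in cand_members$new) {
      state$counter <- state$counter + 1L
      state$candidates[[sprintf("c%05d", state$counter)]] <- mem
    }
    n_candidates <- length(cand_members$new)

    state <- validate_clusters(state, gold, config)
    for (cid in state$newly_accepted)
      state <- grow_cluster(cid, state, gold, config)

    assigned_after <- n - length(state$pool)
    trace[[length(trace) + 1L]] <- data.frame(
      iteration = it,
      n_candidates = n_candidates,
      n_accepted = length(state$newly_accepted),
      objects_assigned = assigned_after - assigned_before,
      cumulative_assigned = assigned_after,
      completeness = assigned_after / n,
      clicks_validation = state$clicks[["validation"]] -
        clicks_before[["validation"]],
      clicks_growing = state$clicks[["growing"]] -
        clicks_before[["growing"]])
    if (assigned_after - assigned_before <= 0L) break
    if (assigned_after / n >= config$completeness_stop) break
  }

  structure(list(state = state,
                 trace = do.call(rbind, trace),
                 config = config,
                 clusterer = clusterer,
                 clusterer_args = clusterer_args,
                 dataset = dataset,
                 runtime_seconds = proc.time()[["elapsed"]] - t0,
                 clustering_seconds = cluster_runtime),
            class = "annotation_run")
}

# Produce candidate clusters for the current iteration. Returns
# list(new = list of member-id vectors, additions = named list of late
# additions per validated cluster).
.propose_candidates <- function(state, clusterer, args, config, it) {
  pool <- state$pool
  feats <- state$features
  empty <- list(new = list(), additions = list())
  seed_it <- config$seed + it
  if (clusterer == "skmeans") {
    k <- args$k %||% 1000
    p_core <- args$p_core %||% 0.01
    if (k > length(pool)) {
      .warnf("k = %d exceeds pool size %d; clamping", k, length(pool))
      k <- length(pool)
    }
    pa <- shrunken_kmeans(feats[pool, , drop = FALSE], k = k,
                          p_core = p_core, seed = seed_it,
                          max_iter = args$max_iter %||% 100)
    list(new = unname(cluster_members(pa)), additions = list())
  } else if (clusterer == "hdbscan") {
    pa <- hdbscan_candidates(feats[pool, , drop = FALSE],
                             neighborhood_k = args$neighborhood_k %||% 8,
                             m0 = args$m0 %||% 128,
                             decay_factor = args$decay_factor %||% 0.5,
                             outer_iteration = it)
    list(new = unname(cluster_members(pa)), additions = list())
  } else { # plkmeans
    prior_of <- stats::setNames(rep(NA_character_, nrow(feats)),
                                rownames(feats))
    for (cid in names(state$clusters))
      prior_of[state$clusters[[cid]]$members] <- cid
    prior <- partial_assignment(prior_of)
    pa <- pl_kmeans(feats, prior = prior, rejections = state$rejections,
                    k0 = args$k0 %||% 500,
                    k_delta = args$k_delta %||% 100,
                    p_noise = args$p_noise %||% 0.1,
                    p_core = args$p_core %||% 0.01,
                    outer_iteration = it, seed = seed_it,
                    max_iter = args$max_iter %||% 100)
    mem <- cluster_members(pa)
    additions <- list()
    for (cid in intersect(names(mem), names(state$clusters))) {
      adds <- setdiff(mem[[cid]], state$clusters[[cid]]$members)
      if (length(adds) > 0) additions[[cid]] <- adds
    }
    list(new = unname(mem[setdiff(names(mem), names(state$clusters))]),
         additions = additions)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotation_run <- function(x, ...) {
  n <- nrow(x$state$features)
  assigned <- n - length(x$state$pool)
  cat(sprintf("<annotation_run> clusterer '%s'\n", x$clusterer))
  cat(sprintf("  iterations: %d   clusters: %d\n",
              x$state$iteration + 1L, length(x$state$clusters)))
  cat(sprintf("  assigned:   %d/%d (completeness %.3f)\n",
              assigned, n, assigned / n))
  cat(sprintf("  clicks:     %d (validation %d, growing %d)\n",
              sum(x$state$clicks), x$state$clicks[["validation"]],
              x$state$clicks[["growing"]]))
  if (sum(x$state$clicks) > 0)
    cat(sprintf("  efficiency: %.2f objects/click\n",
                assigned / sum(x$state$clicks)))
  invisible(x)
}

#' @export
summary.annotation_run <- function(object, ...) metrics_report(object)

#' @export
plot.annotation_run <- function(x, ...) {
  tr <- x$trace
  clicks <- cumsum(tr$clicks_validation + tr$clicks_growing)
  graphics::plot(c(0, clicks), c(0, tr$cumulative_assigned), type = "s",
                 xlab = "cumulative clicks", ylab = "objects assigned",
                 main = sprintf("Annotation progress (%s)", x$clusterer), ...)
  graphics::points(clicks, tr$cumulative_assigned, pch = 16)
  invisible(x)
}
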