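# Plain-text I/O: CSV features (first column id), two-column TSV labels,
# TSV assignments/rejections, JSONL run traces, JSON metric reports.
# Writers embed provenance (seed, config hash) as a comment line; readers
# skip comment lines.

.meta_comment <- function(meta) {
  if (is.null(meta)) return(NULL)
  paste0("# ", paste(sprintf("%s=%s", names(meta), unlist(meta)),
                     collapse = " "))
}

#' Write an embedding set to CSV (+ label TSV)
#'
#' @param dataset An [embedding_set].
#' @param features_path CSV output: first column `object_id`, then one
#'   column per feature dimension.
#' @param labels_path Optional TSV output with columns `object_id`, `label`.
#' @return The dataset, invisibly.
#' @export
write_embeddings <- function(dataset, features_path, labels_path = NULL) {
  stopifnot(inherits(dataset, "embedding_set"))
  df <- data.frame(object_id = dataset$object_ids, dataset$features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("object_id", sprintf("f%d", seq_len(ncol(dataset$features))))
  utils::write.csv(df, features_path, row.names = FALSE, quote = FALSE)
  if (!is.null(labels_path)) {
    if (is.null(dataset$gold_labels)) .stopf("dataset has no gold labels")
    utils::write.table(
      data.frame(object_id = dataset$object_ids,
                 label = unname(dataset$gold_labels)),
      labels_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dataset)
}

#' Read an embedding set from CSV (+ label TSV)
#'
#' @param features_path CSV with the object id in the first column and one
#'   numeric column per feature dimension.
#' @param labels_path Optional two-column TSV (`object_id`, `label`); every
#'   object must be covered.
#' @return An [embedding_set].
#' @export
read_embeddings <- function(features_path, labels_path = NULL) {
  df <- utils::read.csv(features_path, stringsAsFactors = FALSE,
                        comment.char = "#")
  ids <- as.character(df[[1L]])
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    bad <- which(rowSums(!is.finite(x)) > 0)[1L]
    .stopf("non-finite feature value in row %d of '%s'", bad, features_path)
  }
  gold <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(lab) < 2L) .stopf("label table needs columns object_id, label")
    miss <- setdiff(ids, lab[[1L]])
    if (length(miss) > 0)
      .stopf("%d labelled of %d objects; missing e.g. '%s'",
             nrow(lab), length(ids), miss[1L])
    gold <- lab[[2L]][match(ids, lab[[1L]])]
  }
  embedding_set(x, object_ids = ids, gold_labels = gold)
}

#' Write an assignment table
#'
#' TSV with columns `object_id`, `cluster_id` (empty for unassigned).
#'
#' @param x A [partial_assignment] or `annotation_run`.
#' @param path Output path.
#' @param meta Optional named list recorded as a leading `#` comment (e.g.
#'   seed and config hash).
#' @return `x`, invisibly.
#' @export
write_assignment <- function(x, path, meta = NULL) {
  co <- if (inherits(x, "annotation_run")) {
    out <- stats::setNames(rep(NA_character_, nrow(x$state$features)),
                           rownames(x$state$features))
    for (cid in names(x$state$clusters))
      out[x$state$clusters[[cid]]$members] <- cid
    out
  } else x$cluster_of
  con <- file(path, "w")
  on.exit(close(con))
  cmt <- .meta_comment(meta)
  if (!is.null(cmt)) writeLines(cmt, con)
  writeLines("object_id\tcluster_id", con)
  writeLines(sprintf("%s\t%s", names(co), ifelse(is.na(co), "", co)), con)
  invisible(x)
}

#' Read an assignment table
#'
#' @param path TSV written by [write_assignment()].
#' @return A [partial_assignment] (without centroids).
#' @export
read_assignment <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = "")
  partial_assignment(stats::setNames(as.character(df$cluster_id),
                                     df$object_id))
}

#' Write / read a rejection table
#'
#' TSV with columns `object_id`, `cluster_id`, one row per rejection record.
#'
#' @param store A [rejection_store()].
#' @param path File path.
#' @inheritParams write_assignment
#' @return The store (invisibly for the writer).
#' @export
write_rejections <- function(store, path, meta = NULL) {
  df <- as.data.frame(store)
  con <- file(path, "w")
  on.exit(close(con))
  cmt <- .meta_comment(meta)
  if (!is.null(cmt)) writeLines(cmt, con)
  writeLines("object_id\tcluster_id", con)
  if (nrow(df) > 0)
    writeLines(sprintf("%s\t%s", df$object_id, df$cluster_id), con)
  invisible(store)
}

#' @rdname write_rejections
#' @export
read_rejections <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  store <- rejection_store()
  for (i in seq_len(nrow(df)))
    rs_add(store, df$object_id[i], df$cluster_id[i])
  store
}

#' Write / read a run trace as JSON lines
#'
#' One JSON record per iteration with the objects assigned and the clicks
#' spent per phase.
#'
#' @param run An `annotation_run`.
#' @param path File path.
#' @inheritParams write_assignment
#' @return The run (invisibly for the writer); the reader returns a data
#'   frame.
#' @export
write_trace <- function(run, path, meta = NULL) {
  stopifnot(inherits(run, "annotation_run"))
  tr <- run$trace
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(jsonlite::toJSON(c(list(record = "meta"), meta),
                                auto_unbox = TRUE), con)
  for (i in seq_len(nrow(tr)))
    writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(run)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  recs <- Filter(function(r) !identical(r$record, "meta"), recs)
  do.call(rbind, lapply(recs, as.data.frame))
}

#' Write a metrics report as JSON
#'
#' @param report A [metrics_report()] (or plain named list).
#' @param path File path.
#' @param meta Optional named list merged into the JSON under `meta`.
#' @return The report, invisibly.
#' @export
write_report <- function(report, path, meta = NULL) {
  x <- unclass(report)
  if (!is.null(meta)) x$meta <- meta
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(report)
}
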