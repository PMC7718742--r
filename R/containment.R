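#' Build a minimizer index over a sequence collection
#'
#' Indexes canonical minimizers: within every window of `w` consecutive
#' k-mers the k-mer with the smallest hashed canonical code is recorded
#' with its sequence, position and strand. This is the anchor index used
#' for containment detection, the lightweight stand-in for whole-genome
#' self-alignment.
#'
#' @param records Named character vector of sequences.
#' @param k Anchor k-mer length (`<= 31`), default 15.
#' @param w Minimizer window in k-mers, default 10; expected anchor density
#'   is about `2/(w+1)` per position. `w = 1` indexes every k-mer.
#' @return A `minimizer_index` object.
#' @export
index_minimizers <- function(records, k = 15L, w = 10L) {
  stopifnot(is.character(records), length(records) > 0L)
  k <- as.integer(k); w <- as.integer(w)
  if (k < 1L || k > 31L) stop("anchor k must be between 1 and 31")
  if (w < 1L) stop("w must be >= 1")
  ptr <- mz_build(names(records), unname(records), k, w)
  structure(list(ptr = ptr, k = k, w = w, ids = names(records),
                 lengths = stats::setNames(nchar(records), names(records))),
            class = "minimizer_index")
}

#' @export
print.minimizer_index <- function(x, ...) {
  cat(sprintf("minimizer_index: %d sequences, k=%d, w=%d\n",
              length(x$ids), x$k, x$w))
  invisible(x)
}

#' @method as.data.frame minimizer_index
#' @export
as.data.frame.minimizer_index <- function(x, ...) {
  mz_export(x$ptr)
}

#' Find containments of a query within longer indexed sequences
#'
#' Shared minimizers between the query and each indexed sequence are
#' chained by a bounded longest-colinear-subsequence pass (strand
#' consistent, gap-difference bounded); chains with at least
#' `min_chain_anchors` anchors are kept and merged when separated by less
#' than 1 kb on both sequences. Per target:
#' `query_coverage` = union of chained query intervals / query length;
#' `identity` = exactly matched query bases within the chained spans
#' (anchor bases plus direct base comparison across intra-chain gaps along
#' the local diagonal) / total chained span. Hits are sorted by
#' `query_coverage * identity` descending, ties broken by identity then
#' target id.
#'
#' Only targets strictly longer than the query are reported by default,
#' matching the haplotig-removal rule ("aligned to another longer
#' scaffold"); the query's own id is always excluded.
#'
#' @param query Single named character element, or a string plus `query_id`.
#' @param index A `minimizer_index` over the candidate targets.
#' @param min_chain_anchors Minimum anchors per chain (default 3).
#' @param only_longer Restrict to targets strictly longer than the query.
#' @param query_id Id of the query (defaults to `names(query)`).
#' @param max_occ Anchors occurring more often than this in the index are
#'   skipped as repeats.
#' @return Data frame `target_id`, `identity`, `query_coverage`,
#'   `n_chains`.
#' @export
find_containments <- function(query, index, min_chain_anchors = 3L,
                              only_longer = TRUE, query_id = NULL,
                              max_occ = 500L) {
  stopifnot(inherits(index, "minimizer_index"),
            is.character(query), length(query) == 1L)
  if (is.null(query_id)) query_id <- names(query)
  if (is.null(query_id) || !nzchar(query_id)) query_id <- ""
  mz_find(index$ptr, query_id, unname(query),
          as.integer(min_chain_anchors), isTRUE(only_longer),
          as.integer(max_occ),
          band = 200L, max_chain_gap = 5000L, merge_gap = 1000L)
}

#' Write containment hits to TSV
#'
#' @param hits Data frame from [find_containments()], optionally with a
#'   `query_id` column prepended by the caller.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_containments <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
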