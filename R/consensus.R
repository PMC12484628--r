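#' Multi-read consensus with constraint-based filtering
#'
#' Basecalled reads that violate the code constraint or have the wrong length
#' carry little information and are discarded; the survivors vote per
#' position. A consensus that itself violates the constraint falls back to
#' the most frequent whole read; if no read survives filtering the caller
#' treats the sequence as an erasure.
#'
#' @name consensus
NULL

#' Keep constraint-valid reads of the expected length
#'
#' @param reads character vector of padding-removed basecalls.
#' @param graph the `debruijn_graph` defining the constraint.
#' @param expected_len required sequence length in bases.
#' @return character vector (subset of `reads`, order preserved).
#' @export
filter_valid_reads <- function(reads, graph, expected_len) {
  keep <- vapply(reads, function(r) {
    nchar(r) == expected_len && check_sequence(graph, r)$valid
  }, logical(1))
  reads[keep]
}

#' Per-position majority consensus
#'
#' Plurality base per position, ties broken A < C < G < T. If the blended
#' consensus fails `check_sequence` on `graph`, the most frequent whole read
#' is returned instead (first occurrence on ties). With no reads the function
#' abstains (returns NA) so downstream can mark an erasure.
#'
#' @param reads character vector of equal-length valid reads.
#' @param graph optional `debruijn_graph` for the constraint fallback check.
#' @return a DNA string, or `NA_character_` when abstaining.
#' @export
majority_consensus <- function(reads, graph = NULL) {
  if (length(reads) == 0) return(NA_character_)
  stopifnot(length(unique(nchar(reads))) == 1)
  mat <- do.call(rbind, strsplit(reads, "", fixed = TRUE))
  cons <- apply(mat, 2, function(col) {
    counts <- table(factor(col, levels = DNA_BASES))
    DNA_BASES[which.max(counts)]   # which.max takes the first max: A<C<G<T ties
  })
  cons_seq <- paste(cons, collapse = "")
  if (!is.null(graph) && !check_sequence(graph, cons_seq)$valid) {
    counts <- table(factor(reads, levels = unique(reads)))
    cons_seq <- names(counts)[which.max(counts)]
  }
  cons_seq
}
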