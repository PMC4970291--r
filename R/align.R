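#' Percent identity of two sequences by global alignment
#'
#' Aligns the two sequences globally (match +1, mismatch -1, gap -2 per
#' base) and reports `matches / alignment length * 100`, where the
#' alignment length counts matches, mismatches and internal gap bases over
#' the terminal-gap-trimmed region: gap runs touching either end of the
#' optimal path are treated as terminal overhangs and excluded from the
#' counts, so a query identical to a prefix of its reference still scores
#' identity 100.
#'
#' @param a,b DNA strings (A/C/G/T).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  .check_dna(a, "a")
  .check_dna(b, "b")
  if (length(a) != 1L || length(b) != 1L) {
    stop("`a` and `b` must be single sequences", call. = FALSE)
  }
  cts <- cpp_align_counts(a, b, .aln_match, .aln_mismatch, .aln_gap)
  len <- sum(cts[c("matches", "mismatches", "insertions", "deletions")])
  if (len == 0L) return(0)
  100 * cts[["matches"]] / len
}

# Batch alignment of queries against references; returns the component
# matrices (nq x nr) from the compiled aligner.
.align_sets <- function(queries, refs_seqs) {
  cpp_align_sets(queries, refs_seqs, .aln_match, .aln_mismatch, .aln_gap)
}

#' Align queries to their best-matching reference
#'
#' Globally aligns each query against every reference and returns, per
#' query, the reference maximizing percent identity (ties broken by
#' reference input order) together with the alignment composition.
#' `matches + mismatches + insertions + deletions` equals the alignment
#' length (terminal gap runs excluded, as in [pairwise_identity()]).
#'
#' @param query Character vector of DNA sequences (named or not).
#' @param refs A [reference_set()].
#' @return Data frame with one row per query: `query_id`, `best_ref`,
#'   `alignment_length`, `matches`, `mismatches`, `insertions`,
#'   `deletions`, `identity`.
#' @export
align_to_best_reference <- function(query, refs) {
  stopifnot(inherits(refs, "reference_set"))
  .check_dna(query, "query")
  aln <- .align_sets(query, refs$seqs)
  best <- apply(aln$identity, 1L, which.max)
  idx <- cbind(seq_along(query), best)
  m <- aln$matches[idx]
  mm <- aln$mismatches[idx]
  ins <- aln$insertions[idx]
  del <- aln$deletions[idx]
  ids <- names(query)
  if (is.null(ids)) ids <- sprintf("query%d", seq_along(query))
  data.frame(
    query_id = ids,
    best_ref = names(refs$seqs)[best],
    alignment_length = m + mm + ins + del,
    matches = m, mismatches = mm, insertions = ins, deletions = del,
    identity = aln$identity[idx],
    stringsAsFactors = FALSE)
}
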