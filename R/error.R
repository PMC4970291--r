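# Batch reference-based bimera scan. For each candidate breakpoint the
# query is split into a prefix and a suffix, each aligned to every
# reference; a query is flagged when its best left and right parents differ
# and the two-parent model beats the best single-reference identity by at
# least `min_improvement` percentage points.
.chimera_scan <- function(seqs, refs, n_breakpoints = 5,
                          min_improvement = 2) {
  n <- length(seqs)
  full <- .align_sets(seqs, refs$seqs)
  best_single <- apply(full$identity, 1L, max)
  best_combined <- rep(-Inf, n)
  left_parent <- right_parent <- rep(NA_character_, n)
  best_break <- rep(NA_integer_, n)
  lens <- nchar(seqs)
  fracs <- seq_len(n_breakpoints) / (n_breakpoints + 1)
  for (f in fracs) {
    b <- pmax(1L, pmin(lens - 1L, as.integer(round(f * lens))))
    lefts <- substr(seqs, 1L, b)
    rights <- substr(seqs, b + 1L, lens)
    la <- .align_sets(lefts, refs$seqs)
    ra <- .align_sets(rights, refs$seqs)
    li <- apply(la$identity, 1L, which.max)
    ri <- apply(ra$identity, 1L, which.max)
    lidx <- cbind(seq_len(n), li)
    ridx <- cbind(seq_len(n), ri)
    alen_l <- la$matches[lidx] + la$mismatches[lidx] +
      la$insertions[lidx] + la$deletions[lidx]
    alen_r <- ra$matches[ridx] + ra$mismatches[ridx] +
      ra$insertions[ridx] + ra$deletions[ridx]
    denom <- alen_l + alen_r
    combined <- ifelse(denom > 0,
                       100 * (la$matches[lidx] + ra$matches[ridx]) / denom,
                       0)
    upd <- combined > best_combined
    best_combined[upd] <- combined[upd]
    left_parent[upd] <- names(refs$seqs)[li[upd]]
    right_parent[upd] <- names(refs$seqs)[ri[upd]]
    best_break[upd] <- b[upd]
  }
  flagged <- !is.na(left_parent) & left_parent != right_parent &
    (best_combined - best_single) >= min_improvement
  data.frame(
    is_chimera = flagged, left_parent = left_parent,
    right_parent = right_parent, breakpoint = best_break,
    improvement = best_combined - best_single,
    best_single_identity = best_single,
    stringsAsFactors = FALSE)
}

#' Flag a query as a reference-based chimera
#'
#' A deliberately simple bimera test for the mock-community setting where
#' the true parent sequences are known: the query is split at each of
#' `n_breakpoints` evenly spaced interior positions; it is flagged when the
#' best left-segment parent differs from the best right-segment parent and
#' the two-parent identity exceeds the best single-reference identity by at
#' least `min_improvement` percentage points. A chimera of two identical
#' references is undetectable by construction and is not flagged. This is
#' not a UCHIME re-implementation.
#'
#' @param query A single DNA string.
#' @param refs A [reference_set()] with at least 2 references.
#' @param n_breakpoints Number of candidate split points.
#' @param min_improvement Required identity gain (percentage points).
#' @return List: `is_chimera`, `left_parent`, `right_parent`, `breakpoint`,
#'   `improvement`.
#' @export
flag_chimera <- function(query, refs, n_breakpoints = 5,
                         min_improvement = 2) {
  stopifnot(inherits(refs, "reference_set"))
  if (length(refs$seqs) < 2L) {
    stop("chimera flagging needs >= 2 references", call. = FALSE)
  }
  .check_dna(query, "query")
  if (length(query) != 1L) stop("`query` must be a single sequence",
                                call. = FALSE)
  res <- .chimera_scan(query, refs, n_breakpoints, min_improvement)
  as.list(res[1L, c("is_chimera", "left_parent", "right_parent",
                    "breakpoint", "improvement")])
}

#' Abundance-weighted sequencing error rate against known references
#'
#' Aligns each unique sequence to its best-matching reference and reports
#' the abundance-weighted per-base error rate:
#' `sum(count * (mismatches + insertions + deletions)) /
#'  sum(count * alignment_length)`,
#' i.e. every mismatched, inserted or deleted base counts as one error.
#' Sequences flagged as chimeras are excluded from the rate by default (and
#' counted separately).
#'
#' @param table A [useq_table()].
#' @param refs A [reference_set()].
#' @param exclude_chimeras Exclude chimera-flagged sequences from the rate.
#' @param n_breakpoints,min_improvement Passed to the chimera scan.
#' @return An `error_report`: `overall` (fraction), `per_sample` (named
#'   fractions), `reads_assessed`, `chimeras_excluded`, and the
#'   `per_sequence` alignment table.
#' @export
error_rate <- function(table, refs, exclude_chimeras = TRUE,
                       n_breakpoints = 5, min_improvement = 2) {
  stopifnot(inherits(table, "useq_table"), inherits(refs, "reference_set"))
  if (nrow(table$counts) == 0L) stop("table is empty", call. = FALSE)
  aln <- align_to_best_reference(table$seqs, refs)
  chim <- if (exclude_chimeras && length(refs$seqs) >= 2L) {
    .chimera_scan(table$seqs, refs, n_breakpoints, min_improvement)$is_chimera
  } else {
    rep(FALSE, length(table$seqs))
  }
  .error_report(table, aln, chim)
}

# Assemble an error report from precomputed per-sequence alignment stats;
# shared with validate(), which aligns each unique sequence only once.
.error_report <- function(table, aln, chim) {
  errors <- aln$mismatches + aln$insertions + aln$deletions
  alen <- aln$alignment_length
  pooled <- pooled_counts(table)
  keep <- !chim
  rate_of <- function(w) {
    denom <- sum(w[keep] * alen[keep])
    if (denom == 0) return(NA_real_)
    sum(w[keep] * errors[keep]) / denom
  }
  per_sample <- vapply(seq_along(table$samples),
                       function(s) rate_of(table$counts[, s]), numeric(1))
  names(per_sample) <- table$samples
  per_sequence <- cbind(aln,
                        data.frame(pooled_count = as.integer(pooled),
                                   is_chimera = chim))
  structure(
    list(overall = rate_of(pooled), per_sample = per_sample,
         reads_assessed = sum(pooled[keep]),
         chimeras_excluded = sum(pooled[!keep]),
         per_sequence = per_sequence),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "Error rate: %.4f%% over %d reads (%d chimeric reads excluded)\n",
    100 * x$overall, x$reads_assessed, x$chimeras_excluded))
  invisible(x)
}
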