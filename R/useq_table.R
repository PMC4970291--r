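#' Unique-sequence count table
#'
#' The central container of the filtering stage: distinct (exact-identity)
#' amplicon sequences by per-sample read counts. "Cluster" at this stage
#' means an exact-identity unique-sequence group — the pre-OTU clusters of
#' the size spectrum — not a 97% OTU.
#'
#' @param seqs Named character vector of unique sequences (names are
#'   sequence ids).
#' @param counts Integer matrix, rows = sequences (rownames = ids),
#'   columns = samples.
#' @param provenance Character note (raw / rarefied / filtered at t).
#' @return A `useq_table`.
#' @export
useq_table <- function(seqs, counts, provenance = "raw") {
  .check_dna(seqs, "seqs")
  counts <- as.matrix(counts)
  if (anyDuplicated(seqs)) stop("duplicate sequence keys", call. = FALSE)
  if (is.null(names(seqs)) || is.null(rownames(counts)) ||
      !identical(names(seqs), rownames(counts))) {
    stop("`seqs` names and `counts` rownames must match", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    stop("`counts` must have sample column names", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(seqs = seqs, counts = counts, samples = colnames(counts),
         provenance = provenance),
    class = "useq_table")
}

#' @export
print.useq_table <- function(x, ...) {
  cat(sprintf(
    "Unique-sequence table: %d sequences x %d samples, %d reads [%s]\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts),
    paste(x$provenance, collapse = "; ")))
  invisible(x)
}

#' Pooled (cross-sample) counts of a unique-sequence table
#'
#' @param table A [useq_table()].
#' @return Named integer vector: each sequence's read count summed over all
#'   samples.
#' @export
pooled_counts <- function(table) {
  stopifnot(inherits(table, "useq_table"))
  rowSums(table$counts)
}

#' Dereplicate reads into a unique-sequence count table
#'
#' Pools reads across samples and counts each distinct sequence string per
#' sample. Total reads are conserved. Sequences are ordered by decreasing
#' pooled count (ties: sequence string) and assigned stable ids.
#'
#' @param reads A named list of per-sample character vectors of reads, or a
#'   [simulate_run()] result.
#' @return A [useq_table()].
#' @export
dereplicate <- function(reads) {
  if (inherits(reads, "simulated_run")) reads <- reads$reads
  if (!is.list(reads) || length(reads) == 0L || is.null(names(reads))) {
    stop("`reads` must be a non-empty named list of per-sample reads",
         call. = FALSE)
  }
  if (all(lengths(reads) == 0L)) {
    stop("`reads` contains no sequences", call. = FALSE)
  }
  all_seqs <- unlist(reads, use.names = FALSE)
  .check_dna(all_seqs, "reads")
  sample_of <- rep(names(reads), lengths(reads))
  uniq <- unique(all_seqs)
  counts <- table(factor(all_seqs, levels = uniq),
                  factor(sample_of, levels = names(reads)))
  counts <- matrix(as.integer(counts), nrow = length(uniq),
                   dimnames = list(NULL, names(reads)))
  ord <- order(-rowSums(counts), uniq)
  counts <- counts[ord, , drop = FALSE]
  uniq <- uniq[ord]
  ids <- sprintf("Useq%05d", seq_along(uniq))
  rownames(counts) <- ids
  useq_table(stats::setNames(uniq, ids), counts, provenance = "raw")
}

#' Remove low-frequency sequences by cross-sample abundance
#'
#' Retains exactly the sequences whose pooled (summed over all samples)
#' count is at least `min_pooled_count`. Cross-sample singletons are
#' sequences occurring once among all samples, doubletons twice; a threshold
#' of 2 removes singletons, 3 removes singletons and doubletons, 1 is the
#' identity. Per-sample counts of retained sequences are unchanged.
#'
#' @param table A [useq_table()].
#' @param min_pooled_count Minimum pooled count to retain (>= 1).
#' @return List with the filtered `table` and a `report` (threshold,
#'   sequences/reads removed and retained, per-sample totals before/after).
#' @export
remove_rare <- function(table, min_pooled_count) {
  stopifnot(inherits(table, "useq_table"))
  if (!is.numeric(min_pooled_count) || length(min_pooled_count) != 1L ||
      min_pooled_count < 1) {
    stop("`min_pooled_count` must be >= 1", call. = FALSE)
  }
  pooled <- pooled_counts(table)
  keep <- pooled >= min_pooled_count
  out <- table
  out$seqs <- table$seqs[keep]
  out$counts <- table$counts[keep, , drop = FALSE]
  out$provenance <- c(table$provenance,
                      sprintf("filtered at pooled count >= %d",
                              as.integer(min_pooled_count)))
  report <- list(
    threshold = as.integer(min_pooled_count),
    sequences_removed = sum(!keep), sequences_retained = sum(keep),
    reads_removed = sum(pooled[!keep]), reads_retained = sum(pooled[keep]),
    sample_totals_before = colSums(table$counts),
    sample_totals_after = colSums(out$counts))
  list(table = out, report = report)
}

#' Rarefy each sample to a fixed depth
#'
#' Subsamples each sample's reads to exactly `depth` reads without
#' replacement (a single draw per seed, not an average over draws).
#' Sequences whose counts drop to zero in every sample are removed.
#'
#' @param table A [useq_table()].
#' @param depth Target reads per sample (default 6654).
#' @param seed Random seed; fixed seed gives a deterministic draw.
#' @return A rarefied [useq_table()].
#' @export
rarefy <- function(table, depth = 6654, seed = 1) {
  stopifnot(inherits(table, "useq_table"))
  depth <- as.integer(depth)
  if (depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  totals <- colSums(table$counts)
  low <- totals < depth
  if (any(low)) {
    stop("insufficient depth: sample(s) ",
         paste(table$samples[low], collapse = ", "), " have fewer than ",
         depth, " reads", call. = FALSE)
  }
  set.seed(seed)
  counts <- table$counts
  for (s in seq_along(table$samples)) {
    if (totals[s] == depth) next
    expanded <- rep.int(seq_len(nrow(counts)), counts[, s])
    drawn <- sample(expanded, depth, replace = FALSE)
    counts[, s] <- tabulate(drawn, nbins = nrow(counts))
  }
  keep <- rowSums(counts) > 0
  out <- table
  out$seqs <- table$seqs[keep]
  out$counts <- counts[keep, , drop = FALSE]
  out$provenance <- c(table$provenance,
                      sprintf("rarefied to %d reads/sample (seed %d)",
                              depth, as.integer(seed)))
  out
}

#' Cluster-size spectrum of a unique-sequence table
#'
#' Tallies, for each pooled-count value n, the number of unique-sequence
#' clusters containing exactly n reads. Mass conservation: the sum of
#' `cluster_size * n_clusters` equals the total reads in the table.
#'
#' @param table A [useq_table()].
#' @return Data frame with columns `cluster_size` and `n_clusters`, sorted
#'   by size.
#' @export
cluster_size_spectrum <- function(table) {
  stopifnot(inherits(table, "useq_table"))
  pooled <- pooled_counts(table)
  pooled <- pooled[pooled > 0]
  if (length(pooled) == 0L) stop("table is empty", call. = FALSE)
  tab <- base::table(pooled)
  data.frame(cluster_size = as.integer(names(tab)),
             n_clusters = as.integer(tab))
}
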