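#' Assign an OTU representative to a community member by nearest reference
#'
#' Nearest-reference assignment for a defined (mock) community: the label
#' of the reference with the best ends-free alignment identity, provided
#' that identity reaches `min_identity`; otherwise `"unclassified"`. This
#' replaces database classification, which is unnecessary when the true
#' members are known.
#'
#' @param representative A single DNA string (the OTU's most abundant
#'   member sequence).
#' @param refs A [reference_set()].
#' @param min_identity Identity threshold in percent (default 80).
#' @return List: `label` (genus or "unclassified"), `identity`, `ref`
#'   (best reference template), `is_bacterial`.
#' @export
assign_otu <- function(representative, refs, min_identity = 80) {
  stopifnot(inherits(refs, "reference_set"))
  if (min_identity <= 0 || min_identity > 100) {
    stop("`min_identity` must be in (0, 100]", call. = FALSE)
  }
  aln <- align_to_best_reference(representative, refs)
  best <- match(aln$best_ref, names(refs$seqs))
  if (aln$identity >= min_identity) {
    list(label = refs$genus[best], identity = aln$identity,
         ref = aln$best_ref, is_bacterial = refs$is_bacterial[best])
  } else {
    list(label = "unclassified", identity = aln$identity,
         ref = aln$best_ref, is_bacterial = NA)
  }
}

#' Assign every OTU in a table
#'
#' @param otus An [cluster_otus()] table built from a [useq_table()] (so
#'   representatives are available).
#' @param refs A [reference_set()].
#' @param min_identity Identity threshold in percent.
#' @return Data frame: `otu`, `genus`, `identity`, `ref`, `is_bacterial`.
#' @export
assign_otus <- function(otus, refs, min_identity = 80) {
  stopifnot(inherits(otus, "otu_table"))
  if (is.null(otus$representatives)) {
    stop("OTU table has no representative sequences; cluster from a ",
         "useq_table", call. = FALSE)
  }
  aln <- align_to_best_reference(otus$representatives, refs)
  best <- match(aln$best_ref, names(refs$seqs))
  classified <- aln$identity >= min_identity
  data.frame(
    otu = names(otus$representatives),
    genus = ifelse(classified, refs$genus[best], "unclassified"),
    identity = aln$identity,
    ref = aln$best_ref,
    is_bacterial = ifelse(classified, refs$is_bacterial[best], NA),
    stringsAsFactors = FALSE)
}

#' Average relative abundance per genus across samples
#'
#' Per-sample genus fractions are computed from OTU read counts (each
#' sample's fractions sum to 1) and then averaged over samples, mirroring a
#' replicate-averaged genus barplot. Unclassified OTUs form their own bin.
#' With `drop_nonbacterial = TRUE`, reads assigned to non-bacterial control
#' members (the archaeal non-specific-amplification control) are counted
#' and excluded, and fractions are taken over bacterial plus unclassified
#' reads only.
#'
#' @param otus An [cluster_otus()] table.
#' @param assignments Data frame from [assign_otus()] covering every OTU.
#' @param drop_nonbacterial Exclude non-bacterial control assignments.
#' @return A `taxonomy_summary`: `per_sample` genus-by-sample fraction
#'   matrix, `summary` data frame (genus, mean_fraction, sem), the
#'   `unclassified` mean fraction, and `nonbacterial_fraction` (fraction of
#'   all reads assigned to non-bacterial controls).
#' @export
summarize_relative_abundance <- function(otus, assignments,
                                         drop_nonbacterial = TRUE) {
  stopifnot(inherits(otus, "otu_table"))
  if (!all(rownames(otus$counts) %in% assignments$otu)) {
    stop("`assignments` must cover all OTUs", call. = FALSE)
  }
  genus <- assignments$genus[match(rownames(otus$counts),
                                   assignments$otu)]
  bact <- assignments$is_bacterial[match(rownames(otus$counts),
                                         assignments$otu)]
  nonbact <- !is.na(bact) & !bact
  total_reads <- sum(otus$counts)
  nonbact_fraction <- sum(otus$counts[nonbact, , drop = FALSE]) /
    total_reads
  counts <- otus$counts
  if (drop_nonbacterial) {
    counts <- counts[!nonbact, , drop = FALSE]
    genus <- genus[!nonbact]
  }
  genera <- sort(unique(genus))
  agg <- rowsum(counts, group = factor(genus, levels = genera))
  totals <- colSums(agg)
  if (any(totals == 0)) {
    stop("sample(s) with zero assessable reads: ",
         paste(colnames(agg)[totals == 0], collapse = ", "), call. = FALSE)
  }
  frac <- sweep(agg, 2L, totals, "/")
  summary <- data.frame(
    genus = genera,
    mean_fraction = apply(frac, 1L, mean),
    sem = apply(frac, 1L, .sem),
    row.names = NULL, stringsAsFactors = FALSE)
  summary <- summary[order(-summary$mean_fraction), , drop = FALSE]
  unclassified <- summary$mean_fraction[summary$genus == "unclassified"]
  structure(
    list(per_sample = frac, summary = summary,
         unclassified = if (length(unclassified)) unclassified else 0,
         nonbacterial_fraction = nonbact_fraction,
         min_identity = attr(assignments, "min_identity")),
    class = "taxonomy_summary")
}

#' @export
print.taxonomy_summary <- function(x, ...) {
  cat("Mean relative abundance across", ncol(x$per_sample), "samples:\n")
  top <- utils::head(x$summary, 25L)
  cat(sprintf("  %-18s %6.2f%% +/- %.2f%%\n", top$genus,
              100 * top$mean_fraction, 100 * top$sem), sep = "")
  if (x$nonbacterial_fraction > 0) {
    cat(sprintf("  (non-bacterial control reads: %.2f%% of all reads)\n",
                100 * x$nonbacterial_fraction))
  }
  invisible(x)
}
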