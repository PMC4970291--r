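#' All-pairs alignment distance matrix
#'
#' Pairwise distances `d = 1 - identity/100` from global alignment of
#' every sequence pair (the computationally dominant stage of
#' OTU calling, and the reason low-frequency sequences are best removed
#' before it). The matrix is symmetric with a zero diagonal.
#'
#' @param seqs Named character vector of DNA sequences, or a
#'   [useq_table()].
#' @return Symmetric numeric matrix of distances in `[0, 1]`.
#' @export
pairwise_distances <- function(seqs) {
  if (inherits(seqs, "useq_table")) seqs <- seqs$seqs
  .check_dna(seqs, "seqs")
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  d <- 1 - cpp_identity_matrix(seqs, .aln_match, .aln_mismatch,
                               .aln_gap) / 100
  dimnames(d) <- list(ids, ids)
  d
}

#' Cluster sequences into OTUs by average linkage
#'
#' Agglomerative average-linkage (average neighbor / UPGMA) clustering:
#' clusters are merged while their average inter-cluster distance stays at
#' or below the cutoff. A cutoff of 0.03 corresponds to the conventional
#' 97% similarity OTU definition. When a [useq_table()] is supplied its
#' per-sample counts are aggregated per OTU (read totals are conserved) and
#' each OTU's representative sequence is its most abundant member (ties:
#' lexicographically smallest sequence). OTUs are ordered by decreasing
#' total abundance.
#'
#' @param dm Distance matrix from [pairwise_distances()].
#' @param cutoff Distance cutoff in (0, 1); default 0.03.
#' @param table Optional [useq_table()] whose sequences match `dm`; when
#'   absent every sequence counts once in a single pseudo-sample.
#' @return An `otu_table`: `counts` (OTU x sample), `members` (list of
#'   sequence ids), `representatives` (named character, when sequences are
#'   known), `cutoff`.
#' @export
cluster_otus <- function(dm, cutoff = 0.03, table = NULL) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("`dm` must be a square distance matrix", call. = FALSE)
  }
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must be in (0, 1)",
                                       call. = FALSE)
  ids <- rownames(dm)
  n <- nrow(dm)
  membership <- if (n == 1L) {
    stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(dm), method = "average")
    stats::cutree(hc, h = cutoff)
  }
  if (!is.null(table)) {
    stopifnot(inherits(table, "useq_table"))
    if (!identical(ids, names(table$seqs))) {
      stop("`dm` rownames must match the table's sequence ids",
           call. = FALSE)
    }
    counts <- table$counts
    seqs <- table$seqs
  } else {
    counts <- matrix(1L, nrow = n, ncol = 1L,
                     dimnames = list(ids, "all"))
    seqs <- NULL
  }
  k <- max(membership)
  otu_counts <- matrix(0L, nrow = k, ncol = ncol(counts),
                       dimnames = list(NULL, colnames(counts)))
  members <- vector("list", k)
  reps <- rep(NA_character_, k)
  pooled <- rowSums(counts)
  for (g in seq_len(k)) {
    idx <- which(membership == g)
    members[[g]] <- ids[idx]
    otu_counts[g, ] <- colSums(counts[idx, , drop = FALSE])
    if (!is.null(seqs)) {
      cand <- idx[pooled[idx] == max(pooled[idx])]
      reps[g] <- seqs[[cand[order(seqs[cand])][1L]]]
    }
  }
  ord <- order(-rowSums(otu_counts),
               vapply(members, `[[`, character(1), 1L))
  otu_counts <- otu_counts[ord, , drop = FALSE]
  members <- members[ord]
  reps <- reps[ord]
  otu_ids <- sprintf("Otu%04d", seq_len(k))
  rownames(otu_counts) <- otu_ids
  names(members) <- otu_ids
  names(reps) <- otu_ids
  structure(
    list(counts = otu_counts, members = members,
         representatives = if (is.null(seqs)) NULL else reps,
         cutoff = cutoff, samples = colnames(otu_counts)),
    class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples at cutoff %.3g (%d reads)\n",
              nrow(x$counts), ncol(x$counts), x$cutoff, sum(x$counts)))
  invisible(x)
}

# Per-sample alpha-diversity closed forms (mothur conventions):
# bias-corrected Chao1 with (n2 + 1) denominators, Shannon with natural
# log, unbiased finite-sample inverse Simpson. A single-read sample has an
# undefined inverse Simpson (NA).
.alpha_one <- function(counts) {
  counts <- counts[counts > 0]
  n_reads <- sum(counts)
  s_obs <- length(counts)
  n1 <- sum(counts == 1L)
  n2 <- sum(counts == 2L)
  chao <- s_obs + n1 * (n1 - 1) / (2 * (n2 + 1))
  p <- counts / n_reads
  shannon <- -sum(p * log(p))
  invsimpson <- if (n_reads < 2L) {
    NA_real_
  } else {
    d <- sum(counts * (counts - 1)) / (n_reads * (n_reads - 1))
    if (d == 0) Inf else 1 / d
  }
  c(n_reads = n_reads, sobs = s_obs, n1 = n1, n2 = n2, chao = chao,
    shannon = shannon, invsimpson = invsimpson)
}

#' Alpha-diversity panel of an OTU table
#'
#' Per sample: observed OTUs (S_obs), bias-corrected Chao richness
#' `S_obs + n1(n1-1) / (2(n2+1))` (n1, n2 = OTUs seen once and twice in the
#' sample; defined for n2 = 0), Shannon index (natural log), and the
#' unbiased inverse Simpson index `1 / sum(n_i(n_i-1)) / (N(N-1))`.
#' Summary rows report the mean plus or minus the standard error of the
#' mean over samples.
#'
#' @param otus An [cluster_otus()] table.
#' @return A `diversity_report`: `per_sample` data frame and `summary`
#'   (metric, mean, sem).
#' @export
alpha_diversity <- function(otus) {
  stopifnot(inherits(otus, "otu_table"))
  totals <- colSums(otus$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero reads: ",
         paste(otus$samples[totals == 0], collapse = ", "),
         "; diversity indices are undefined", call. = FALSE)
  }
  per <- t(apply(otus$counts, 2L, .alpha_one))
  per_sample <- data.frame(sample = otus$samples, per,
                           row.names = NULL, stringsAsFactors = FALSE)
  metrics <- c("sobs", "chao", "shannon", "invsimpson")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_sample[[m]]), numeric(1)),
    sem = vapply(metrics, function(m) .sem(per_sample[[m]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample, summary = summary),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("Alpha diversity (mean +/- SEM over",
      nrow(x$per_sample), "samples):\n")
  with(x$summary, cat(sprintf("  %-11s %.4g +/- %.3g\n", metric, mean, sem),
                      sep = ""))
  invisible(x)
}

#' Estimated total OTU richness (Chao-type)
#'
#' Stand-in for a parametric total-richness estimator: reports the
#' bias-corrected Chao estimate per sample with an approximate normal
#' interval from the classic Chao variance (with `(n2 + 1)` denominators so
#' it is defined when no doubletons are present), clearly labeled as a
#' Chao-type estimate. With no rare OTUs the estimate equals S_obs; many
#' singleton OTUs inflate it far above S_obs.
#'
#' @param otus An [cluster_otus()] table.
#' @param conf Confidence level for the normal interval.
#' @return Data frame: sample, sobs, estimate, se, lower, upper; the
#'   estimator label is in attribute `estimator`.
#' @export
estimated_total_otus <- function(otus, conf = 0.95) {
  stopifnot(inherits(otus, "otu_table"))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- lapply(seq_along(otus$samples), function(s) {
    a <- .alpha_one(otus$counts[, s])
    n1 <- a[["n1"]]; n2 <- a[["n2"]]
    v <- n1 * (n1 - 1) / (2 * (n2 + 1)) +
      n1 * (2 * n1 - 1)^2 / (4 * (n2 + 1)^2) +
      n1^2 * n2 * (2 * n1 - 1)^2 / (4 * (n2 + 1)^4)
    se <- sqrt(v)
    data.frame(sample = otus$samples[s], sobs = a[["sobs"]],
               estimate = a[["chao"]], se = se,
               lower = max(a[["sobs"]], a[["chao"]] - z * se),
               upper = a[["chao"]] + z * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "estimator") <- "bias-corrected Chao"
  out
}
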