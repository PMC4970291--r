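#' Pipeline configuration for the three-way validation
#'
#' Collects the tunable parameters of the end-to-end comparison: rarefaction
#' depth (default 6654 reads/sample), the pooled-count filter thresholds
#' (1 = all sequences, 2 = cross-sample singletons removed, 3 = singletons
#' and doubletons removed), the OTU distance cutoff (0.03, i.e. 97%
#' similarity), the taxonomy identity threshold, chimera-scan settings, the
#' stage order, and the seeds. Round-trips losslessly through
#' [write_config()] / [read_config()].
#'
#' @param rarefy_depth Reads per sample after rarefaction.
#' @param thresholds Pooled-count filter thresholds to compare.
#' @param otu_cutoff OTU distance cutoff in (0, 1).
#' @param assign_min_identity Taxonomy identity threshold (percent).
#' @param chimera_margin Chimera-scan improvement margin (percentage
#'   points).
#' @param chimera_breakpoints Candidate breakpoints in the chimera scan.
#' @param exclude_chimeras Exclude flagged chimeras from error rates.
#' @param drop_nonbacterial Exclude non-bacterial control reads from genus
#'   summaries.
#' @param rarefy_first Rarefy before filtering (the default stage order);
#'   `FALSE` filters first, then rarefies.
#' @param seed Seed for the rarefaction draw.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(rarefy_depth = 6654, thresholds = c(1, 2, 3),
                            otu_cutoff = 0.03, assign_min_identity = 80,
                            chimera_margin = 2, chimera_breakpoints = 5,
                            exclude_chimeras = TRUE,
                            drop_nonbacterial = TRUE, rarefy_first = TRUE,
                            seed = 1) {
  if (rarefy_depth < 1 || any(thresholds < 1)) {
    stop("depths and thresholds must be positive", call. = FALSE)
  }
  if (otu_cutoff <= 0 || otu_cutoff >= 1) {
    stop("`otu_cutoff` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(rarefy_depth = as.integer(rarefy_depth),
         thresholds = as.integer(thresholds),
         otu_cutoff = otu_cutoff,
         assign_min_identity = assign_min_identity,
         chimera_margin = chimera_margin,
         chimera_breakpoints = as.integer(chimera_breakpoints),
         exclude_chimeras = isTRUE(exclude_chimeras),
         drop_nonbacterial = isTRUE(drop_nonbacterial),
         rarefy_first = isTRUE(rarefy_first),
         seed = as.integer(seed)),
    class = "pipeline_config")
}

.branch_label <- function(threshold) {
  switch(as.character(threshold),
         "1" = "all",
         "2" = "no_singletons",
         "3" = "no_singletons_doubletons",
         sprintf("min_count_%d", threshold))
}

#' Run the full three-way mock-community validation
#'
#' Executes the complete comparison on one set of multi-sample reads with
#' known references: dereplication, rarefaction, then for each filter
#' threshold — error analysis against the references (chimeras flagged and
#' excluded), average-linkage OTU clustering, the alpha-diversity panel,
#' nearest-reference taxonomy, and the log-log cluster-size spectrum fit.
#' Sequences are aligned to the references, scanned for chimeras, and
#' placed in the all-pairs distance matrix once, on the unfiltered table;
#' each filtered branch reuses the relevant subset.
#'
#' @param reads A named list of per-sample read vectors, or a
#'   [simulate_run()] result.
#' @param refs A [reference_set()]; taken from the run when `reads` is a
#'   `simulated_run` and `refs` is `NULL`.
#' @param config A [pipeline_config()].
#' @return A `validation_report`: `summary` (one row per branch: observed
#'   OTUs, Chao, Shannon, inverse Simpson as mean +/- SEM over samples, and
#'   the error rate in percent), `genus_summary` (per-branch
#'   [summarize_relative_abundance()] results), `branches` (full per-branch
#'   objects), and the rarefied input `table`.
#' @export
validate <- function(reads, refs = NULL, config = pipeline_config()) {
  if (inherits(reads, "simulated_run")) {
    if (is.null(refs)) refs <- reads$refs
    reads <- reads$reads
  }
  stopifnot(inherits(refs, "reference_set"),
            inherits(config, "pipeline_config"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("validate: stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  tab <- stage("dereplicate", dereplicate(reads))
  if (config$rarefy_first) {
    tab <- stage("rarefy", rarefy(tab, config$rarefy_depth, config$seed))
  }

  # Per-unique-sequence statistics computed once on the widest table.
  aln <- stage("alignment", align_to_best_reference(tab$seqs, refs))
  chim <- if (config$exclude_chimeras && length(refs$seqs) >= 2L) {
    stage("chimera_scan",
          .chimera_scan(tab$seqs, refs, config$chimera_breakpoints,
                        config$chimera_margin)$is_chimera)
  } else {
    rep(FALSE, length(tab$seqs))
  }
  dm <- stage("distance_matrix", pairwise_distances(tab$seqs))

  branches <- list()
  summary_rows <- list()
  genus_summaries <- list()
  for (t in sort(config$thresholds)) {
    label <- .branch_label(t)
    ft <- stage(paste0("filter_t", t), remove_rare(tab, t))
    btab <- ft$table
    if (!config$rarefy_first) {
      btab <- stage(paste0("rarefy_t", t),
                    rarefy(btab, config$rarefy_depth, config$seed))
    }
    idx <- match(names(btab$seqs), names(tab$seqs))
    err <- stage(paste0("error_t", t),
                 .error_report(btab, aln[idx, , drop = FALSE], chim[idx]))
    otus <- stage(paste0("cluster_t", t),
                  cluster_otus(dm[idx, idx, drop = FALSE],
                               config$otu_cutoff, btab))
    div <- stage(paste0("diversity_t", t), alpha_diversity(otus))
    est <- stage(paste0("richness_t", t), estimated_total_otus(otus))
    assignments <- stage(paste0("taxonomy_t", t),
                         assign_otus(otus, refs,
                                     config$assign_min_identity))
    taxsum <- stage(paste0("abundance_t", t),
                    summarize_relative_abundance(
                      otus, assignments,
                      drop_nonbacterial = config$drop_nonbacterial))
    spec <- stage(paste0("spectrum_t", t), fit_spectrum(btab))

    sm <- div$summary
    g <- function(metric, col) sm[[col]][sm$metric == metric]
    summary_rows[[label]] <- data.frame(
      branch = label, threshold = t,
      unique_sequences = nrow(btab$counts),
      total_otus = nrow(otus$counts),
      observed_otus = g("sobs", "mean"), observed_otus_sem = g("sobs", "sem"),
      chao = g("chao", "mean"), chao_sem = g("chao", "sem"),
      shannon = g("shannon", "mean"), shannon_sem = g("shannon", "sem"),
      invsimpson = g("invsimpson", "mean"),
      invsimpson_sem = g("invsimpson", "sem"),
      error_rate_pct = 100 * err$overall,
      estimated_total_otus = mean(est$estimate),
      unclassified_pct = 100 * taxsum$unclassified,
      stringsAsFactors = FALSE)
    genus_summaries[[label]] <- taxsum
    branches[[label]] <- list(
      threshold = t, table = btab, filter_report = ft$report,
      error = err, otus = otus, diversity = div,
      estimated_richness = est, assignments = assignments,
      taxonomy = taxsum, spectrum = spec)
  }
  structure(
    list(summary = do.call(rbind, c(summary_rows,
                                    list(make.row.names = FALSE))),
         genus_summary = genus_summaries,
         branches = branches,
         table = tab,
         config = config),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Mock-community validation (",
      ncol(x$table$counts), " samples, rarefied to ",
      x$config$rarefy_depth, " reads/sample)\n\n", sep = "")
  cols <- c("branch", "observed_otus", "chao", "shannon", "invsimpson",
            "error_rate_pct")
  print(x$summary[, cols], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a validation report's tables to a directory
#'
#' Emits the Table-3-shaped branch summary, one genus-summary TSV per
#' branch, and the rarefied count table with its companion FASTA — each
#' re-loadable with the package's readers.
#'
#' @param report A [validate()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "summary.tsv")
  con <- file(path, "w")
  writeLines(.provenance_line(
    "validate", depth = report$config$rarefy_depth,
    cutoff = report$config$otu_cutoff, seed = report$config$seed), con)
  utils::write.table(report$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  for (label in names(report$genus_summary)) {
    ts <- report$genus_summary[[label]]
    utils::write.table(
      ts$summary, file.path(dir, paste0("genus_", label, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_counts(report$table, file.path(dir, "counts.tsv"))
  invisible(dir)
}
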