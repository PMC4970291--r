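#' Read and write FASTA / FASTQ
#'
#' Thin wrappers over Biostrings. Sequences are normalized to upper case on
#' reading; CRLF line endings are handled transparently. FASTQ qualities
#' are carried in the `"qualities"` attribute but are otherwise unused by
#' the pipeline; `write_fastq()` emits flat qualities when none are given.
#'
#' @param path File path.
#' @return `read_fasta()` / `read_fastq()`: a named character vector of
#'   sequences (FASTQ with a `qualities` attribute). Writers return `path`
#'   invisibly.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  .check_dna(toupper(seqs), "seqs")
  x <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  out <- stats::setNames(toupper(as.character(x)), names(x))
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  attr(out, "qualities") <- stats::setNames(quals, names(x))
  out
}

#' @rdname read_fasta
#' @param qualities Optional named character vector of per-read quality
#'   strings; flat `"I"` qualities are used when absent.
#' @export
write_fastq <- function(seqs, path, qualities = NULL) {
  .check_dna(toupper(seqs), "seqs")
  if (is.null(qualities)) qualities <- attr(seqs, "qualities")
  if (is.null(qualities)) {
    qualities <- vapply(nchar(seqs), function(n) {
      paste(rep("I", n), collapse = "")
    }, character(1))
  }
  x <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(unname(qualities)))
  invisible(path)
}

# Provenance comment written at the top of every table this package emits.
.provenance_line <- function(stage, ...) {
  extra <- c(...)
  sprintf("# ampmock %s%s", stage,
          if (length(extra)) paste0(" ", paste(names(extra), extra,
                                               sep = "=", collapse = " "))
          else "")
}

#' Read and write unique-sequence count tables
#'
#' The count table is a TSV with a `#` provenance comment line, a header
#' row, an `id` column and one integer column per sample; the sequences
#' themselves travel in a companion FASTA keyed by the same ids.
#'
#' @param table A [useq_table()].
#' @param path Count-table TSV path.
#' @param fasta_path Companion FASTA path; defaults to `path` with a
#'   `.fasta` extension.
#' @return `read_counts()` a [useq_table()]; `write_counts()` `path`,
#'   invisibly.
#' @export
write_counts <- function(table, path, fasta_path = NULL) {
  stopifnot(inherits(table, "useq_table"))
  if (is.null(fasta_path)) fasta_path <- paste0(path, ".fasta")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_line(
    "counts", provenance = paste(table$provenance, collapse = "; ")), con)
  df <- data.frame(id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(table$seqs, fasta_path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, fasta_path = NULL) {
  if (is.null(fasta_path)) fasta_path <- paste0(path, ".fasta")
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  seqs <- read_fasta(fasta_path)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$id
  first <- readLines(path, n = 1L)
  prov <- sub("^# ampmock counts provenance=", "", first)
  useq_table(seqs[df$id], counts,
             provenance = if (startsWith(first, "#")) prov else "raw")
}

#' Read and write read-to-sample group files
#'
#' @param groups Data frame with columns `read_id` and `sample`.
#' @param path File path.
#' @return `read_groups()` a data frame; `write_groups()` `path`,
#'   invisibly.
#' @export
write_groups <- function(groups, path) {
  stopifnot(all(c("read_id", "sample") %in% names(groups)))
  utils::write.table(groups[, c("read_id", "sample")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write OTU tables in shared-style TSV
#'
#' One row per sample with the OTU cutoff and per-OTU integer counts,
#' plus a companion membership list file (OTU id, comma-separated member
#' sequence ids).
#'
#' @param otus An [cluster_otus()] table.
#' @param path Shared TSV path.
#' @param list_path Membership list path; defaults to `path` + `.list`.
#' @return `read_shared()` a list with `counts` and `cutoff`;
#'   `write_shared()` `path`, invisibly.
#' @export
write_shared <- function(otus, path, list_path = NULL) {
  stopifnot(inherits(otus, "otu_table"))
  if (is.null(list_path)) list_path <- paste0(path, ".list")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_line("shared", cutoff = otus$cutoff), con)
  df <- data.frame(sample = colnames(otus$counts), t(otus$counts),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  members <- vapply(otus$members, paste, character(1), collapse = ",")
  utils::write.table(
    data.frame(otu = names(otus$members), members = members),
    list_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shared
#' @export
read_shared <- function(path) {
  first <- readLines(path, n = 1L)
  cutoff <- if (grepl("cutoff=", first)) {
    as.numeric(sub(".*cutoff=([0-9.]+).*", "\\1", first))
  } else {
    NA_real_
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(counts) <- df$sample
  list(counts = counts, cutoff = cutoff)
}

#' Read and write key-value configuration files
#'
#' A flat `key = value` text format that round-trips a [pipeline_config()]
#' losslessly.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config()` a [pipeline_config()]; `write_config()` `path`,
#'   invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  keys <- names(config)
  vals <- vapply(config, function(v) paste(format(v, digits = 15),
                                           collapse = ","), character(1))
  writeLines(c("# ampmock config", paste(keys, vals, sep = " = ")), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- lapply(kv, function(p) {
    v <- strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(v))
    if (!any(is.na(num))) num else if (identical(v, "TRUE") ||
                                       identical(v, "FALSE")) {
      as.logical(v)
    } else {
      v
    }
  })
  do.call(pipeline_config, stats::setNames(vals, keys))
}
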