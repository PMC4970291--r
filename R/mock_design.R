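#' Genome copies per microgram of double-stranded DNA
#'
#' Converts a genome size in base pairs to the number of genome copies
#' contained in one microgram of double-stranded genomic DNA, using the
#' standard dsDNA mass of 650 g/mol per base pair and Avogadro's number
#' (6.022e23), i.e. `9.2646e14 / genome_size`.
#'
#' @param genome_size Genome size in base pairs (positive numeric, may be a
#'   vector).
#' @return Numeric vector of genome copies per microgram.
#' @examples
#' copies_per_microgram(4656144) # E. coli K-12 MG1655, ~1.99e8
#' @export
copies_per_microgram <- function(genome_size) {
  if (!is.numeric(genome_size) || length(genome_size) == 0L ||
      any(is.na(genome_size)) || any(genome_size <= 0)) {
    stop("`genome_size` must be positive (base pairs)", call. = FALSE)
  }
  1e-6 * 6.022e23 / (genome_size * 650)
}

#' Construct a mock-community member
#'
#' A member is a genome that contributes 16S rRNA gene copies to a defined
#' (mock) community: its genome size fixes how many genome copies one
#' microgram of DNA holds, and its per-genome 16S copy number converts
#' genome copies to 16S copies.
#'
#' @param name Member label.
#' @param genome_size Genome size in base pairs.
#' @param n_16s_copies 16S rRNA gene copies per genome (integer >= 1).
#' @param is_bacterial `FALSE` marks a non-bacterial control member (e.g. an
#'   archaeon included as a control for non-specific amplification).
#' @param copies_per_ug Genome copies per microgram; computed from
#'   `genome_size` when `NULL`.
#' @return A `mock_member` object.
#' @export
mock_member <- function(name, genome_size, n_16s_copies,
                        is_bacterial = TRUE, copies_per_ug = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(n_16s_copies) || length(n_16s_copies) != 1L ||
      is.na(n_16s_copies) || n_16s_copies < 1) {
    stop("`n_16s_copies` must be >= 1", call. = FALSE)
  }
  if (is.null(copies_per_ug)) {
    copies_per_ug <- copies_per_microgram(genome_size)
  }
  if (copies_per_ug <= 0) stop("`copies_per_ug` must be > 0", call. = FALSE)
  structure(
    list(name = name, genome_size = as.numeric(genome_size),
         n_16s_copies = as.numeric(n_16s_copies),
         copies_per_ug = as.numeric(copies_per_ug),
         is_bacterial = isTRUE(is_bacterial)),
    class = "mock_member")
}

#' Microgram of genomic DNA needed for a 16S copy target
#'
#' Implements the balancing arithmetic
#' `mass = target_copies / (n_16s_copies * copies_per_ug)`:
#' the mass of a member's genomic DNA whose 16S rRNA gene copy total equals
#' `target_copies`.
#'
#' @param member A [mock_member()].
#' @param target_copies Desired number of 16S rRNA gene copies (>= 0).
#' @return Mass in micrograms.
#' @export
mass_for_target_copies <- function(member, target_copies) {
  if (!inherits(member, "mock_member")) {
    stop("`member` must be a mock_member", call. = FALSE)
  }
  if (!is.numeric(target_copies) || length(target_copies) != 1L ||
      is.na(target_copies) || target_copies < 0) {
    stop("`target_copies` must be >= 0", call. = FALSE)
  }
  target_copies / (member$n_16s_copies * member$copies_per_ug)
}

#' Design an equal-copy mock community
#'
#' Splits a total 16S rRNA gene copy target evenly over the members (each
#' member contributes `1/n` of the community; 5% for 20 members) and
#' computes the microgram of each genomic DNA required.
#'
#' @param members List of [mock_member()] objects.
#' @param target_total_16s_copies Total 16S copies in the stock community.
#' @return A `mock_recipe`: the input members, the per-member copy target,
#'   and a `table` data frame (name, genome_size_bp, n_16s_copies,
#'   copies_per_ug, target_copies, mass_ug, fraction_16s).
#' @export
design_equal_mock <- function(members, target_total_16s_copies) {
  if (inherits(members, "mock_member")) members <- list(members)
  if (!is.list(members) || length(members) == 0L ||
      !all(vapply(members, inherits, logical(1), "mock_member"))) {
    stop("`members` must be a non-empty list of mock_member objects",
         call. = FALSE)
  }
  if (!is.numeric(target_total_16s_copies) ||
      length(target_total_16s_copies) != 1L ||
      is.na(target_total_16s_copies) || target_total_16s_copies <= 0) {
    stop("`target_total_16s_copies` must be > 0", call. = FALSE)
  }
  n <- length(members)
  per_member <- target_total_16s_copies / n
  mass <- vapply(members, mass_for_target_copies, numeric(1),
                 target_copies = per_member)
  tab <- data.frame(
    name = vapply(members, `[[`, character(1), "name"),
    genome_size_bp = vapply(members, `[[`, numeric(1), "genome_size"),
    n_16s_copies = vapply(members, `[[`, numeric(1), "n_16s_copies"),
    copies_per_ug = vapply(members, `[[`, numeric(1), "copies_per_ug"),
    target_copies = per_member,
    mass_ug = mass,
    fraction_16s = 1 / n,
    stringsAsFactors = FALSE)
  structure(
    list(members = members,
         target_total_16s_copies = target_total_16s_copies,
         per_member_target_copies = per_member,
         table = tab),
    class = "mock_recipe")
}

#' @export
print.mock_recipe <- function(x, ...) {
  cat("Equal-copy mock community recipe\n")
  cat(sprintf("  %d members, %.3g total 16S copies (%.3g per member)\n",
              length(x$members), x$target_total_16s_copies,
              x$per_member_target_copies))
  print(x$table, digits = 4)
  invisible(x)
}

#' The packaged 20-member mock community table
#'
#' Composition of a 20-member (19 bacteria + 1 archaeon) mock community:
#' strain name, genus, genome size, per-genome 16S rRNA gene copy number, a
#' bacterial flag (the archaeon *Methanobrevibacter smithii* is a control
#' for non-specific amplification) and the published genome-copies-per-
#' microgram estimate alongside the value this package computes.
#'
#' @return Data frame with one row per member.
#' @export
mock_community_members <- function() {
  path <- system.file("extdata", "mock_members.tsv", package = "ampmock",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$computed_copies_per_ug <- copies_per_microgram(tab$genome_size_bp)
  tab
}

#' @rdname mock_community_members
#' @param table Data frame with columns `name`, `genome_size_bp`,
#'   `n_16s_copies` and optionally `is_bacterial` (as written by
#'   [mock_community_members()] or read from a design TSV).
#' @export
as_mock_members <- function(table) {
  required <- c("name", "genome_size_bp", "n_16s_copies")
  if (!all(required %in% names(table))) {
    stop("design table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  bact <- if ("is_bacterial" %in% names(table)) table$is_bacterial else TRUE
  bact <- rep_len(bact, nrow(table))
  lapply(seq_len(nrow(table)), function(i) {
    mock_member(table$name[i], table$genome_size_bp[i],
                table$n_16s_copies[i], is_bacterial = bact[i])
  })
}

#' Read a mock design table / write a recipe
#'
#' The design table is tab-separated with columns `name`, `genome_size_bp`,
#' `n_16s_copies` and optionally `is_bacterial`; the recipe output adds
#' `copies_per_ug`, `target_copies` and `mass_ug` per member.
#'
#' @param path File path.
#' @return `read_design_table()` a data frame; `write_recipe()` the path,
#'   invisibly.
#' @export
read_design_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_design_table
#' @param recipe A `mock_recipe` from [design_equal_mock()].
#' @export
write_recipe <- function(recipe, path) {
  stopifnot(inherits(recipe, "mock_recipe"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ampmock recipe: %d members, total_16s_copies=%.12g",
                     length(recipe$members),
                     recipe$target_total_16s_copies), con)
  utils::write.table(recipe$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
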