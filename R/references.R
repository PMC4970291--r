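#' Construct a reference set of known 16S gene sequences
#'
#' A reference set holds the true 16S rRNA gene sequences of a defined
#' community, one template per distinct gene copy (a genome with divergent
#' copies contributes more than one template), together with the relative
#' template abundance expected from the community design and a per-template
#' amplification efficiency in `[0, 1]` (used to model primer-binding-site
#' mismatches that depress a member's amplification).
#'
#' @param seqs Named character vector of A/C/G/T sequences.
#' @param genus Genus (member) label per template; defaults to template
#'   names.
#' @param is_bacterial Logical per template; non-bacterial templates mark
#'   control members excluded from bacterial summaries.
#' @param weights Relative template abundance (>= 0, at least one > 0).
#' @param efficiency Amplification efficiency per template in `[0, 1]`.
#' @return A `reference_set` object.
#' @export
reference_set <- function(seqs, genus = NULL, is_bacterial = TRUE,
                          weights = 1, efficiency = 1) {
  .check_dna(seqs, "seqs")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("`seqs` must have unique names", call. = FALSE)
  }
  n <- length(seqs)
  if (is.null(genus)) genus <- names(seqs)
  genus <- rep_len(as.character(genus), n)
  is_bacterial <- rep_len(as.logical(is_bacterial), n)
  weights <- rep_len(as.numeric(weights), n)
  efficiency <- rep_len(as.numeric(efficiency), n)
  if (any(weights < 0) || all(weights == 0)) {
    stop("`weights` must be >= 0 with at least one > 0", call. = FALSE)
  }
  if (any(efficiency < 0 | efficiency > 1)) {
    stop("`efficiency` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(seqs = seqs, genus = genus, is_bacterial = is_bacterial,
         weights = weights, efficiency = efficiency),
    class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set: %d templates (%d bacterial), lengths %d-%d bp\n",
              length(x$seqs), sum(x$is_bacterial),
              min(nchar(x$seqs)), max(nchar(x$seqs))))
  invisible(x)
}

.random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(.dna_bases, length, replace = TRUE), collapse = "")
  }, character(1))
}

.mutate_to_identity <- function(seq, identity) {
  # substitute round((1 - identity) * L) distinct positions so the realized
  # alignment identity lands on the target
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- round((1 - identity) * length(ch))
  if (k > 0) {
    pos <- sample.int(length(ch), k)
    ch[pos] <- vapply(ch[pos], function(b) {
      sample(setdiff(.dna_bases, b), 1L)
    }, character(1))
  }
  paste(ch, collapse = "")
}

#' Generate synthetic reference templates with controlled divergence
#'
#' Draws random templates and then rewrites constrained templates as mutated
#' copies of their partners so that selected pairs realize a target percent
#' identity — e.g. one within-genome pair at 94% identity, emulating a
#' genome whose two 16S copies diverge enough to split into separate OTUs at
#' a 97% cutoff. Unconstrained pairs are independent random sequences and
#' are verified to sit below a background identity ceiling.
#'
#' @param n_templates Number of templates (>= 2).
#' @param length Template length in bases (default 490, a V1-V3 amplicon).
#' @param divergence_spec List of constraints, each
#'   `list(pair = c(i, j), identity = x)` with `0 < x <= 1`: template `j` is
#'   rebuilt as a copy of template `i` at the given identity. A template may
#'   be the rebuilt member of at most one constraint.
#' @param seed Random seed.
#' @param max_background_identity Ceiling (fraction) enforced on all
#'   unconstrained pairs; exceeding it raises an error.
#' @param ... Passed to [reference_set()] (names, genus, weights, ...).
#' @return A `reference_set`.
#' @export
generate_references <- function(n_templates, length = 490,
                                divergence_spec = NULL, seed = 1,
                                max_background_identity = 0.97, ...) {
  if (n_templates < 2) stop("`n_templates` must be >= 2", call. = FALSE)
  if (length < 20) stop("`length` must be >= 20 bases", call. = FALSE)
  constrained <- integer(0)
  if (!is.null(divergence_spec)) {
    for (cs in divergence_spec) {
      if (!is.list(cs) || is.null(cs$pair) || length(cs$pair) != 2L ||
          is.null(cs$identity)) {
        stop("each divergence constraint needs `pair` (length 2) and ",
             "`identity`", call. = FALSE)
      }
      if (any(cs$pair < 1) || any(cs$pair > n_templates) ||
          cs$pair[1] == cs$pair[2]) {
        stop("divergence constraint pair out of range", call. = FALSE)
      }
      if (cs$identity <= 0 || cs$identity > 1) {
        stop("constraint identity must be in (0, 1]", call. = FALSE)
      }
      if (cs$pair[2] %in% constrained || cs$pair[2] %in%
          vapply(divergence_spec, function(z) z$pair[1], numeric(1))) {
        stop("contradictory divergence_spec: template ", cs$pair[2],
             " is constrained more than once or used as both source and ",
             "target", call. = FALSE)
      }
      constrained <- c(constrained, cs$pair[2])
    }
  }
  set.seed(seed)
  seqs <- .random_dna(n_templates, length)
  if (!is.null(divergence_spec)) {
    for (cs in divergence_spec) {
      seqs[cs$pair[2]] <- .mutate_to_identity(seqs[cs$pair[1]], cs$identity)
    }
  }
  names(seqs) <- sprintf("Template%02d", seq_len(n_templates))
  refs <- reference_set(seqs, ...)

  idm <- cpp_identity_matrix(refs$seqs, .aln_match, .aln_mismatch, .aln_gap)
  if (!is.null(divergence_spec)) {
    for (cs in divergence_spec) {
      realized <- idm[cs$pair[1], cs$pair[2]] / 100
      if (abs(realized - cs$identity) > 0.01) {
        stop(sprintf(
          "infeasible divergence_spec: pair (%d, %d) realized %.1f%%, target %.1f%%",
          cs$pair[1], cs$pair[2], 100 * realized, 100 * cs$identity),
          call. = FALSE)
      }
    }
  }
  free <- upper.tri(idm)
  if (base::length(constrained)) {
    for (cs in divergence_spec) {
      free[cs$pair[1], cs$pair[2]] <- FALSE
      free[cs$pair[2], cs$pair[1]] <- FALSE
    }
  }
  if (any(idm[free] > 100 * max_background_identity)) {
    stop("infeasible divergence_spec: an unconstrained template pair ",
         "exceeds the background identity ceiling", call. = FALSE)
  }
  refs
}

#' Synthetic reference set emulating the 20-member mock community
#'
#' Builds one template per member of the packaged mock table
#' ([mock_community_members()]), plus a second *Haemophilus* template
#' constrained to 94% identity with the first — emulating a genome whose
#' two 16S rRNA gene copies cluster into separate OTUs at a 97% cutoff, so
#' the 19 bacterial genomes yield 20 bacterial OTUs. Template weights split
#' each member's equal (5%) 16S-copy share over its templates. With
#' `primer_bias = TRUE` the *Desulfovibrio* and *Coriobacterium* templates
#' get strongly reduced amplification efficiency, mimicking primer-binding-
#' site mismatches that cause those members to be under-detected.
#'
#' The sequences themselves are synthetic random templates, not the
#' organisms' real 16S genes; only the community structure (membership,
#' copy-pair divergence, dosage, bias) is emulated.
#'
#' @param length Template length in bases.
#' @param seed Random seed.
#' @param primer_bias Apply the two under-amplified members.
#' @return A `reference_set` with 21 templates (20 bacterial + 1 archaeal
#'   control).
#' @export
mock_reference_set <- function(length = 490, seed = 1, primer_bias = TRUE) {
  members <- mock_community_members()
  n_members <- nrow(members)
  hp <- which(members$genus == "Haemophilus")
  n_templates <- n_members + 1L
  genus <- c(members$genus, members$genus[hp])
  bact <- c(members$is_bacterial, TRUE)
  weights <- rep(1 / n_members, n_templates)
  weights[c(hp, n_templates)] <- 1 / (2 * n_members)
  eff <- rep(1, n_templates)
  if (primer_bias) {
    eff[members$genus == "Desulfovibrio"] <- 0.01
    eff[members$genus == "Coriobacterium"] <- 0.05
  }
  refs <- generate_references(
    n_templates, length = length, seed = seed,
    divergence_spec = list(list(pair = c(hp, n_templates), identity = 0.94)),
    genus = genus, is_bacterial = bact, weights = weights, efficiency = eff)
  copy_no <- stats::ave(seq_along(genus), genus, FUN = seq_along)
  names(refs$seqs) <- sprintf("%s_%d", genus, copy_no)
  refs
}
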