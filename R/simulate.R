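#' Simulation configuration for a multi-sample amplicon run
#'
#' Parameters of the synthetic MiSeq-style run: replicate count and depth,
#' per-base substitution/insertion/deletion probabilities, a per-read
#' chimera probability, and a low-frequency noise tail (reads drawn from a
#' pool of random contaminant templates, emulating unclassifiable spurious
#' sequences such as between-run carry-over). Defaults describe the
#' run-scale study conditions: 12 replicate samples, 8000 assembled
#' 490 bp V1-V3 amplicons each.
#'
#' @param n_samples Number of replicate samples.
#' @param depth Reads per sample.
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities.
#' @param chimera_prob Per-read probability of a two-parent chimera.
#' @param noise_rate Per-read probability of a contaminant (noise) read.
#' @param n_noise_templates Size of the contaminant template pool.
#' @param seed Random seed; identical seeds give identical runs.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_samples = 12, depth = 8000, sub_rate = 0.005,
                       ins_rate = 5e-4, del_rate = 5e-4,
                       chimera_prob = 0.01, noise_rate = 0.05,
                       n_noise_templates = 5000, seed = 1) {
  probs <- c(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
             chimera_prob = chimera_prob, noise_rate = noise_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("rates and probabilities must be in [0, 1]", call. = FALSE)
  }
  if (chimera_prob + noise_rate > 1) {
    stop("`chimera_prob` + `noise_rate` must be <= 1", call. = FALSE)
  }
  if (n_samples < 1 || depth < 1) {
    stop("`n_samples` and `depth` must be >= 1", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), depth = as.integer(depth),
         sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
         chimera_prob = chimera_prob, noise_rate = noise_rate,
         n_noise_templates = as.integer(n_noise_templates),
         seed = as.integer(seed)),
    class = "sim_config")
}

# Inject per-base errors; returns the read and the injected operation counts.
.inject_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_del <- 0L
  if (del_rate > 0) {
    keep <- stats::runif(length(ch)) >= del_rate
    n_del <- sum(!keep)
    ch <- ch[keep]
  }
  n_sub <- 0L
  if (sub_rate > 0 && length(ch)) {
    hit <- stats::runif(length(ch)) < sub_rate
    n_sub <- sum(hit)
    if (n_sub > 0) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(.dna_bases, b), 1L)
      }, character(1))
    }
  }
  n_ins <- 0L
  if (ins_rate > 0) {
    slots <- stats::runif(length(ch) + 1L) < ins_rate
    n_ins <- sum(slots)
    if (n_ins > 0) {
      out <- character(length(ch) + n_ins)
      k <- 1L
      for (i in seq_along(slots)) {
        if (slots[i]) {
          out[k] <- sample(.dna_bases, 1L)
          k <- k + 1L
        }
        if (i <= length(ch)) {
          out[k] <- ch[i]
          k <- k + 1L
        }
      }
      ch <- out
    }
  }
  list(seq = paste(ch, collapse = ""), n_sub = n_sub, n_ins = n_ins,
       n_del = n_del)
}

#' Simulate a ground-truthed multi-sample amplicon run
#'
#' Per sample, `depth` reads are drawn. Each read is, mutually exclusively,
#' a contaminant-pool read (probability `noise_rate`), a chimera joining the
#' prefix of one template to the suffix of another at a uniform interior
#' breakpoint (probability `chimera_prob`), or an ordinary template read.
#' Template draws follow `weights * efficiency`, renormalized; chimera
#' parents are drawn from the same distribution. Substitutions (uniform over
#' the three alternative bases), single-base insertions and deletions are
#' then injected per base at the configured rates. Reads are simulated as
#' already-assembled full amplicons; paired-end overlap assembly is not
#' modeled.
#'
#' @param refs A [reference_set()].
#' @param cfg A [sim_config()].
#' @return A `simulated_run`: `reads` (per-sample named character vectors),
#'   `truth` (one row per read: source template(s), chimera/noise flags,
#'   breakpoint, injected error counts), and the `refs` used.
#' @export
simulate_run <- function(refs, cfg) {
  stopifnot(inherits(refs, "reference_set"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- refs$weights * refs$efficiency
  if (all(p == 0)) stop("all templates have zero effective weight",
                        call. = FALSE)
  p <- p / sum(p)
  tlen <- nchar(refs$seqs)
  noise_pool <- if (cfg$noise_rate > 0) {
    stats::setNames(.random_dna(cfg$n_noise_templates, max(tlen)),
                    sprintf("noise_%04d", seq_len(cfg$n_noise_templates)))
  } else character(0)

  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  reads <- vector("list", cfg$n_samples)
  names(reads) <- samples
  truth_rows <- vector("list", cfg$n_samples)

  for (s in seq_len(cfg$n_samples)) {
    type <- sample(c("template", "chimera", "noise"), cfg$depth,
                   replace = TRUE,
                   prob = c(1 - cfg$chimera_prob - cfg$noise_rate,
                            cfg$chimera_prob, cfg$noise_rate))
    ids <- sprintf("%s_R%05d", samples[s], seq_len(cfg$depth))
    seqs <- character(cfg$depth)
    tmpl <- character(cfg$depth)
    tmpl2 <- rep(NA_character_, cfg$depth)
    brk <- rep(NA_integer_, cfg$depth)
    nsub <- nins <- ndel <- integer(cfg$depth)
    for (r in seq_len(cfg$depth)) {
      if (type[r] == "noise") {
        k <- sample.int(length(noise_pool), 1L)
        base_seq <- noise_pool[[k]]
        tmpl[r] <- names(noise_pool)[k]
      } else if (type[r] == "chimera") {
        par <- sample.int(length(p), 2L, replace = TRUE, prob = p)
        b <- sample.int(min(tlen[par]) - 1L, 1L)  # interior breakpoint
        base_seq <- paste0(substr(refs$seqs[[par[1]]], 1L, b),
                           substr(refs$seqs[[par[2]]], b + 1L,
                                  tlen[par[2]]))
        tmpl[r] <- names(refs$seqs)[par[1]]
        tmpl2[r] <- names(refs$seqs)[par[2]]
        brk[r] <- b
      } else {
        k <- sample.int(length(p), 1L, prob = p)
        base_seq <- refs$seqs[[k]]
        tmpl[r] <- names(refs$seqs)[k]
      }
      err <- .inject_errors(base_seq, cfg$sub_rate, cfg$ins_rate,
                            cfg$del_rate)
      seqs[r] <- err$seq
      nsub[r] <- err$n_sub
      nins[r] <- err$n_ins
      ndel[r] <- err$n_del
    }
    names(seqs) <- ids
    reads[[s]] <- seqs
    truth_rows[[s]] <- data.frame(
      read_id = ids, sample = samples[s], template = tmpl,
      template2 = tmpl2, breakpoint = brk,
      is_chimera = type == "chimera", is_noise = type == "noise",
      n_sub = nsub, n_ins = nins, n_del = ndel,
      stringsAsFactors = FALSE)
  }
  structure(
    list(reads = reads, truth = do.call(rbind, truth_rows), refs = refs,
         config = cfg),
    class = "simulated_run")
}

#' @export
print.simulated_run <- function(x, ...) {
  cat(sprintf(
    "Simulated amplicon run: %d samples x %d reads (%.1f%% chimera, %.1f%% noise reads)\n",
    length(x$reads), x$config$depth,
    100 * mean(x$truth$is_chimera), 100 * mean(x$truth$is_noise)))
  invisible(x)
}

#' Write a simulated run to disk
#'
#' One FASTA per sample, a two-column group file (read id, sample) and the
#' truth table as TSV.
#'
#' @param run A [simulate_run()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "simulated_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(run$reads)) {
    write_fasta(run$reads[[s]], file.path(dir, paste0(s, ".fasta")))
  }
  groups <- data.frame(
    read_id = unlist(lapply(run$reads, names), use.names = FALSE),
    sample = rep(names(run$reads), lengths(run$reads)))
  write_groups(groups, file.path(dir, "groups.tsv"))
  utils::write.table(run$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
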