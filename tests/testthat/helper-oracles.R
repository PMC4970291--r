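# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Global-alignment score oracle: memoised recursion over the edit graph,
# written independently of the package's dynamic-programming matrix fill.
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- if (i == 0L && j == 0L) {
      0
    } else if (i == 0L) {
      j * gap
    } else if (j == 0L) {
      i * gap
    } else {
      max(rec(i - 1L, j - 1L) +
            (if (av[i] == bv[j]) match else mismatch),
          rec(i - 1L, j) + gap,
          rec(i, j - 1L) + gap)
    }
    memo[[key]] <- res
    res
  }
  rec(length(av), length(bv))
}

# Greedy average-linkage oracle: repeatedly merge the closest cluster pair
# while the mean inter-cluster distance stays at or below the cutoff.
oracle_average_linkage <- function(dm, cutoff) {
  clusters <- as.list(seq_len(nrow(dm)))
  while (length(clusters) > 1L) {
    bestd <- Inf
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        d <- mean(dm[clusters[[j]], clusters[[i]]])
        if (d < bestd) {
          bestd <- d
          best <- c(j, i)
        }
      }
    }
    if (bestd > cutoff) break
    clusters[[best[1L]]] <- sort(c(clusters[[best[1L]]],
                                   clusters[[best[2L]]]))
    clusters[[best[2L]]] <- NULL
  }
  membership <- integer(nrow(dm))
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  membership
}

# Canonical label for a partition so memberships can be compared across
# implementations that number clusters differently.
partition_signature <- function(membership) {
  groups <- split(seq_along(membership), membership)
  paste(sort(vapply(groups, paste, character(1), collapse = ",")),
        collapse = ";")
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sum(resid^2) / ss_tot)
}

# Tricube-weighted local linear fit evaluated at each x with a full-span
# window: what lowess reduces to at fraction 1 with no robustifying steps.
oracle_global_weighted_fit <- function(x, y) {
  vapply(seq_along(x), function(i) {
    d <- abs(x - x[i])
    h <- max(d)
    w <- (1 - pmin(1, d / h)^3)^3
    fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y), weights = w)
    unname(stats::predict(fit, data.frame(x = x[i])))
  }, numeric(1))
}

# Unique-sequence table with prescribed counts and arbitrary distinct
# sequences (or caller-supplied ones).
make_useq <- function(counts, seqs = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("Useq%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  }
  if (is.null(seqs)) seqs <- random_dna(nrow(counts), 40)
  useq_table(stats::setNames(seqs, rownames(counts)), counts)
}

# OTU table with prescribed counts, bypassing clustering, for testing the
# diversity formulas in isolation.
make_otus <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("Otu%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  }
  structure(
    list(counts = counts,
         members = stats::setNames(as.list(rownames(counts)),
                                   rownames(counts)),
         representatives = NULL, cutoff = 0.03,
         samples = colnames(counts)),
    class = "otu_table")
}

# Deterministic spectrum fixture: a clean power law with excess singleton
# and doubleton clusters, emulating a low-frequency noise tail on top of a
# linear log-log trend.
noisy_spectrum_table <- function() {
  sizes <- 1:20
  base <- pmax(1L, as.integer(round(2000 * sizes^-2)))
  n_clusters <- base
  n_clusters[1] <- base[1] * 5L
  n_clusters[2] <- base[2] * 2L
  pooled <- rep.int(sizes, n_clusters)
  make_useq(matrix(pooled, ncol = 1))
}
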