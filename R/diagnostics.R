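#' Log-log points of a cluster-size spectrum
#'
#' Converts a cluster-size spectrum (size -> number of unique-sequence
#' clusters of that size) to `(log10 size, log10 frequency)` points, sorted
#' by size. Zero-frequency entries are dropped rather than logged.
#'
#' @param spectrum Data frame from [cluster_size_spectrum()] (columns
#'   `cluster_size`, `n_clusters`).
#' @return Data frame with columns `x` (log10 cluster size) and `y`
#'   (log10 frequency).
#' @export
loglog_spectrum <- function(spectrum) {
  if (!all(c("cluster_size", "n_clusters") %in% names(spectrum)) ||
      nrow(spectrum) == 0L) {
    stop("`spectrum` must have columns cluster_size and n_clusters",
         call. = FALSE)
  }
  spectrum <- spectrum[spectrum$n_clusters > 0, , drop = FALSE]
  if (any(spectrum$cluster_size < 1)) {
    stop("cluster sizes must be >= 1", call. = FALSE)
  }
  spectrum <- spectrum[order(spectrum$cluster_size), , drop = FALSE]
  data.frame(x = log10(spectrum$cluster_size),
             y = log10(spectrum$n_clusters))
}

#' Ordinary least-squares fit of log-log spectrum points
#'
#' @param points Data frame with columns `x`, `y` (>= 3 rows).
#' @return List: `slope`, `intercept`, `r_squared`, `residual_se`,
#'   `n_points`.
#' @export
fit_linear <- function(points) {
  if (!all(c("x", "y") %in% names(points))) {
    stop("`points` must have columns x and y", call. = FALSE)
  }
  if (nrow(points) < 3L) {
    stop("insufficient data: need >= 3 points for a linear fit",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = points)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((points$y - mean(points$y))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (tss > 0) 1 - rss / tss else 1,
       residual_se = sqrt(rss / (nrow(points) - 2L)),
       n_points = nrow(points))
}

#' Lowess smooth of log-log spectrum points
#'
#' Locally weighted (tricube) linear regression with robustifying
#' iterations, via the classic lowess algorithm. Defaults (span 2/3,
#' 3 iterations) are the conventional choices. The smoother reproduces any
#' affine trend exactly.
#'
#' @param points Data frame with columns `x`, `y` (>= 4 rows).
#' @param fraction Smoother span in (0, 1]; the window must cover at least
#'   2 points.
#' @param iterations Robustifying iterations (>= 0).
#' @return Data frame with the smoothed curve (`x`, `y_smooth`).
#' @export
lowess_fit <- function(points, fraction = 2 / 3, iterations = 3) {
  if (!all(c("x", "y") %in% names(points)) || nrow(points) < 4L) {
    stop("`points` must have columns x and y with >= 4 rows",
         call. = FALSE)
  }
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  if (floor(fraction * nrow(points)) < 2) {
    stop("`fraction` too small: each window must cover >= 2 points",
         call. = FALSE)
  }
  # delta = 0: fit at every x rather than interpolating between close
  # points; spectra are small enough that exactness beats speed.
  # When the non-robust smooth already interpolates the data (e.g.
  # collinear points) the robustifying iterations would divide by a zero
  # median residual, so they are skipped as a no-op.
  ord <- order(points$x)
  sm <- stats::lowess(points$x, points$y, f = fraction, iter = 0,
                      delta = 0)
  scale <- max(1, diff(range(points$y)))
  if (iterations > 0 &&
      max(abs(points$y[ord] - sm$y)) > 1e-10 * scale) {
    sm <- stats::lowess(points$x, points$y, f = fraction,
                        iter = iterations, delta = 0)
  }
  data.frame(x = sm$x, y_smooth = sm$y)
}

#' Spectrum fit: points, regression line, lowess curve
#'
#' Bundles the Fig.-1-style analysis of one unique-sequence table: the
#' log-log cluster-size points, their OLS fit and the lowess smooth. The
#' low-frequency (small cluster size) end departing from the straight-line
#' trend is the signature that motivates singleton/doubleton removal.
#'
#' @param table A [useq_table()].
#' @param fraction,iterations Lowess parameters.
#' @return A `spectrum_fit`: `points`, `linear`, `lowess`.
#' @export
fit_spectrum <- function(table, fraction = 2 / 3, iterations = 3) {
  pts <- loglog_spectrum(cluster_size_spectrum(table))
  lin <- if (nrow(pts) >= 3L) fit_linear(pts) else NULL
  low <- if (nrow(pts) >= 4L && floor(fraction * nrow(pts)) >= 2) {
    lowess_fit(pts, fraction, iterations)
  } else {
    NULL
  }
  structure(list(points = pts, linear = lin, lowess = low),
            class = "spectrum_fit")
}

#' Does low-frequency filtering improve the spectrum's linear fit?
#'
#' Fits the log-log cluster-size spectrum of the table after filtering at
#' each threshold (1 = all sequences, 2 = singletons removed,
#' 3 = singletons and doubletons removed) and reports the r-squared values,
#' flagging whether the fit improves monotonically with filtering.
#' Spectra with fewer than 3 distinct sizes are marked not evaluable.
#'
#' @param table A [useq_table()].
#' @param thresholds Pooled-count thresholds to compare.
#' @return Data frame (threshold, n_sizes, slope, r_squared, evaluable)
#'   with attribute `monotone_improvement` (logical, NA when any branch is
#'   not evaluable).
#' @export
filtering_improves_fit <- function(table, thresholds = c(1, 2, 3)) {
  stopifnot(inherits(table, "useq_table"))
  rows <- lapply(thresholds, function(t) {
    ft <- remove_rare(table, t)$table
    if (nrow(ft$counts) == 0L) {
      return(data.frame(threshold = t, n_sizes = 0L, slope = NA_real_,
                        r_squared = NA_real_, evaluable = FALSE))
    }
    pts <- loglog_spectrum(cluster_size_spectrum(ft))
    if (nrow(pts) < 3L) {
      return(data.frame(threshold = t, n_sizes = nrow(pts),
                        slope = NA_real_, r_squared = NA_real_,
                        evaluable = FALSE))
    }
    lin <- fit_linear(pts)
    data.frame(threshold = t, n_sizes = nrow(pts), slope = lin$slope,
               r_squared = lin$r_squared, evaluable = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "monotone_improvement") <- if (all(out$evaluable)) {
    all(diff(out$r_squared) >= 0)
  } else {
    NA
  }
  out
}
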