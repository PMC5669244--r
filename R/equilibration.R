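#' Assign the equilibration period by CV histogramming
#'
#' Splits the trajectory into `n_intervals` equal consecutive time intervals,
#' histograms the biased CV in each on a common grid, and takes the
#' equilibration time as the start of the first interval from which all
#' successive pairwise L1 distances between normalised histograms stay at or
#' below `threshold`. If no such interval exists, the start of the last
#' interval is returned and the report is flagged as non-equilibrated.
#'
#' @param frames a [frame_series()].
#' @param n_intervals number of equal-time intervals (>= 3).
#' @param threshold L1 tolerance on normalised histograms (default 0.1).
#' @param binning CV bin width, nm.
#' @return an object of class `equilibration_report` with fields
#'   `interval_edges`, `histograms` (intervals x bins), `distances`, `t_eq`,
#'   `threshold`, and `equilibrated`.
#' @export
assign_equilibration <- function(frames, n_intervals = 5, threshold = 0.1,
                                 binning = 0.02) {
  stopifnot(n_intervals >= 3, threshold > 0, binning > 0)
  n <- length(frames)
  if (n < n_intervals) stop("fewer frames than intervals")
  t0 <- frames$times[1]
  t1 <- frames$times[n]
  edges <- t0 + (t1 - t0) * (seq_len(n_intervals) - 1) / n_intervals

  r <- range(frames$cv)
  nb <- max(2L, ceiling((r[2] - r[1]) / binning))
  breaks <- seq(r[1], r[2], length.out = nb + 1L)
  # half-open bins [lo, hi); top edge closed so no frame is dropped
  bin <- pmin(findInterval(frames$cv, breaks, rightmost.closed = TRUE), nb)

  # interval index of each frame (last interval closed on the right)
  iv <- pmin(findInterval(frames$times, c(edges, t1), rightmost.closed = TRUE),
             n_intervals)
  H <- matrix(0, n_intervals, nb)
  for (k in seq_len(n_intervals)) {
    cnt <- tabulate(bin[iv == k], nbins = nb)
    if (sum(cnt) == 0) stop("interval ", k, " contains no frames")
    H[k, ] <- cnt / sum(cnt)
  }
  d <- vapply(seq_len(n_intervals - 1), function(k) sum(abs(H[k + 1, ] - H[k, ])), 0)

  ok_from <- NA_integer_
  for (j in seq_len(n_intervals - 1)) {
    if (all(d[j:(n_intervals - 1)] <= threshold)) { ok_from <- j; break }
  }
  equilibrated <- !is.na(ok_from)
  if (!equilibrated) ok_from <- n_intervals

  structure(list(interval_edges = edges, histograms = H, distances = d,
                 t_eq = edges[ok_from], threshold = threshold,
                 equilibrated = equilibrated, breaks = breaks),
            class = "equilibration_report")
}

#' @export
print.equilibration_report <- function(x, ...) {
  cat(sprintf("equilibration_report: t_eq = %g ps (%sequilibrated, threshold %g)\n",
              x$t_eq, if (x$equilibrated) "" else "NOT ", x$threshold))
  cat("  successive L1 distances:", paste(sprintf("%.3f", x$distances),
                                          collapse = " "), "\n")
  invisible(x)
}
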