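#' Per-frame unbiased statistical weights
#'
#' @param times frame times, ps.
#' @param W per-frame weights; normalised to sum to 1.
#' @param scheme one of `"average_weight"`, `"time_period"`, `"bonomi"`,
#'   `"uniform"`.
#' @param n_of_s optional per-bin frame counts N(s) (average-weight scheme).
#' @param n_excluded number of frames dropped (e.g. empty-bin frames).
#' @return an object of class `frame_weights` with effective sample size
#'   `ess = 1 / sum(W^2)`.
#' @export
frame_weights <- function(times, W, scheme, n_of_s = NULL, n_excluded = 0L) {
  stopifnot(length(times) == length(W), all(W >= 0))
  s <- sum(W)
  if (s <= 0) stop("weights sum to zero")
  W <- W / s
  structure(list(times = as.numeric(times), W = W, scheme = scheme,
                 ess = 1 / sum(W^2), n_of_s = n_of_s,
                 n_excluded = as.integer(n_excluded)),
            class = "frame_weights")
}

#' @export
print.frame_weights <- function(x, ...) {
  cat(sprintf("frame_weights (%s): %d frames, ESS = %.1f%s\n", x$scheme,
              length(x$W), x$ess,
              if (x$n_excluded > 0) sprintf(", %d frames excluded", x$n_excluded)
              else ""))
  invisible(x)
}

bin_breaks <- function(config) {
  seq(config$grid_min, config$grid_max, by = config$binning)
}

# half-open bins [lo, hi); frames outside the grid raise an error
cv_bins <- function(cv, config) {
  breaks <- bin_breaks(config)
  if (breaks[length(breaks)] < config$grid_max)
    breaks <- c(breaks, config$grid_max)
  out <- which(cv < config$grid_min | cv > config$grid_max)
  if (length(out))
    stop("frame CV outside the profile grid at frame(s): ",
         paste(head(out, 10), collapse = ", "),
         if (length(out) > 10) " ..." else "")
  nb <- length(breaks) - 1L
  bin <- pmin(findInterval(cv, breaks, rightmost.closed = TRUE), nb)
  list(bin = bin, breaks = breaks, nb = nb,
       centers = (breaks[-1] + breaks[-length(breaks)]) / 2)
}

#' 'Average Weight' re-weighting
#'
#' All frames sharing a CV bin are weighted equally:
#' `W(t) = exp(-G(s(t), t_f) / kT) / N(s(t))`, normalised, where G is the
#' (symmetrised) end-of-run free-energy estimate and N(s) the number of frames
#' in the bin of s(t). Bins with no frames contribute nothing.
#'
#' @param frames a [frame_series()], already restricted to the
#'   post-equilibration window.
#' @param profile a [free_energy_profile()] (conventionally symmetrised).
#' @param config a [run_config()] (supplies kT and the N(s) binning).
#' @return a [frame_weights()] with `n_of_s` filled in.
#' @export
average_weight <- function(frames, profile, config) {
  b <- cv_bins(frames$cv, config)
  N <- tabulate(b$bin, nbins = b$nb)
  Gc <- profile_at(profile, pmin(pmax(b$centers, profile$grid[1]),
                                 profile$grid[length(profile$grid)]))
  kt <- config$kB * config$temperature
  Wraw <- exp(-Gc[b$bin] / kt) / N[b$bin]
  frame_weights(frames$times, Wraw, "average_weight", n_of_s = N)
}

#' 'Bonomi' re-weighting (time-dependent bias with running offset)
#'
#' `W(t) = exp((V(s(t), t) - c(t)) / kT)`, normalised, where V is the bias
#' accumulated up to the frame time and
#' `c(t) = kT log < exp(V(s, t)/kT) >_grid` (trapezoid average over the CV
#' grid), updated at every hill deposition. Frames before the first hill see
#' zero bias.
#'
#' @param frames a [frame_series()].
#' @param hills a [hill_records()] data frame, time-aligned with the frames.
#' @param config a [run_config()].
#' @return a [frame_weights()].
#' @export
bonomi_weights <- function(frames, hills, config) {
  grid <- cv_grid(config)
  kt <- config$kB * config$temperature
  nh <- nrow(hills)
  # hill interval of each frame: number of hills with time <= t
  k_of_t <- if (nh) findInterval(frames$times, hills$time) else rep(0L, length(frames))
  logw <- numeric(length(frames))
  V <- numeric(length(grid))
  cK <- 0 # kT log <exp(0)> = 0
  for (k in 0:nh) {
    if (k > 0) {
      c0 <- hills$center[k]; sg <- hills$sigma[k]; h <- hills$height[k]
      j1 <- findInterval(c0 - 6 * sg, grid) + 1L
      j2 <- findInterval(c0 + 6 * sg, grid)
      if (j2 >= j1) {
        d <- grid[j1:j2] - c0
        V[j1:j2] <- V[j1:j2] + h * exp(-0.5 * d * d / (sg * sg))
      }
      cK <- kt * log(trapz(grid, exp(V / kt)) / (grid[length(grid)] - grid[1]))
    }
    idx <- which(k_of_t == k)
    if (length(idx)) {
      Vf <- approx(grid, V, xout = frames$cv[idx], rule = 2)$y
      logw[idx] <- (Vf - cK) / kt
    }
  }
  frame_weights(frames$times, exp(logw - max(logw)), "bonomi")
}

#' 'Time Period' re-weighting (block-frozen bias)
#'
#' The trajectory is split into `n_blocks` equal time blocks; within block b
#' the bias is frozen at its value at the block end, giving static-bias
#' umbrella weights `W(t) = exp(V(s(t), t_b_end) / kT)`. Blocks are combined
#' with equal mass (each block's weights sum to `1/n_blocks`). This block
#' construction is one reasonable reading of the scheme; see the methods
#' vignette.
#'
#' @param frames a [frame_series()] (post-equilibration window).
#' @param hills a [hill_records()] data frame.
#' @param n_blocks number of equal time blocks (>= 1).
#' @param config a [run_config()].
#' @return a [frame_weights()].
#' @export
time_period_weights <- function(frames, hills, n_blocks = 4, config) {
  stopifnot(n_blocks >= 1)
  n <- length(frames)
  grid <- cv_grid(config)
  kt <- config$kB * config$temperature
  t0 <- frames$times[1]
  t1 <- frames$times[n]
  edges <- t0 + (t1 - t0) * seq_len(n_blocks) / n_blocks
  blk <- pmin(findInterval(frames$times, c(t0, edges), rightmost.closed = TRUE),
              n_blocks)
  W <- numeric(n)
  for (b in seq_len(n_blocks)) {
    idx <- which(blk == b)
    if (!length(idx)) stop("time block ", b, " contains no frames")
    Vb <- sum_hills(hills, grid, until = edges[b])$final_bias
    Vf <- approx(grid, Vb, xout = frames$cv[idx], rule = 2)$y
    wb <- exp((Vf - max(Vf)) / kt)
    W[idx] <- wb / sum(wb) / n_blocks
  }
  frame_weights(frames$times, W, "time_period")
}

#' Uniform weights (plain time average)
#'
#' @param frames a [frame_series()].
#' @return a [frame_weights()].
#' @export
uniform_weights <- function(frames) {
  n <- length(frames)
  frame_weights(frames$times, rep(1 / n, n), "uniform")
}

#' Re-weighted ensemble average with block-bootstrap error
#'
#' Computes `sum(W * x)` for a named observable and a standard error from a
#' weighted moving-block bootstrap (blocks of consecutive frames, resampled
#' with replacement; each resample is re-normalised).
#'
#' @param frames a [frame_series()] carrying the observable.
#' @param weights a [frame_weights()] aligned with `frames`.
#' @param observable observable name.
#' @param block_length bootstrap block length, frames.
#' @param n_resamples number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list with `estimate`, `se`, `ess`, and `low_ess` (TRUE when the
#'   effective sample size is below 10, flagged with a warning).
#' @export
weighted_average <- function(frames, weights, observable, block_length = 100,
                             n_resamples = 200, seed = 1L) {
  if (!observable %in% names(frames$observables))
    stop("observable not present: ", observable)
  x <- frames$observables[[observable]]
  n <- length(x)
  if (length(weights$W) != n) stop("weights not aligned with frames")
  W <- weights$W
  est <- sum(W * x)
  low_ess <- weights$ess < 10
  if (low_ess) warning("effective sample size below 10; estimate unreliable")

  set.seed(seed)
  L <- max(1L, min(as.integer(block_length), n))
  nblk <- ceiling(n / L)
  starts_max <- n - L + 1L
  boot <- vapply(seq_len(n_resamples), function(r) {
    st <- sample.int(starts_max, nblk, replace = TRUE)
    idx <- as.vector(outer(0:(L - 1L), st, "+"))[seq_len(n)]
    sw <- sum(W[idx])
    if (sw == 0) return(NA_real_)
    sum(W[idx] * x[idx]) / sw
  }, 0)
  se <- stats::sd(boot, na.rm = TRUE)
  if (!is.finite(se)) se <- 0
  list(estimate = est, se = se, ess = weights$ess, low_ess = low_ess)
}

# trapezoid rule on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
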