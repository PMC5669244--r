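#' Vertical interfacial water density profile
#'
#' Histograms water-oxygen heights above the gold top layer across frames
#' (optionally frame-weighted) and converts counts to mass density using the
#' water molecular mass and the slab cross-section. The first interfacial
#' layer boundary is the first local minimum (trough) after the first local
#' maximum (peak) of the profile; extrema are strict sign changes of the
#' discrete first difference, ties resolved to the smaller z.
#'
#' @param frames list of [slab_frame()] objects sharing box dimensions.
#' @param weights a [frame_weights()] aligned with `frames`, or `NULL` for
#'   uniform weights.
#' @param bin_width vertical bin width, nm.
#' @param smooth apply a 3-bin moving average before extremum detection
#'   (flagged in the output; the returned densities are unsmoothed).
#' @return an object of class `density_profile` with fields `axis` (bin
#'   centers, nm above the gold top), `density` (kg/m^3), `first_peak_z`,
#'   `first_trough_z` (NA with `trough_defined = FALSE` when no local minimum
#'   exists), and `layer1_count` (mean waters with height <= trough).
#' @export
vertical_profile <- function(frames, weights = NULL, bin_width = 0.01,
                             smooth = FALSE) {
  n <- length(frames)
  stopifnot(n > 0, bin_width > 0)
  box <- frames[[1]]$box
  for (fr in frames)
    if (max(abs(fr$box - box)) > 1e-6) stop("frames do not share box dimensions")
  W <- if (is.null(weights)) rep(1 / n, n) else weights$W / sum(weights$W)
  if (length(W) != n) stop("weights not aligned with frames")

  zmax <- box[3] - frames[[1]]$gold_top_z
  nb <- ceiling(zmax / bin_width) + 1L
  counts <- numeric(nb)
  for (f in seq_len(n)) {
    h <- frames[[f]]$water_oxygens[, 3] - frames[[f]]$gold_top_z
    b <- pmin(pmax(floor(h / bin_width) + 1L, 1L), nb)
    counts <- counts + W[f] * tabulate(b, nbins = nb)
  }
  axis <- (seq_len(nb) - 0.5) * bin_width
  # kg/m^3: molecules * m_w[kg] / (A[nm^2] * dz[nm] * 1e-27 m^3/nm^3)
  vol_m3 <- box[1] * box[2] * bin_width * 1e-27
  density <- counts * WATER_MASS_KG / vol_m3

  d <- if (smooth) stats::filter(density, rep(1 / 3, 3), sides = 2) else density
  d[is.na(d)] <- 0
  ext <- first_peak_trough(as.numeric(d))
  first_peak_z <- if (is.na(ext$peak)) NA_real_ else axis[ext$peak]
  first_trough_z <- if (is.na(ext$trough)) NA_real_ else axis[ext$trough]

  layer1_count <- NA_real_
  if (!is.na(first_trough_z)) {
    layer1_count <- sum(vapply(seq_len(n), function(f) {
      h <- frames[[f]]$water_oxygens[, 3] - frames[[f]]$gold_top_z
      W[f] * sum(h <= first_trough_z)
    }, 0))
  }
  structure(list(axis = axis, density = density, bin_width = bin_width,
                 box = box, first_peak_z = first_peak_z,
                 first_trough_z = first_trough_z,
                 trough_defined = !is.na(first_trough_z),
                 layer1_count = layer1_count, smoothed = smooth,
                 n_frames = n),
            class = "density_profile")
}

# Strict local maxima (plateau ties resolved to the smaller z) that reach at
# least min_peak_frac of the global maximum; the first-layer trough is the
# minimum of the stretch between the first two such peaks (ties -> smaller z).
# The density floor suppresses single-molecule spikes in empirical histograms.
first_peak_trough <- function(d, min_peak_frac = 0.25) {
  n <- length(d)
  floor_d <- min_peak_frac * max(d)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (d[i] > d[i - 1] && d[i] >= floor_d) {
      j <- i
      while (j < n && d[j + 1] == d[j]) j <- j + 1L  # walk plateaus
      if (j < n && d[j + 1] < d[j]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(peaks) < 1)
    return(list(peak = NA_integer_, trough = NA_integer_))
  peak <- peaks[1]
  if (length(peaks) < 2)
    return(list(peak = peak, trough = NA_integer_))
  span <- (peak + 1L):(peaks[2] - 1L)
  trough <- span[which.min(d[span])]
  list(peak = peak, trough = trough)
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d bins of %g nm over %d frames%s\n",
              length(x$axis), x$bin_width, x$n_frames,
              if (x$smoothed) " (smoothed extrema)" else ""))
  if (x$trough_defined)
    cat(sprintf("  first peak %.3f nm, first trough %.3f nm, layer-1 count %.1f\n",
                x$first_peak_z, x$first_trough_z, x$layer1_count))
  else cat("  no first-layer trough found (featureless profile)\n")
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$axis, x$density, type = "l",
                 xlab = "height above gold top (nm)",
                 ylab = expression(rho ~ (kg ~ m^-3)), ...)
  if (x$trough_defined) graphics::abline(v = x$first_trough_z, lty = 2)
  invisible(x)
}

#' Lateral density map of the first interfacial water layer
#'
#' In-plane 2-D histogram of the waters below the first-layer boundary, with
#' periodic wrapping in x and y, converted to mass density using the layer
#' thickness.
#'
#' @param frames list of [slab_frame()] objects.
#' @param profile a [density_profile()] with a defined first trough.
#' @param cell in-plane cell edge, nm.
#' @param weights optional [frame_weights()] aligned with `frames`.
#' @return an object of class `lateral_map` with `x`, `y` cell centers and a
#'   `density` matrix (kg/m^3).
#' @export
lateral_map <- function(frames, profile, cell = 0.025, weights = NULL) {
  if (!profile$trough_defined) stop("profile has no defined first trough")
  n <- length(frames)
  box <- frames[[1]]$box
  if (cell > box[1] || cell > box[2]) stop("cell larger than the box")
  W <- if (is.null(weights)) rep(1 / n, n) else weights$W / sum(weights$W)
  nx <- max(1L, floor(box[1] / cell))
  ny <- max(1L, floor(box[2] / cell))
  cx <- box[1] / nx
  cy <- box[2] / ny
  counts <- matrix(0, nx, ny)
  for (f in seq_len(n)) {
    wo <- frames[[f]]$water_oxygens
    h <- wo[, 3] - frames[[f]]$gold_top_z
    sel <- h <= profile$first_trough_z
    if (!any(sel)) next
    ix <- floor((wo[sel, 1] %% box[1]) / cx) + 1L
    iy <- floor((wo[sel, 2] %% box[2]) / cy) + 1L
    ix[ix > nx] <- nx; iy[iy > ny] <- ny
    for (k in seq_along(ix))
      counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + W[f]
  }
  thickness <- profile$first_trough_z
  density <- counts * WATER_MASS_KG / (cx * cy * thickness * 1e-27)
  structure(list(x = (seq_len(nx) - 0.5) * cx, y = (seq_len(ny) - 0.5) * cy,
                 density = density, thickness = thickness,
                 cell = c(cx, cy), box = box),
            class = "lateral_map")
}

#' @export
print.lateral_map <- function(x, ...) {
  cat(sprintf("lateral_map: %d x %d cells (%.3f x %.3f nm), layer thickness %.3f nm\n",
              length(x$x), length(x$y), x$cell[1], x$cell[2], x$thickness))
  cat(sprintf("  density range %.1f - %.1f kg/m^3\n",
              min(x$density), max(x$density)))
  invisible(x)
}

#' Peptide-displaced first-layer water count
#'
#' Difference between the bare-surface first-layer water count and the
#' weighted mean first-layer count over bound-state frames, using the bare
#' profile's trough boundary for both. The spread is the weighted standard
#' deviation of the per-frame counts.
#'
#' @param bare a [density_profile()] of the peptide-free surface with a
#'   defined first layer.
#' @param bound_frames list of [slab_frame()] objects restricted to the bound
#'   state (CV at the bottom of the free-energy well).
#' @param weights a [frame_weights()] aligned with `bound_frames`, or `NULL`.
#' @return list with `count` (waters displaced) and `spread`.
#' @export
displaced_waters <- function(bare, bound_frames, weights = NULL) {
  if (!bare$trough_defined) stop("bare profile has no defined first trough")
  n <- length(bound_frames)
  stopifnot(n > 0)
  W <- if (is.null(weights)) rep(1 / n, n) else weights$W / sum(weights$W)
  n1 <- vapply(bound_frames, function(fr) {
    sum(fr$water_oxygens[, 3] - fr$gold_top_z <= bare$first_trough_z)
  }, 0)
  m <- sum(W * n1)
  spread <- sqrt(sum(W * (n1 - m)^2))
  list(count = bare$layer1_count - m, spread = spread)
}
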