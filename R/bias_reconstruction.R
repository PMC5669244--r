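#' Free-energy profile along the CV
#'
#' @param grid CV values, nm (strictly increasing).
#' @param G free energy per grid point, kJ/mol.
#' @param reference `"bulk-zeroed"` or `"min-zeroed"`.
#' @param asym_error per-point (or scalar) asymmetry error, kJ/mol, or `NULL`.
#' @param symmetrised has the profile been mirror-averaged?
#' @param bulk_region the CV interval used for bulk zeroing, if any.
#' @return an object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(grid, G, reference = c("bulk-zeroed", "min-zeroed"),
                                asym_error = NULL, symmetrised = FALSE,
                                bulk_region = NULL) {
  reference <- match.arg(reference)
  grid <- as.numeric(grid)
  G <- as.numeric(G)
  stopifnot(length(grid) == length(G), length(grid) >= 2)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  structure(list(grid = grid, G = G, reference = reference,
                 asym_error = asym_error, symmetrised = symmetrised,
                 bulk_region = bulk_region),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free_energy_profile: %d points on [%g, %g] nm, %s%s\n",
              length(x$grid), min(x$grid), max(x$grid), x$reference,
              if (x$symmetrised) ", symmetrised" else ""))
  cat(sprintf("  min G = %.3f kJ/mol at s = %.3f nm\n",
              min(x$G), x$grid[which.min(x$G)]))
  invisible(x)
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  graphics::plot(x$grid, x$G, type = "l", xlab = "s (nm)",
                 ylab = expression(G ~ "(kJ/mol)"), ...)
  if (!is.null(x$asym_error) && length(x$asym_error) == length(x$grid)) {
    graphics::lines(x$grid, x$G + x$asym_error, lty = 3)
    graphics::lines(x$grid, x$G - x$asym_error, lty = 3)
  }
  invisible(x)
}

#' Evaluate a profile at arbitrary CV values (linear interpolation)
#'
#' @param profile a [free_energy_profile()].
#' @param s CV values inside the grid range.
#' @return G(s), kJ/mol.
#' @export
profile_at <- function(profile, s) {
  if (any(s < profile$grid[1] - 1e-9 | s > profile$grid[length(profile$grid)] + 1e-9))
    stop("CV value(s) outside the profile grid")
  approx(profile$grid, profile$G, xout = s, rule = 2)$y
}

#' Reconstruct the metadynamics bias from hill records
#'
#' Sums the deposited Gaussians on a grid:
#' `V(s) = sum_h w_h exp(-(s - s0_h)^2 / (2 sigma_h^2))` over hills with
#' `time <= until`. Each Gaussian is truncated beyond 6 sigma (relative error
#' below 1.6e-8 of the hill height). Recorded heights are taken as deposited,
#' so well-tempered scaling is already reflected in them.
#'
#' @param hills a [hill_records()] data frame (may be empty: zero bias).
#' @param grid CV grid, nm (strictly increasing).
#' @param until include hills deposited up to this time (ps).
#' @return an object of class `bias_grid` with fields `grid`, `final_bias`,
#'   `t_f`, `bias_factor` (NA unless well-tempered) and `bias_of_time`, a
#'   function `(s, t) -> V` for off-grid evaluation.
#' @export
sum_hills <- function(hills, grid, until = Inf) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  sel <- which(hills$time <= until)
  V <- numeric(length(grid))
  for (i in sel) {
    c0 <- hills$center[i]; sg <- hills$sigma[i]; h <- hills$height[i]
    j1 <- findInterval(c0 - 6 * sg, grid) + 1L
    j2 <- findInterval(c0 + 6 * sg, grid)
    if (j2 < j1) next
    d <- grid[j1:j2] - c0
    V[j1:j2] <- V[j1:j2] + h * exp(-0.5 * d * d / (sg * sg))
  }
  t_f <- if (length(sel)) max(hills$time[sel]) else 0
  bias_factor <- if (!is.null(hills$bias_factor) && nrow(hills) > 0)
    hills$bias_factor[1] else NA_real_
  bias_of_time <- function(s, t) {
    sel2 <- which(hills$time <= t)
    vapply(s, function(si) {
      if (!length(sel2)) return(0)
      d <- si - hills$center[sel2]
      keep <- abs(d) <= 6 * hills$sigma[sel2]
      sum(hills$height[sel2][keep] *
            exp(-0.5 * (d[keep] / hills$sigma[sel2][keep])^2))
    }, 0)
  }
  structure(list(grid = grid, final_bias = V, t_f = t_f,
                 bias_factor = bias_factor, bias_of_time = bias_of_time),
            class = "bias_grid")
}

#' @export
print.bias_grid <- function(x, ...) {
  cat(sprintf("bias_grid: %d points, t_f = %g ps, max V = %.3f kJ/mol\n",
              length(x$grid), x$t_f, max(x$final_bias)))
  invisible(x)
}

#' End-of-run free-energy estimate from a reconstructed bias
#'
#' Standard metadynamics: `G(s) = -V(s, t_f)`. Well-tempered (when the hills
#' carried a bias factor gamma): `G(s) = -gamma/(gamma - 1) * V(s, t_f)`.
#' The profile is then shifted to the requested reference.
#'
#' @param bias a `bias_grid` from [sum_hills()].
#' @param reference `"bulk-zeroed"` (default; needs `bulk_region`) or
#'   `"min-zeroed"`.
#' @param bulk_region length-2 CV interval whose mean G is set to zero.
#' @return a [free_energy_profile()].
#' @export
free_energy_estimate <- function(bias, reference = c("bulk-zeroed", "min-zeroed"),
                                 bulk_region = NULL) {
  reference <- match.arg(reference)
  fac <- if (!is.na(bias$bias_factor) && is.finite(bias$bias_factor))
    bias$bias_factor / (bias$bias_factor - 1) else 1
  G <- -fac * bias$final_bias
  if (reference == "bulk-zeroed") {
    if (is.null(bulk_region)) stop("bulk-zeroed reference needs bulk_region")
    sel <- bias$grid >= bulk_region[1] & bias$grid <= bulk_region[2]
    if (!any(sel)) stop("bulk_region contains no grid points")
    G <- G - mean(G[sel])
  } else {
    G <- G - min(G)
  }
  free_energy_profile(bias$grid, G, reference = reference,
                      bulk_region = bulk_region)
}

#' Symmetrise a free-energy profile about the slab midplane
#'
#' Exploits the two equivalent interfaces (slab top and the underside of its
#' periodic image): `G_sym(s) = (G(s) + G(2 m - s)) / 2` on the common
#' reflected support, with per-point asymmetry error
#' `(|G(s) - G(2 m - s)|) / 2`. Averaging is done in G (not in exp(-G/kT));
#' see the methods vignette for the rationale and the alternative.
#'
#' @param profile a [free_energy_profile()].
#' @param midplane mirror plane m (nm); must lie inside the grid.
#' @param average `"G"` (default) or `"boltzmann"` to average exp(-G/kT).
#' @param temperature K, used only for `average = "boltzmann"`.
#' @return a symmetrised [free_energy_profile()] restricted to grid points
#'   whose mirror image lies inside the grid.
#' @export
symmetrise <- function(profile, midplane, average = c("G", "boltzmann"),
                       temperature = 300) {
  average <- match.arg(average)
  g <- profile$grid
  if (midplane <= g[1] || midplane >= g[length(g)])
    stop("midplane outside the profile grid")
  refl <- 2 * midplane - g
  keep <- refl >= g[1] - 1e-12 & refl <= g[length(g)] + 1e-12
  if (!any(keep)) stop("no common reflected support")
  refl <- pmin(pmax(refl[keep], g[1]), g[length(g)])
  Gd <- profile$G[keep]
  Gr <- approx(g, profile$G, xout = refl)$y
  if (average == "G") {
    Gs <- (Gd + Gr) / 2
  } else {
    kt <- kT(temperature)
    Gs <- -kt * log((exp(-Gd / kt) + exp(-Gr / kt)) / 2)
  }
  asym <- abs(Gd - Gr) / 2
  out <- free_energy_profile(g[keep], Gs, reference = profile$reference,
                             asym_error = asym, symmetrised = TRUE,
                             bulk_region = profile$bulk_region)
  # restore the reference convention after averaging
  if (profile$reference == "bulk-zeroed" && !is.null(profile$bulk_region)) {
    sel <- out$grid >= profile$bulk_region[1] & out$grid <= profile$bulk_region[2]
    if (any(sel)) out$G <- out$G - mean(out$G[sel])
  }
  out
}
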