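#' Analytic toy adsorption landscape
#'
#' A one-dimensional free-energy landscape G(s) for the surface-normal CV s,
#' with a binding well near the wall at `wall_z`, a flat bulk plateau at zero,
#' and an exact mirror image of the well near `image_wall_z` (the underside of
#' the periodic image of the slab). The orthogonal "conformation" coordinate is
#' a two-state system whose energy gap interpolates between `gap_bulk` (bulk)
#' and `gap_well` (inside the well) with the well occupancy, so re-weighted
#' structural averages have a known ground truth.
#'
#' `square_well` uses tanh-smoothed edges of width `edge` (nm); `edge = 0`
#' gives the ideal hard-edged profile (static analysis only; dynamics needs a
#' finite force). `gaussian_well` is a Gaussian of depth `depth` and width
#' `well_width`. `double_well` adds a second Gaussian sub-well of depth
#' `0.6 * depth` at `well_center + 2.5 * well_width`. `harmonic` is a
#' calibration landscape `0.5 * depth * (s - well_center)^2` (depth acts as
#' the force constant, kJ mol^-1 nm^-2; not mirrored), whose closed-form
#' stationary variance kT/depth anchors the integrator tests.
#'
#' @param profile_kind one of `"square_well"`, `"gaussian_well"`, `"double_well"`.
#' @param depth well depth, kJ/mol (>= 0).
#' @param well_center,well_width well position and width, nm.
#' @param wall_z,image_wall_z positions of the surface and its periodic image, nm.
#' @param edge tanh edge width for the square well, nm.
#' @param gap_bulk,gap_well conformer energy gap in bulk and in the well, kJ/mol.
#' @return an object of class `toy_landscape`.
#' @export
#' @examples
#' tl <- toy_landscape("square_well", depth = 10, well_center = 0.5,
#'                     well_width = 0.5, wall_z = 0, image_wall_z = 4)
toy_landscape <- function(profile_kind = c("square_well", "gaussian_well", "double_well",
                                           "harmonic"),
                          depth = 10, well_center = 0.5, well_width = 0.5,
                          wall_z = 0, image_wall_z = 4, edge = 0.05,
                          gap_bulk = 0, gap_well = 2) {
  profile_kind <- match.arg(profile_kind)
  stopifnot(depth >= 0, well_width > 0, edge >= 0,
            wall_z < well_center, well_center < image_wall_z)
  structure(list(profile_kind = profile_kind, depth = depth,
                 well_center = well_center, well_width = well_width,
                 wall_z = wall_z, image_wall_z = image_wall_z, edge = edge,
                 orthogonal_coupling = list(gap_bulk = gap_bulk,
                                            gap_well = gap_well)),
            class = "toy_landscape")
}

#' @export
print.toy_landscape <- function(x, ...) {
  cat(sprintf("toy_landscape: %s, depth %g kJ/mol, well at %g nm (width %g nm)\n",
              x$profile_kind, x$depth, x$well_center, x$well_width))
  cat(sprintf("  walls at %g and %g nm%s\n", x$wall_z, x$image_wall_z,
              if (x$profile_kind == "harmonic") ""
              else " (well mirrored about the midplane)"))
  invisible(x)
}

# parameter list handed to the C++ kernels
landscape_params <- function(landscape) {
  kind <- match(landscape$profile_kind,
                c("square_well", "gaussian_well", "double_well", "harmonic")) - 1L
  mid <- (landscape$wall_z + landscape$image_wall_z) / 2
  c1 <- landscape$well_center
  c2 <- 2 * mid - c1
  c1b <- c1 + 2.5 * landscape$well_width
  list(kind = kind, depth = landscape$depth, w = landscape$well_width,
       edge = max(landscape$edge, 1e-12), c1 = c1, c2 = c2,
       d2 = 0.6 * landscape$depth, c1b = c1b, c2b = 2 * mid - c1b,
       wall_z = landscape$wall_z, image_wall_z = landscape$image_wall_z)
}

# exact potential; hard edges handled in R, smoothed edges in C++
landscape_potential <- function(landscape, s) {
  if (landscape$profile_kind == "square_well" && landscape$edge == 0) {
    mid <- (landscape$wall_z + landscape$image_wall_z) / 2
    c1 <- landscape$well_center
    c2 <- 2 * mid - c1
    hw <- landscape$well_width / 2
    inside <- (s >= c1 - hw & s <= c1 + hw) | (s >= c2 - hw & s <= c2 + hw)
    return(-landscape$depth * as.numeric(inside))
  }
  .landscape_potential_cpp(as.numeric(s), landscape_params(landscape))
}

#' Conformer energy gap and state-1 probability along the CV
#'
#' The two-state orthogonal coordinate has gap
#' `gap(s) = gap_bulk + (gap_well - gap_bulk) * occupancy(s)` where the well
#' occupancy is `-G(s)/depth` (1 inside the well, 0 in bulk). The stationary
#' probability of state 1 at fixed s is `1 / (1 + exp(-gap(s)/kT))`.
#'
#' @param landscape a [toy_landscape()].
#' @param s CV values, nm.
#' @param temperature K (for `conformer_probability`).
#' @return numeric vector.
#' @export
conformer_gap <- function(landscape, s) {
  occ <- if (landscape$depth > 0)
    pmin(1, pmax(0, -landscape_potential(landscape, s) / landscape$depth))
  else rep(0, length(s))
  oc <- landscape$orthogonal_coupling
  oc$gap_bulk + (oc$gap_well - oc$gap_bulk) * occ
}

#' @rdname conformer_gap
#' @export
conformer_probability <- function(landscape, s, temperature = 300) {
  gap <- conformer_gap(landscape, s)
  if (temperature == 0) return(as.numeric(gap > 0) + 0.5 * (gap == 0))
  1 / (1 + exp(-gap / kT(temperature)))
}

#' Exact free-energy profile of a toy landscape
#'
#' @param landscape a [toy_landscape()].
#' @param grid CV grid (nm), spanning at most `[wall_z, image_wall_z]`.
#' @return a [free_energy_profile()] (bulk plateau at zero by construction).
#' @export
landscape_free_energy <- function(landscape, grid) {
  grid <- as.numeric(grid)
  if (min(grid) < landscape$wall_z - 1e-9 || max(grid) > landscape$image_wall_z + 1e-9)
    stop("grid must lie between the walls")
  free_energy_profile(grid, landscape_potential(landscape, grid),
                      reference = "bulk-zeroed")
}

#' Langevin run specification
#'
#' Overdamped (position) Langevin dynamics via Euler-Maruyama, with optional
#' metadynamics hill deposition. Reflecting boundaries at the two walls.
#'
#' @param dt time step, ps.
#' @param friction friction coefficient, ps^-1 (mobility = 1/friction in
#'   nm^2 ps^-1 mol kJ^-1).
#' @param temperature K.
#' @param n_steps number of integration steps.
#' @param seed integer RNG seed.
#' @param out_stride record a frame every `out_stride` steps.
#' @param metad `NULL` for unbiased dynamics, else a list with elements
#'   `height` (kJ/mol), `sigma` (nm), `stride` (steps), and optionally
#'   `well_tempered` (flag) and `bias_factor`.
#' @return an object of class `langevin_spec`.
#' @export
langevin_spec <- function(dt = 0.01, friction = 1, temperature = 300,
                          n_steps = 1e5, seed = 1L, out_stride = 10L,
                          metad = NULL) {
  stopifnot(dt > 0, friction > 0, temperature >= 0, n_steps > 0, out_stride >= 1)
  if (!is.null(metad)) {
    stopifnot(is.list(metad), metad$sigma > 0, metad$height >= 0, metad$stride >= 1)
    if (is.null(metad$well_tempered)) metad$well_tempered <- FALSE
    if (isTRUE(metad$well_tempered) && (is.null(metad$bias_factor) ||
                                        metad$bias_factor <= 1))
      stop("well-tempered deposition needs bias_factor > 1")
    if (is.null(metad$bias_factor)) metad$bias_factor <- Inf
  }
  structure(list(dt = dt, friction = friction, temperature = temperature,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 out_stride = as.integer(out_stride), metad = metad),
            class = "langevin_spec")
}

#' Run a (metadynamics-)biased Langevin trajectory on a toy landscape
#'
#' Integrates overdamped Langevin dynamics for the CV under the landscape
#' potential plus the accumulating Gaussian bias, emits hills every
#' `metad$stride` steps, and samples the orthogonal two-state conformer label
#' for each recorded frame from its exact conditional distribution at s.
#' Bit-reproducible under a fixed `spec$seed`.
#'
#' @param landscape a [toy_landscape()] (needs `edge > 0` for a square well).
#' @param spec a [langevin_spec()].
#' @param s0 initial CV value; default is the midplane (bulk).
#' @return list with elements `frames` (a [frame_series()] with observable
#'   `conformer`) and `hills` (a [hill_records()] data frame).
#' @export
run_langevin <- function(landscape, spec, s0 = NULL) {
  if (landscape$profile_kind == "square_well" && landscape$edge <= 0)
    stop("square_well dynamics needs edge > 0 (finite force)")
  lpar <- landscape_params(landscape)
  if (is.null(s0)) s0 <- (landscape$wall_z + landscape$image_wall_z) / 2
  kt <- spec$temperature * KB_KJ_MOL_K
  do_metad <- !is.null(spec$metad)
  m <- spec$metad
  grid_n <- max(801L, ceiling((landscape$image_wall_z - landscape$wall_z) / 0.005) + 1L)

  set.seed(spec$seed)
  res <- .run_langevin_cpp(lpar, s0, spec$n_steps, spec$dt, spec$friction, kt,
                           spec$out_stride, do_metad,
                           if (do_metad) m$height else 0,
                           if (do_metad) m$sigma else 1,
                           if (do_metad) as.integer(m$stride) else 1L,
                           do_metad && isTRUE(m$well_tempered),
                           if (do_metad && is.finite(m$bias_factor)) m$bias_factor else 2,
                           as.integer(grid_n))

  p1 <- conformer_probability(landscape, res$cv, spec$temperature)
  conformer <- rbinom(length(p1), 1L, p1)
  frames <- frame_series(res$times, res$cv, list(conformer = as.numeric(conformer)))
  hills <- hill_records(res$hill_time, res$hill_center, res$hill_sigma,
                        res$hill_height,
                        bias_factor = if (do_metad && isTRUE(m$well_tempered))
                          m$bias_factor else NULL)
  list(frames = frames, hills = hills)
}

#' Slab fixture specification
#'
#' Geometric snapshot fixtures with planted ground truth: a gold lattice,
#' per-residue reference atoms at Gaussian-distributed heights above the gold
#' top layer, and water oxygens in Gaussian vertical layers with uniform
#' in-plane positions.
#'
#' @param n_frames number of snapshots.
#' @param box length-3 box (nm); gold top layer sits at `gold_top_z`.
#' @param gold_top_z height of the gold top layer, nm.
#' @param lattice in-plane gold spacing, nm.
#' @param layer_params list of `list(mean=, spread=, count=)` water layers
#'   (mean height above the gold top, nm).
#' @param residue_height_dists named list of `c(mean, spread)` reference-atom
#'   heights above the gold top (nm); one reference atom per residue.
#' @param contact_cutoff cutoff (nm) used to declare the planted contact
#'   probabilities recorded in the manifest.
#' @param seed integer RNG seed.
#' @return an object of class `slab_fixture_spec`.
#' @export
slab_fixture_spec <- function(n_frames = 500, box = c(4, 4, 6), gold_top_z = 1,
                              lattice = 0.25,
                              layer_params = list(list(mean = 0.25, spread = 0.05, count = 100),
                                                  list(mean = 0.60, spread = 0.05, count = 80)),
                              residue_height_dists = list(TRP1 = c(0.25, 0.08),
                                                          ALA2 = c(0.8, 0.2)),
                              contact_cutoff = 0.45, seed = 1L) {
  stopifnot(n_frames > 0, length(box) == 3, all(box > 0),
            gold_top_z > 0, gold_top_z < box[3], lattice > 0, contact_cutoff > 0)
  for (lp in layer_params) stopifnot(lp$count > 0, lp$spread > 0, lp$mean > 0)
  for (rd in residue_height_dists) stopifnot(length(rd) == 2, rd[2] > 0)
  structure(list(n_frames = as.integer(n_frames), box = as.numeric(box),
                 gold_top_z = gold_top_z, lattice = lattice,
                 layer_params = layer_params,
                 residue_height_dists = residue_height_dists,
                 contact_cutoff = contact_cutoff, seed = as.integer(seed)),
            class = "slab_fixture_spec")
}

# draw z offsets from a normal clipped into (lo_gap, hi_gap) by resampling;
# layer means are validated to sit >= 5 spreads from the clip edges, so the
# planted normal probabilities are unaffected in practice
rnorm_clipped <- function(n, mean, sd, lo, hi) {
  z <- rnorm(n, mean, sd)
  bad <- which(z <= lo | z >= hi)
  tries <- 0
  while (length(bad)) {
    z[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(z <= lo | z >= hi)
    tries <- tries + 1
    if (tries > 100) stop("layer/residue height distribution does not fit the box")
  }
  z
}

#' Generate slab snapshot fixtures with a ground-truth manifest
#'
#' @param spec a [slab_fixture_spec()].
#' @return list with `frames` (list of [slab_frame()]) and `manifest`, which
#'   records the planted per-residue contact probabilities
#'   (`P(height <= contact_cutoff)` under the sampling distribution), the
#'   per-layer water counts, and a warning string when two layers overlap.
#' @export
make_slab_fixture <- function(spec) {
  set.seed(spec$seed)
  box <- spec$box
  zmax_gap <- box[3] - spec$gold_top_z

  planted_p <- vapply(spec$residue_height_dists, function(rd)
    pnorm((spec$contact_cutoff - rd[1]) / rd[2]), 0)
  layer_counts <- vapply(spec$layer_params, function(lp) lp$count, 0)

  overlap_warning <- NULL
  lp <- spec$layer_params
  if (length(lp) > 1) {
    for (i in seq_len(length(lp) - 1)) {
      if (abs(lp[[i + 1]]$mean - lp[[i]]$mean) <
          2 * (lp[[i]]$spread + lp[[i + 1]]$spread)) {
        overlap_warning <- sprintf("layers %d and %d overlap", i, i + 1)
        warning(overlap_warning)
      }
    }
  }

  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    refs <- lapply(spec$residue_height_dists, function(rd) {
      h <- rnorm_clipped(1, rd[1], rd[2], 0.01, zmax_gap - 0.01)
      m <- cbind(runif(1, 0, box[1]), runif(1, 0, box[2]), spec$gold_top_z + h)
      rownames(m) <- "REF"
      m
    })
    waters <- do.call(rbind, lapply(lp, function(l) {
      z <- spec$gold_top_z +
        rnorm_clipped(l$count, l$mean, l$spread, 0.005, zmax_gap - 0.005)
      cbind(runif(l$count, 0, box[1]), runif(l$count, 0, box[2]), z)
    }))
    frames[[f]] <- slab_frame(box, spec$gold_top_z,
                              refs, waters)
  }

  manifest <- list(n_frames = spec$n_frames,
                   planted_contact_prob = planted_p,
                   contact_cutoff = spec$contact_cutoff,
                   layer_counts = layer_counts,
                   layer_means = vapply(lp, function(l) l$mean, 0),
                   waters_per_frame = sum(layer_counts),
                   overlap_warning = overlap_warning,
                   seed = spec$seed)
  list(frames = frames, manifest = manifest)
}
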