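#' Default toy-campaign configuration
#'
#' Three synthetic "facets" are modelled as three well depths on the same
#' slab geometry, each paired with a slab fixture carrying planted
#' residue-contact probabilities and water layering, so the campaign exercises
#' the comparative logic of a facet study (ranking, contact-class counts,
#' displaced-water ordering) on ground truth. Depths, hill parameters and
#' integrator settings are discussed in the methods vignette.
#'
#' @param seed campaign seed (all stage seeds derive from it).
#' @param n_steps Langevin steps per facet.
#' @return a nested configuration list of class `campaign_config`.
#' @export
campaign_config <- function(seed = 1L, n_steps = 1e6) {
  facet_names <- c("facetA", "facetB", "facetC")
  depths <- c(facetA = 16, facetB = 10, facetC = 6)
  planted_p <- list(
    facetA = c(0.90, 0.80, 0.60, 0.55, 0.35, 0.30),
    facetB = c(0.80, 0.60, 0.55, 0.35, 0.30, 0.10),
    facetC = c(0.60, 0.35, 0.30, 0.10, 0.05, 0.05))
  bound_layer1 <- c(facetA = 65, facetB = 80, facetC = 95)

  fixtures <- lapply(facet_names, function(fn) {
    spread <- 0.08
    cutoff <- 0.45
    means <- cutoff - qnorm(planted_p[[fn]]) * spread
    rhd <- lapply(means, function(m) c(m, spread))
    names(rhd) <- paste0("RES", seq_along(rhd))
    list(residue_height_dists = rhd, contact_cutoff = cutoff,
         bare_layer1 = 100, layer2 = 80,
         bound_layer1 = unname(bound_layer1[fn]), n_frames = 200)
  })
  names(fixtures) <- facet_names

  structure(list(
    seed = as.integer(seed),
    facets = lapply(facet_names, function(fn) list(name = fn, depth = depths[[fn]])),
    landscape = list(profile_kind = "square_well", well_center = 0.5,
                     well_width = 0.5, edge = 0.05, wall_z = 0,
                     image_wall_z = 4, gap_bulk = 0, gap_well = 2),
    langevin = list(dt = 0.005, friction = 20, temperature = 300,
                    n_steps = as.integer(n_steps), out_stride = 10,
                    metad = list(height = 0.3, sigma = 0.05, stride = 250)),
    analysis = list(grid_min = 0, grid_max = 4, grid_n = 801,
                    bound_region = c(0.3, 0.7), bulk_region = c(1.8, 2.2),
                    binning = 0.02, n_intervals = 5, eq_threshold = 0.1,
                    scheme = "average_weight"),
    fixtures = fixtures), class = "campaign_config")
}

campaign_run_config <- function(config, seed) {
  a <- config$analysis
  run_config(temperature = config$langevin$temperature,
             grid_min = a$grid_min, grid_max = a$grid_max, grid_n = a$grid_n,
             bound_region = a$bound_region, bulk_region = a$bulk_region,
             seed = seed, binning = a$binning)
}

campaign_landscape <- function(config, depth) {
  L <- config$landscape
  toy_landscape(L$profile_kind, depth = depth, well_center = L$well_center,
                well_width = L$well_width, wall_z = L$wall_z,
                image_wall_z = L$image_wall_z, edge = L$edge,
                gap_bulk = L$gap_bulk, gap_well = L$gap_well)
}

#' Analyse one facet: simulate, equilibrate, reconstruct, re-weight, extract
#'
#' The per-facet stage chain of [run_campaign()], exposed for direct use:
#' biased Langevin run, equilibration assignment, bias reconstruction and
#' symmetrised profile, re-weighting, adsorption free energy, and the
#' re-weighted conformer population in the bound state.
#'
#' @param config a [campaign_config()].
#' @param depth well depth for this facet, kJ/mol.
#' @param seed facet-specific seed.
#' @param outdir optional directory for stage output files.
#' @param tag file-name tag for stage outputs.
#' @param resume reuse existing simulation output files in `outdir`.
#' @return list with the landscape, frames, hills, equilibration report,
#'   symmetrised profile, weights, adsorption result and conformer estimate.
#' @export
analyse_facet <- function(config, depth, seed, outdir = NULL, tag = "facet",
                          resume = TRUE) {
  lc <- config$langevin
  landscape <- campaign_landscape(config, depth)
  rc <- campaign_run_config(config, seed)

  hills_path <- if (!is.null(outdir)) file.path(outdir, paste0("hills_", tag, ".dat"))
  frames_path <- if (!is.null(outdir)) file.path(outdir, paste0("frames_", tag, ".dat"))
  if (resume && !is.null(outdir) && file.exists(hills_path) &&
      file.exists(frames_path)) {
    hills <- read_hills(hills_path)
    frames <- read_frames(frames_path, "conformer")
  } else {
    spec <- langevin_spec(dt = lc$dt, friction = lc$friction,
                          temperature = lc$temperature, n_steps = lc$n_steps,
                          seed = seed, out_stride = lc$out_stride,
                          metad = lc$metad)
    sim <- run_langevin(landscape, spec)
    hills <- sim$hills
    frames <- sim$frames
    if (!is.null(outdir)) {
      write_hills(hills, hills_path)
      write_frames(frames, frames_path)
    }
  }

  eq <- assign_equilibration(frames, n_intervals = config$analysis$n_intervals,
                             threshold = config$analysis$eq_threshold,
                             binning = rc$binning)
  post <- subset_frames(frames, t_min = eq$t_eq)

  bias <- sum_hills(hills, cv_grid(rc))
  prof <- free_energy_estimate(bias, reference = "bulk-zeroed",
                               bulk_region = rc$bulk_region)
  midplane <- (landscape$wall_z + landscape$image_wall_z) / 2
  prof_sym <- symmetrise(prof, midplane)

  weights <- switch(config$analysis$scheme,
    average_weight = average_weight(post, prof_sym, rc),
    bonomi = bonomi_weights(post, hills, rc),
    time_period = time_period_weights(post, hills, n_blocks = 4, config = rc),
    stop("unknown re-weighting scheme: ", config$analysis$scheme))

  dg <- extract_dG(prof_sym, rc, estimator = "partition_ratio")

  in_bound <- post$cv >= rc$bound_region[1] & post$cv <= rc$bound_region[2]
  if (any(in_bound) && sum(weights$W[in_bound]) > 0) {
    bound_frames <- subset_frames(post, cv_range = rc$bound_region)
    bw <- frame_weights(bound_frames$times, weights$W[in_bound], weights$scheme)
    conf <- weighted_average(bound_frames, bw, "conformer", seed = seed)
  } else {
    # bound state unsampled (or zero-weighted) in the analysis window
    conf <- list(estimate = NA_real_, se = NA_real_, ess = NA_real_,
                 low_ess = TRUE)
  }

  if (!is.null(outdir)) {
    m <- cbind(prof_sym$grid, prof_sym$G, prof_sym$asym_error)
    write_column_file(m, c("s", "G", "asym_error"),
                      file.path(outdir, paste0("profile_", tag, ".dat")))
  }
  list(landscape = landscape, frames = frames, hills = hills, equilibration = eq,
       profile = prof_sym, weights = weights, dG = dg, conformer = conf,
       t_eq = eq$t_eq)
}

facet_fixture_specs <- function(fx, seed) {
  base_layers <- function(n1) list(list(mean = 0.25, spread = 0.05, count = n1),
                                   list(mean = 0.60, spread = 0.05, count = fx$layer2))
  list(bare = slab_fixture_spec(n_frames = fx$n_frames,
                                layer_params = base_layers(fx$bare_layer1),
                                residue_height_dists = fx$residue_height_dists,
                                contact_cutoff = fx$contact_cutoff, seed = seed),
       bound = slab_fixture_spec(n_frames = fx$n_frames,
                                 layer_params = base_layers(fx$bound_layer1),
                                 residue_height_dists = fx$residue_height_dists,
                                 contact_cutoff = fx$contact_cutoff,
                                 seed = seed + 1L))
}

#' Run the full toy campaign
#'
#' Executes simulate -> equilibrate -> bias reconstruction -> symmetrised
#' profile -> re-weight -> adsorption free energy for each synthetic facet,
#' plus the contact and water-structure analyses on that facet's slab
#' fixtures, then ranks the facets. All stages are pure functions of
#' (config, seed): re-running with the same configuration reproduces the
#' report bit for bit. With `resume = TRUE` and an `outdir`, completed
#' simulation outputs on disk are reused.
#'
#' @param config a [campaign_config()].
#' @param outdir optional output directory for stage files and `report.json`.
#' @param resume reuse existing stage outputs in `outdir`.
#' @return the campaign report (class `campaign_report`): per-facet adsorption
#'   results, ranking with significance flags, contact tables, water
#'   summaries, and provenance (config hash, seeds, package version).
#' @export
run_campaign <- function(config = campaign_config(), outdir = NULL,
                         resume = TRUE) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  facet_out <- list()
  for (i in seq_along(config$facets)) {
    fc <- config$facets[[i]]
    seed_i <- config$seed * 100L + i
    message(sprintf("stage simulate+analyse: %s (depth %g kJ/mol, seed %d)",
                    fc$name, fc$depth, seed_i))
    fa <- analyse_facet(config, fc$depth, seed_i, outdir = outdir,
                        tag = fc$name, resume = resume)

    fx <- config$fixtures[[fc$name]]
    fspecs <- facet_fixture_specs(fx, seed_i * 10L)
    bare <- make_slab_fixture(fspecs$bare)
    bound <- make_slab_fixture(fspecs$bound)
    cd <- contact_definition(
      setNames(rep(fx$contact_cutoff, length(fx$residue_height_dists)),
               names(fx$residue_height_dists)))
    contacts <- contact_probabilities(bound$frames, weights = NULL, definition = cd)
    vp_bare <- vertical_profile(bare$frames)
    disp <- displaced_waters(vp_bare, bound$frames)

    facet_out[[fc$name]] <- list(
      analysis = fa, contacts = contacts, water = list(
        bare_profile = vp_bare, displaced = disp,
        bare_manifest = bare$manifest, bound_manifest = bound$manifest))
  }

  results <- lapply(facet_out, function(f) f$analysis$dG)
  ranking <- if (length(results) >= 2) rank_facets(facet_set(results)) else
    data.frame(facet = names(results),
               dG = vapply(results, function(r) r$dG, 0),
               err = vapply(results, function(r) r$err, 0),
               significant_vs_next = NA)

  report <- list(
    facets = lapply(facet_out, function(f) list(
      dG = f$analysis$dG$dG, err = f$analysis$dG$err,
      estimator = f$analysis$dG$estimator,
      t_eq = f$analysis$t_eq, ess = f$analysis$weights$ess,
      conformer_population = f$analysis$conformer$estimate,
      conformer_se = f$analysis$conformer$se,
      contacts = data.frame(residue = f$contacts$residue, p = f$contacts$p,
                            class = f$contacts$class),
      mean_simultaneous = attr(f$contacts, "mean_simultaneous"),
      water = list(first_trough_z = f$water$bare_profile$first_trough_z,
                   layer1_count = f$water$bare_profile$layer1_count,
                   displaced = f$water$displaced$count,
                   displaced_spread = f$water$displaced$spread))),
    ranking = ranking,
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      version = as.character(utils::packageVersion("toygold"))))
  class(report) <- "campaign_report"
  if (!is.null(outdir))
    jsonlite::write_json(unclass_report(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

unclass_report <- function(report) {
  rapply(unclass(report), f = identity, how = "replace")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.campaign_report <- function(x, ...) {
  cat("campaign_report\n")
  cat("ranking (strongest binder first):\n")
  print(x$ranking)
  for (fn in names(x$facets)) {
    f <- x$facets[[fn]]
    cat(sprintf("%s: dG = %.2f +/- %.2f kJ/mol, mean contacts %.2f, displaced waters %.1f\n",
                fn, f$dG, f$err, f$mean_simultaneous, f$water$displaced))
  }
  invisible(x)
}

#' Validate a campaign report against the shipped schema
#'
#' Structural check of the report against the JSON schema in
#' `inst/schema/campaign-report.json`: required fields present with the right
#' basic types.
#'
#' @param report a `campaign_report` (or the list parsed from `report.json`).
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_report <- function(report) {
  need_num <- function(x, where) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop("schema violation: ", where, " must be a finite number")
  }
  if (!all(c("facets", "ranking", "provenance") %in% names(report)))
    stop("schema violation: report needs facets, ranking, provenance")
  for (fn in names(report$facets)) {
    f <- report$facets[[fn]]
    for (k in c("dG", "err", "t_eq", "ess", "mean_simultaneous"))
      need_num(f[[k]], paste0("facets$", fn, "$", k))
    if (is.null(f$contacts)) stop("schema violation: contacts missing in ", fn)
    if (is.null(f$water$layer1_count))
      stop("schema violation: water$layer1_count missing in ", fn)
  }
  if (is.null(report$provenance$config_hash) || is.null(report$provenance$seed))
    stop("schema violation: provenance incomplete")
  invisible(TRUE)
}
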