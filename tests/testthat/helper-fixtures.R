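# Shared fixtures and independent oracles used across the test files.

# untruncated brute-force hill summation (independent of sum_hills)
naive_sum_hills <- function(hills, grid, until = Inf) {
  V <- numeric(length(grid))
  for (i in seq_len(nrow(hills))) {
    if (hills$time[i] > until) next
    V <- V + hills$height[i] *
      exp(-0.5 * ((grid - hills$center[i]) / hills$sigma[i])^2)
  }
  V
}

random_hills <- function(n, seed = 1, t_spacing = 1) {
  set.seed(seed)
  hill_records(time = seq_len(n) * t_spacing,
               center = runif(n, 0.2, 3.8),
               sigma = runif(n, 0.03, 0.15),
               height = runif(n, 0.1, 1.5))
}

# the reference square-well campaign conditions
toy_square_landscape <- function(depth = 10) {
  toy_landscape("square_well", depth = depth, well_center = 0.5,
                well_width = 0.5, wall_z = 0, image_wall_z = 4, edge = 0.05,
                gap_bulk = 0, gap_well = 2)
}

toy_metad_spec <- function(seed, n_steps = 1e6) {
  langevin_spec(dt = 0.005, friction = 20, temperature = 300,
                n_steps = n_steps, seed = seed, out_stride = 10,
                metad = list(height = 0.3, sigma = 0.05, stride = 250))
}

toy_unbiased_spec <- function(seed, n_steps = 1e6, out_stride = 10) {
  langevin_spec(dt = 0.005, friction = 20, temperature = 300,
                n_steps = n_steps, seed = seed, out_stride = out_stride)
}

toy_config <- function(seed = 1) {
  run_config(bound_region = c(0.3, 0.7), bulk_region = c(1.8, 2.2), seed = seed)
}

# full analysis chain: biased run -> final bias -> symmetrised bulk-zeroed profile
recover_profile <- function(sim, config) {
  bias <- sum_hills(sim$hills, cv_grid(config))
  prof <- free_energy_estimate(bias, bulk_region = config$bulk_region)
  symmetrise(prof, (config$grid_min + config$grid_max) / 2)
}

# two-layer slab fixture with one residue planted at contact probability p
two_layer_fixture <- function(n_frames = 100, seed = 5, layer1 = 100, layer2 = 80,
                              planted_p = c(RES1 = 0.8), spread = 0.08,
                              cutoff = 0.45) {
  means <- cutoff - qnorm(planted_p) * spread
  rhd <- lapply(means, function(m) c(m, spread))
  names(rhd) <- names(planted_p)
  make_slab_fixture(slab_fixture_spec(
    n_frames = n_frames,
    layer_params = list(list(mean = 0.25, spread = 0.05, count = layer1),
                        list(mean = 0.60, spread = 0.05, count = layer2)),
    residue_height_dists = rhd, contact_cutoff = cutoff, seed = seed))
}

# minimal hand-built slab frame
tiny_frame <- function(res_z, water_z = numeric(0), box = c(4, 4, 6),
                       gold_top = 1) {
  refs <- lapply(res_z, function(z) {
    m <- matrix(c(1, 1, gold_top + z), 1)
    rownames(m) <- "REF"
    m
  })
  names(refs) <- names(res_z)
  wo <- if (length(water_z)) cbind(2, 2, gold_top + water_z)
        else matrix(numeric(0), 0, 3)
  slab_frame(box, gold_top, refs, wo)
}
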