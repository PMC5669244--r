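test_that("landscape free energy matches its closed forms", {
  grid <- seq(0, 4, by = 0.005)

  # hard-edged square well: -depth inside both wells, 0 in bulk, mirrored
  tl0 <- toy_landscape("square_well", depth = 10, well_center = 0.4,
                       well_width = 0.3, wall_z = 0, image_wall_z = 4, edge = 0)
  G <- landscape_free_energy(tl0, grid)$G
  expect_equal(G[grid >= 0.25 & grid <= 0.55], rep(-10, sum(grid >= 0.25 & grid <= 0.55)))
  expect_equal(G[grid > 0.6 & grid < 3.4], rep(0, sum(grid > 0.6 & grid < 3.4)))
  # mirror image near the periodic-image wall
  expect_equal(G[grid >= 3.45 & grid <= 3.75], rep(-10, sum(grid >= 3.45 & grid <= 3.75)))

  # depth 0 is identically zero
  tlz <- toy_landscape("square_well", depth = 0)
  expect_equal(landscape_free_energy(tlz, grid)$G, rep(0, length(grid)))

  # gaussian well equals the pointwise formula evaluated independently
  tg <- toy_landscape("gaussian_well", depth = 7, well_center = 0.6,
                      well_width = 0.25, wall_z = 0, image_wall_z = 4)
  expected <- -7 * (exp(-(grid - 0.6)^2 / (2 * 0.25^2)) +
                    exp(-(grid - 3.4)^2 / (2 * 0.25^2)))
  expect_equal(landscape_free_energy(tg, grid)$G, expected, tolerance = 1e-12)

  expect_error(landscape_free_energy(tg, seq(-1, 4, 0.1)), "between the walls")
})

test_that("unbiased Langevin statistics match closed forms", {
  # harmonic landscape: stationary variance kT/kappa within 3 standard errors
  kappa <- 5
  tl <- toy_landscape("harmonic", depth = kappa, well_center = 2,
                      wall_z = 0, image_wall_z = 4)
  spec <- langevin_spec(dt = 0.005, friction = 20, temperature = 300,
                        n_steps = 1e6, seed = 11, out_stride = 1)
  sim <- run_langevin(tl, spec, s0 = 2)
  v <- var(sim$frames$cv)
  v_true <- kT(300) / kappa
  tau_steps <- 20 / (kappa * 0.005)              # OU relaxation time in steps
  se <- v_true * sqrt(2 / (1e6 / (2 * tau_steps)))
  expect_lt(abs(v - v_true), 3 * se)

  # zero-temperature limit: deterministic descent to the well minimum
  tg <- toy_landscape("gaussian_well", depth = 10, well_center = 0.5,
                      well_width = 0.3, wall_z = 0, image_wall_z = 4)
  simz <- run_langevin(tg, langevin_spec(dt = 0.005, friction = 20,
                                         temperature = 0, n_steps = 2e4,
                                         seed = 1), s0 = 0.9)
  expect_equal(tail(simz$frames$cv, 1), 0.5, tolerance = 1e-6)

  # determinism: same seed gives bit-identical trajectories and hills
  spec2 <- toy_metad_spec(seed = 21, n_steps = 5e4)
  a <- run_langevin(toy_square_landscape(), spec2)
  b <- run_langevin(toy_square_landscape(), spec2)
  expect_identical(a$frames$cv, b$frames$cv)
  expect_identical(a$frames$observables$conformer, b$frames$observables$conformer)
  expect_identical(a$hills$height, b$hills$height)
})

test_that("unbiased CV histogram converges to the Boltzmann law", {
  tl <- toy_landscape("gaussian_well", depth = 5, well_center = 0.5,
                      well_width = 0.3, wall_z = 0, image_wall_z = 2)
  spec <- langevin_spec(dt = 0.005, friction = 2, temperature = 300,
                        n_steps = 1e6, seed = 31, out_stride = 5)
  sim <- run_langevin(tl, spec, s0 = 1)
  grid <- seq(0, 2, by = 0.01)
  G <- landscape_free_energy(tl, grid)$G
  p <- exp(-G / kT(300))
  p <- p / sum(p)
  cdf_true <- cumsum(p)
  ecdf_at <- ecdf(sim$frames$cv)(grid)
  ks <- max(abs(ecdf_at - cdf_true))
  expect_lt(ks, 0.05)
})

test_that("conformer labels follow the planted two-state law at fixed s", {
  tl <- toy_square_landscape()
  spec <- toy_unbiased_spec(seed = 41, n_steps = 5e5, out_stride = 5)
  sim <- run_langevin(tl, spec, s0 = 0.5)
  sel <- sim$frames$cv >= 0.4 & sim$frames$cv <= 0.6
  n <- sum(sel)
  expect_gt(n, 1000)
  phat <- mean(sim$frames$observables$conformer[sel])
  ptrue <- mean(conformer_probability(tl, sim$frames$cv[sel]))
  # labels are drawn independently per frame, so the binomial error applies
  expect_lt(abs(phat - ptrue), 3 * sqrt(ptrue * (1 - ptrue) / n))
})

test_that("slab fixtures carry a faithful ground-truth manifest", {
  # residue far below the cutoff: planted contact probability ~ 1
  fx <- two_layer_fixture(n_frames = 50, seed = 13,
                          planted_p = c(LOW1 = 0.999, MID2 = 0.5))
  expect_gt(fx$manifest$planted_contact_prob[["LOW1"]], 0.99)
  expect_equal(unname(fx$manifest$layer_counts), c(100, 80))

  # empirical contact fraction matches the manifest within binomial error
  fx2 <- two_layer_fixture(n_frames = 400, seed = 17, planted_p = c(RES1 = 0.7))
  cd <- contact_definition(c(RES1 = fx2$manifest$contact_cutoff))
  frac <- mean(vapply(fx2$frames, function(fr) contact_vector(fr, cd), TRUE))
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 400))

  # overlapping layers produce a manifest warning
  expect_warning(
    make_slab_fixture(slab_fixture_spec(
      n_frames = 2,
      layer_params = list(list(mean = 0.25, spread = 0.1, count = 10),
                          list(mean = 0.30, spread = 0.1, count = 10)),
      residue_height_dists = list(R1 = c(0.3, 0.05)), seed = 1)),
    "overlap")

  # generators are pure functions of spec + seed
  fa <- two_layer_fixture(n_frames = 3, seed = 19)
  fb <- two_layer_fixture(n_frames = 3, seed = 19)
  expect_identical(fa$frames[[2]]$water_oxygens, fb$frames[[2]]$water_oxygens)
})
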