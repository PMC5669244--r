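# frames laid out uniformly over the CV grid: equal N(s) in every bin
uniform_frames <- function(config, per_bin = 10) {
  centers <- seq(config$grid_min + config$binning / 2,
                 config$grid_max - config$binning / 2, by = config$binning)
  cv <- rep(centers, each = per_bin)
  frame_series(seq_along(cv), cv, list(x = cv^2))
}

flat_profile <- function(config) {
  free_energy_profile(cv_grid(config), rep(0, config$grid_n),
                      reference = "bulk-zeroed", bulk_region = config$bulk_region)
}

test_that("flat free energy and uniform sampling give exactly uniform weights", {
  cfg <- toy_config()
  fr <- uniform_frames(cfg)
  w <- average_weight(fr, flat_profile(cfg), cfg)
  expect_equal(w$W, rep(1 / length(fr), length(fr)), tolerance = 1e-14)
  expect_equal(sum(w$W), 1, tolerance = 1e-12)
  expect_equal(w$ess, length(fr), tolerance = 1e-6)
})

test_that("two-bin analytic case: summed bin weights in ratio 1:2", {
  cfg <- run_config(grid_min = 0, grid_max = 0.04, grid_n = 5,
                    bound_region = c(0, 0.01), bulk_region = c(0.03, 0.04),
                    binning = 0.02)
  kt <- cfg$kB * cfg$temperature
  # G = 0 on bin 1, G = -kT ln 2 on bin 2, equal frame counts
  G <- ifelse(cv_grid(cfg) < 0.02, 0, -kt * log(2))
  prof <- free_energy_profile(cv_grid(cfg), G, reference = "min-zeroed")
  cv <- c(rep(0.01, 50), rep(0.03, 50))
  fr <- frame_series(seq_along(cv), cv)
  w <- average_weight(fr, prof, cfg)
  s1 <- sum(w$W[cv == 0.01])
  s2 <- sum(w$W[cv == 0.03])
  expect_equal(s2 / s1, 2, tolerance = 1e-9)
})

test_that("weights are gauge invariant under constant shifts of G or V", {
  cfg <- toy_config()
  set.seed(4)
  cv <- runif(2000, 0.1, 3.9)
  fr <- frame_series(seq_along(cv), cv)
  grid <- cv_grid(cfg)
  G <- -8 * exp(-(grid - 0.5)^2 / 0.08)
  p1 <- free_energy_profile(grid, G, reference = "min-zeroed")
  p2 <- free_energy_profile(grid, G + 37, reference = "min-zeroed")
  w1 <- average_weight(fr, p1, cfg)
  w2 <- average_weight(fr, p2, cfg)
  expect_equal(w1$W, w2$W, tolerance = 1e-12)

  # bias-based schemes normalise away any overall offset by construction
  h <- random_hills(100, seed = 2)
  wb1 <- bonomi_weights(fr, h, cfg)
  wt1 <- time_period_weights(fr, h, n_blocks = 2, config = cfg)
  expect_equal(sum(wb1$W), 1, tolerance = 1e-12)
  expect_equal(sum(wt1$W), 1, tolerance = 1e-12)
})

test_that("bonomi weights reduce to umbrella unbiasing for a static bias", {
  cfg <- toy_config()
  set.seed(11)
  cv <- runif(3000, 0.1, 3.9)
  # all hills deposited before the first frame: bias static over the window
  h <- random_hills(80, seed = 6, t_spacing = 0.001)
  fr <- frame_series(seq_along(cv) + 1, cv)
  w <- bonomi_weights(fr, h, cfg)
  Vf <- approx(cv_grid(cfg), sum_hills(h, cv_grid(cfg))$final_bias, xout = cv)$y
  kt <- cfg$kB * cfg$temperature
  expected <- exp(Vf / kt) / sum(exp(Vf / kt))
  expect_equal(w$W, expected, tolerance = 1e-6)

  # zero bias throughout: uniform weights
  empty <- hill_records(numeric(0), numeric(0), numeric(0), numeric(0))
  w0 <- bonomi_weights(fr, empty, cfg)
  expect_equal(w0$W, rep(1 / 3000, 3000), tolerance = 1e-14)
})

test_that("time-period weights: static-bias and zero-bias reductions", {
  cfg <- toy_config()
  set.seed(12)
  cv <- runif(2000, 0.1, 3.9)
  h <- random_hills(80, seed = 6, t_spacing = 0.001)
  fr <- frame_series(seq_along(cv) + 1, cv)
  # n_blocks = 1 with an already-static bias equals the bonomi static limit
  w1 <- time_period_weights(fr, h, n_blocks = 1, config = cfg)
  wb <- bonomi_weights(fr, h, cfg)
  expect_equal(w1$W, wb$W, tolerance = 1e-6)

  empty <- hill_records(numeric(0), numeric(0), numeric(0), numeric(0))
  for (nb in c(1, 4, 8)) {
    w0 <- time_period_weights(fr, empty, n_blocks = nb, config = cfg)
    expect_equal(w0$W, rep(1 / 2000, 2000), tolerance = 1e-14)
  }
})

test_that("weighted averages match brute force and flag degeneracy", {
  cfg <- toy_config()
  fr <- uniform_frames(cfg, per_bin = 5)
  n <- length(fr)
  # uniform weights: plain mean
  wu <- uniform_weights(fr)
  r <- weighted_average(fr, wu, "x")
  expect_equal(r$estimate, mean(fr$observables$x), tolerance = 1e-12)

  # brute-force sum(W x) with arbitrary weights
  set.seed(5)
  Wraw <- runif(n)
  w <- frame_weights(fr$times, Wraw, "uniform")
  r2 <- weighted_average(fr, w, "x", seed = 3)
  expect_equal(r2$estimate, sum(Wraw / sum(Wraw) * fr$observables$x),
               tolerance = 1e-12)

  # all weight on one frame: that frame's value, degenerate bootstrap flagged
  W1 <- c(1, rep(0, n - 1))
  wd <- frame_weights(fr$times, W1, "uniform")
  expect_warning(r3 <- weighted_average(fr, wd, "x"), "effective sample size")
  expect_equal(r3$estimate, fr$observables$x[1])
  expect_true(r3$low_ess)
  expect_equal(wd$ess, 1)

  expect_error(weighted_average(fr, wu, "missing_obs"), "missing_obs")
})

test_that("frames outside the profile grid are reported by index", {
  cfg <- toy_config()
  fr <- frame_series(1:3, c(0.5, 4.5, 2.0))
  expect_error(average_weight(fr, flat_profile(cfg), cfg), "frame\\(s\\): 2")
})

test_that("re-weighted CV histogram is flat (Boltzmann self-consistency)", {
  tl <- toy_square_landscape()
  cfg <- toy_config()
  sim <- run_langevin(tl, toy_metad_spec(seed = 42))
  ps <- recover_profile(sim, cfg)
  post <- subset_frames(sim$frames, t_min = 1000)
  w <- average_weight(post, ps, cfg)
  b <- toygold:::cv_bins(post$cv, cfg)
  H <- vapply(seq_len(b$nb), function(k) sum(w$W[b$bin == k]), 0)
  kt <- cfg$kB * cfg$temperature
  Gc <- profile_at(ps, pmin(pmax(b$centers, min(ps$grid)), max(ps$grid)))
  flat <- H * exp(Gc / kt)
  sampled <- flat[H > 0]
  p <- sampled / sum(sampled)
  L1 <- sum(abs(p - 1 / length(p)))
  expect_lt(L1, 0.05)
})

test_that("all three schemes agree on the bound-state conformer population", {
  tl <- toy_square_landscape()
  cfg <- toy_config()
  sim <- run_langevin(tl, toy_metad_spec(seed = 42))
  ps <- recover_profile(sim, cfg)
  post <- subset_frames(sim$frames, t_min = 4000)
  in_b <- post$cv >= cfg$bound_region[1] & post$cv <= cfg$bound_region[2]
  bf <- subset_frames(post, cv_range = cfg$bound_region)
  pop <- function(w) {
    bw <- frame_weights(bf$times, w$W[in_b], w$scheme)
    weighted_average(bf, bw, "conformer", seed = 7)
  }
  r_aw <- pop(average_weight(post, ps, cfg))
  r_bo <- pop(bonomi_weights(post, sim$hills, cfg))
  r_tp <- pop(time_period_weights(post, sim$hills, 4, cfg))
  # pairwise agreement within combined bootstrap errors
  expect_lt(abs(r_aw$estimate - r_bo$estimate),
            3 * sqrt(r_aw$se^2 + r_bo$se^2))
  expect_lt(abs(r_aw$estimate - r_tp$estimate),
            3 * sqrt(r_aw$se^2 + r_tp$se^2))
})
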