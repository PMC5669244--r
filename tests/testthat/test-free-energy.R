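test_that("partition ratio is exact on the hard-edged square well", {
  tl <- toy_landscape("square_well", depth = 10, well_center = 0.5,
                      well_width = 0.5, wall_z = 0, image_wall_z = 4, edge = 0)
  cfg <- toy_config()
  prof <- landscape_free_energy(tl, cv_grid(cfg))
  r <- extract_dG(prof, cfg, estimator = "partition_ratio")
  expect_equal(r$dG, -10, tolerance = 1e-7)
  expect_equal(extract_dG(prof, cfg, estimator = "well_depth")$dG, -10)

  # zero landscape: dG = 0 for both estimators
  flat <- free_energy_profile(cv_grid(cfg), rep(0, cfg$grid_n),
                              reference = "bulk-zeroed")
  expect_equal(extract_dG(flat, cfg, "partition_ratio")$dG, 0, tolerance = 1e-12)
  expect_equal(extract_dG(flat, cfg, "well_depth")$dG, 0)
})

test_that("partition ratio matches an independent quadrature oracle", {
  tl <- toy_landscape("gaussian_well", depth = 5, well_center = 0.5,
                      well_width = 0.2, wall_z = 0, image_wall_z = 4)
  cfg <- run_config(grid_min = 0, grid_max = 2, grid_n = 40001,
                    bound_region = c(0.3, 0.7), bulk_region = c(1.5, 1.9))
  prof <- landscape_free_energy(tl, cv_grid(cfg))
  r <- extract_dG(prof, cfg)
  kt <- cfg$kB * cfg$temperature
  Gfun <- function(s) -5 * (exp(-(s - 0.5)^2 / (2 * 0.2^2)) +
                            exp(-(s - 3.5)^2 / (2 * 0.2^2)))
  Ib <- integrate(function(s) exp(-Gfun(s) / kt), 0.3, 0.7,
                  rel.tol = 1e-12)$value
  Iu <- integrate(function(s) exp(-Gfun(s) / kt), 1.5, 1.9,
                  rel.tol = 1e-12)$value
  expect_lt(abs(r$dG - (-kt * log(Ib / Iu))), 1e-6)
})

test_that("partition ratio is invariant to constant shifts of G", {
  cfg <- toy_config()
  set.seed(2)
  G <- cumsum(rnorm(cfg$grid_n, 0, 0.05))
  p1 <- free_energy_profile(cv_grid(cfg), G, reference = "min-zeroed")
  p2 <- free_energy_profile(cv_grid(cfg), G + 12.3, reference = "min-zeroed")
  d1 <- extract_dG(p1, cfg)$dG
  d2 <- extract_dG(p2, cfg)$dG
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("well depth bounds the partition estimate on random profiles", {
  cfg <- toy_config()
  for (seed in 1:10) {
    set.seed(seed)
    G <- cumsum(rnorm(cfg$grid_n, 0, 0.05))
    p <- free_energy_profile(cv_grid(cfg), G, reference = "min-zeroed")
    d_pr <- extract_dG(p, cfg, "partition_ratio")$dG
    d_wd <- extract_dG(p, cfg, "well_depth")$dG
    g <- cv_grid(cfg)
    max_bulk <- max(G[g >= cfg$bulk_region[1] & g <= cfg$bulk_region[2]])
    expect_gte(d_pr, d_wd - max_bulk - 1e-9)
  }
})

test_that("error handling: unsampled regions and unequal widths", {
  cfg <- toy_config()
  narrow <- free_energy_profile(seq(1, 3, 0.01), rep(0, 201))
  expect_error(extract_dG(narrow, cfg), "unsampled|not covered")
  cfg2 <- run_config(bound_region = c(0.3, 0.6), bulk_region = c(1.8, 2.2))
  flat <- free_energy_profile(cv_grid(cfg2), rep(0, cfg2$grid_n))
  expect_error(extract_dG(flat, cfg2, "partition_ratio"), "equal-width")
})

test_that("facets rank by dG with error-bar significance flags", {
  mk <- function(dG, err) adsorption_result(dG, err, "partition_ratio",
                                            c(0.3, 0.7), c(1.8, 2.2))
  # the three-facet example: strongest at Au(111), weakest at native Au(100)
  fs <- facet_set(list("Au(111)" = mk(-51.8, 18.1),
                       "Au(100)(1x1)" = mk(-10.3, 1.5),
                       "Au(100)(5x1)" = mk(-21.3, 4.2)))
  rk <- rank_facets(fs)
  expect_equal(rk$facet, c("Au(111)", "Au(100)(5x1)", "Au(100)(1x1)"))
  expect_true(all(rk$significant_vs_next[1:2]))
  expect_true(is.na(rk$significant_vs_next[3]))

  # overlapping error bars are not significant
  fs2 <- facet_set(list(a = mk(-12, 5), b = mk(-10, 5)))
  expect_false(rank_facets(fs2)$significant_vs_next[1])

  # ties are ordered by label
  fs3 <- facet_set(list(zeta = mk(-10, 1), alpha = mk(-10, 1)))
  expect_equal(rank_facets(fs3)$facet, c("alpha", "zeta"))

  # random sets match a brute-force sort
  for (seed in 1:5) {
    set.seed(seed)
    vals <- round(rnorm(6, -20, 10), 3)
    fs4 <- facet_set(setNames(lapply(vals, mk, err = 1), paste0("f", 1:6)))
    expect_equal(rank_facets(fs4)$dG, sort(vals))
  }
  expect_error(rank_facets(facet_set(list(a = mk(-1, 0)))), "at least two")
})

test_that("polycrystalline mixing is the fraction-weighted combination", {
  mk <- function(dG, err) adsorption_result(dG, err, "partition_ratio",
                                            c(0.3, 0.7), c(1.8, 2.2))
  one <- facet_set(list(a = mk(-30, 3)), fractions = c(a = 1))
  m1 <- polycrystalline_mix(one)
  expect_equal(m1$dG, -30)
  expect_equal(m1$err, 3)

  # equal fractions of +a and -a cancel
  sym <- facet_set(list(p = mk(8, 1), m = mk(-8, 1)),
                   fractions = c(p = 0.5, m = 0.5))
  expect_equal(polycrystalline_mix(sym)$dG, 0)

  # random fractions against the direct sum
  for (seed in 1:5) {
    set.seed(seed)
    dg <- rnorm(4, -20, 8); er <- runif(4, 0.5, 5)
    f <- runif(4); f <- f / sum(f)
    fs <- facet_set(setNames(Map(mk, dg, er), letters[1:4]),
                    fractions = setNames(f, letters[1:4]))
    m <- polycrystalline_mix(fs)
    expect_equal(m$dG, sum(f * dg), tolerance = 1e-12)
    expect_equal(m$err, sqrt(sum(f^2 * er^2)), tolerance = 1e-12)
  }

  expect_error(polycrystalline_mix(facet_set(list(a = mk(-1, 0)))), "fractions")
  expect_error(facet_set(list(a = mk(-1, 0)), fractions = c(a = 0.7)), "sum to 1")
})

test_that("recovered and analytic profiles give consistent dG on the toy run", {
  tl <- toy_square_landscape(depth = 10)
  cfg <- toy_config()
  sim <- run_langevin(tl, toy_metad_spec(seed = 42))
  ps <- recover_profile(sim, cfg)
  d_rec <- extract_dG(ps, cfg)
  d_true <- extract_dG(landscape_free_energy(tl, cv_grid(cfg)), cfg)
  expect_lt(abs(d_rec$dG - d_true$dG), d_rec$err)
})
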