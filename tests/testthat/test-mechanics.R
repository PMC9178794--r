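test_that("hydrocarbon thickness subtracts the 1 nm phosphate offset", {
  expect_equal(hydrocarbon_thickness(3.1), 2.1)
  expect_equal(hydrocarbon_thickness(2.9), 1.9)
  expect_equal(hydrocarbon_thickness(1.0001), 0.0001)
  expect_error(hydrocarbon_thickness(1.0), "exceed")
})

test_that("fractional thinning is signed and bounded", {
  expect_equal(round(fractional_thinning(0.2, 2.1), 1), -0.1)
  expect_equal(fractional_thinning(0.2, 2.1), -0.2 / 2.1)
  expect_equal(fractional_thinning(0, 1.7), 0)
  expect_equal(fractional_thinning(2.1, 2.1), -1)
  expect_error(fractional_thinning(0.2, 0), "> 0")
})

test_that("tension-area elasticity is linear and exactly invertible", {
  expect_equal(area_from_tension(70, 200), 0.35)
  expect_equal(area_from_tension(60, 200), 0.30)
  expect_equal(tension_from_area(0.1, 200), 20)
  expect_equal(tension_from_area(0, 123), 0)
  for (x in c(-0.2, 0, 0.05, 0.35, 1)) {
    expect_equal(area_from_tension(tension_from_area(x, 200), 200), x,
                 tolerance = 1e-12)
  }
  expect_error(tension_from_area(0.1, 0), "> 0")
  es <- elastic_state(ka = 200, p2p = 3.1, delta_h = 0.21)
  expect_equal(es$rel_thickness_change, -0.1)
  expect_equal(es$gamma, 20)
})

test_that("the area-fluctuation estimator recovers a constructed K_A", {
  kB <- 1.380649e-23
  target <- 200 # mN/m
  a0 <- 45.1584 # nm^2
  temp <- 310
  # invert the estimator: choose the variance that makes K_A = 200 mN/m
  var_nm4 <- kB * temp * (a0 * 1e-18) / (target * 1e-3) * 1e36
  for (s in 1:5) {
    set.seed(s)
    a <- rnorm(10000, a0, sqrt(var_nm4))
    est <- estimate_ka(a, temp)
    expect_equal(est$ka, target, tolerance = 0.1)
    expect_gt(est$ka_se, 0)
  }
  # scaling law: doubling areas (hence 4x variance) halves K_A
  set.seed(6)
  a <- rnorm(5000, a0, sqrt(var_nm4))
  expect_equal(estimate_ka(2 * a, temp)$ka, estimate_ka(a, temp)$ka / 2,
               tolerance = 1e-10)
  # linearity in temperature
  expect_equal(estimate_ka(a, 2 * temp)$ka, 2 * estimate_ka(a, temp)$ka,
               tolerance = 1e-10)
  expect_error(estimate_ka(rep(a0, 200), temp), "zero area variance")
  expect_error(estimate_ka(a[1:50], temp), "at least 100")
})

test_that("water census matches a brute-force z filter on random fixtures", {
  cell <- unit_cell(5, 5, 8)
  slab <- c(3.5, 4.0)
  for (s in 1:10) {
    set.seed(100 + s)
    xyz <- cbind(runif(400, 0, 5), runif(400, 0, 5), runif(400, -4, 12))
    traj <- traj_from_coords(list(xyz), cell,
                             top = point_topology(400, name = "OW",
                                                  resname = "SOL"))
    got <- water_census(traj, slab, seq_len(400))$count
    expect_identical(got, oracle_census(xyz[, 3], 8, slab))
  }
  # no pore: zero at every frame
  spec <- bilayer_spec(lipids_per_leaflet = 16, cell = unit_cell(4, 4, 9),
                       water_slab_thickness = 0.5, n_frames = 3, seed = 2)
  traj <- generate_bilayer(spec)
  ow <- select_atoms(traj$topology, name = "OW")
  expect_equal(water_census(traj, c(4.25, 4.75), ow)$count, rep(0L, 3))
  expect_error(water_census(traj, c(4.25, 4.75), integer(0)), "empty water")
  expect_error(water_census(traj, c(8.5, 9.5), ow), "inside the cell")
})

test_that("plateau statistics find step, constant and noisy-ramp plateaus", {
  # step 0 -> 10 at frame 41, flat after
  step <- census_series(c(rep(0, 40), rep(10, 80)))
  pl <- plateau_stats(step, window = 10)
  expect_equal(pl$onset_frame, 41, tolerance = 10)
  expect_equal(pl$mean, 10)
  expect_equal(pl$sd, 0)
  # constant series stabilises immediately
  const <- census_series(rep(7, 60))
  plc <- plateau_stats(const, window = 10)
  expect_equal(plc$onset_frame, 1)
  expect_equal(plc$mean, 7)
  # ramp + noisy plateau: recovered within 1 count of the generator truth
  set.seed(77)
  ramp <- pmin(seq(0, 12, length.out = 60), 12)
  series <- census_series(pmax(0, round(c(ramp, rep(12, 140)) + rnorm(200, 0, 1))))
  plr <- plateau_stats(series, window = 10)
  expect_equal(plr$mean, 12, tolerance = 1 / 12)
  expect_error(plateau_stats(census_series(rep(1, 5)), window = 10), "longer")
})

test_that("pore diameters follow the cylindrical water-volume model", {
  expect_equal(pore_diameter(10), 0.87, tolerance = 0.005)
  expect_equal(round(pore_diameter(10), 1), 0.9)
  expect_equal(pore_diameter(5), 0.62, tolerance = 0.005)
  expect_equal(round(pore_diameter(5), 1), 0.6)
  expect_equal(pore_diameter(0), 0)
  # d grows as sqrt(NW)
  for (nw in c(1, 5, 10, 40)) {
    expect_equal(pore_diameter(4 * nw), 2 * pore_diameter(nw), tolerance = 1e-12)
  }
  # monotone in NW, decreasing in h and rho
  d <- pore_diameter(1:50)
  expect_true(all(diff(d) > 0))
  expect_gt(pore_diameter(10, h_cyl = 0.5), pore_diameter(10, h_cyl = 1.0))
  expect_gt(pore_diameter(10, rho = 1.0), pore_diameter(10, rho = 2.0))
  expect_error(pore_diameter(-1), ">= 0")
  pc <- pore_cylinder(10)
  expect_equal(pc$diameter_reported, 0.9)
  expect_equal(pc$volume_cm3, 10 * 18.015 / (1 * 6.02214076e23))
  # invariant: d = sqrt(4V / (pi h)) after cm^3 -> nm^3
  expect_equal(pc$diameter_nm,
               sqrt(4 * pc$volume_cm3 * 1e21 / (pi * pc$h_cyl)))
})

test_that("disruption detection fires on sustained blow-up only", {
  flat <- census_series(rep(10, 100))
  expect_true(is.na(detect_disruption(flat)))
  # plateau then monotone blow-up at frame 81
  blow <- census_series(c(rep(10, 80), 10 + cumsum(rep(8, 40))))
  t_det <- detect_disruption(blow, k_sd = 5, persistence = 5)
  expect_false(is.na(t_det))
  expect_lte(abs(t_det - 80), 5) # times are frame-1 = 0-based
  # noisy fixtures: detected within 2 x persistence in at least 9/10 seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    base <- pmax(0, round(c(seq(0, 10, length.out = 30), rep(10, 120)) +
                            rnorm(150, 0, 1)))
    j <- 151
    series <- census_series(c(base, round(10 + cumsum(runif(30, 5, 12)))))
    t_det <- detect_disruption(series, k_sd = 5, persistence = 5)
    if (!is.na(t_det) && abs(t_det - (j - 1)) <= 10) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("generated pores are recovered end-to-end through the census", {
  for (d0 in c(0.6, 0.9, 1.2, 1.5)) {
    spec <- bilayer_spec(
      lipids_per_leaflet = 16, cell = unit_cell(5, 5, 9),
      water_slab_thickness = 0.3,
      pore = pore_spec(diameter = d0), # slab occupancy from bulk density
      n_frames = 2, seed = round(1000 * d0)
    )
    traj <- generate_bilayer(spec)
    ow <- select_atoms(traj$topology, name = "OW")
    census <- water_census(traj, c(4.25, 4.75), ow)
    d_est <- pore_diameter(mean(census$count))
    expect_equal(d_est, d0, tolerance = 0.15)
  }
})
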