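cell672 <- unit_cell(6.72, 6.72, 9)

test_that("thickness maps reproduce flat, dimpled and in-phase geometries", {
  up <- surface_grid(matrix(4.05, 64, 64), cell672)
  lo <- surface_grid(matrix(0.95, 64, 64), cell672)
  tm <- thickness_map(up, lo)
  expect_equal(range(tm$values), c(3.1, 3.1))
  # map mean equals the difference of surface means exactly
  expect_equal(mean(tm$values), mean(up$heights) - mean(lo$heights))

  # a 0.2 nm dimple on the bound leaflet thins the 3.1 nm bilayer to 2.9 nm
  spec <- bilayer_spec(
    lipids_per_leaflet = 400,
    dimple = list(center = c(3.36, 3.36), depth = 0.2, radius = 1.2),
    water_slab_thickness = 0, bulk_water_density = 0, seed = 14
  )
  traj <- generate_bilayer(spec)
  p <- select_atoms(traj$topology, name = "P")
  split <- leaflet_split(traj$frames[[1]]$xyz[p, ])
  fit_up <- fit_leaflet(traj$frames[[1]]$xyz[p[split$upper], ], cell672,
                        grid_n = 64, bandwidth = 0.3)
  fit_lo <- fit_leaflet(traj$frames[[1]]$xyz[p[split$lower], ], cell672,
                        grid_n = 64, bandwidth = 0.3)
  dm <- thickness_map(fit_up, fit_lo)
  expect_equal(min(dm$values), 2.9, tolerance = 0.02)
  expect_equal(max(dm$values), 3.1, tolerance = 0.02)

  # identical in-phase undulation on both leaflets leaves a uniform map
  k <- 2 * pi / 6.72
  gx <- (seq_len(64) - 1) * 6.72 / 64
  und <- outer(gx, gx, function(x, y) 0.25 * sin(k * x) * sin(k * y))
  tm2 <- thickness_map(surface_grid(und + 4.05, cell672),
                       surface_grid(und + 0.95, cell672))
  expect_equal(range(tm2$values), c(3.1, 3.1), tolerance = 1e-12)

  expect_error(
    thickness_map(up, surface_grid(matrix(0.95, 32, 32), cell672)),
    "grid_n"
  )
})

test_that("order maps hit the three reference angles of P2", {
  flat <- surface_grid(matrix(2, 64, 64), cell672)
  om <- order_map(flat)
  expect_equal(range(om$values), c(1, 1))

  # magic angle: P2 crosses zero at 54.7356 degrees
  theta_magic <- 54.7356 * pi / 180
  n <- 64
  gx <- (seq_len(n) - 1) * 6.72 / (n - 1)
  tilt <- surface_grid(matrix(gx * tan(theta_magic), n, n), cell672,
                       periodic = FALSE)
  expect_lt(max(abs(order_map(tilt)$values)), 1e-6)

  # perpendicular surface normal: P2 = -0.5
  expect_equal(legendre_p2(cos(pi / 2)), -0.5)
  expect_equal(legendre_p2(1), 1)

  # bounds hold on arbitrary fitted surfaces
  set.seed(8)
  pts <- cbind(runif(200, 0, 6.72), runif(200, 0, 6.72), rnorm(200, 2, 0.3))
  rough <- fit_leaflet(pts, cell672, grid_n = 48, bandwidth = 0.3)
  v <- order_map(rough)$values
  expect_true(all(v >= -0.5 - 1e-9 & v <= 1 + 1e-9))
})

test_that("area per lipid and its inverse are consistent", {
  flat <- surface_grid(matrix(2, 64, 64), cell672)
  apl <- area_per_lipid(flat, 64)
  expect_equal(apl$area_per_lipid, 0.7056)
  expect_equal(apl$area_per_lipid * apl$lipids_per_nm2, 1)
  # 0.77 nm^2 per lipid is 1.3 lipids per nm^2
  apl2 <- area_per_lipid(0.77 * 64, 64)
  expect_equal(round(apl2$lipids_per_nm2, 1), 1.3)
  # undulation strictly increases the area per lipid at fixed cell
  k <- 2 * pi / 6.72
  gx <- (seq_len(64) - 1) * 6.72 / 64
  und <- surface_grid(outer(gx, gx, function(x, y) 2 + 0.4 * sin(k * x) * sin(k * y)),
                      cell672)
  expect_gt(area_per_lipid(und, 64)$area_per_lipid, apl$area_per_lipid)
  expect_error(area_per_lipid(flat, 0), "> 0")
})

test_that("density profiles are flat in bulk and sharpened by the correction", {
  # bulk water far from a flat bilayer: flat profile at the generator density
  spec <- bilayer_spec(lipids_per_leaflet = 64, water_slab_thickness = 1.5,
                       n_frames = 4, seed = 18)
  traj <- generate_bilayer(spec)
  top <- traj$topology
  p <- select_atoms(top, name = "P")
  ow <- select_atoms(top, name = "OW")
  surfaces <- purrr::map(traj$frames, function(fr) {
    split <- leaflet_split(fr$xyz[p, ])
    list(upper = fit_leaflet(fr$xyz[p[split$upper], ], fr$cell, 32, 0.75),
         lower = fit_leaflet(fr$xyz[p[split$lower], ], fr$cell, 32, 0.75))
  })
  prof <- density_profile(traj, surfaces, list(water = ow), bin_width = 0.25)
  bulk <- dplyr::filter(prof, abs(z) > 2.2, abs(z) < 2.8)
  expect_gt(nrow(bulk), 1)
  expect_equal(mean(bulk$density), spec$bulk_water_density, tolerance = 0.05)

  # flat bilayer: corrected and naive profiles coincide
  naive <- density_profile(traj, surfaces, list(water = ow), bin_width = 0.25,
                           corrected = FALSE)
  expect_equal(prof$density, naive$density, tolerance = 0.02)

  # undulating bilayer: the midsurface correction sharpens the P peaks
  spec_u <- bilayer_spec(lipids_per_leaflet = 400, undulation_amplitude = 0.35,
                         water_slab_thickness = 0, bulk_water_density = 0,
                         n_frames = 1, seed = 19)
  tu <- generate_bilayer(spec_u)
  pu <- select_atoms(tu$topology, name = "P")
  fr <- tu$frames[[1]]
  split <- leaflet_split(fr$xyz[pu, ])
  surf <- list(list(
    upper = fit_leaflet(fr$xyz[pu[split$upper], ], fr$cell, 48, 0.3),
    lower = fit_leaflet(fr$xyz[pu[split$lower], ], fr$cell, 48, 0.3)
  ))
  corr <- density_profile(tu, surf, list(P = pu), bin_width = 0.1)
  nai <- density_profile(tu, surf, list(P = pu), bin_width = 0.1,
                         corrected = FALSE)
  expect_gt(max(corr$density), max(nai$density))

  expect_error(density_profile(traj, surfaces, list(none = integer(0))),
               "empty species")
})

test_that("density profile integrates back to the atom count", {
  spec <- bilayer_spec(lipids_per_leaflet = 36, water_slab_thickness = 1.0,
                       n_frames = 2, seed = 23)
  traj <- generate_bilayer(spec)
  p <- select_atoms(traj$topology, name = "P")
  ow <- select_atoms(traj$topology, name = "OW")
  surfaces <- purrr::map(traj$frames, function(fr) {
    split <- leaflet_split(fr$xyz[p, ])
    list(upper = fit_leaflet(fr$xyz[p[split$upper], ], fr$cell, 32, 0.75),
         lower = fit_leaflet(fr$xyz[p[split$lower], ], fr$cell, 32, 0.75))
  })
  bw <- 0.2
  prof <- density_profile(traj, surfaces, list(water = ow), bin_width = bw)
  cellA <- unname(traj$frames[[1]]$cell[1] * traj$frames[[1]]$cell[2])
  expect_equal(sum(prof$density) * cellA * bw, length(ow))
})
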