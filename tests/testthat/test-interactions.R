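test_that("contact counts honour the cutoff and periodic images", {
  cell <- unit_cell(5, 5, 5)
  near <- traj_from_coords(list(rbind(c(1, 1, 1), c(1.59, 1, 1))), cell)
  far <- traj_from_coords(list(rbind(c(1, 1, 1), c(1.61, 1, 1))), cell)
  expect_equal(count_contacts(near, 1, 2, cutoff = 0.6)$count, 1L)
  expect_equal(count_contacts(far, 1, 2, cutoff = 0.6)$count, 0L)
  # contact only through the periodic image
  wrap <- traj_from_coords(list(rbind(c(0.1, 1, 1), c(4.8, 1, 1))), cell)
  expect_equal(count_contacts(wrap, 1, 2, cutoff = 0.6)$count, 1L)
  expect_equal(count_contacts(wrap, 1, 2, cutoff = 0.2)$count, 0L)
  expect_error(count_contacts(near, integer(0), 2), "empty")
})

test_that("cell-list contact counting equals the all-pairs oracle", {
  cell <- unit_cell(5, 5, 5)
  for (s in 1:10) {
    set.seed(300 + s)
    xyz <- cbind(runif(500, 0, 5), runif(500, 0, 5), runif(500, 0, 5))
    traj <- traj_from_coords(list(xyz), cell)
    ga <- 1:250; gb <- 251:500
    got <- count_contacts(traj, ga, gb, cutoff = 0.6)$count
    expect_identical(got, oracle_contacts(xyz, ga, gb, 0.6, cell))
    # identical groups count unordered pairs once
    gg <- 1:120
    got_same <- count_contacts(traj, gg, gg, cutoff = 0.6)$count
    expect_identical(got_same, oracle_contacts(xyz, gg, gg, 0.6, cell))
  }
})

test_that("residue distance maps average frame-wise minimum distances", {
  cell <- unit_cell(10, 10, 10)
  # two single-atom residues at fixed distance over two frames
  xyz1 <- rbind(c(1, 1, 1), c(1, 1, 3.5))
  traj <- traj_from_coords(list(xyz1, xyz1), cell)
  dm <- min_distance_map(traj, residues = list(r1 = 1L, r2 = 2L))
  expect_equal(dm$matrix["r1", "r2"], 2.5)
  expect_equal(dm$matrix, t(dm$matrix))
  expect_equal(diag(dm$matrix), c(r1 = 0, r2 = 0))
  # random fixture versus brute force
  set.seed(44)
  frames <- purrr::map(1:3, ~cbind(runif(12, 0, 10), runif(12, 0, 10),
                                   runif(12, 0, 10)))
  rtraj <- traj_from_coords(frames, cell)
  residues <- list(a = 1:4, b = 5:8, c = 9:12)
  dm2 <- min_distance_map(rtraj, residues = residues)
  brute <- matrix(0, 3, 3)
  for (f in frames) {
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      dmin <- Inf
      for (ai in residues[[i]]) for (bj in residues[[j]]) {
        dmin <- min(dmin, oracle_min_image(f[ai, ], f[bj, ], cell))
      }
      brute[i, j] <- brute[i, j] + dmin / 3
    }
  }
  expect_equal(unname(dm2$matrix), brute, tolerance = 1e-9)
  expect_error(min_distance_map(rtraj, residues = list(a = integer(0))), "empty")
})

test_that("hydrogen bonds require both distance and angle criteria", {
  cell <- unit_cell(6, 6, 6)
  top <- topology(tibble::tibble(
    name = c("OD", "HD", "OA"), resname = c("GLU", "GLU", "PGL"),
    resid = c(1L, 1L, 2L)
  ))
  geometry <- function(da, angle_deg) {
    # donor at origin-ish, hydrogen on the D->A axis rotated by angle
    d <- c(2, 2, 2)
    a <- d + c(da, 0, 0)
    ang <- angle_deg * pi / 180
    h <- d + 0.1 * c(cos(ang), sin(ang), 0)
    rbind(d, h, a)
  }
  ok <- md_trajectory(top, list(md_frame(0, geometry(0.28, 0), cell)))
  hb <- find_hbonds(ok, donors = 1L, acceptors = 3L,
                    hydrogens = data.frame(donor = 1L, hydrogen = 2L))
  expect_equal(nrow(hb$bonds), 1)
  too_far <- md_trajectory(top, list(md_frame(0, geometry(0.40, 0), cell)))
  expect_equal(nrow(find_hbonds(too_far, 1L, 3L,
                                hydrogens = data.frame(donor = 1L, hydrogen = 2L))$bonds), 0)
  bent <- md_trajectory(top, list(md_frame(0, geometry(0.28, 45), cell)))
  expect_equal(nrow(find_hbonds(bent, 1L, 3L,
                                hydrogens = data.frame(donor = 1L, hydrogen = 2L))$bonds), 0)
})

test_that("hbond existence maps follow constructed on/off toggling", {
  cell <- unit_cell(6, 6, 6)
  top <- topology(tibble::tibble(
    name = c("OD", "HD1", "OA"), resname = c("SER", "SER", "SOL"),
    resid = c(1L, 1L, 2L)
  ))
  on_xyz <- rbind(c(2, 2, 2), c(2.1, 2, 2), c(2.30, 2, 2))
  off_xyz <- rbind(c(2, 2, 2), c(2.1, 2, 2), c(2.90, 2, 2))
  frames <- purrr::imap(1:8, function(i, ...) {
    md_frame(i - 1, if (i %% 2 == 0) on_xyz else off_xyz, cell)
  })
  traj <- md_trajectory(top, frames)
  # hydrogen auto-detected by the H* naming convention within the residue
  hb <- find_hbonds(traj, donors = 1L, acceptors = 3L)
  expect_equal(nrow(hb$bonds), 1)
  expect_equal(as.vector(hb$presence[1, ]), as.integer(1:8 %% 2 == 0))
  # rigid rotation + translation leaves detection unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- purrr::map(frames, function(f) {
    md_frame(f$time, sweep(f$xyz %*% rot, 2, c(0.4, -0.2, 0.3), "+"), cell)
  })
  hb2 <- find_hbonds(md_trajectory(top, moved), donors = 1L, acceptors = 3L)
  expect_equal(hb2$presence, hb$presence)
  # donor with no hydrogen is skipped with a warning
  top2 <- topology(tibble::tibble(
    name = c("OD", "OD", "OA"), resname = c("SER", "THR", "SOL"),
    resid = c(1L, 2L, 3L)
  ))
  t2 <- md_trajectory(top2, list(md_frame(0, on_xyz, cell)))
  expect_warning(expect_error(find_hbonds(t2, donors = 1L, acceptors = 3L),
                              "no usable"), "no attached hydrogen")
})

test_that("centre-of-mass tracks are mass-weighted and translation-covariant", {
  cell <- unit_cell(10, 10, 10)
  top <- topology(tibble::tibble(
    name = c("P", "P", "CA"), resname = c("PGL", "PGL", "TRP"),
    resid = 1:3, mass = c(30, 30, 110)
  ))
  xyz <- rbind(c(1, 1, 1), c(3, 1, 1), c(5, 5, 5))
  traj <- md_trajectory(top, list(
    md_frame(0, xyz, cell),
    md_frame(10, xyz + 0.5, cell)
  ))
  single <- com_track(traj, 3L)
  expect_equal(c(single$x[1], single$y[1], single$z[1]), c(5, 5, 5))
  pair <- com_track(traj, 1:2)
  expect_equal(pair$x, c(2, 2.5)) # equal masses -> midpoint, shifts with Delta
  expect_equal(pair$z[2] - pair$z[1], 0.5)
  d <- com_track(traj, 1:2, selection2 = 3L)
  expect_equal(d$distance[1],
               oracle_min_image(c(2, 1, 1), c(5, 5, 5), cell))
  top0 <- topology(tibble::tibble(name = "X", resname = "UNK", resid = 1L,
                                  mass = 1))
  expect_error(com_track(md_trajectory(top0, list(md_frame(0, matrix(1, 1, 3),
                                                           cell))), integer(0)),
               "zero total mass")
})

test_that("MSD diffusion recovers Brownian coefficients and flags drift", {
  # stationary particles diffuse with D = 0
  cell <- unit_cell(50, 50, 50)
  still <- traj_from_coords(purrr::map(1:60, ~matrix(25, 5, 3)), cell, dt = 10)
  est0 <- msd_diffusion(still, 1:5)
  expect_equal(est0$d_cm2_s, 0)
  # known-D random walks recovered within 15% (free-solution scale)
  d_target <- 6.0e-7
  for (s in 1:5) {
    set.seed(400 + s)
    traj <- make_brownian_traj(120, 200, d_target)
    est <- msd_diffusion(traj, 1:120, dimensionality = 3)
    expect_equal(est$d_cm2_s, d_target, tolerance = 0.15)
    expect_false(est$non_diffusive)
  }
  # a 60x mobility contrast is recovered within 20%
  set.seed(500)
  fast <- msd_diffusion(make_brownian_traj(150, 200, 6.0e-7), 1:150)
  slow <- msd_diffusion(make_brownian_traj(150, 200, 1.0e-8), 1:150)
  expect_equal(fast$d_cm2_s / slow$d_cm2_s, 60, tolerance = 0.2)
  # ballistic drift is non-diffusive (MSD ~ t^2)
  drift <- traj_from_coords(
    purrr::map(1:80, function(i) matrix(rep(c(i * 0.1, 0, 0), each = 4), 4, 3) + 10),
    cell, dt = 10
  )
  estd <- msd_diffusion(drift, 1:4)
  expect_true(estd$non_diffusive)
  expect_equal(estd$exponent, 2, tolerance = 0.01)
  # wrapped coordinates are refused
  wrapped <- traj_from_coords(purrr::map(1:60, function(i) {
    matrix(c((i * 30) %% 50, 25, 25), 1, 3)
  }), cell, dt = 10)
  expect_error(msd_diffusion(wrapped, 1L), "unwrap")
})

test_that("charge bookkeeping reproduces both protonation states", {
  neutral <- charge_book(8, 2, 4)
  lowph <- charge_book(8, 2, 4, glu_protonated = TRUE)
  expect_equal(net_charge(neutral), 6L)
  expect_equal(net_charge(lowph), 10L)
  expect_equal(counterions_needed(128, 2, neutral), 116L)
  expect_equal(counterions_needed(128, 2, lowph), 108L)
  expect_error(charge_book(-1, 2, 4), ">= 0")
  # electroneutrality: counterions + peptide charge - lipid charge = 0
  for (nl in c(64, 128)) for (np in 0:3) for (book in list(neutral, lowph)) {
    ions <- counterions_needed(nl, np, book)
    expect_equal(ions + np * net_charge(book) - nl, 0L)
  }
})
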