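# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (brute force / dense quadrature) and never
# call the implementation path they check.

# exhaustive 27-periodic-image distance
oracle_min_image <- function(a, b, cell) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- b + c(ix * cell[1], iy * cell[2], iz * cell[3]) - a
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# all-pairs contact count by explicit 27-image enumeration
oracle_contacts <- function(xyz, group_a, group_b, cutoff, cell) {
  A <- xyz[group_a, , drop = FALSE]
  B <- xyz[group_b, , drop = FALSE]
  best <- matrix(Inf, nrow(A), nrow(B))
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    dx <- outer(A[, 1], B[, 1] + ix * cell[1], "-")
    dy <- outer(A[, 2], B[, 2] + iy * cell[2], "-")
    dz <- outer(A[, 3], B[, 3] + iz * cell[3], "-")
    best <- pmin(best, sqrt(dx^2 + dy^2 + dz^2))
  }
  if (setequal(group_a, group_b)) {
    as.integer(sum(best < cutoff & outer(group_a, group_b, "<")))
  } else {
    as.integer(sum(best < cutoff))
  }
}

# direct z-filter water census
oracle_census <- function(z, lz, slab) {
  zw <- z %% lz
  sum(zw >= slab[1] & zw < slab[2])
}

# dense midpoint quadrature of the area of an analytic height field
oracle_surface_area <- function(hx_fun, hy_fun, lx, ly, n = 1200) {
  xs <- (seq_len(n) - 0.5) * lx / n
  ys <- (seq_len(n) - 0.5) * ly / n
  gx <- outer(xs, ys, hx_fun)
  gy <- outer(xs, ys, hy_fun)
  sum(sqrt(1 + gx^2 + gy^2)) * (lx / n) * (ly / n)
}

# 3-D Brownian walk trajectory with known diffusion coefficient (cm^2/s)
make_brownian_traj <- function(n_atoms, nf, d_cm2_s, dt = 10, box = 50) {
  d_nm2_ps <- d_cm2_s * 1e2
  step_sd <- sqrt(2 * d_nm2_ps * dt)
  top <- topology(tibble::tibble(
    name = "CA", resname = "ALA", resid = seq_len(n_atoms)
  ))
  cell <- unit_cell(box, box, box)
  pos <- matrix(box / 2, n_atoms, 3)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    if (f > 1) pos <- pos + matrix(rnorm(n_atoms * 3, 0, step_sd), n_atoms, 3)
    frames[[f]] <- md_frame((f - 1) * dt, pos, cell)
  }
  md_trajectory(top, frames)
}

# bare topology of n identically named atoms
point_topology <- function(n, name = "X", resname = "UNK") {
  topology(tibble::tibble(name = name, resname = resname, resid = seq_len(n)))
}

# trajectory from a list of coordinate matrices over a fixed cell
traj_from_coords <- function(coord_list, cell, dt = 1, top = NULL) {
  top <- top %||% point_topology(nrow(coord_list[[1]]))
  frames <- purrr::imap(coord_list, function(m, i) md_frame((i - 1) * dt, m, cell))
  md_trajectory(top, frames)
}

`%||%` <- rlang::`%||%`
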