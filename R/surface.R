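#' Height-field surface grids
#'
#' A `surface_grid` is a regular lateral grid of surface heights (nm) over
#' the periodic cell, the representation used for a leaflet surface fitted
#' to its phosphorus atoms. Fitted grids are periodic: node `a` sits at
#' `(a-1) * L / grid_n` and the field wraps across the seam. Analytic test
#' surfaces that are not box-periodic (tilted planes) can be represented
#' with `periodic = FALSE`, in which case nodes span `[0, L]` inclusive and
#' edge handling is one-sided.
#'
#' @param heights A `grid_n x grid_n` numeric matrix of z-values, nm;
#'   rows index x, columns index y.
#' @param cell A [unit_cell()].
#' @param periodic Is the field periodic in both lateral directions?
#' @param bandwidth Gaussian kernel bandwidth used for fitting, nm
#'   (`NA` for constructed grids).
#' @param fit_rmsd Root-mean-square deviation between the fitted surface
#'   and the input points, nm (`NA` for constructed grids).
#' @param n_points Number of points the surface was fitted to.
#' @return An object of class `surface_grid`.
#' @export
surface_grid <- function(heights, cell, periodic = TRUE, bandwidth = NA_real_,
                         fit_rmsd = NA_real_, n_points = NA_integer_) {
  heights <- as.matrix(heights)
  if (nrow(heights) != ncol(heights)) abort("heights must be a square matrix")
  if (!is.na(fit_rmsd) && fit_rmsd < 0) abort("fit_rmsd must be >= 0")
  structure(
    list(heights = heights, grid_n = nrow(heights), cell = as_unit_cell(cell),
         periodic = isTRUE(periodic), bandwidth = bandwidth,
         fit_rmsd = fit_rmsd, n_points = n_points),
    class = "surface_grid"
  )
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf(
    "<surface_grid> %d x %d nodes, cell %.3f x %.3f nm, %s%s\n",
    x$grid_n, x$grid_n, x$cell[1], x$cell[2],
    if (x$periodic) "periodic" else "non-periodic",
    if (is.na(x$fit_rmsd)) "" else sprintf(", fit RMSD %.4f nm", x$fit_rmsd)
  ))
  invisible(x)
}

# lateral node coordinates along one axis
grid_axis <- function(surface, which = c("x", "y")) {
  which <- match.arg(which)
  L <- if (which == "x") surface$cell[1] else surface$cell[2]
  n <- surface$grid_n
  if (surface$periodic) (seq_len(n) - 1) * L / n else (seq_len(n) - 1) * L / (n - 1)
}

#' Fit a leaflet surface to phosphorus positions
#'
#' Node heights are kernel-weighted means of the point heights under a
#' periodic Gaussian lateral kernel; the surface value at an arbitrary
#' lateral position is defined by the same kernel formula, and `fit_rmsd`
#' is the RMS of (point height - surface height at the point's lateral
#' position). With `bandwidth = "auto"` a fixed bandwidth ladder is
#' scanned and the largest (smoothest) value achieving RMSD <= 0.1 nm,
#' the usual fit-quality bar for P-atom surfaces, is chosen; if no ladder
#' value achieves it, the RMSD-minimising value is used.
#'
#' @param points P-atom coordinates: n x 3 matrix or data frame with
#'   `x`, `y`, `z` (nm); at least 4 points from a single leaflet.
#' @param cell A [unit_cell()].
#' @param grid_n Grid nodes per lateral dimension (default 500; all
#'   contracts hold for any `grid_n >= 32`).
#' @param bandwidth Kernel bandwidth in nm, or `"auto"`.
#' @return A [surface_grid()] with `bandwidth`, `fit_rmsd` and `n_points`
#'   populated.
#' @export
fit_leaflet <- function(points, cell, grid_n = 500, bandwidth = "auto") {
  cell <- as_unit_cell(cell)
  pts <- to_xyz_matrix(points)
  if (nrow(pts) < 4) abort("need at least 4 points to fit a leaflet surface")
  if (sd(pts[, 1]) < 1e-9 && sd(pts[, 2]) < 1e-9) {
    abort("degenerate fit: all points share one lateral position")
  }
  if (grid_n < 8) abort("grid_n must be >= 8")
  if (identical(bandwidth, "auto")) {
    ladder <- c(1.5, 1.0, 0.75, 0.5, 0.4, 0.3, 0.25, 0.2, 0.15)
    rmsds <- vapply(ladder, function(b) surface_rmsd_at_points(pts, cell, b),
                    numeric(1))
    ok <- which(rmsds <= 0.1)
    bandwidth <- if (length(ok)) ladder[min(ok)] else ladder[which.min(rmsds)]
  }
  if (bandwidth <= 0) abort("bandwidth must be > 0")
  gx <- (seq_len(grid_n) - 1) * cell[1] / grid_n
  gy <- (seq_len(grid_n) - 1) * cell[2] / grid_n
  Wx <- periodic_gauss_weights(gx, pts[, 1], cell[1], bandwidth)
  Wy <- periodic_gauss_weights(gy, pts[, 2], cell[2], bandwidth)
  num <- Wx %*% t(Wy * rep(pts[, 3], each = nrow(Wy)))
  den <- Wx %*% t(Wy)
  if (any(den < 1e-300)) {
    abort("bandwidth too small: some grid nodes receive no kernel weight")
  }
  heights <- num / den
  rmsd <- surface_rmsd_at_points(pts, cell, bandwidth)
  surface_grid(heights, cell, periodic = TRUE, bandwidth = bandwidth,
               fit_rmsd = rmsd, n_points = nrow(pts))
}

# grid-of-targets x points Gaussian weight matrix with periodic wrap
periodic_gauss_weights <- function(targets, points, L, bw) {
  d <- outer(targets, points, "-")
  d <- d - L * round(d / L)
  exp(-d^2 / (2 * bw^2))
}

# kernel-smoothed surface evaluated at the points themselves -> fit RMSD
surface_rmsd_at_points <- function(pts, cell, bw) {
  n <- nrow(pts)
  s <- numeric(n)
  chunk <- max(1L, as.integer(2e6 / n))
  for (start in seq(1, n, by = chunk)) {
    i <- start:min(n, start + chunk - 1)
    wx <- periodic_gauss_weights(pts[i, 1], pts[, 1], cell[1], bw)
    wy <- periodic_gauss_weights(pts[i, 2], pts[, 2], cell[2], bw)
    w <- wx * wy
    s[i] <- (w %*% pts[, 3]) / rowSums(w)
  }
  sqrt(mean((pts[, 3] - s)^2))
}

#' Evaluate a surface at arbitrary lateral positions
#'
#' Bilinear interpolation on the height grid, respecting periodicity.
#'
#' @param surface A [surface_grid()].
#' @param x,y Lateral positions, nm (vectors of equal length).
#' @return Surface heights at `(x, y)`, nm.
#' @export
surface_eval <- function(surface, x, y) {
  n <- surface$grid_n
  if (surface$periodic) {
    dx <- surface$cell[1] / n; dy <- surface$cell[2] / n
    fx <- (x %% surface$cell[1]) / dx
    fy <- (y %% surface$cell[2]) / dy
    i0 <- floor(fx); j0 <- floor(fy)
    tx <- fx - i0; ty <- fy - j0
    i0 <- (i0 %% n) + 1; j0 <- (j0 %% n) + 1
    i1 <- (i0 %% n) + 1; j1 <- (j0 %% n) + 1
  } else {
    dx <- surface$cell[1] / (n - 1); dy <- surface$cell[2] / (n - 1)
    fx <- pmin(pmax(x / dx, 0), n - 1 - 1e-12)
    fy <- pmin(pmax(y / dy, 0), n - 1 - 1e-12)
    i0 <- floor(fx); j0 <- floor(fy)
    tx <- fx - i0; ty <- fy - j0
    i0 <- i0 + 1; j0 <- j0 + 1
    i1 <- pmin(i0 + 1, n); j1 <- pmin(j0 + 1, n)
  }
  h <- surface$heights
  h00 <- h[cbind(i0, j0)]; h10 <- h[cbind(i1, j0)]
  h01 <- h[cbind(i0, j1)]; h11 <- h[cbind(i1, j1)]
  (1 - tx) * (1 - ty) * h00 + tx * (1 - ty) * h10 +
    (1 - tx) * ty * h01 + tx * ty * h11
}

#' Split phosphorus atoms into upper and lower leaflets
#'
#' One-dimensional two-class partition of the z coordinates (exact 1-D
#' 2-means over all split thresholds, deterministic). The split fails with
#' an error when the z distribution is not clearly bimodal, i.e. when the
#' class means are separated by less than twice the sum of the class
#' standard deviations.
#'
#' @param points P-atom coordinates (n x 3 matrix or data frame).
#' @param cell A [unit_cell()] (currently unused by the partition itself;
#'   kept for interface symmetry).
#' @return A list with integer index vectors `upper` and `lower` (indices
#'   into `points`, ascending) and the `midplane` z between the class means.
#' @export
leaflet_split <- function(points, cell = NULL) {
  pts <- to_xyz_matrix(points)
  z <- pts[, 3]
  if (length(z) < 4) abort("need at least 4 points to split leaflets")
  ord <- order(z)
  zs <- z[ord]
  n <- length(zs)
  # exact 1-D 2-means: best threshold minimises within-class sum of squares
  cum <- cumsum(zs); cum2 <- cumsum(zs^2)
  k <- seq_len(n - 1)
  ss_lo <- cum2[k] - cum[k]^2 / k
  ss_hi <- (cum2[n] - cum2[k]) - (cum[n] - cum[k])^2 / (n - k)
  k_best <- k[which.min(ss_lo + ss_hi)]
  lower_idx <- sort(ord[seq_len(k_best)])
  upper_idx <- sort(ord[(k_best + 1):n])
  mu_lo <- mean(z[lower_idx]); mu_hi <- mean(z[upper_idx])
  sd_lo <- if (length(lower_idx) > 1) sd(z[lower_idx]) else 0
  sd_hi <- if (length(upper_idx) > 1) sd(z[upper_idx]) else 0
  if ((mu_hi - mu_lo) < 2 * (sd_lo + sd_hi) || (mu_hi - mu_lo) <= 0) {
    abort("cannot split leaflets: z distribution is not bimodal")
  }
  list(upper = upper_idx, lower = lower_idx, midplane = (mu_lo + mu_hi) / 2)
}

#' Surface normal field
#'
#' Unit normals at every grid node, from central-difference height
#' gradients (periodic wrap for periodic surfaces, one-sided differences at
#' the edges otherwise).
#'
#' @param surface A [surface_grid()].
#' @return An object of class `normal_field`: list of `grid_n x grid_n`
#'   matrices `nx`, `ny`, `nz` with unit norm at every node.
#' @export
surface_normals <- function(surface) {
  h <- surface$heights
  n <- surface$grid_n
  if (surface$periodic) {
    dx <- surface$cell[1] / n; dy <- surface$cell[2] / n
    ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
    dhdx <- (h[ip, , drop = FALSE] - h[im, , drop = FALSE]) / (2 * dx)
    dhdy <- (h[, ip, drop = FALSE] - h[, im, drop = FALSE]) / (2 * dy)
  } else {
    dx <- surface$cell[1] / (n - 1); dy <- surface$cell[2] / (n - 1)
    dhdx <- matrix(0, n, n); dhdy <- matrix(0, n, n)
    dhdx[2:(n - 1), ] <- (h[3:n, ] - h[1:(n - 2), ]) / (2 * dx)
    dhdx[1, ] <- (h[2, ] - h[1, ]) / dx
    dhdx[n, ] <- (h[n, ] - h[n - 1, ]) / dx
    dhdy[, 2:(n - 1)] <- (h[, 3:n] - h[, 1:(n - 2)]) / (2 * dy)
    dhdy[, 1] <- (h[, 2] - h[, 1]) / dy
    dhdy[, n] <- (h[, n] - h[, n - 1]) / dy
  }
  norm <- sqrt(dhdx^2 + dhdy^2 + 1)
  structure(list(nx = -dhdx / norm, ny = -dhdy / norm, nz = 1 / norm,
                 grid_n = n, cell = surface$cell),
            class = "normal_field")
}

#' Surface area of a height field
#'
#' Sum of the areas of the two triangles per grid cell. For periodic
#' surfaces the seam cells (wrapping back to the first node) are included;
#' for non-periodic grids the `(grid_n - 1)^2` interior cells tile the
#' cell exactly. The area of any height field is >= `lx * ly`, with
#' equality only for a flat surface.
#'
#' @param surface A [surface_grid()].
#' @return Area in nm^2.
#' @export
surface_area <- function(surface) {
  h <- surface$heights
  n <- surface$grid_n
  if (surface$periodic) {
    dx <- surface$cell[1] / n; dy <- surface$cell[2] / n
    ip <- c(2:n, 1)
    h00 <- h; h10 <- h[ip, , drop = FALSE]
    h01 <- h[, ip, drop = FALSE]; h11 <- h[ip, ip, drop = FALSE]
  } else {
    dx <- surface$cell[1] / (n - 1); dy <- surface$cell[2] / (n - 1)
    idx <- 1:(n - 1)
    h00 <- h[idx, idx]; h10 <- h[idx + 1, idx]
    h01 <- h[idx, idx + 1]; h11 <- h[idx + 1, idx + 1]
  }
  # triangle (00,10,01): cross((dx,0,h10-h00),(0,dy,h01-h00))
  a1 <- 0.5 * sqrt((dy * (h10 - h00))^2 + (dx * (h01 - h00))^2 + (dx * dy)^2)
  # triangle (11,01,10): cross((dx,0,h11-h01),(0,dy,h11-h10))
  a2 <- 0.5 * sqrt((dy * (h11 - h01))^2 + (dx * (h11 - h10))^2 + (dx * dy)^2)
  sum(a1) + sum(a2)
}

#' @rdname surface_grid
#' @param x A `surface_grid`.
#' @param ... Unused.
#' @method tidy surface_grid
#' @export
tidy.surface_grid <- function(x, ...) {
  gx <- grid_axis(x, "x"); gy <- grid_axis(x, "y")
  n <- x$grid_n
  h <- as.vector(x$heights)
  tibble(x = rep(gx, times = n), y = rep(gy, each = n), height = h)
}

#' @rdname surface_grid
#' @method glance surface_grid
#' @export
glance.surface_grid <- function(x, ...) {
  tibble(
    grid_n = x$grid_n, periodic = x$periodic, bandwidth = x$bandwidth,
    fit_rmsd = x$fit_rmsd, n_points = x$n_points,
    area = surface_area(x),
    mean_height = mean(x$heights)
  )
}

#' Write / read a surface grid as a delimited text matrix
#'
#' A small `#`-prefixed header records grid size, cell, periodicity,
#' bandwidth and fit RMSD; the body is the whitespace-delimited height
#' matrix.
#'
#' @param surface A [surface_grid()].
#' @param path File path.
#' @return `write_surface()`: `path` invisibly; `read_surface()`: the
#'   [surface_grid()].
#' @export
write_surface <- function(surface, path) {
  hdr <- c(
    sprintf("# grid_n %d", surface$grid_n),
    sprintf("# cell %.8f %.8f %.8f", surface$cell[1], surface$cell[2], surface$cell[3]),
    sprintf("# periodic %d", as.integer(surface$periodic)),
    sprintf("# bandwidth %.8f", surface$bandwidth),
    sprintf("# fit_rmsd %.8f", surface$fit_rmsd)
  )
  body <- apply(surface$heights, 1, function(r) paste(sprintf("%.8f", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", ln[1]), "\\s+")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  heights <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  cell <- get("cell")
  surface_grid(heights, unit_cell(cell[1], cell[2], cell[3]),
               periodic = get("periodic") == 1,
               bandwidth = get("bandwidth"), fit_rmsd = get("fit_rmsd"))
}
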