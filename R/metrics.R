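#' Lateral scalar field maps
#'
#' A `field_map` holds a `grid_n x grid_n` lateral scalar field over the
#' bilayer plane: local P-to-P thickness (nm) or the surface order
#' parameter. Order-parameter values live in `[-0.5, 1]`; thickness values
#' must be positive.
#'
#' @param values Square numeric matrix (rows x, columns y).
#' @param quantity `"thickness_nm"` or `"order_parameter"`.
#' @param cell A [unit_cell()].
#' @param frames_averaged How many frames were averaged node-wise.
#' @return An object of class `field_map`.
#' @export
field_map <- function(values, quantity = c("thickness_nm", "order_parameter"),
                      cell, frames_averaged = 1L) {
  quantity <- match.arg(quantity)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("field_map values must be square")
  if (quantity == "thickness_nm" && any(values <= 0)) {
    abort("thickness map values must be > 0")
  }
  if (quantity == "order_parameter" &&
      (any(values < -0.5 - 1e-9) || any(values > 1 + 1e-9))) {
    abort("order parameter values must lie in [-0.5, 1]")
  }
  structure(list(values = values, quantity = quantity,
                 grid_n = nrow(values), cell = as_unit_cell(cell),
                 frames_averaged = as.integer(frames_averaged)),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %s, %d x %d, range [%.4g, %.4g], %d frame(s)\n",
              x$quantity, x$grid_n, x$grid_n, min(x$values), max(x$values),
              x$frames_averaged))
  invisible(x)
}

#' @rdname field_map
#' @param x A `field_map`.
#' @param ... Unused.
#' @method tidy field_map
#' @export
tidy.field_map <- function(x, ...) {
  n <- x$grid_n
  gx <- (seq_len(n) - 1) * x$cell[1] / n
  gy <- (seq_len(n) - 1) * x$cell[2] / n
  v <- as.vector(x$values)
  q <- x$quantity
  tibble(x = rep(gx, times = n), y = rep(gy, each = n),
         value = v, quantity = q)
}

#' Local bilayer thickness map
#'
#' Node-wise vertical P-to-P distance between the two fitted leaflet
#' surfaces: `upper height - lower height` at matched lateral nodes. The
#' map mean equals the difference of the surface mean heights exactly.
#'
#' @param upper,lower [surface_grid()]s of the two leaflets with matching
#'   `grid_n` and cell.
#' @return A [field_map()] with quantity `"thickness_nm"`.
#' @export
thickness_map <- function(upper, lower) {
  stopifnot(inherits(upper, "surface_grid"), inherits(lower, "surface_grid"))
  if (upper$grid_n != lower$grid_n) abort("leaflet grids must share grid_n")
  if (max(abs(upper$cell - lower$cell)) > 1e-9) {
    abort("leaflet grids must share the unit cell")
  }
  field_map(upper$heights - lower$heights, "thickness_nm", upper$cell)
}

#' Surface order-parameter map
#'
#' Node-wise second Legendre polynomial `P2(cos theta) = (3 cos^2 theta - 1) / 2`
#' of the angle between the local fitted-surface normal and the bilayer
#' normal (the box z-axis): 1 for a perfectly flat surface, 0 at the magic
#' angle (54.74 degrees), -0.5 for a locally perpendicular surface. Lower
#' values mean higher local curvature.
#'
#' @param surface A [surface_grid()], or a `normal_field` from
#'   [surface_normals()].
#' @return A [field_map()] with quantity `"order_parameter"`.
#' @export
order_map <- function(surface) {
  normals <- if (inherits(surface, "normal_field")) surface else surface_normals(surface)
  cos_theta <- normals$nz # reference axis (0, 0, 1), normals are unit
  field_map(legendre_p2(cos_theta), "order_parameter", normals$cell)
}

#' @param cos_theta Cosine(s) of the angle between two unit vectors.
#' @rdname order_map
#' @export
legendre_p2 <- function(cos_theta) (3 * cos_theta^2 - 1) / 2

#' Average field maps node-wise over frames
#'
#' @param maps A list of [field_map()]s with identical quantity, grid and
#'   cell (one per frame).
#' @return A [field_map()] with `frames_averaged` set.
#' @export
average_field_maps <- function(maps) {
  stopifnot(length(maps) >= 1, all(map_dbl(maps, "grid_n") == maps[[1]]$grid_n))
  q <- unique(vapply(maps, function(m) m$quantity, character(1)))
  if (length(q) != 1) abort("cannot average maps of different quantities")
  avg <- Reduce(`+`, map(maps, "values")) / length(maps)
  field_map(avg, q, maps[[1]]$cell, frames_averaged = length(maps))
}

#' Area per lipid
#'
#' Leaflet surface area divided by the number of lipids in that leaflet,
#' together with its inverse (lipids per nm^2), the packing measure used to
#' track tension-driven lipid separation.
#'
#' @param surface A [surface_grid()] (or a precomputed area in nm^2).
#' @param n_lipids Number of lipids in the leaflet (> 0).
#' @return A one-row tibble with `area_nm2` (total leaflet area),
#'   `n_lipids`, `area_per_lipid` (nm^2) and `lipids_per_nm2`
#'   (`= 1 / area_per_lipid`).
#' @examples
#' s <- surface_grid(matrix(2, 64, 64), unit_cell(6.72, 6.72, 9))
#' area_per_lipid(s, 64) # 0.7056 nm^2 per lipid
#' @export
area_per_lipid <- function(surface, n_lipids) {
  if (n_lipids <= 0) abort("n_lipids must be > 0")
  area <- if (inherits(surface, "surface_grid")) surface_area(surface) else as.numeric(surface)
  apl <- area / n_lipids
  tibble(area_nm2 = area, n_lipids = as.integer(n_lipids),
         area_per_lipid = apl, lipids_per_nm2 = 1 / apl)
}

#' Curvature-corrected number density profiles
#'
#' Number density of each selected species along the bilayer normal,
#' referenced to the local midsurface: each atom is binned by
#' `z' = z - midsurface(x, y)` where the midsurface is the mean of the two
#' fitted leaflet heights at the atom's lateral position. This removes the
#' smearing that bilayer undulation and peptide-induced curvature produce
#' in a naive absolute-z histogram (`corrected = FALSE` gives that naive
#' profile, referenced to the mean midsurface height). Counts are
#' normalised by slab volume and frame count.
#'
#' @param traj An [md_trajectory()].
#' @param surfaces Per-frame list of `list(upper =, lower =)` fitted
#'   [surface_grid()]s (length = number of frames).
#' @param species Named list of atom index vectors (e.g. from
#'   [select_atoms()]); all must be non-empty.
#' @param bin_width Bin width, nm (default 0.1).
#' @param corrected Use the local midsurface reference (default `TRUE`).
#' @return A tibble with `species`, `z` (bin centre, nm, signed distance
#'   from the bilayer midsurface) and `density` (nm^-3).
#' @export
density_profile <- function(traj, surfaces, species, bin_width = 0.1,
                            corrected = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (length(surfaces) != nf) abort("need one surface pair per frame")
  if (!length(species) || is.null(names(species))) {
    abort("species must be a named list of atom index vectors")
  }
  if (any(vapply(species, length, integer(1)) == 0)) {
    abort("empty species selection")
  }
  zprimes <- lapply(species, function(sel) vector("list", nf))
  for (f in seq_len(nf)) {
    fr <- traj$frames[[f]]
    up <- surfaces[[f]]$upper; lo <- surfaces[[f]]$lower
    for (sp in names(species)) {
      xyz <- fr$xyz[species[[sp]], , drop = FALSE]
      if (corrected) {
        msf <- (surface_eval(up, xyz[, 1], xyz[, 2]) +
                surface_eval(lo, xyz[, 1], xyz[, 2])) / 2
      } else {
        msf <- (mean(up$heights) + mean(lo$heights))
        msf <- rep(msf / 2, nrow(xyz))
      }
      zprimes[[sp]][[f]] <- xyz[, 3] - msf
    }
  }
  all_z <- unlist(zprimes)
  lo_edge <- floor(min(all_z) / bin_width) * bin_width
  hi_edge <- ceiling(max(all_z) / bin_width) * bin_width
  if (hi_edge <= max(all_z)) hi_edge <- hi_edge + bin_width
  breaks <- seq(lo_edge, hi_edge, by = bin_width)
  cellA <- traj$frames[[1]]$cell[1] * traj$frames[[1]]$cell[2]
  out <- purrr::imap(zprimes, function(zl, sp) {
    counts <- tabulate(findInterval(unlist(zl), breaks, rightmost.closed = FALSE),
                       nbins = length(breaks) - 1)
    tibble(species = sp,
           z = head(breaks, -1) + bin_width / 2,
           density = counts / (cellA * bin_width * nf))
  })
  bind_rows(out)
}
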