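#' Orthorhombic unit cell
#'
#' All analyses in bilayr assume an orthorhombic periodic box with edges
#' aligned to the Cartesian axes, the geometry of semi-isotropically coupled
#' bilayer simulations. Edge lengths are in nanometres.
#'
#' @param lx,ly,lz Box edge lengths in nm; all must be strictly positive.
#' @return An object of class `unit_cell`: a named numeric vector
#'   `c(lx, ly, lz)`.
#' @examples
#' unit_cell(6.72, 6.72, 9)
#' @export
unit_cell <- function(lx, ly, lz) {
  edges <- c(lx = as.numeric(lx), ly = as.numeric(ly), lz = as.numeric(lz))
  if (any(!is.finite(edges)) || any(edges <= 0)) {
    abort("unit_cell edges must be finite and > 0")
  }
  structure(edges, class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> %.4f x %.4f x %.4f nm\n", x[1], x[2], x[3]))
  invisible(x)
}

as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(x)
  if (is.numeric(x) && length(x) == 3) return(unit_cell(x[1], x[2], x[3]))
  abort("cannot interpret `cell`: supply unit_cell() or a length-3 numeric")
}

#' Minimum-image displacement and distance
#'
#' Distances under the minimum-image convention for an orthorhombic cell:
#' each Cartesian component of `b - a` is wrapped into `[-L/2, L/2)` before
#' the Euclidean norm is taken. The result is symmetric in `a`/`b` and never
#' exceeds half the box diagonal.
#'
#' @param a,b Coordinates in nm: length-3 vectors or n x 3 matrices
#'   (recycled row-wise if one argument is a single point).
#' @param cell A [unit_cell()].
#' @return `min_image_displacement()`: an n x 3 matrix of wrapped component
#'   differences `b - a`; `min_image_distance()`: a numeric vector of
#'   distances in nm.
#' @examples
#' min_image_distance(c(0.1, 0, 0), c(4.9, 0, 0), unit_cell(5, 5, 5)) # 0.2
#' @export
min_image_displacement <- function(a, b, cell) {
  cell <- as_unit_cell(cell)
  a <- to_xyz_matrix(a)
  b <- to_xyz_matrix(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) abort("a and b must have matching numbers of points")
  d <- b - a
  for (k in 1:3) {
    L <- cell[k]
    d[, k] <- d[, k] - L * round(d[, k] / L)
  }
  d
}

#' @rdname min_image_displacement
#' @export
min_image_distance <- function(a, b, cell) {
  d <- min_image_displacement(a, b, cell)
  sqrt(rowSums(d^2))
}

#' Wrap coordinates into the primary cell
#'
#' Coordinates are kept as-read by all readers; wrapping is an explicit
#' operation because some analyses (the water census) want wrapped
#' coordinates while others (mean-squared displacement) require unwrapped
#' ones.
#'
#' @param xyz An n x 3 coordinate matrix in nm.
#' @param cell A [unit_cell()].
#' @return An n x 3 matrix with every component wrapped into `[0, L)`.
#' @export
wrap_coordinates <- function(xyz, cell) {
  cell <- as_unit_cell(cell)
  xyz <- to_xyz_matrix(xyz)
  for (k in 1:3) xyz[, k] <- xyz[, k] %% cell[k]
  xyz
}

# coerce vectors / data frames to an n x 3 numeric matrix
to_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) abort("coordinate matrix must have 3 columns")
    return(x)
  }
  if (is.data.frame(x)) {
    if (!all(c("x", "y", "z") %in% names(x))) {
      abort("coordinate data frame needs columns x, y, z")
    }
    return(cbind(x = x$x, y = x$y, z = x$z))
  }
  if (is.numeric(x) && length(x) == 3) return(matrix(x, nrow = 1))
  abort("cannot interpret coordinates: need length-3 vector, n x 3 matrix, or data frame")
}
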