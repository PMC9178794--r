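#' Trajectory container
#'
#' A trajectory couples one topology with an ordered sequence of frames.
#' Each frame holds a time (ps), an n-atom x 3 coordinate matrix (nm) and a
#' [unit_cell()]. Frame times must be strictly increasing. Coordinates are
#' stored exactly as supplied (no implicit wrapping).
#'
#' @param topology A [topology()].
#' @param frames A list of frames built with [md_frame()].
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "bilayr_topology"))
  if (!length(frames)) abort("trajectory needs at least one frame")
  n_atoms <- nrow(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "md_frame")) abort("frames must be md_frame objects")
    if (nrow(f$xyz) != n_atoms) {
      abort(sprintf("frame %d has %d atoms but topology has %d",
                    i, nrow(f$xyz), n_atoms))
    }
  }
  times <- map_dbl(frames, "time")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames), class = "md_trajectory")
}

#' @param time Frame time in ps (non-negative).
#' @param xyz n x 3 coordinate matrix, nm.
#' @param cell A [unit_cell()].
#' @rdname md_trajectory
#' @export
md_frame <- function(time, xyz, cell) {
  xyz <- to_xyz_matrix(xyz)
  if (!is.finite(time) || time < 0) abort("frame time must be non-negative")
  structure(list(time = as.numeric(time), xyz = xyz, cell = as_unit_cell(cell)),
            class = "md_frame")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms, %d frames, t = %g..%g ps\n",
              nrow(x$topology), length(x$frames),
              x$frames[[1]]$time, x$frames[[length(x$frames)]]$time))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

frame_times <- function(traj) map_dbl(traj$frames, "time")

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> t = %g ps, %d atoms\n", x$time, nrow(x$xyz)))
  invisible(x)
}

#' Tidy a trajectory into a long atom table
#'
#' @param x An `md_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per atom per frame: `frame`, `time`,
#'   the topology columns, and `x`, `y`, `z` (nm).
#' @method tidy md_trajectory
#' @export
tidy.md_trajectory <- function(x, ...) {
  purrr::imap(x$frames, function(f, i) {
    dplyr::bind_cols(
      tibble(frame = i, time = f$time),
      x$topology,
      tibble(x = f$xyz[, 1], y = f$xyz[, 2], z = f$xyz[, 3])
    )
  }) |>
    bind_rows()
}

#' @method glance md_trajectory
#' @export
glance.md_trajectory <- function(x, ...) {
  cells <- map(x$frames, "cell")
  tibble(
    n_atoms = nrow(x$topology),
    n_frames = length(x$frames),
    t_start = x$frames[[1]]$time,
    t_end = x$frames[[length(x$frames)]]$time,
    lx = cells[[1]][1], ly = cells[[1]][2], lz = cells[[1]][3]
  )
}

# coordinates of selected atoms in one frame
frame_coords <- function(traj, frame, selection = NULL) {
  xyz <- traj$frames[[frame]]$xyz
  if (is.null(selection)) xyz else xyz[selection, , drop = FALSE]
}
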