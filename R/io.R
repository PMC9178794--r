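#' Read a molecular structure file
#'
#' Readers for the two plain-text structure formats used throughout:
#' GROMACS GRO (fixed columns, nm) and PDB (ATOM/HETATM + CRYST1,
#' angstroms converted to nm at this boundary). File indices are 1-based as
#' in the formats themselves. Triclinic boxes are rejected: all bilayr
#' geometry assumes an orthorhombic cell.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"gro"` or `"pdb"`.
#' @param cell Optional [unit_cell()] used when the file carries no box
#'   (PDB without CRYST1); an error is raised if neither is available.
#' @return A list with elements `topology` ([topology()]) and `frame`
#'   ([md_frame()]).
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb"), cell = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      gro = "gro", pdb = "pdb",
      abort("cannot infer format from extension; pass format=")
    )
  }
  if (format == "gro") read_gro(path) else read_pdb(path, cell = cell)
}

#' Read a (multi-frame) GRO file
#'
#' @param path Path to a `.gro` file; may contain several concatenated
#'   frames (title/count/atoms/box blocks).
#' @return `read_gro()`: list(`topology`, `frame`) for the first frame;
#'   `read_gro_trajectory()`: an [md_trajectory()] with all frames.
#' @export
read_gro <- function(path) {
  parsed <- parse_gro(path, max_frames = 1)
  list(topology = parsed$topology, frame = parsed$frames[[1]])
}

#' @param topology Optional [topology()] the frames must match; defaults to
#'   the topology parsed from the first frame.
#' @rdname read_gro
#' @export
read_gro_trajectory <- function(path, topology = NULL) {
  parsed <- parse_gro(path, max_frames = Inf)
  top <- topology %||% parsed$topology
  if (nrow(top) != nrow(parsed$topology)) {
    abort("supplied topology does not match atom count in file")
  }
  frames <- parsed$frames
  # files written without time stamps: synthesise strictly increasing times
  times <- map_dbl(frames, "time")
  if (any(duplicated(times)) || any(diff(times) <= 0)) {
    for (i in seq_along(frames)) frames[[i]]$time <- as.numeric(i - 1)
  }
  md_trajectory(top, frames)
}

parse_gro <- function(path, max_frames = Inf) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    abort(paste0("no frames in GRO file: ", path))
  }
  frames <- list()
  topology <- NULL
  pos <- 1
  n_expected <- NA_integer_
  while (pos <= length(lines) && length(frames) < max_frames) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1; next }
    title <- lines[pos]
    if (pos + 1 > length(lines)) abort(sprintf("GRO truncated at line %d", pos + 1))
    n <- suppressWarnings(as.integer(trimws(lines[pos + 1])))
    if (is.na(n) || n <= 0) {
      abort(sprintf("GRO parse error at line %d: expected atom count", pos + 1))
    }
    if (is.na(n_expected)) n_expected <- n
    if (n != n_expected) {
      abort(sprintf("frame %d has %d atoms, expected %d", length(frames) + 1, n, n_expected))
    }
    atom_lines <- pos + 1 + seq_len(n)
    if (max(atom_lines) + 1 > length(lines)) {
      abort(sprintf("GRO truncated: frame %d incomplete", length(frames) + 1))
    }
    al <- lines[atom_lines]
    if (any(nchar(al) < 44)) {
      bad <- atom_lines[which(nchar(al) < 44)[1]]
      abort(sprintf("GRO parse error at line %d: truncated coordinate line", bad))
    }
    resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
    resname <- trimws(substr(al, 6, 10))
    name <- trimws(substr(al, 11, 15))
    xs <- suppressWarnings(as.numeric(substr(al, 21, 28)))
    ys <- suppressWarnings(as.numeric(substr(al, 29, 36)))
    zs <- suppressWarnings(as.numeric(substr(al, 37, 44)))
    bad <- which(is.na(resid) | is.na(xs) | is.na(ys) | is.na(zs))
    if (length(bad)) {
      abort(sprintf("GRO parse error at line %d: malformed record", atom_lines[bad[1]]))
    }
    box_line <- lines[max(atom_lines) + 1]
    box <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
    if (length(box) < 3 || any(is.na(box[1:3]))) {
      abort(sprintf("GRO parse error at line %d: malformed box line", max(atom_lines) + 1))
    }
    if (length(box) > 3 && any(abs(box[-(1:3)]) > 1e-9)) {
      abort("triclinic cells are not supported; only orthorhombic boxes")
    }
    time <- NA_real_
    tm <- regmatches(title, regexec("t=\\s*([0-9eE.+-]+)", title))[[1]]
    if (length(tm) == 2) time <- as.numeric(tm[2])
    if (is.na(time)) time <- length(frames)
    if (is.null(topology)) {
      topology <- topology(tibble(
        atom = seq_len(n), name = name, resname = resname, resid = resid
      ))
    }
    frames[[length(frames) + 1]] <-
      md_frame(time, cbind(xs, ys, zs), unit_cell(box[1], box[2], box[3]))
    pos <- max(atom_lines) + 2
  }
  if (!length(frames)) abort(paste0("no frames in GRO file: ", path))
  list(topology = topology, frames = frames)
}

#' Write structures and trajectories as GRO
#'
#' Coordinates are written with the format's native three-decimal precision,
#' so a write/read round trip preserves coordinates to 0.001 nm.
#'
#' @param topology A [topology()].
#' @param frame A single [md_frame()], or for the trajectory writer a
#'   trajectory / list of frames.
#' @param path Output path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_gro <- function(topology, frame, path, title = "bilayr") {
  writeLines(format_gro_frame(topology, frame, title), path)
  invisible(path)
}

#' @param traj An [md_trajectory()].
#' @rdname write_gro
#' @export
write_gro_trajectory <- function(traj, path, title = "bilayr") {
  blocks <- map(traj$frames, function(f) format_gro_frame(traj$topology, f, title))
  writeLines(unlist(blocks), path)
  invisible(path)
}

format_gro_frame <- function(topology, frame, title) {
  stopifnot(inherits(frame, "md_frame"))
  n <- nrow(topology)
  lines <- character(n + 3)
  lines[1] <- sprintf("%s t= %.3f", title, frame$time)
  lines[2] <- sprintf("%5d", n)
  # GRO residue/atom numbers wrap at 5 digits
  lines[2 + seq_len(n)] <- sprintf(
    "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
    topology$resid %% 100000, substr(topology$resname, 1, 5),
    substr(topology$name, 1, 5), topology$atom %% 100000,
    frame$xyz[, 1], frame$xyz[, 2], frame$xyz[, 3]
  )
  lines[n + 3] <- sprintf("%10.5f%10.5f%10.5f",
                          frame$cell[1], frame$cell[2], frame$cell[3])
  lines
}

#' Read / write PDB structures
#'
#' Minimal fixed-column PDB support: ATOM/HETATM records and the CRYST1
#' cell. Coordinates are converted between the PDB's angstroms and bilayr's
#' internal nm at this boundary. Non-90-degree cell angles are rejected.
#'
#' @param path File path.
#' @param cell Optional [unit_cell()] (nm) used when the file has no CRYST1.
#' @return As [read_structure()].
#' @export
read_pdb <- function(path, cell = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    a <- as.numeric(substr(cr[1], 7, 15)); b <- as.numeric(substr(cr[1], 16, 24))
    c3 <- as.numeric(substr(cr[1], 25, 33))
    ang <- c(as.numeric(substr(cr[1], 34, 40)), as.numeric(substr(cr[1], 41, 47)),
             as.numeric(substr(cr[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-3)) {
      abort("triclinic cells are not supported; only orthorhombic boxes")
    }
    cell <- unit_cell(a / 10, b / 10, c3 / 10)
  }
  if (is.null(cell)) abort("PDB has no CRYST1 record; supply cell=")
  idx <- grep("^(ATOM  |HETATM)", lines)
  if (!length(idx)) abort(paste0("no ATOM/HETATM records in ", path))
  al <- lines[idx]
  short <- which(nchar(al) < 54)
  if (length(short)) {
    abort(sprintf("PDB parse error at line %d: truncated ATOM record", idx[short[1]]))
  }
  name <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 21))
  chain <- trimws(substr(al, 22, 22))
  resid <- suppressWarnings(as.integer(substr(al, 23, 26)))
  xs <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  bad <- which(is.na(resid) | is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad)) {
    abort(sprintf("PDB parse error at line %d: malformed record", idx[bad[1]]))
  }
  top <- topology(tibble(
    atom = seq_along(al), name = name, resname = resname,
    resid = resid, chain = ifelse(nzchar(chain), chain, NA_character_)
  ))
  list(topology = top,
       frame = md_frame(0, cbind(xs, ys, zs) / 10, cell))
}

#' @param topology,frame As for [write_gro()].
#' @rdname read_pdb
#' @export
write_pdb <- function(topology, frame, path) {
  stopifnot(inherits(frame, "md_frame"))
  ang <- frame$xyz * 10
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            frame$cell[1] * 10, frame$cell[2] * 10, frame$cell[3] * 10,
            90, 90, 90),
    sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            topology$atom %% 100000, substr(topology$name, 1, 4),
            substr(topology$resname, 1, 4),
            ifelse(is.na(topology$chain), " ", substr(topology$chain, 1, 1)),
            topology$resid %% 10000, ang[, 1], ang[, 2], ang[, 3], 1, 0),
    "END"
  )
  writeLines(lines, path)
  invisible(path)
}
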