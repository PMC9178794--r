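#' Specify a synthetic bilayer trajectory
#'
#' The generator emulates the statistical structure the membrane analyses
#' assume: two leaflets of minimal pseudo-lipids whose phosphorus atoms lie
#' on smooth, box-commensurate undulating surfaces separated by a mean
#' P-to-P distance of 3.1 nm (the anionic-bilayer value the analyses are
#' calibrated against), bulk water slabs, an optional cylindrical
#' trans-bilayer water pore with an exactly specified census-slab occupancy,
#' an optional bound pseudo-peptide cluster with labelled residue classes,
#' and an optional per-frame lateral dilation schedule mimicking applied
#' surface tension.
#'
#' Defaults describe a 128-lipid (64 per leaflet) bilayer in a
#' 6.72 x 6.72 nm box (0.7056 nm^2 per lipid), midplane at `lz/2`.
#' Each pseudo-lipid is a P atom, two tail beads and a carbonyl-oxygen
#' acceptor; water is a single O site (two H sites optional, for
#' hydrogen-bond geometry tests).
#'
#' @param cell A [unit_cell()] (nm). Default `unit_cell(6.72, 6.72, 9)`.
#' @param lipids_per_leaflet Lipids in each leaflet (default 64).
#' @param p2p_mean Mean vertical P-to-P distance between leaflets, nm
#'   (default 3.1).
#' @param undulation_amplitude Amplitude of the separable sinusoidal
#'   undulation, nm (default 0).
#' @param undulation_modes Integer mode counts `c(nx, ny)` so the
#'   undulation is periodic in the box (default `c(1, 1)`).
#' @param dimple Optional list `list(center = c(x, y), depth, radius)`:
#'   a Gaussian depression of the upper (peptide-bound) leaflet, thinning
#'   the bilayer locally as bound peptide does.
#' @param positional_noise_sd Gaussian noise added to P-atom heights, nm.
#' @param water_slab_thickness Thickness of each bulk water slab, nm
#'   (default 1.2).
#' @param bulk_water_density Bulk water number density, molecules/nm^3
#'   (default 33.4, i.e. 1 g/cm^3).
#' @param midplane_z Bilayer midplane height, nm (default `lz/2`). Set it
#'   to 1.95 to reproduce an absolute census window of 1.7--2.2 nm.
#' @param pore Optional [pore_spec()].
#' @param peptide Optional [peptide_spec()].
#' @param dilation Optional per-frame lateral scale factors (length
#'   `n_frames`), applied via [apply_dilation()] with volume conservation.
#' @param water_hydrogens If `TRUE`, each water gets two H sites at fixed
#'   ideal geometry.
#' @param n_frames Number of frames (default 1).
#' @param dt Time step between frames, ps (default 10).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `bilayer_spec` list.
#' @export
bilayer_spec <- function(cell = unit_cell(6.72, 6.72, 9),
                         lipids_per_leaflet = 64,
                         p2p_mean = 3.1,
                         undulation_amplitude = 0,
                         undulation_modes = c(1, 1),
                         dimple = NULL,
                         positional_noise_sd = 0,
                         water_slab_thickness = 1.2,
                         bulk_water_density = .water_number_density,
                         midplane_z = NULL,
                         pore = NULL,
                         peptide = NULL,
                         dilation = NULL,
                         water_hydrogens = FALSE,
                         n_frames = 1,
                         dt = 10,
                         seed = 1) {
  cell <- as_unit_cell(cell)
  midplane_z <- midplane_z %||% (cell[3] / 2)
  spec <- list(
    cell = cell, lipids_per_leaflet = as.integer(lipids_per_leaflet),
    p2p_mean = p2p_mean, undulation_amplitude = undulation_amplitude,
    undulation_modes = as.integer(undulation_modes), dimple = dimple,
    positional_noise_sd = positional_noise_sd,
    water_slab_thickness = water_slab_thickness,
    bulk_water_density = bulk_water_density,
    midplane_z = midplane_z, pore = pore, peptide = peptide,
    dilation = dilation, water_hydrogens = isTRUE(water_hydrogens),
    n_frames = as.integer(n_frames), dt = dt, seed = as.integer(seed)
  )
  validate_bilayer_spec(spec)
  structure(spec, class = "bilayer_spec")
}

validate_bilayer_spec <- function(s) {
  if (s$p2p_mean <= 0) abort("p2p_mean must be > 0")
  if (s$undulation_amplitude < 0) abort("undulation_amplitude must be >= 0")
  if (s$positional_noise_sd < 0) abort("positional_noise_sd must be >= 0")
  if (s$lipids_per_leaflet < 4) abort("need at least 4 lipids per leaflet")
  if (s$n_frames < 1) abort("n_frames must be >= 1")
  if (!is.null(s$dilation)) {
    if (length(s$dilation) != s$n_frames) {
      abort("dilation schedule length must equal n_frames")
    }
    if (any(s$dilation <= 0)) abort("dilation factors must be > 0")
  }
  if (!is.null(s$dimple)) {
    thinned <- s$p2p_mean - s$dimple$depth
    if (thinned <= 0) abort("dimple depth leaves non-positive thickness")
  }
  if (!is.null(s$pore)) {
    if (s$pore$diameter >= min(s$cell[1], s$cell[2])) {
      abort("pore diameter exceeds the lateral cell size")
    }
  }
  invisible(s)
}

#' Specify a cylindrical trans-bilayer water pore
#'
#' @param diameter Pore diameter, nm.
#' @param axis Lateral `(x, y)` position of the pore axis, nm; `NULL`
#'   centres it in the cell.
#' @param occupancy_in_center_slab Exact number of water molecules placed
#'   with z inside the 0.5 nm census slab about the midplane; `NULL` fills
#'   the slab at `fill_density`.
#' @param fill_density Water density inside the pore, g/cm^3 (default 1.0,
#'   the bulk value assumed by the cylindrical pore-sizing model).
#' @return A `pore_spec` list.
#' @export
pore_spec <- function(diameter, axis = NULL, occupancy_in_center_slab = NULL,
                      fill_density = 1.0) {
  if (diameter <= 0) abort("pore diameter must be > 0")
  if (!is.null(occupancy_in_center_slab) && occupancy_in_center_slab < 0) {
    abort("pore occupancy must be >= 0")
  }
  if (fill_density <= 0) abort("fill_density must be > 0")
  structure(list(diameter = diameter, axis = axis,
                 occupancy_in_center_slab = occupancy_in_center_slab,
                 fill_density = fill_density),
            class = "pore_spec")
}

#' Specify a bound pseudo-peptide
#'
#' One pseudo-atom per residue (a CA-like bead of 110 amu), arranged as a
#' compact globular cluster. Residue classes drive selection-based
#' analyses (contacts between cationic residues and lipids, etc.).
#'
#' @param residues Data frame with columns `resname` and `class`, one row
#'   per residue; default is a 70-residue circular-bacteriocin-like
#'   composition (8 LYS, 2 ARG, 4 GLU, remainder hydrophobic/polar).
#' @param n_protomers Number of copies (default 2, a bound dimer).
#' @param placement `"surface_bound"` (COM just above the upper P surface),
#'   `"inserted"` (COM `depth` below the upper P surface) or `"solution"`
#'   (in the upper water slab).
#' @param depth Insertion depth below the upper leaflet P level, nm.
#' @param radius Cluster radius, nm (default 1.0).
#' @return A `peptide_spec` list.
#' @export
peptide_spec <- function(residues = NULL, n_protomers = 2,
                         placement = c("surface_bound", "inserted", "solution"),
                         depth = 0.5, radius = 1.0) {
  placement <- match.arg(placement)
  if (is.null(residues)) {
    res <- c(rep("LYS", 8), rep("ARG", 2), rep("GLU", 4),
             rep("TRP", 2), rep("SER", 6), rep("THR", 6),
             rep("ALA", 14), rep("LEU", 14), rep("VAL", 8), rep("GLY", 6))
    residues <- tibble(resname = res, class = guess_class(res))
  }
  residues <- as_tibble(residues)
  if (!all(c("resname", "class") %in% names(residues))) {
    abort("residues needs columns resname and class")
  }
  bad <- setdiff(unique(residues$class), bilayr_atom_classes())
  if (length(bad)) abort(paste0("unknown residue class: ", paste(bad, collapse = ", ")))
  structure(list(residues = residues, n_protomers = as.integer(n_protomers),
                 placement = placement, depth = depth, radius = radius),
            class = "peptide_spec")
}

undulation_height <- function(x, y, spec, cell = spec$cell) {
  if (spec$undulation_amplitude == 0) return(rep(0, length(x)))
  spec$undulation_amplitude *
    sin(2 * pi * spec$undulation_modes[1] * x / cell[1]) *
    sin(2 * pi * spec$undulation_modes[2] * y / cell[2])
}

dimple_depth_at <- function(x, y, dimple, cell) {
  if (is.null(dimple)) return(rep(0, length(x)))
  dx <- x - dimple$center[1]; dx <- dx - cell[1] * round(dx / cell[1])
  dy <- y - dimple$center[2]; dy <- dy - cell[2] * round(dy / cell[2])
  dimple$depth * exp(-(dx^2 + dy^2) / (2 * dimple$radius^2))
}

#' Generate a synthetic bilayer trajectory
#'
#' Builds the trajectory described by a [bilayer_spec()]: leaflet P atoms on
#' `z = midplane +/- p2p_mean/2 + undulation(x, y)` (upper leaflet
#' additionally depressed by the dimple) plus Gaussian noise, tail beads and
#' carbonyl-O acceptors filling the hydrocarbon region, bulk water slabs,
#' exact pore-water placement, and an optional bound peptide cluster.
#' Output is bit-reproducible from `spec$seed` and leaves the global RNG
#' state untouched.
#'
#' @param spec A [bilayer_spec()].
#' @return An [md_trajectory()]. The topology carries resnames `PGL`
#'   (pseudo-lipid: atoms `P`, `OC`, `C1`, `C2`), `SOL` (water `OW`
#'   (+`HW1`, `HW2`)) and peptide residue names; chains label leaflets
#'   (`U`/`L`), water (`W`) and protomers (`A`, `B`, ...).
#' @export
generate_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  validate_bilayer_spec(spec)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  cell <- spec$cell
  n_lip <- spec$lipids_per_leaflet
  mid <- spec$midplane_z
  half <- spec$p2p_mean / 2

  # lateral lipid lattice, jittered once (shared by all frames)
  m <- ceiling(sqrt(n_lip))
  gx <- (rep(seq_len(m), m)[seq_len(n_lip)] - 0.5) * cell[1] / m
  gy <- (rep(seq_len(m), each = m)[seq_len(n_lip)] - 0.5) * cell[2] / m
  jitter_sd <- 0.05 * cell[1] / m
  lat_upper <- cbind(gx + rnorm(n_lip, 0, jitter_sd),
                     gy + rnorm(n_lip, 0, jitter_sd))
  lat_lower <- cbind(gx + rnorm(n_lip, 0, jitter_sd),
                     gy + rnorm(n_lip, 0, jitter_sd))
  lat_upper[, 1] <- lat_upper[, 1] %% cell[1]; lat_upper[, 2] <- lat_upper[, 2] %% cell[2]
  lat_lower[, 1] <- lat_lower[, 1] %% cell[1]; lat_lower[, 2] <- lat_lower[, 2] %% cell[2]

  # water counts fixed across frames
  slab_lo_z <- c(mid - half - 0.35 - spec$water_slab_thickness, mid - half - 0.35)
  slab_hi_z <- c(mid + half + 0.35, mid + half + 0.35 + spec$water_slab_thickness)
  slab_vol <- cell[1] * cell[2] * spec$water_slab_thickness
  n_wat_slab <- max(0L, as.integer(round(spec$bulk_water_density * slab_vol)))

  pore <- spec$pore
  census_slab <- c(mid - 0.25, mid + 0.25)
  if (!is.null(pore)) {
    axis <- pore$axis %||% c(cell[1] / 2, cell[2] / 2)
    r_pore <- pore$diameter / 2
    n_density <- pore$fill_density * .N_avogadro / .M_water * 1e-21
    slab_cyl_vol <- pi * r_pore^2 * 0.5
    n_pore_slab <- pore$occupancy_in_center_slab %||%
      as.integer(round(n_density * slab_cyl_vol))
    rest_h <- (spec$p2p_mean - 0.5)
    n_pore_rest <- as.integer(round(n_density * pi * r_pore^2 * rest_h))
  }

  # topology assembled once from frame-1 placement
  build_frame <- function(frame_i) {
    atoms <- list(); coords <- list()
    add <- function(df, xyz) {
      atoms[[length(atoms) + 1]] <<- df
      coords[[length(coords) + 1]] <<- xyz
    }
    lipid_atoms <- function(lat, leaflet) {
      n <- nrow(lat)
      und <- undulation_height(lat[, 1], lat[, 2], spec)
      zP <- if (leaflet == "U") {
        mid + half + und - dimple_depth_at(lat[, 1], lat[, 2], spec$dimple, cell)
      } else {
        mid - half + und
      }
      zP <- zP + rnorm(n, 0, spec$positional_noise_sd)
      sgn <- if (leaflet == "U") -1 else 1 # tails point to midplane
      xyz <- rbind(
        cbind(lat, zP),                         # P
        cbind(lat, zP + sgn * 0.20),            # OC carbonyl acceptor
        cbind(lat, zP + sgn * 0.60),            # C1
        cbind(lat, zP + sgn * 1.10)             # C2
      )
      ord <- as.vector(t(matrix(seq_len(4 * n), ncol = 4)))
      xyz <- xyz[ord, , drop = FALSE]
      df <- tibble(
        name = rep(c("P", "OC", "C1", "C2"), n),
        resname = "PGL",
        resid = rep(seq_len(n), each = 4),
        chain = leaflet,
        class = "lipid"
      )
      list(df = df, xyz = xyz)
    }
    up <- lipid_atoms(lat_upper, "U")
    lo <- lipid_atoms(lat_lower, "L")
    lo$df$resid <- lo$df$resid + n_lip
    add(up$df, up$xyz); add(lo$df, lo$xyz)

    water_block <- function(n, zr, first_resid) {
      if (n == 0) return(NULL)
      x <- runif(n, 0, cell[1]); y <- runif(n, 0, cell[2])
      z <- runif(n, zr[1], zr[2])
      list(x = x, y = y, z = z, resid = first_resid + seq_len(n) - 1L)
    }
    resid0 <- 2L * n_lip
    wb <- list(
      water_block(n_wat_slab, slab_lo_z, resid0 + 1L),
      water_block(n_wat_slab, slab_hi_z, resid0 + n_wat_slab + 1L)
    )
    # pore waters: exact slab occupancy + density fill of the rest
    if (!is.null(pore)) {
      place_in_disc <- function(n) {
        th <- runif(n, 0, 2 * pi); rr <- r_pore * sqrt(runif(n))
        cbind((axis[1] + rr * cos(th)) %% cell[1],
              (axis[2] + rr * sin(th)) %% cell[2])
      }
      next_resid <- resid0 + 2L * n_wat_slab + 1L
      if (n_pore_slab > 0) {
        d <- place_in_disc(n_pore_slab)
        wb[[length(wb) + 1]] <- list(
          x = d[, 1], y = d[, 2],
          z = runif(n_pore_slab, census_slab[1], census_slab[2] - 1e-9),
          resid = next_resid + seq_len(n_pore_slab) - 1L
        )
        next_resid <- next_resid + n_pore_slab
      }
      if (n_pore_rest > 0) {
        d <- place_in_disc(n_pore_rest)
        zlo <- runif(n_pore_rest, mid - half, census_slab[1] - 1e-9)
        zhi <- runif(n_pore_rest, census_slab[2] + 1e-9, mid + half)
        pick_hi <- runif(n_pore_rest) < 0.5
        wb[[length(wb) + 1]] <- list(
          x = d[, 1], y = d[, 2], z = ifelse(pick_hi, zhi, zlo),
          resid = next_resid + seq_len(n_pore_rest) - 1L
        )
      }
    }
    for (blk in wb) {
      if (is.null(blk)) next
      nw <- length(blk$x)
      if (spec$water_hydrogens) {
        # ideal SPC-like geometry: O-H 0.1 nm, one H along +x, one at 104.5 deg
        hx <- 0.1; h2 <- 0.1 * c(cos(104.5 * pi / 180), sin(104.5 * pi / 180))
        xyz <- matrix(0, nw * 3, 3)
        xyz[seq(1, 3 * nw, 3), ] <- cbind(blk$x, blk$y, blk$z)
        xyz[seq(2, 3 * nw, 3), ] <- cbind(blk$x + hx, blk$y, blk$z)
        xyz[seq(3, 3 * nw, 3), ] <- cbind(blk$x + h2[1], blk$y + h2[2], blk$z)
        df <- tibble(name = rep(c("OW", "HW1", "HW2"), nw), resname = "SOL",
                     resid = rep(blk$resid, each = 3), chain = "W",
                     class = "solvent")
      } else {
        xyz <- cbind(blk$x, blk$y, blk$z)
        df <- tibble(name = "OW", resname = "SOL", resid = blk$resid,
                     chain = "W", class = "solvent")
      }
      add(df, xyz)
    }

    if (!is.null(spec$peptide)) {
      pep <- spec$peptide
      n_res <- nrow(pep$residues)
      for (p in seq_len(pep$n_protomers)) {
        ctr_xy <- c(cell[1] * (0.3 + 0.4 * (p - 1) / max(1, pep$n_protomers - 1)),
                    cell[2] / 2)
        upper_surface <- mid + half
        ctr_z <- switch(pep$placement,
          surface_bound = upper_surface + 0.3 + pep$radius * 0.3,
          inserted = upper_surface - pep$depth,
          solution = mean(slab_hi_z)
        )
        # deterministic Fibonacci-sphere cluster
        k <- seq_len(n_res)
        phi <- acos(1 - 2 * (k - 0.5) / n_res)
        th <- pi * (1 + sqrt(5)) * k
        xyz <- cbind(
          (ctr_xy[1] + pep$radius * sin(phi) * cos(th)) %% cell[1],
          (ctr_xy[2] + pep$radius * sin(phi) * sin(th)) %% cell[2],
          ctr_z + pep$radius * cos(phi)
        )
        max_resid <- if (length(atoms)) max(purrr::map_int(atoms, ~max(.x$resid))) else 0L
        df <- tibble(name = "CA", resname = pep$residues$resname,
                     resid = max_resid + seq_len(n_res),
                     chain = LETTERS[p], class = pep$residues$class)
        add(df, xyz)
      }
    }

    top <- dplyr::bind_rows(atoms)
    top$atom <- seq_len(nrow(top))
    top$mass <- ifelse(top$name == "CA", 110, guess_mass(top$name))
    list(topology = topology(top), xyz = do.call(rbind, coords))
  }

  frames <- vector("list", spec$n_frames)
  top <- NULL
  for (i in seq_len(spec$n_frames)) {
    built <- build_frame(i)
    if (is.null(top)) top <- built$topology
    frames[[i]] <- md_frame((i - 1) * spec$dt, built$xyz, cell)
  }
  traj <- md_trajectory(top, frames)
  if (!is.null(spec$dilation)) {
    traj <- apply_dilation(traj, spec$dilation, conserve_volume = TRUE)
  }
  traj
}

#' Apply a lateral area-dilation schedule
#'
#' Emulates the geometric effect of an applied surface tension: lateral
#' coordinates and box edges are scaled per frame by `factors`; with
#' `conserve_volume = TRUE` the z coordinates and box height are scaled by
#' `1/factor^2`, the incompressible-hydrocarbon limit in which relative
#' thinning mirrors relative area growth.
#'
#' @param traj An [md_trajectory()].
#' @param factors Per-frame lateral scale factor (length = number of
#'   frames), all > 0. A factor `f` multiplies the leaflet area by `f^2`.
#' @param conserve_volume Scale z by `1/f^2` (default `TRUE`).
#' @return The dilated trajectory.
#' @export
apply_dilation <- function(traj, factors, conserve_volume = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(factors) != length(traj$frames)) {
    abort("dilation factor count must equal frame count")
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    abort("dilation factors must be positive")
  }
  frames <- purrr::map2(traj$frames, factors, function(f, fac) {
    xyz <- f$xyz
    xyz[, 1] <- xyz[, 1] * fac
    xyz[, 2] <- xyz[, 2] * fac
    zfac <- if (conserve_volume) 1 / fac^2 else 1
    xyz[, 3] <- xyz[, 3] * zfac
    md_frame(f$time, xyz,
             unit_cell(f$cell[1] * fac, f$cell[2] * fac, f$cell[3] * zfac))
  })
  md_trajectory(traj$topology, frames)
}
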