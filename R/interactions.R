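#' Count atom-pair contacts between two groups
#'
#' Per-frame number of atom pairs (one atom from each group) closer than
#' `cutoff` under the minimum-image convention. Pairs are counted
#' individually (every atom pair, not unique atoms); when the two groups
#' are identical each unordered pair is counted once and self-pairs are
#' excluded. Internally a periodic cell list is used when the box admits
#' one (>= 3 cells per dimension), falling back to all-pairs otherwise;
#' the result is identical to an exhaustive all-pairs scan either way.
#'
#' @param traj An [md_trajectory()].
#' @param group_a,group_b Non-empty atom index vectors.
#' @param cutoff Contact cutoff, nm (default 0.6, i.e. 6 angstroms).
#' @return A `contact_series`: tibble with `frame`, `time`, `count`.
#' @export
count_contacts <- function(traj, group_a, group_b, cutoff = 0.6) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (!length(group_a) || !length(group_b)) abort("empty contact group")
  if (cutoff <= 0) abort("cutoff must be > 0")
  same <- setequal(group_a, group_b)
  counts <- map_int(traj$frames, function(f) {
    count_contacts_frame(f$xyz, group_a, group_b, cutoff, f$cell, same)
  })
  out <- tibble(frame = seq_along(counts), time = frame_times(traj),
                count = counts)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_series", class(out))
  out
}

count_contacts_frame <- function(xyz, group_a, group_b, cutoff, cell, same) {
  n_cells <- pmax(1L, as.integer(floor(cell / cutoff)))
  if (any(n_cells < 3) || length(group_a) * length(group_b) < 1e4) {
    return(count_contacts_brute(xyz, group_a, group_b, cutoff, cell, same))
  }
  a_xyz <- wrap_coordinates(xyz[group_a, , drop = FALSE], cell)
  b_xyz <- wrap_coordinates(xyz[group_b, , drop = FALSE], cell)
  cell_of <- function(p) {
    ix <- pmin(floor(p[, 1] / cell[1] * n_cells[1]), n_cells[1] - 1)
    iy <- pmin(floor(p[, 2] / cell[2] * n_cells[2]), n_cells[2] - 1)
    iz <- pmin(floor(p[, 3] / cell[3] * n_cells[3]), n_cells[3] - 1)
    cbind(ix, iy, iz)
  }
  cid <- function(ijk) {
    ijk[, 1] + n_cells[1] * (ijk[, 2] + n_cells[2] * ijk[, 3])
  }
  b_cells <- cell_of(b_xyz)
  b_by_cell <- split(seq_along(group_b), cid(b_cells))
  a_cells <- cell_of(a_xyz)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  total <- 0L
  for (i in seq_along(group_a)) {
    neigh <- t((t(offsets) + a_cells[i, ]) %% n_cells)
    cand <- unlist(b_by_cell[as.character(unique(cid(neigh)))], use.names = FALSE)
    if (!length(cand)) next
    d <- min_image_distance(a_xyz[i, ], b_xyz[cand, , drop = FALSE], cell)
    if (same) {
      hits <- sum(d < cutoff & group_b[cand] != group_a[i])
    } else {
      hits <- sum(d < cutoff)
    }
    total <- total + hits
  }
  as.integer(if (same) total / 2 else total)
}

count_contacts_brute <- function(xyz, group_a, group_b, cutoff, cell, same) {
  a_xyz <- xyz[group_a, , drop = FALSE]
  b_xyz <- xyz[group_b, , drop = FALSE]
  total <- 0L
  for (i in seq_along(group_a)) {
    d <- min_image_distance(a_xyz[i, ], b_xyz, cell)
    if (same) {
      total <- total + sum(d < cutoff & group_b > group_a[i])
    } else {
      total <- total + sum(d < cutoff)
    }
  }
  as.integer(total)
}

#' Frame-averaged residue minimum-distance map
#'
#' Entry (i, j) is the frame average of the minimum atom-atom
#' minimum-image distance between residues i and j; the matrix is
#' symmetric with a zero diagonal. This is the map used to follow
#' inter-protomer hydrophobic contacts of a bound dimer.
#'
#' @param traj An [md_trajectory()].
#' @param residues A named list of non-empty atom index vectors, one per
#'   residue (names label the map rows), or `NULL` to partition the atoms
#'   in `selection` by topology residue.
#' @param selection Atom indices to partition when `residues` is `NULL`.
#' @return An object of class `distance_map`: list with `matrix`
#'   (n_res x n_res, nm) and `residues` (labels).
#' @export
min_distance_map <- function(traj, residues = NULL, selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(residues)) {
    if (is.null(selection)) abort("supply residues or selection")
    top <- traj$topology[selection, ]
    key <- paste(top$chain, top$resid, sep = ":")
    residues <- split(selection, factor(key, levels = unique(key)))
  }
  if (any(vapply(residues, length, integer(1)) == 0)) abort("empty residue group")
  nr <- length(residues)
  acc <- matrix(0, nr, nr)
  for (f in traj$frames) {
    m <- matrix(0, nr, nr)
    for (i in seq_len(nr - 1)) {
      xi <- f$xyz[residues[[i]], , drop = FALSE]
      for (j in (i + 1):nr) {
        xj <- f$xyz[residues[[j]], , drop = FALSE]
        dmin <- Inf
        for (k in seq_len(nrow(xi))) {
          dmin <- min(dmin, min(min_image_distance(xi[k, ], xj, f$cell)))
        }
        m[i, j] <- m[j, i] <- dmin
      }
    }
    acc <- acc + m
  }
  avg <- acc / length(traj$frames)
  labels <- names(residues) %||% as.character(seq_len(nr))
  dimnames(avg) <- list(labels, labels)
  structure(list(matrix = avg, residues = labels), class = "distance_map")
}

#' @rdname min_distance_map
#' @param x A `distance_map`.
#' @param ... Unused.
#' @method tidy distance_map
#' @export
tidy.distance_map <- function(x, ...) {
  nr <- length(x$residues)
  tibble(
    residue_i = rep(x$residues, times = nr),
    residue_j = rep(x$residues, each = nr),
    distance = as.vector(x$matrix)
  )
}

#' Geometric hydrogen-bond detection
#'
#' A donor-hydrogen-acceptor triple forms a hydrogen bond in a frame when
#' the donor-acceptor minimum-image distance is at most `d_max` and the
#' hydrogen-donor-acceptor angle is at most `angle_max` — the de facto
#' geometric convention (0.35 nm / 30 degrees) of standard trajectory
#' tools. Hydrogens are taken from an explicit `hydrogens` table or found
#' by convention: atoms in the donor's residue whose name starts with "H"
#' and which sit within 0.12 nm of the donor in the first frame. Donors
#' without any hydrogen are skipped with a warning.
#'
#' @param traj An [md_trajectory()].
#' @param donors Atom indices of donor heavy atoms.
#' @param acceptors Atom indices of acceptor atoms.
#' @param hydrogens Optional data frame with columns `donor`, `hydrogen`
#'   (atom indices).
#' @param d_max Donor-acceptor distance criterion, nm (default 0.35).
#' @param angle_max H-D-A angle criterion, degrees (default 30).
#' @return An object of class `hbond_map`: list with `bonds` (tibble:
#'   `donor`, `hydrogen`, `acceptor`, `first_frame`), `presence`
#'   (bonds x frames 0/1 matrix, rows ordered by first occurrence) and
#'   `criteria`.
#' @export
find_hbonds <- function(traj, donors, acceptors, hydrogens = NULL,
                        d_max = 0.35, angle_max = 30) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (!length(donors) || !length(acceptors)) abort("empty donor or acceptor selection")
  top <- traj$topology
  if (is.null(hydrogens)) {
    xyz1 <- traj$frames[[1]]$xyz
    cell1 <- traj$frames[[1]]$cell
    rows <- list()
    for (d in donors) {
      cand <- which(top$resid == top$resid[d] &
                    (is.na(top$chain) | is.na(top$chain[d]) |
                       top$chain == top$chain[d]) &
                    startsWith(top$name, "H"))
      cand <- setdiff(cand, d)
      if (length(cand)) {
        dist <- min_image_distance(xyz1[d, ], xyz1[cand, , drop = FALSE], cell1)
        cand <- cand[dist <= 0.12]
      }
      if (!length(cand)) {
        warn(sprintf("donor atom %d has no attached hydrogen; skipped", d))
        next
      }
      rows[[length(rows) + 1]] <- tibble(donor = d, hydrogen = cand)
    }
    if (!length(rows)) abort("no usable donor-hydrogen pairs")
    hydrogens <- bind_rows(rows)
  }
  hydrogens <- as_tibble(hydrogens)
  nf <- n_frames(traj)
  cos_min <- cos(angle_max * pi / 180)
  found <- list() # key -> presence vector
  order_seen <- character(0)
  for (fi in seq_len(nf)) {
    fr <- traj$frames[[fi]]
    for (r in seq_len(nrow(hydrogens))) {
      d <- hydrogens$donor[r]; hyd <- hydrogens$hydrogen[r]
      acc <- setdiff(acceptors, c(d, hyd))
      da <- min_image_displacement(fr$xyz[d, ], fr$xyz[acc, , drop = FALSE], fr$cell)
      dist <- sqrt(rowSums(da^2))
      ok <- dist <= d_max
      if (any(ok)) {
        dh <- min_image_displacement(fr$xyz[d, ], fr$xyz[hyd, , drop = FALSE], fr$cell)
        dh <- dh / sqrt(sum(dh^2))
        cosang <- (da[ok, , drop = FALSE] %*% t(dh)) / dist[ok]
        ok_idx <- which(ok)[cosang >= cos_min]
      } else {
        ok_idx <- integer(0)
      }
      for (ai in ok_idx) {
        key <- paste(d, hyd, acc[ai], sep = "-")
        if (is.null(found[[key]])) {
          found[[key]] <- logical(nf)
          order_seen <- c(order_seen, key)
        }
        found[[key]][fi] <- TRUE
      }
    }
  }
  if (!length(found)) {
    bonds <- tibble(donor = integer(0), hydrogen = integer(0),
                    acceptor = integer(0), first_frame = integer(0))
    presence <- matrix(0L, 0, nf)
  } else {
    parts <- do.call(rbind, strsplit(order_seen, "-"))
    presence <- do.call(rbind, lapply(order_seen, function(k) as.integer(found[[k]])))
    bonds <- tibble(donor = as.integer(parts[, 1]),
                    hydrogen = as.integer(parts[, 2]),
                    acceptor = as.integer(parts[, 3]),
                    first_frame = apply(presence, 1, function(p) which(p == 1)[1]))
  }
  structure(list(bonds = bonds, presence = presence,
                 criteria = list(d_max = d_max, angle_max = angle_max)),
            class = "hbond_map")
}

#' @rdname find_hbonds
#' @param x An `hbond_map`.
#' @param ... Unused.
#' @method tidy hbond_map
#' @export
tidy.hbond_map <- function(x, ...) {
  if (!nrow(x$bonds)) {
    return(tibble(bond = integer(0), donor = integer(0), hydrogen = integer(0),
                  acceptor = integer(0), frame = integer(0), present = logical(0)))
  }
  nf <- ncol(x$presence)
  dplyr::bind_cols(
    x$bonds[rep(seq_len(nrow(x$bonds)), each = nf),
            c("donor", "hydrogen", "acceptor")],
    tibble(bond = rep(seq_len(nrow(x$bonds)), each = nf),
           frame = rep(seq_len(nf), times = nrow(x$bonds)),
           present = as.logical(t(x$presence)))
  )
}

#' Centre-of-mass tracks
#'
#' Mass-weighted centre of mass of a selection per frame; with a second
#' selection, the minimum-image distance between the two centres of mass.
#'
#' @param traj An [md_trajectory()].
#' @param selection Non-empty atom indices.
#' @param selection2 Optional second selection for the COM-distance mode.
#' @return A tibble with `frame`, `time` and either `x`, `y`, `z` (COM,
#'   nm) or `distance` (nm).
#' @export
com_track <- function(traj, selection, selection2 = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  com_of <- function(f, sel) {
    m <- traj$topology$mass[sel]
    if (!length(sel) || sum(m) <= 0) abort("selection has zero total mass")
    colSums(f$xyz[sel, , drop = FALSE] * m) / sum(m)
  }
  rows <- purrr::imap(traj$frames, function(f, i) {
    c1 <- com_of(f, selection)
    if (is.null(selection2)) {
      tibble(frame = i, time = f$time, x = c1[1], y = c1[2], z = c1[3])
    } else {
      c2 <- com_of(f, selection2)
      tibble(frame = i, time = f$time,
             distance = min_image_distance(c1, c2, f$cell))
    }
  })
  bind_rows(rows)
}

#' Diffusion coefficient from mean-squared displacement
#'
#' Einstein-relation estimate: the MSD over all time origins is fitted by
#' least squares over a middle lag window (default 10--50% of the maximum
#' lag, avoiding both the short-time ballistic region and the noisy long
#' lags) and `D = slope / (2 n_dim)`, converted to cm^2/s. Requires
#' unwrapped coordinates: per-frame jumps larger than half a box edge are
#' treated as wrapping and raise an error. A log-log slope (`exponent`) of
#' the MSD is reported alongside; values far from 1 flag non-diffusive
#' (e.g. ballistic drift, exponent 2) motion.
#'
#' @param traj An [md_trajectory()] with unwrapped coordinates and at
#'   least 50 frames.
#' @param selection Non-empty atom indices; the MSD is averaged over them.
#' @param dimensionality 2 (lateral, xy) or 3.
#' @param fit_window Fraction range of the maximum lag to fit
#'   (default `c(0.1, 0.5)`).
#' @return An object of class `diffusion_estimate`: list with `d_cm2_s`,
#'   `dimensionality`, `slope_nm2_ps`, `exponent`, `non_diffusive`,
#'   `fit_window_ps` and the `msd` tibble (`lag_ps`, `msd_nm2`).
#' @export
msd_diffusion <- function(traj, selection, dimensionality = 3,
                          fit_window = c(0.1, 0.5)) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (!length(selection)) abort("empty selection")
  if (!dimensionality %in% c(2, 3)) abort("dimensionality must be 2 or 3")
  nf <- n_frames(traj)
  if (nf < 50) abort("need at least 50 frames for a diffusion estimate")
  dims <- seq_len(dimensionality)
  coords <- lapply(traj$frames, function(f) f$xyz[selection, dims, drop = FALSE])
  cell <- traj$frames[[1]]$cell
  for (i in 2:nf) {
    jump <- abs(coords[[i]] - coords[[i - 1]])
    if (any(jump > rep(cell[dims] / 2, each = nrow(jump)))) {
      abort("coordinates look wrapped (jump > L/2); unwrap before msd_diffusion")
    }
  }
  times <- frame_times(traj)
  arr <- simplify2array(coords) # atoms x dims x frames
  max_lag <- nf - 1
  msd <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    disp <- arr[, , (1 + lag):nf, drop = FALSE] - arr[, , 1:(nf - lag), drop = FALSE]
    msd[lag] <- mean(apply(disp^2, c(1, 3), sum))
  }
  dt <- times[2] - times[1]
  lag_ps <- seq_len(max_lag) * dt
  lo <- fit_window[1] * max(lag_ps); hi <- fit_window[2] * max(lag_ps)
  in_fit <- lag_ps >= lo & lag_ps <= hi
  if (sum(in_fit) < 3) abort("fit window contains fewer than 3 lags")
  fit <- lm(msd[in_fit] ~ lag_ps[in_fit])
  slope <- unname(coef(fit)[2]) # nm^2 / ps
  pos <- in_fit & msd > 0
  expo <- if (sum(pos) >= 3) {
    unname(coef(lm(log(msd[pos]) ~ log(lag_ps[pos])))[2])
  } else NA_real_
  d_cm2_s <- slope / (2 * dimensionality) * 1e-2 # nm^2/ps -> cm^2/s
  structure(list(
    d_cm2_s = max(d_cm2_s, 0), dimensionality = dimensionality,
    slope_nm2_ps = slope, exponent = expo,
    non_diffusive = is.finite(expo) && (expo > 1.5 || expo < 0.5),
    fit_window_ps = c(lo, hi),
    msd = tibble(lag_ps = lag_ps, msd_nm2 = msd)
  ), class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.3g cm^2/s (%d-D)%s\n",
              x$d_cm2_s, x$dimensionality,
              if (isTRUE(x$non_diffusive)) " [non-diffusive]" else ""))
  invisible(x)
}

#' @rdname msd_diffusion
#' @param x A `diffusion_estimate`.
#' @param ... Unused.
#' @method tidy diffusion_estimate
#' @export
tidy.diffusion_estimate <- function(x, ...) x$msd

#' @rdname msd_diffusion
#' @method glance diffusion_estimate
#' @export
glance.diffusion_estimate <- function(x, ...) {
  tibble(d_cm2_s = x$d_cm2_s, dimensionality = x$dimensionality,
         slope_nm2_ps = x$slope_nm2_ps, exponent = x$exponent,
         non_diffusive = x$non_diffusive)
}

#' Peptide charge bookkeeping
#'
#' Net charge of a peptide monomer from its ionisable-residue composition,
#' and the counterions needed to neutralise a peptide + anionic-lipid
#' system. Each LYS/ARG contributes +1; each GLU contributes -1 unless
#' protonated (low pH); a circular backbone has no free termini so they
#' contribute nothing (a linear peptide's zwitterionic termini also sum to
#' zero). For a 70-residue circular bacteriocin with 8 LYS, 2 ARG and
#' 4 GLU this gives +6 (neutral pH) or +10 (GLU protonated); with two
#' bound monomers on 128 anionic lipids, 116 or 108 monovalent cations
#' neutralise the box.
#'
#' @param n_lys,n_arg,n_glu Residue counts (>= 0).
#' @param glu_protonated Are the GLU residues protonated (uncharged)?
#' @param circular Head-to-tail cyclised backbone?
#' @return `charge_book()`: a `charge_book` list; `net_charge()`: integer
#'   monomer charge; `counterions_needed()`: integer count of monovalent
#'   counter-cations.
#' @examples
#' net_charge(charge_book(8, 2, 4)) # +6
#' net_charge(charge_book(8, 2, 4, glu_protonated = TRUE)) # +10
#' counterions_needed(128, 2, charge_book(8, 2, 4)) # 116
#' @export
charge_book <- function(n_lys, n_arg, n_glu, glu_protonated = FALSE,
                        circular = TRUE) {
  counts <- c(n_lys, n_arg, n_glu)
  if (any(counts < 0)) abort("residue counts must be >= 0")
  structure(list(n_lys = as.integer(n_lys), n_arg = as.integer(n_arg),
                 n_glu = as.integer(n_glu),
                 glu_protonated = isTRUE(glu_protonated),
                 circular = isTRUE(circular)),
            class = "charge_book")
}

#' @param book A [charge_book()].
#' @rdname charge_book
#' @export
net_charge <- function(book) {
  stopifnot(inherits(book, "charge_book"))
  glu_charge <- if (book$glu_protonated) 0L else book$n_glu
  book$n_lys + book$n_arg - glu_charge
}

#' @param n_anionic_lipids Number of monovalent anionic lipids.
#' @param n_peptides Number of peptide monomers.
#' @rdname charge_book
#' @export
counterions_needed <- function(n_anionic_lipids, n_peptides, book) {
  if (n_anionic_lipids < 0 || n_peptides < 0) abort("counts must be >= 0")
  as.integer(n_anionic_lipids - n_peptides * net_charge(book))
}
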