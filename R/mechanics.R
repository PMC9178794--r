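#' Hydrocarbon thickness from the P-to-P distance
#'
#' The hydrocarbon (acyl) region is 1.0 nm thinner than the P-to-P
#' distance: the phosphate plane sits about 0.5 nm above the hydrocarbon
#' boundary on each leaflet. A P-to-P distance of 3.1 nm thus corresponds
#' to a 2.1 nm hydrocarbon core.
#'
#' @param p2p P-to-P distance, nm; must exceed 1.0 nm.
#' @return Hydrocarbon thickness, nm.
#' @export
hydrocarbon_thickness <- function(p2p) {
  if (any(p2p <= 1.0)) abort("p2p must exceed 1.0 nm (non-physical otherwise)")
  p2p - 1.0
}

#' Fractional thinning of the hydrocarbon core
#'
#' Signed relative thickness change `-delta_h / h`: thinning (positive
#' `delta_h`) gives a negative ratio. Under hydrocarbon incompressibility
#' the relative thickness change mirrors the relative area change,
#' `dh/h ~ -dA/A`, which is how a measured thinning is converted into an
#' area strain and then a tension.
#'
#' @param delta_h Thickness decrement, nm (positive for thinning).
#' @param h Reference hydrocarbon thickness, nm (> 0).
#' @return Dimensionless signed ratio.
#' @examples
#' fractional_thinning(0.2, 2.1) # about -0.095, i.e. -0.1 at one decimal
#' @export
fractional_thinning <- function(delta_h, h) {
  if (any(h <= 0)) abort("h must be > 0")
  -delta_h / h
}

#' Tension--area elasticity
#'
#' Linear membrane elasticity `Gamma = K_A * dA/A`: the surface tension is
#' the area compressibility modulus times the relative area increment, and
#' conversely `dA/A = Gamma / K_A`. With `K_A = 200 mN/m`, tensions of 70
#' and 60 mN/m correspond to 35% and 30% area increments.
#'
#' @param rel_area_change Relative area increment `dA/A` (dimensionless).
#' @param gamma Surface tension, mN/m.
#' @param ka Area compressibility modulus, mN/m (> 0).
#' @return `tension_from_area()`: tension in mN/m;
#'   `area_from_tension()`: dimensionless `dA/A`. The two are exact
#'   inverses.
#' @export
tension_from_area <- function(rel_area_change, ka) {
  if (any(ka <= 0)) abort("ka must be > 0")
  ka * rel_area_change
}

#' @rdname tension_from_area
#' @export
area_from_tension <- function(gamma, ka) {
  if (any(ka <= 0)) abort("ka must be > 0")
  gamma / ka
}

#' Elastic state record
#'
#' Bundles the tension-elasticity symbols for reporting: tension, modulus,
#' relative area and thickness changes, P-to-P and hydrocarbon thickness.
#'
#' @param gamma Surface tension, mN/m.
#' @param ka Area compressibility modulus, mN/m (> 0).
#' @param rel_area_change `dA/A`.
#' @param p2p P-to-P distance, nm.
#' @param delta_h Hydrocarbon thickness decrement, nm.
#' @return A one-row tibble of class `elastic_state` with columns `gamma`,
#'   `ka`, `rel_area_change`, `rel_thickness_change`, `p2p`,
#'   `h_hydrocarbon`, `delta_h`.
#' @export
elastic_state <- function(gamma = NULL, ka = 200, rel_area_change = NULL,
                          p2p = 3.1, delta_h = 0) {
  if (ka <= 0) abort("ka must be > 0")
  h <- hydrocarbon_thickness(p2p)
  rel_dh <- fractional_thinning(delta_h, h)
  if (is.null(rel_area_change)) rel_area_change <- -rel_dh
  if (is.null(gamma)) gamma <- tension_from_area(rel_area_change, ka)
  out <- tibble(gamma = gamma, ka = ka, rel_area_change = rel_area_change,
                rel_thickness_change = rel_dh, p2p = p2p,
                h_hydrocarbon = h, delta_h = delta_h)
  class(out) <- c("elastic_state", class(out))
  out
}

#' Area compressibility modulus from area fluctuations
#'
#' Equilibrium fluctuation estimator `K_A = kB T <A> / var(A)` on a
#' stationary series of total bilayer areas, converted to mN/m. The
#' uncertainty is a contiguous-block bootstrap standard error, which
#' respects the serial correlation of the series.
#'
#' @param area_series Per-frame total bilayer area, nm^2 (>= 100 frames).
#' @param temperature Temperature, K.
#' @param n_blocks Number of contiguous blocks for the bootstrap
#'   (default 20).
#' @param n_boot Bootstrap replicates (default 200).
#' @return An object of class `ka_estimate`: list with `ka` (mN/m),
#'   `ka_se` (mN/m), `mean_area`, `var_area`, `temperature`, `n_frames`.
#' @export
estimate_ka <- function(area_series, temperature, n_blocks = 20, n_boot = 200) {
  a <- as.numeric(area_series)
  if (length(a) < 100) abort("need at least 100 frames for the fluctuation estimator")
  if (temperature <= 0) abort("temperature must be > 0")
  v <- var(a)
  if (v <= 0) abort("fluctuation estimator undefined: zero area variance")
  ka_of <- function(x) {
    # nm^2 / nm^4 -> 1/m^2 x 1e18; J/m^2 -> mN/m x 1e3
    .kB_J_per_K * temperature * mean(x) / var(x) * 1e18 * 1e3
  }
  blocks <- split(a, cut(seq_along(a), n_blocks, labels = FALSE))
  boots <- vapply(seq_len(n_boot), function(i) {
    ka_of(unlist(blocks[sample.int(n_blocks, n_blocks, replace = TRUE)],
                 use.names = FALSE))
  }, numeric(1))
  structure(list(ka = ka_of(a), ka_se = sd(boots), mean_area = mean(a),
                 var_area = v, temperature = temperature, n_frames = length(a)),
            class = "ka_estimate")
}

#' @export
print.ka_estimate <- function(x, ...) {
  cat(sprintf("<ka_estimate> K_A = %.1f +- %.1f mN/m (T = %g K, %d frames)\n",
              x$ka, x$ka_se, x$temperature, x$n_frames))
  invisible(x)
}

#' @rdname estimate_ka
#' @param x A `ka_estimate`.
#' @param ... Unused.
#' @method glance ka_estimate
#' @export
glance.ka_estimate <- function(x, ...) {
  tibble(ka = x$ka, ka_se = x$ka_se, mean_area = x$mean_area,
         var_area = x$var_area, temperature = x$temperature,
         n_frames = x$n_frames)
}

#' Water census over the bilayer-centre slab
#'
#' Counts, per frame, the selected water oxygens whose wrapped z lies in
#' the half-open slab `[z_min, z_max)` — the 0.5 nm bottleneck about the
#' bilayer centre whose occupancy sizes the pore. The half-open interval
#' and wrapped coordinates guarantee no double counting at the slab
#' boundaries.
#'
#' @param traj An [md_trajectory()].
#' @param slab Numeric `c(z_min, z_max)`, nm, `z_min < z_max`, inside the
#'   cell.
#' @param water Atom indices of water oxygens (e.g.
#'   `select_atoms(top, name = "OW")`); must be non-empty.
#' @return An object of class `census_series`: a tibble with `frame`,
#'   `time` (ps) and `count`, carrying the slab as an attribute.
#' @export
water_census <- function(traj, slab, water) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (!length(water)) abort("empty water selection")
  if (length(slab) != 2 || slab[1] >= slab[2]) abort("slab must be c(z_min, z_max)")
  counts <- map_int(traj$frames, function(f) {
    if (slab[1] < 0 || slab[2] > f$cell[3]) abort("slab must lie inside the cell")
    z <- f$xyz[water, 3] %% f$cell[3]
    sum(z >= slab[1] & z < slab[2])
  })
  out <- tibble(frame = seq_along(counts), time = frame_times(traj),
                count = counts)
  attr(out, "slab") <- slab
  class(out) <- c("census_series", class(out))
  out
}

#' @rdname water_census
#' @param counts Integer counts per frame.
#' @param times Frame times, ps.
#' @export
census_series <- function(counts, times = seq_along(counts) - 1,
                          slab = c(NA_real_, NA_real_)) {
  if (any(counts < 0)) abort("census counts must be >= 0")
  out <- tibble(frame = seq_along(counts), time = as.numeric(times),
                count = as.integer(counts))
  attr(out, "slab") <- slab
  class(out) <- c("census_series", class(out))
  out
}

#' Plateau statistics of a census series
#'
#' Finds the stable plateau a census series settles into. Rolling means
#' over `window` frames are compared pairwise (consecutive, non-overlapping
#' windows); a position is "stable" when the two window means differ by
#' less than 10% (relative to `max(|m1|, |m2|, 1)`, so an all-zero series
#' is stable). The plateau is the last maximal stable run — this skips
#' both an initial filling ramp and trailing pre-collapse blow-up — and the
#' onset is its first frame. If no stable run exists the mean is taken
#' over all frames with a warning and the onset is `NA`.
#'
#' @param series A `census_series` (or any tibble with `frame`, `time`,
#'   `count`).
#' @param window Window length in frames (default 10).
#' @return A list with `onset_frame`, `onset_time`, `end_frame` (last
#'   frame of the plateau run), `mean` and `sd`.
#' @export
plateau_stats <- function(series, window = 10) {
  n <- nrow(series)
  if (n <= window) abort("series must be longer than the window")
  x <- as.numeric(series$count)
  w <- as.integer(window)
  n_pos <- n - 2 * w + 1
  if (n_pos < 1) {
    warn("series shorter than two windows; using the whole series")
    return(list(onset_frame = NA_integer_, onset_time = NA_real_,
                end_frame = n, mean = mean(x), sd = sd(x)))
  }
  cs <- cumsum(c(0, x))
  wmean <- function(t) (cs[t + w] - cs[t]) / w # mean over frames [t, t+w)
  t_idx <- seq_len(n_pos)
  m1 <- wmean(t_idx)
  m2 <- wmean(t_idx + w)
  stable <- abs(m2 - m1) < 0.1 * pmax(abs(m1), abs(m2), 1)
  if (!any(stable)) {
    warn("census series never stabilises; plateau over all frames")
    return(list(onset_frame = NA_integer_, onset_time = NA_real_,
                end_frame = n, mean = mean(x), sd = sd(x)))
  }
  runs <- rle(stable)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  stable_runs <- which(runs$values)
  ri <- stable_runs[length(stable_runs)] # last maximal stable run
  onset <- starts[ri]
  run_end <- min(n, ends[ri] + 2 * w - 1) # frames covered by last stable pair
  vals <- x[onset:run_end]
  list(onset_frame = as.integer(onset),
       onset_time = series$time[onset],
       end_frame = as.integer(run_end),
       mean = mean(vals), sd = sd(vals))
}

#' Cylindrical pore sizing from a water count
#'
#' Converts a census count into a pore diameter under the cylindrical-pore
#' model: `NW` water molecules of mass `M = NW * M_w / N_A` occupy volume
#' `V = M / rho`; a cylinder of height `h_cyl` with that volume has
#' diameter `d = sqrt(4 V / (pi * h_cyl))`. Defaults assume bulk water
#' density (1 g/cm^3) and the 0.5 nm census-slab height. The unrounded
#' diameter is returned; report to one decimal (10 waters give 0.87 nm,
#' reported 0.9; 5 give 0.62 nm, reported 0.6). `d` grows as `sqrt(NW)`
#' and falls with `h_cyl` and `rho`.
#'
#' @param nw Number of water molecules in the slab (>= 0).
#' @param h_cyl Cylinder height, nm (default 0.5, the slab height).
#' @param rho Water density inside the pore, g/cm^3 (default 1.0).
#' @param m_w Water molecular weight, g/mol (default 18.015).
#' @return `pore_diameter()`: diameter in nm (vectorised over `nw`).
#'   `pore_cylinder()`: a one-row tibble with the full record: `nw`,
#'   `h_cyl`, `rho`, `m_w`, `mass_g`, `volume_cm3`, `diameter_nm` and
#'   `diameter_reported` (one decimal).
#' @examples
#' pore_diameter(10) # 0.873 nm
#' round(pore_diameter(c(10, 5)), 1) # 0.9, 0.6
#' @export
pore_diameter <- function(nw, h_cyl = 0.5, rho = 1.0, m_w = .M_water) {
  if (any(nw < 0)) abort("nw must be >= 0")
  if (h_cyl <= 0 || rho <= 0) abort("h_cyl and rho must be > 0")
  v_cm3 <- nw * m_w / (rho * .N_avogadro)
  v_nm3 <- v_cm3 * 1e21
  sqrt(4 * v_nm3 / (pi * h_cyl))
}

#' @rdname pore_diameter
#' @export
pore_cylinder <- function(nw, h_cyl = 0.5, rho = 1.0, m_w = .M_water) {
  d <- pore_diameter(nw, h_cyl, rho, m_w)
  tibble(nw = nw, h_cyl = h_cyl, rho = rho, m_w = m_w,
         mass_g = nw * m_w / .N_avogadro,
         volume_cm3 = nw * m_w / (rho * .N_avogadro),
         diameter_nm = d, diameter_reported = round(d, 1))
}

#' Detect bilayer disruption in a census series
#'
#' Membrane collapse announces itself as an abrupt, sustained rise of the
#' slab water count above its plateau. The rule: the first time the count
#' exceeds `plateau_mean + k_sd * max(plateau_sd, 1)` for `persistence`
#' consecutive frames. Both knobs are heuristic conventions (the underlying
#' event is qualitative) and are exposed as arguments.
#'
#' @param series A `census_series`.
#' @param k_sd Threshold multiplier (default 5).
#' @param persistence Frames the excursion must persist (default 5).
#' @param window Plateau window passed to [plateau_stats()].
#' @param plateau Optional precomputed [plateau_stats()] result.
#' @return Disruption time in ps, or `NA` if never detected.
#' @export
detect_disruption <- function(series, k_sd = 5, persistence = 5, window = 10,
                              plateau = NULL) {
  plateau <- plateau %||% plateau_stats(series, window = window)
  psd <- if (is.na(plateau$sd)) 0 else plateau$sd
  threshold <- plateau$mean + k_sd * max(psd, 1)
  start <- if (is.na(plateau$onset_frame)) 1L else plateau$onset_frame
  above <- series$count > threshold & series$frame >= start
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= persistence)
  if (!length(hit)) return(NA_real_)
  series$time[starts[hit[1]]]
}

#' Annotate a census series with plateau and disruption calls
#'
#' Convenience wrapper: plateau statistics, disruption detection, then the
#' plateau mean/sd recomputed over `[onset, disruption)` when a disruption
#' is found (the pre-collapse occupancy is the physically meaningful
#' plateau).
#'
#' @inheritParams detect_disruption
#' @return A list with `plateau_onset` (ps), `plateau_mean`, `plateau_sd`,
#'   `disruption_time` (ps or `NA`), `pore_diameter_nm` (from the plateau
#'   mean via [pore_diameter()]).
#' @export
census_annotate <- function(series, k_sd = 5, persistence = 5, window = 10) {
  pl <- plateau_stats(series, window = window)
  dt <- detect_disruption(series, k_sd = k_sd, persistence = persistence,
                          window = window, plateau = pl)
  if (!is.na(dt) && !is.na(pl$onset_frame)) {
    keep <- series$frame >= pl$onset_frame & series$time < dt
    if (sum(keep) >= 2) {
      pl$mean <- mean(series$count[keep])
      pl$sd <- sd(series$count[keep])
    }
  }
  list(plateau_onset = pl$onset_time, plateau_mean = pl$mean,
       plateau_sd = pl$sd, disruption_time = dt,
       pore_diameter_nm = pore_diameter(pl$mean))
}

#' @rdname water_census
#' @param x A `census_series`.
#' @param ... Unused.
#' @method glance census_series
#' @export
glance.census_series <- function(x, ...) {
  ann <- census_annotate(x)
  tibble(n_frames = nrow(x), plateau_onset = ann$plateau_onset,
         plateau_mean = ann$plateau_mean, plateau_sd = ann$plateau_sd,
         disruption_time = ann$disruption_time,
         pore_diameter_nm = ann$pore_diameter_nm)
}
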