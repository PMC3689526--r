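#' Uniform random crystal orientations
#'
#' Rotation matrices drawn from the Haar (uniform) measure on SO(3) via
#' normalised Gaussian quaternions, using R's RNG stream (seed with
#' [set.seed()]).
#'
#' @param n number of rotations.
#' @return a 3x3 matrix for `n = 1`, else a list of matrices.
#' @export
random_orientation <- function(n = 1) {
  one <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
             2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
             2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
  }
  if (n == 1) one() else replicate(n, one(), simplify = FALSE)
}

#' Excitation errors against the limiting Ewald spheres
#'
#' For each reciprocal point, the signed distances `r_low` and `r_high` to
#' the two limiting Ewald spheres of a flat-top spectrum with a convergent
#' beam. `r_low` uses the shortest wavelength with the sphere centre tilted
#' (by half the convergence angle, about the origin, in the plane of the beam
#' axis and the point's azimuth) towards the point; `r_high` uses the longest
#' wavelength tilted away. Positive values mean the point lies inside that
#' sphere.
#'
#' @param q matrix or data frame of reciprocal vectors (1/angstrom).
#' @param beam an [beam_parameters()].
#' @return tibble with columns `r_low`, `r_high` (1/angstrom).
#' @export
excitation_errors <- function(q, beam) {
  q <- as.matrix(as.data.frame(q)[, 1:3])
  e <- excitation_cpp(q, beam$wavelength, beam$bandwidth, beam$convergence)
  tibble::tibble(r_low = e[, 1], r_high = e[, 2])
}

#' Reflection partiality from the spherical-profile model
#'
#' The reflection profile is a sphere of radius `profile_r`; the excited
#' region is the slab between the limiting Ewald spheres. The partiality is
#' the fraction of the sphere's volume inside the slab, computed as a
#' difference of spherical-cap volume fractions: with
#' `u_i = clamp((r_i + R) / (2R), 0, 1)` and `f(u) = 3u^2 - 2u^3`,
#' `p = f(u_low) - f(u_high)`.
#'
#' @param r_low,r_high excitation errors (1/angstrom), `r_low >= r_high`.
#' @param profile_r profile radius R (1/angstrom).
#' @return partialities in \[0, 1\].
#' @export
partiality_fraction <- function(r_low, r_high, profile_r) {
  stopifnot(profile_r > 0)
  if (any(r_low < r_high - 1e-12 * profile_r))
    stop("r_low < r_high: excitation pair out of order", call. = FALSE)
  f <- function(u) {
    u <- pmin(1, pmax(0, u))
    u^2 * (3 - 2 * u)
  }
  f((r_low + profile_r) / (2 * profile_r)) -
    f((r_high + profile_r) / (2 * profile_r))
}

#' Lorentz factor for a still exposure
#'
#' Proportional to the excited slab thickness `r_low - r_high`, which grows
#' with scattering angle as the limiting Ewald spheres separate; the
#' proportionality constant is fixed by `L = 1` when the slab exactly spans
#' the profile diameter (it cancels in any scale-invariant statistic such as
#' R_split).
#'
#' @inheritParams partiality_fraction
#' @return Lorentz factors (>= 0).
#' @export
lorentz_factor <- function(r_low, r_high, profile_r) {
  stopifnot(profile_r > 0)
  (r_low - r_high) / (2 * profile_r)
}

# all Miller indices (excluding 0,0,0) inside the resolution sphere 1/d_min,
# plus their reciprocal-space positions in the reference orientation
enumerate_hkl <- function(cell, d_min) {
  B <- reciprocal_basis(cell)
  qmax <- 1 / d_min
  lens <- cell_lengths(cell)
  hmax <- floor(lens * qmax) + 1
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                                k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  q <- grid %*% t(B)
  keep <- rowSums(q^2) <= qmax^2 & rowSums(abs(grid)) > 0
  list(hkl = grid[keep, , drop = FALSE], q0 = q[keep, , drop = FALSE])
}

#' Synthetic fully-integrated intensities
#'
#' A Wilson-like synthetic intensity model standing in for structure factors
#' computed from an atomic model: intensities are exponentially distributed
#' with a resolution-dependent mean that falls from `mean_low` for the
#' lowest-order reflections to `mean_high` in the highest-resolution shell at
#' `d_min`. The defaults (500 and 100 detector units) calibrate the model so
#' an additive noise SD of 10 equals 2% of the low-order mean and 10% of the
#' corner-shell mean. Intensities respect the symmetry given by `pg` (one
#' draw per unique reflection) and Friedel symmetry.
#'
#' @param cell an [unit_cell()].
#' @param d_min resolution limit in angstroms.
#' @param pg point group of the synthetic crystal (name or
#'   [point_group()]; default `"1"`).
#' @param mean_low,mean_high shell-mean calibration (detector units).
#' @return tibble of unique reflections: `h`, `k`, `l`, `s` (1/d, 1/angstrom),
#'   `I`.
#' @export
synthetic_intensities <- function(cell, d_min, pg = "1",
                                  mean_low = 500, mean_high = 100) {
  if (is.character(pg)) pg <- point_group(pg)
  en <- enumerate_hkl(cell, d_min)
  can <- canonical_hkl(en$hkl[, 1], en$hkl[, 2], en$hkl[, 3], pg, friedel = TRUE)
  uniq <- !duplicated(can)
  hkl <- can[uniq, , drop = FALSE]
  s <- sqrt(rowSums((hkl %*% t(reciprocal_basis(cell)))^2))
  b <- log(mean_low / mean_high) / (1 / d_min)^2
  mu <- mean_low * exp(-b * s^2)
  tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3], s = s,
                 I = stats::rexp(length(mu), rate = 1 / mu))
}

#' Default configuration of the partiality simulation
#'
#' The reference simulation conditions: a proteinase-K-like tetragonal
#' crystal (point group 422, a = b = 68.17, c = 108.26 angstrom), a square
#' 76.8 mm detector at 70 mm camera length (2.8 angstrom resolution at the
#' edge, 2.1 at the corner) with the beam at its centre, wavelength 1.3776
#' angstrom, spherical profile radius 3e-4 1/angstrom, per-pattern Gaussian
#' scale factors (mean 1, SD 0.3) and additive Gaussian intensity noise
#' (SD 10 detector units, i.e. 2% of the low-order shell mean and 10% of the
#' corner-shell mean of the synthetic intensities).
#'
#' @param bandwidth fractional spectral width (default 0.001).
#' @param convergence full convergence angle in rad (default 0.001).
#' @return list with `cell`, `geom`, `beam`, `profile_r`, `scale_sd`,
#'   `noise_sd`, `point_group`, `d_min`.
#' @export
sim_config <- function(bandwidth = 0.001, convergence = 0.001) {
  geom <- detector_geometry(768, 768, pixel_size = 0.1, camera_length = 70)
  beam <- beam_parameters(9000, bandwidth = bandwidth, convergence = convergence)
  list(cell = unit_cell(68.17, 68.17, 108.26, lattice_type = "tetragonal"),
       geom = geom, beam = beam,
       profile_r = 3e-4, scale_sd = 0.3, noise_sd = 10,
       point_group = "422",
       d_min = detector_corner_resolution(geom, beam$wavelength))
}

# precompute lattice points, unique-reflection ids and full intensities for
# the simulation engine (draws intensities: caller controls the RNG seed)
partiality_setup <- function(config = sim_config(), intensities = NULL) {
  en <- enumerate_hkl(config$cell, config$d_min)
  pg <- point_group(config$point_group)
  can <- canonical_hkl(en$hkl[, 1], en$hkl[, 2], en$hkl[, 3], pg, friedel = TRUE)
  key <- paste(can[, 1], can[, 2], can[, 3])
  if (is.null(intensities))
    intensities <- synthetic_intensities(config$cell, config$d_min,
                                         pg = config$point_group)
  ikey <- paste(intensities$h, intensities$k, intensities$l)
  idx <- match(key, ikey)
  keep <- !is.na(idx)
  asu <- match(key[keep], unique(key[keep]))
  list(hkl = en$hkl[keep, , drop = FALSE],
       q0 = en$q0[keep, , drop = FALSE],
       asu = as.integer(asu),
       I_full = intensities$I[idx[keep]],
       intensities = intensities,
       config = config)
}

detector_half_side <- function(geom) {
  p <- geom$panels[[1]]
  p$n_fast * p$pixel_size / 2
}

#' Simulate the partial reflections of one still pattern
#'
#' For every reciprocal-lattice point inside the detector resolution sphere:
#' rotate into the given orientation, compute the excitation pair,
#' partiality and Lorentz factor, and keep reflections with `p > 0` whose
#' predicted position falls on the detector. The recorded intensity is
#' `I = scale * (p / Lambda) * I_full + N(0, noise_sd)` where
#' `Lambda = (r_low - r_high) / (2R)` is the Lorentz (slab-to-profile
#' thickness) factor: a flat-top spectrum spreads the fixed pulse energy over
#' the excited slab, so thicker slabs dilute the flux reaching each
#' reflection's profile and the partiality enters per unit slab thickness.
#'
#' @param orientation 3x3 rotation matrix (e.g. [random_orientation()]).
#' @param config simulation configuration from [sim_config()].
#' @param intensities unique-reflection intensities
#'   ([synthetic_intensities()]); drawn fresh when `NULL`.
#' @param scale pattern scale factor (default 1).
#' @param noise_sd additive intensity noise SD (default 0: noise-free).
#' @param setup optional precomputed [partiality_setup()] (overrides
#'   `config`/`intensities`); use when simulating many patterns.
#' @return tibble: `h`, `k`, `l`, `r_low`, `r_high`, `p`, `lorentz`,
#'   `I_full`, `I_partial`, `fast`, `slow`.
#' @export
simulate_pattern <- function(orientation, config = sim_config(),
                             intensities = NULL, scale = 1, noise_sd = 0,
                             setup = NULL) {
  if (is.null(setup)) setup <- partiality_setup(config, intensities)
  cfg <- setup$config
  obs <- pattern_obs_cpp(setup$q0, orientation,
                         cfg$beam$wavelength, cfg$beam$bandwidth,
                         cfg$beam$convergence, cfg$profile_r,
                         cfg$geom$camera_length, detector_half_side(cfg$geom))
  keep <- obs[, "on_detector"] == 1
  obs <- obs[keep, , drop = FALSE]
  i <- as.integer(obs[, "index"])
  pan <- cfg$geom$panels[[1]]
  ifull <- setup$I_full[i]
  ipart <- scale * obs[, "weight"] * ifull
  if (noise_sd > 0) ipart <- ipart + stats::rnorm(length(ipart), 0, noise_sd)
  tibble::tibble(h = setup$hkl[i, 1], k = setup$hkl[i, 2], l = setup$hkl[i, 3],
                 r_low = obs[, "r_low"], r_high = obs[, "r_high"],
                 p = obs[, "p"], lorentz = obs[, "lorentz"],
                 I_full = ifull, I_partial = ipart,
                 fast = (obs[, "x_mm"] - pan$origin[1]) / pan$pixel_size,
                 slow = (obs[, "y_mm"] - pan$origin[2]) / pan$pixel_size)
}

#' R_split convergence of Monte-Carlo merging
#'
#' Simulates `max(n_patterns_grid)` still patterns per condition (random
#' orientations, per-pattern Gaussian scales, additive intensity noise),
#' merges the odd- and even-numbered patterns separately under the
#' configured point group, and reports R_split at every pattern count in
#' `n_patterns_grid`. Conditions are the cross product of
#' `bandwidth_grid` and `convergence_grid`; all other parameters come from
#' `config`.
#'
#' @param n_patterns_grid increasing pattern counts at which to evaluate
#'   R_split.
#' @param bandwidth_grid fractional bandwidths (default 0.001).
#' @param convergence_grid full convergence angles in rad (default 0.001).
#' @param config base configuration ([sim_config()]); its bandwidth and
#'   convergence are overridden per condition.
#' @param intensities optional fixed unique-reflection intensities shared by
#'   all conditions (drawn once internally when `NULL`).
#' @return tibble of class `sfx_rsplit_curve`: `bandwidth`, `convergence`,
#'   `n_patterns`, `r_split` (fraction), `n_common`, `mean_obs_per_pattern`.
#' @export
convergence_experiment <- function(n_patterns_grid,
                                   bandwidth_grid = 0.001,
                                   convergence_grid = 0.001,
                                   config = sim_config(),
                                   intensities = NULL) {
  stopifnot(length(n_patterns_grid) >= 1)
  n_patterns_grid <- sort(unique(as.integer(n_patterns_grid)))
  if (is.null(intensities))
    intensities <- synthetic_intensities(config$cell, config$d_min,
                                         pg = config$point_group)
  conds <- expand.grid(bandwidth = bandwidth_grid,
                       convergence = convergence_grid)
  out <- vector("list", nrow(conds))
  for (ci in seq_len(nrow(conds))) {
    cfg <- config
    cfg$beam <- beam_parameters(config$beam$photon_energy,
                                bandwidth = conds$bandwidth[ci],
                                convergence = conds$convergence[ci])
    setup <- partiality_setup(cfg, intensities)
    res <- rsplit_engine_cpp(setup$q0, setup$asu, setup$I_full,
                             cfg$beam$wavelength, cfg$beam$bandwidth,
                             cfg$beam$convergence, cfg$profile_r,
                             cfg$geom$camera_length,
                             detector_half_side(cfg$geom),
                             cfg$scale_sd, cfg$noise_sd,
                             max(n_patterns_grid), n_patterns_grid)
    out[[ci]] <- tibble::tibble(bandwidth = conds$bandwidth[ci],
                                convergence = conds$convergence[ci],
                                n_patterns = res$n_patterns,
                                r_split = res$r_split,
                                n_common = res$n_common,
                                mean_obs_per_pattern = res$mean_obs_per_pattern)
  }
  out <- dplyr::bind_rows(out)
  class(out) <- c("sfx_rsplit_curve", class(out))
  out
}

#' Pattern count at which an R_split curve crosses a level
#'
#' Log-log interpolation between the bracketing grid points of a (noisy but
#' essentially monotone) R_split-versus-n curve.
#'
#' @param curve tibble with `n_patterns` and `r_split` for a single
#'   condition.
#' @param level target R_split (fraction).
#' @return interpolated pattern count (`NA` if the curve never crosses).
#' @export
rsplit_crossing <- function(curve, level) {
  curve <- curve[order(curve$n_patterns), ]
  r <- curve$r_split; n <- curve$n_patterns
  below <- which(r <= level)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(as.numeric(n[1]))
  exp(stats::approx(x = log(c(r[i - 1], r[i])),
                    y = log(c(n[i - 1], n[i])),
                    xout = log(level))$y)
}
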