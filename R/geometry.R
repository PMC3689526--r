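#' Detector geometry
#'
#' Describes a flat detector normal to the beam in a right-handed lab frame
#' with the beam along +z. Pixel indices are 0-based with pixel centres at
#' integer coordinates; `fast` indexes along the panel fast axis (+x by
#' default) and `slow` along the slow axis (+y). The geometry is stored as a
#' list of panels so segment-wise corrections and tiled detectors stay
#' representable, but a single panel is the default and the only layout the
#' pipeline constructs itself.
#'
#' @param n_fast,n_slow pixel counts along the fast and slow axes.
#' @param pixel_size pixel edge length in mm (square pixels).
#' @param camera_length sample-to-detector distance in mm.
#' @param beam_centre position of the direct beam in (fast, slow) pixels;
#'   defaults to the detector centre.
#' @param central_hole optional rectangular mask for the direct-beam hole,
#'   as `c(fast_min, fast_max, slow_min, slow_max)` in pixels.
#' @return An object of class `sfx_geometry`.
#' @examples
#' geom <- detector_geometry(768, 768, pixel_size = 0.1, camera_length = 70)
#' @export
detector_geometry <- function(n_fast, n_slow, pixel_size, camera_length,
                              beam_centre = NULL, central_hole = NULL) {
  stopifnot(pixel_size > 0, camera_length > 0, n_fast >= 1, n_slow >= 1)
  if (is.null(beam_centre)) beam_centre <- c((n_fast - 1) / 2, (n_slow - 1) / 2)
  stopifnot(length(beam_centre) == 2)
  fast_axis <- c(1, 0, 0)
  slow_axis <- c(0, 1, 0)
  origin <- c(-beam_centre[1] * pixel_size, -beam_centre[2] * pixel_size,
              camera_length)
  structure(list(
    panels = list(list(origin = origin, fast_axis = fast_axis,
                       slow_axis = slow_axis, n_fast = as.integer(n_fast),
                       n_slow = as.integer(n_slow), pixel_size = pixel_size)),
    camera_length = camera_length,
    beam_centre = as.numeric(beam_centre),
    central_hole = central_hole
  ), class = "sfx_geometry")
}

#' @export
print.sfx_geometry <- function(x, ...) {
  p <- x$panels[[1]]
  cat(sprintf("<sfx_geometry> %d x %d px, %.4g mm/px, camera length %.4g mm\n",
              p$n_fast, p$n_slow, p$pixel_size, x$camera_length))
  cat(sprintf("  beam centre (%.2f, %.2f) px\n", x$beam_centre[1], x$beam_centre[2]))
  invisible(x)
}

#' Beam parameters
#'
#' X-ray beam description for still-pattern simulation and prediction. The
#' spectrum is modelled as a flat (rectangular) distribution of fractional
#' full width `bandwidth` centred on the nominal wavelength, and the beam may
#' converge with full angle `convergence`.
#'
#' @param photon_energy photon energy in eV; the wavelength is
#'   `12398.42 / photon_energy` angstroms.
#' @param bandwidth fractional full spectral width (dimensionless, in \[0, 1)).
#' @param convergence full beam-convergence angle in radians.
#' @return An object of class `sfx_beam` with fields `photon_energy`,
#'   `wavelength`, `bandwidth`, `convergence`.
#' @export
beam_parameters <- function(photon_energy, bandwidth = 0, convergence = 0) {
  stopifnot(photon_energy > 0, bandwidth >= 0, bandwidth < 1, convergence >= 0)
  structure(list(photon_energy = photon_energy,
                 wavelength = 12398.42 / photon_energy,
                 bandwidth = bandwidth,
                 convergence = convergence), class = "sfx_beam")
}

#' @export
print.sfx_beam <- function(x, ...) {
  cat(sprintf("<sfx_beam> %.1f eV (%.4f A), bandwidth %.3g, convergence %.3g rad\n",
              x$photon_energy, x$wavelength, x$bandwidth, x$convergence))
  invisible(x)
}

pixel_lab_position <- function(geom, fast, slow) {
  p <- geom$panels[[1]]
  cbind(p$origin[1] + fast * p$pixel_size * p$fast_axis[1],
        p$origin[2] + slow * p$pixel_size * p$slow_axis[2],
        p$origin[3])
}

check_pixel_bounds <- function(geom, fast, slow) {
  p <- geom$panels[[1]]
  # continuous pixel coordinates: the active area spans the physical pixel
  # extent, half a pixel beyond the outermost pixel centres
  bad <- fast < -0.5 | fast > p$n_fast - 0.5 | slow < -0.5 | slow > p$n_slow - 0.5
  if (any(bad)) {
    stop(sprintf("pixel coordinates outside panel bounds: (%s, %s)",
                 paste(signif(fast[bad][1], 6)), paste(signif(slow[bad][1], 6))),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Map a detector pixel to reciprocal space
#'
#' Maps pixel coordinates onto the Ewald sphere: with `s_hat` the unit vector
#' from the interaction point to the pixel and `z_hat` the beam direction,
#' `q = (s_hat - z_hat) / lambda`, so that `|q| = 2 sin(theta) / lambda` and
#' every mapped point satisfies `|q + z_hat/lambda| = 1/lambda`.
#'
#' @param geom an [detector_geometry()] object.
#' @param wavelength wavelength in angstroms.
#' @param fast,slow pixel coordinates (vectors allowed, 0-based).
#' @return A tibble with columns `qx`, `qy`, `qz` (1/angstrom).
#' @export
map_pixel_to_reciprocal <- function(geom, wavelength, fast, slow) {
  stopifnot(wavelength > 0)
  check_pixel_bounds(geom, fast, slow)
  pos <- pixel_lab_position(geom, fast, slow)
  nrm <- sqrt(rowSums(pos^2))
  tibble::tibble(qx = pos[, 1] / (nrm * wavelength),
                 qy = pos[, 2] / (nrm * wavelength),
                 qz = (pos[, 3] / nrm - 1) / wavelength)
}

#' Resolution (d-spacing) at a detector pixel
#'
#' @inheritParams map_pixel_to_reciprocal
#' @return d-spacings in angstroms (`Inf` at the beam centre).
#' @export
resolution_at_pixel <- function(geom, wavelength, fast, slow) {
  q <- map_pixel_to_reciprocal(geom, wavelength, fast, slow)
  qn <- sqrt(q$qx^2 + q$qy^2 + q$qz^2)
  ifelse(qn == 0, Inf, 1 / qn)
}

#' Highest resolution recorded by the detector (its corner)
#'
#' @inheritParams map_pixel_to_reciprocal
#' @return d-spacing in angstroms at the most extreme pixel corner distance.
#' @export
detector_corner_resolution <- function(geom, wavelength) {
  p <- geom$panels[[1]]
  corners_f <- c(0, 0, p$n_fast - 1, p$n_fast - 1)
  corners_s <- c(0, p$n_slow - 1, 0, p$n_slow - 1)
  min(resolution_at_pixel(geom, wavelength, corners_f, corners_s))
}

#' Predict the detector position of a reciprocal-space point
#'
#' Intersects the scattered ray `s ~ q + z_hat/lambda` with the detector
#' plane. Points whose ray does not reach the active region (outside the
#' panel, inside the central hole, or travelling away from the detector) are
#' reported off-detector.
#'
#' @param q matrix or data frame of reciprocal vectors (columns qx, qy, qz,
#'   1/angstrom).
#' @param geom an [detector_geometry()] object.
#' @param wavelength wavelength in angstroms.
#' @return A tibble with columns `panel`, `fast`, `slow`, `on_detector`.
#'   `fast`/`slow` are `NA` when the ray cannot intersect the plane.
#' @export
predict_spot_position <- function(q, geom, wavelength) {
  q <- as.matrix(as.data.frame(q)[, 1:3])
  p <- geom$panels[[1]]
  sz <- q[, 3] + 1 / wavelength
  ok <- sz > 1e-12
  x <- ifelse(ok, q[, 1] * geom$camera_length / sz, NA_real_)
  y <- ifelse(ok, q[, 2] * geom$camera_length / sz, NA_real_)
  fast <- (x - p$origin[1]) / p$pixel_size
  slow <- (y - p$origin[2]) / p$pixel_size
  on <- ok & !is.na(fast) &
    fast >= -0.5 & fast <= p$n_fast - 0.5 &
    slow >= -0.5 & slow <= p$n_slow - 0.5
  if (!is.null(geom$central_hole)) {
    h <- geom$central_hole
    in_hole <- fast >= h[1] & fast <= h[2] & slow >= h[3] & slow <= h[4]
    on <- on & !(ifelse(is.na(in_hole), FALSE, in_hole))
  }
  tibble::tibble(panel = 1L, fast = fast, slow = slow,
                 on_detector = ifelse(is.na(on), FALSE, on))
}

#' Read / write a geometry configuration file
#'
#' Flat `key = value` text format holding the panel layout, camera length,
#' beam centre and optional central hole. The same description is echoed into
#' the headers of downstream output files.
#'
#' @param path file path.
#' @return `read_geometry()` returns an `sfx_geometry`; `write_geometry()`
#'   returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed geometry line: ", lines[bad][1], call. = FALSE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  need <- c("n_fast", "n_slow", "pixel_size_mm", "camera_length_mm")
  miss <- setdiff(need, names(vals))
  if (length(miss)) stop("geometry file missing keys: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  num <- function(k) as.numeric(vals[[k]])
  bc <- if (all(c("beam_centre_fast_px", "beam_centre_slow_px") %in% names(vals)))
    c(num("beam_centre_fast_px"), num("beam_centre_slow_px")) else NULL
  hole <- if (all(paste0("hole_", c("fast_min", "fast_max", "slow_min", "slow_max")) %in%
                  names(vals)))
    c(num("hole_fast_min"), num("hole_fast_max"),
      num("hole_slow_min"), num("hole_slow_max")) else NULL
  detector_geometry(num("n_fast"), num("n_slow"), num("pixel_size_mm"),
                    num("camera_length_mm"), beam_centre = bc, central_hole = hole)
}

#' @param geom geometry to write.
#' @rdname read_geometry
#' @export
write_geometry <- function(geom, path) {
  p <- geom$panels[[1]]
  lines <- c(
    sprintf("n_fast = %d", p$n_fast),
    sprintf("n_slow = %d", p$n_slow),
    sprintf("pixel_size_mm = %.10g", p$pixel_size),
    sprintf("camera_length_mm = %.10g", geom$camera_length),
    sprintf("beam_centre_fast_px = %.10g", geom$beam_centre[1]),
    sprintf("beam_centre_slow_px = %.10g", geom$beam_centre[2]))
  if (!is.null(geom$central_hole)) {
    h <- geom$central_hole
    lines <- c(lines,
               sprintf("hole_fast_min = %.10g", h[1]),
               sprintf("hole_fast_max = %.10g", h[2]),
               sprintf("hole_slow_min = %.10g", h[3]),
               sprintf("hole_slow_max = %.10g", h[4]))
  }
  writeLines(lines, path)
  invisible(path)
}

geometry_header_lines <- function(geom) {
  p <- geom$panels[[1]]
  sprintf("geometry: %dx%d px, %.6g mm/px, clen %.6g mm, beam (%.4g, %.4g) px",
          p$n_fast, p$n_slow, p$pixel_size, geom$camera_length,
          geom$beam_centre[1], geom$beam_centre[2])
}
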