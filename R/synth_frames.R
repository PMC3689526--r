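#' Synthetic background frame
#'
#' A smooth radial water-ring bump over a flat base level, Poisson-sampled:
#' `b(r) = base + amplitude * exp(-(r - radius)^2 / (2 width^2))` with `r`
#' the pixel distance from the beam centre. Emulates the dominant nuisance
#' of liquid-jet data (broad solvent ring plus shot noise); it does not model
#' coherent speckle.
#'
#' @param geom an [detector_geometry()].
#' @param water_ring list with `radius`, `width` (pixels) and `amplitude`
#'   (detector units).
#' @param base flat base level (detector units).
#' @param poisson sample the result from a Poisson distribution? (default
#'   TRUE; FALSE returns the noise-free expectation).
#' @return numeric matrix (n_fast x n_slow).
#' @export
generate_background <- function(geom,
                                water_ring = list(radius = 60, width = 12,
                                                  amplitude = 30),
                                base = 40, poisson = TRUE) {
  stopifnot(base >= 0, water_ring$amplitude >= 0)
  p <- geom$panels[[1]]
  f <- matrix(0:(p$n_fast - 1), p$n_fast, p$n_slow)
  s <- matrix(0:(p$n_slow - 1), p$n_fast, p$n_slow, byrow = TRUE)
  r <- sqrt((f - geom$beam_centre[1])^2 + (s - geom$beam_centre[2])^2)
  mu <- base + water_ring$amplitude *
    exp(-(r - water_ring$radius)^2 / (2 * water_ring$width^2))
  if (!poisson) return(mu)
  matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
}

# integral of an isotropic Gaussian PSF over each pixel of a (2h+1)^2 window
gaussian_kernel <- function(dx, dy, sigma, half) {
  u <- (-half):(half)
  px <- stats::pnorm(u + 0.5, mean = dx, sd = sigma) -
        stats::pnorm(u - 0.5, mean = dx, sd = sigma)
  py <- stats::pnorm(u + 0.5, mean = dy, sd = sigma) -
        stats::pnorm(u - 0.5, mean = dy, sd = sigma)
  outer(px, py)
}

#' Synthetic diffraction frame with ground truth
#'
#' Renders the partial reflections of one crystal orientation into pixels:
#' spot positions and partial intensities come from the partiality model
#' ([simulate_pattern()]), each spot is drawn as an isotropic Gaussian
#' point-spread integrating to its partial intensity, added to the water-ring
#' background, and the sum is Poisson-sampled (per-pixel photon statistics at
#' the given gain). Dark offsets and per-segment shifts can be injected to
#' exercise the frame-preparation stage.
#'
#' @param orientation 3x3 rotation matrix.
#' @param config simulation configuration ([sim_config()]); its geometry
#'   should be coarse enough that spots are separated (the fixture default
#'   [synth_config()] uses a 256-pixel detector).
#' @param intensities unique-reflection intensities; drawn when `NULL`.
#' @param setup optional precomputed [partiality_setup()].
#' @param spot_sigma Gaussian PSF sigma in pixels (default 0.8).
#' @param max_spots render only the strongest `max_spots` partial
#'   reflections (default 80), keeping the fixture sparse like a real
#'   pattern.
#' @param background list of [generate_background()] arguments
#'   (`water_ring`, `base`), or `NULL` for no background.
#' @param gain detector units per photon (default 1).
#' @param dark_offset constant electronic offset added after photon
#'   sampling (default 0).
#' @param segment_shifts optional numeric vector of per-segment common-mode
#'   shifts (one per segment of `segments`).
#' @param segments number of segment stripes along the slow axis (default 4).
#' @param noise_free skip all Poisson sampling (exact expectations, for
#'   conservation tests).
#' @param id frame id.
#' @return list with `frame` ([sfx_frame()]) and `truth` (tibble: `h`, `k`,
#'   `l`, `I` partial intensity in detector units, `fast`, `slow`, `p`,
#'   `lorentz`) plus the `orientation` and background field used.
#' @export
generate_frame <- function(orientation, config = synth_config(),
                           intensities = NULL, setup = NULL,
                           spot_sigma = 0.8, max_spots = 80,
                           background = list(), gain = 1,
                           dark_offset = 0, segment_shifts = NULL,
                           segments = 4, noise_free = FALSE, id = 1L) {
  obs <- simulate_pattern(orientation, config = config,
                          intensities = intensities, setup = setup,
                          scale = 1, noise_sd = 0)
  obs <- obs[order(-obs$I_partial), ]
  if (nrow(obs) > max_spots) obs <- obs[seq_len(max_spots), ]
  geom <- config$geom
  p <- geom$panels[[1]]
  img <- if (is.null(background)) {
    matrix(0, p$n_fast, p$n_slow)
  } else {
    do.call(generate_background,
            c(list(geom = geom, poisson = FALSE), background))
  }
  half <- max(3, ceiling(4 * spot_sigma))
  for (i in seq_len(nrow(obs))) {
    cf <- obs$fast[i]; cs <- obs$slow[i]
    f0 <- round(cf); s0 <- round(cs)
    ker <- gaussian_kernel(cf - f0, cs - s0, spot_sigma, half) * obs$I_partial[i]
    fr <- (f0 - half):(f0 + half) + 1
    sr <- (s0 - half):(s0 + half) + 1
    okf <- fr >= 1 & fr <= p$n_fast
    oks <- sr >= 1 & sr <= p$n_slow
    img[fr[okf], sr[oks]] <- img[fr[okf], sr[oks]] + ker[okf, oks]
  }
  if (!noise_free) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0) / gain) * gain,
                  nrow(img), ncol(img))
  }
  seg <- matrix(rep(1:segments, each = ceiling(p$n_slow / segments))[1:p$n_slow],
                p$n_fast, p$n_slow, byrow = TRUE)
  if (!is.null(segment_shifts)) {
    stopifnot(length(segment_shifts) == segments)
    img <- img + matrix(segment_shifts[seg], p$n_fast, p$n_slow)
  }
  img <- img + dark_offset
  truth <- tibble::tibble(h = obs$h, k = obs$k, l = obs$l, I = obs$I_partial,
                          fast = obs$fast, slow = obs$slow,
                          p = obs$p, lorentz = obs$lorentz)
  list(frame = sfx_frame(img, segment_map = seg, id = id),
       truth = truth, orientation = orientation)
}

#' Fixture-scale simulation configuration
#'
#' The reference conditions of [sim_config()] on a coarser 256-pixel
#' detector (0.3 mm pixels, same 76.8 mm square at 70 mm) with a wider
#' 2% bandwidth so single frames carry enough strong spots, and brighter
#' synthetic intensities so rendered spots clear the water-ring noise.
#'
#' @param bandwidth fractional bandwidth (default 0.02).
#' @param convergence convergence angle, rad (default 0.001).
#' @return configuration list (see [sim_config()]).
#' @export
synth_config <- function(bandwidth = 0.02, convergence = 0.001) {
  cfg <- sim_config(bandwidth = bandwidth, convergence = convergence)
  cfg$geom <- detector_geometry(256, 256, pixel_size = 0.3, camera_length = 70)
  cfg$d_min <- detector_corner_resolution(cfg$geom, cfg$beam$wavelength)
  cfg
}

#' Generate a synthetic frame set with ground truth
#'
#' @param n number of frames.
#' @param config fixture configuration ([synth_config()]).
#' @param intensity_scale multiplier applied to the synthetic intensities so
#'   rendered spots reach the requested signal-to-noise (default 40).
#' @param ... further arguments for [generate_frame()].
#' @return list with `frames` (list of [sfx_frame()]), `truth` (tibble with
#'   `frame_id` column), `orientations`, `intensities`, `config`.
#' @export
generate_frame_set <- function(n, config = synth_config(),
                               intensity_scale = 40, ...) {
  intensities <- synthetic_intensities(config$cell, config$d_min,
                                       pg = config$point_group)
  intensities$I <- intensities$I * intensity_scale
  setup <- partiality_setup(config, intensities)
  frames <- vector("list", n)
  truth <- vector("list", n)
  orientations <- vector("list", n)
  for (i in seq_len(n)) {
    rot <- random_orientation()
    g <- generate_frame(rot, config = config, setup = setup, id = i, ...)
    frames[[i]] <- g$frame
    truth[[i]] <- dplyr::mutate(g$truth, frame_id = i, .before = 1)
    orientations[[i]] <- rot
  }
  list(frames = frames, truth = dplyr::bind_rows(truth),
       orientations = orientations, intensities = intensities,
       config = config)
}
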