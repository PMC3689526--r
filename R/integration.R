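#' Three-ring integration domain
#'
#' Radii (pixels) of the three concentric circles of summation integration:
#' pixels inside `r_peak` are summed as the peak, pixels between `r_gap` and
#' `r_bg` estimate the background, and the annulus between `r_peak` and
#' `r_gap` is an unused buffer against small prediction errors. Typical
#' values are 3, 4 and 5 pixels.
#'
#' @param r_peak,r_gap,r_bg strictly increasing positive radii.
#' @return list of class `sfx_rings`.
#' @export
integration_rings <- function(r_peak = 3, r_gap = 4, r_bg = 5) {
  stopifnot(r_peak > 0, r_peak < r_gap, r_gap < r_bg)
  structure(list(r_peak = r_peak, r_gap = r_gap, r_bg = r_bg),
            class = "sfx_rings")
}

#' Predict reflection positions for an indexed pattern
#'
#' All integer Miller indices whose reciprocal point lies within
#' `profile_r` of an Ewald sphere in the beam's bandwidth/convergence range
#' (i.e. could be partially excited) and whose scattered ray hits the active
#' detector area. The forward beam (0,0,0) is excluded.
#'
#' @param solution successful `sfx_solution` (or any list with a reciprocal
#'   `basis` matrix, columns a*, b*, c*).
#' @param beam an [beam_parameters()].
#' @param geom an [detector_geometry()].
#' @param profile_r reflection-profile radius (1/angstrom).
#' @return tibble: `h`, `k`, `l`, `fast`, `slow`, `p`, `lorentz`.
#' @export
predict_reflections <- function(solution, beam, geom, profile_r = 3e-4) {
  if (!isTRUE(solution$success) && is.null(solution$basis))
    stop("needs a successful indexing solution", call. = FALSE)
  B <- solution$basis
  A <- t(solve(B))
  d_min <- detector_corner_resolution(geom, beam$wavelength)
  qmax <- 1 / d_min
  lens <- sqrt(colSums(A^2))
  hmax <- floor(lens * qmax) + 1
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                                k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  q <- grid %*% t(B)
  keep <- rowSums(q^2) <= qmax^2
  grid <- grid[keep, , drop = FALSE]; q <- q[keep, , drop = FALSE]
  # excited: the profile sphere overlaps the slab between the limiting Ewald
  # spheres (for a monochromatic parallel beam this degenerates to lying
  # within the profile radius of the single sphere, where p is identically 0)
  e <- excitation_errors(q, beam)
  idx <- which(e$r_low > -profile_r & e$r_high < profile_r)
  pos <- predict_spot_position(q[idx, , drop = FALSE], geom, beam$wavelength)
  on <- pos$on_detector
  tibble::tibble(h = grid[idx, 1], k = grid[idx, 2], l = grid[idx, 3],
                 fast = pos$fast, slow = pos$slow,
                 p = partiality_fraction(e$r_low[idx], e$r_high[idx], profile_r),
                 lorentz = lorentz_factor(e$r_low[idx], e$r_high[idx],
                                          profile_r))[on, ]
}

ring_pixels <- function(frame, centre, radius) {
  nr <- nrow(frame$data); nc <- ncol(frame$data)
  f0 <- max(1, floor(centre[1] + 1 - radius)); f1 <- min(nr, ceiling(centre[1] + 1 + radius))
  s0 <- max(1, floor(centre[2] + 1 - radius)); s1 <- min(nc, ceiling(centre[2] + 1 + radius))
  if (f0 > f1 || s0 > s1) return(cbind(integer(0), integer(0)))
  fs <- as.matrix(expand.grid(f = f0:f1, s = s0:s1))
  d2 <- (fs[, 1] - 1 - centre[1])^2 + (fs[, 2] - 1 - centre[2])^2
  fs[d2 < radius^2, , drop = FALSE]
}

#' Integrate one spot with the three-ring scheme
#'
#' The background is the mean of the unmasked annulus pixels (between
#' `r_gap` and `r_bg`), excluding pixels inside the peak region of any other
#' reflection; it is subtracted from each peak pixel (inside `r_peak`) and
#' the residuals are summed. The standard error combines the background
#' variance over the peak region, the uncertainty of the subtracted
#' background mean, and Poisson counting on the photon count:
#' `sigma^2 = N * var_bg * (1 + N/M) + k * max(I, 0)` with `N` peak pixels,
#' `M` background pixels and `k` detector units per photon. Negative
#' integrated intensities are retained (required for unbiased Monte-Carlo
#' merging). If fewer than 5 usable background pixels remain, the
#' measurement is flagged and sigma carries the counting term only.
#'
#' @param frame an [sfx_frame()].
#' @param centre spot centre `(fast, slow)` in pixels (0-based).
#' @param rings an [integration_rings()].
#' @param gain detector units per photon `k` (default 1).
#' @param other_peak_regions optional matrix/tibble of other reflections'
#'   centres (columns fast, slow) whose peak regions are excluded from the
#'   background annulus.
#' @return list: `I`, `sigma`, `N`, `background`, `flagged`.
#' @export
integrate_spot <- function(frame, centre, rings = integration_rings(),
                           gain = 1, other_peak_regions = NULL) {
  stopifnot(gain > 0)
  peak_px <- ring_pixels(frame, centre, rings$r_peak)
  bg_all <- ring_pixels(frame, centre, rings$r_bg)
  if (nrow(bg_all)) {
    d2 <- (bg_all[, 1] - 1 - centre[1])^2 + (bg_all[, 2] - 1 - centre[2])^2
    bg_px <- bg_all[d2 >= rings$r_gap^2, , drop = FALSE]
  } else bg_px <- bg_all
  unmasked <- function(px) {
    if (!nrow(px)) return(px)
    px[!frame$mask[px], , drop = FALSE]
  }
  peak_px <- unmasked(peak_px)
  bg_px <- unmasked(bg_px)
  if (!is.null(other_peak_regions) && nrow(bg_px)) {
    oc <- as.matrix(as.data.frame(other_peak_regions)[, 1:2])
    excl <- rep(FALSE, nrow(bg_px))
    for (r in seq_len(nrow(oc))) {
      d2 <- (bg_px[, 1] - 1 - oc[r, 1])^2 + (bg_px[, 2] - 1 - oc[r, 2])^2
      excl <- excl | d2 < rings$r_peak^2
    }
    bg_px <- bg_px[!excl, , drop = FALSE]
  }
  N <- nrow(peak_px)
  if (N == 0)
    return(list(I = NA_real_, sigma = NA_real_, N = 0L,
                background = NA_real_, flagged = TRUE))
  M <- nrow(bg_px)
  flagged <- M < 5
  bg_mean <- if (M >= 1) mean(frame$data[bg_px]) else 0
  bg_var <- if (M >= 2) stats::var(frame$data[bg_px]) else 0
  I <- sum(frame$data[peak_px] - bg_mean)
  var_poisson <- gain * max(I, 0)
  sigma <- if (flagged) sqrt(var_poisson)
           else sqrt(N * bg_var * (1 + N / M) + var_poisson)
  list(I = I, sigma = sigma, N = as.integer(N), background = bg_mean,
       flagged = flagged)
}

#' Integrate all predicted reflections of a pattern
#'
#' Runs [integrate_spot()] at each predicted position, excluding every other
#' reflection's peak region from each background annulus. No solid-angle
#' correction is applied: the summed total peak intensity does not need one.
#'
#' @param frame an [sfx_frame()].
#' @param solution successful `sfx_solution`.
#' @param beam,geom beam and geometry.
#' @param rings an [integration_rings()].
#' @param gain detector units per photon (default 1).
#' @param profile_r profile radius for prediction (1/angstrom).
#' @param predictions optional precomputed [predict_reflections()] tibble.
#' @return reflection tibble of class `sfx_reflections`: `h`, `k`, `l`, `I`,
#'   `sigma`, `N`, `fast`, `slow`, `panel`, `flagged`.
#' @export
integrate_pattern <- function(frame, solution, beam, geom,
                              rings = integration_rings(), gain = 1,
                              profile_r = 3e-4, predictions = NULL) {
  pred <- if (is.null(predictions))
    predict_reflections(solution, beam, geom, profile_r) else predictions
  n <- nrow(pred)
  empty <- tibble::tibble(h = integer(), k = integer(), l = integer(),
                          I = numeric(), sigma = numeric(), N = integer(),
                          fast = numeric(), slow = numeric(),
                          panel = integer(), flagged = logical())
  if (n == 0) return(structure(empty, class = c("sfx_reflections", class(empty))))
  centres <- cbind(pred$fast, pred$slow)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- integrate_spot(frame, centres[i, ], rings = rings, gain = gain,
                        other_peak_regions = centres[-i, , drop = FALSE])
    rows[[i]] <- tibble::tibble(h = pred$h[i], k = pred$k[i], l = pred$l[i],
                                I = m$I, sigma = m$sigma, N = m$N,
                                fast = pred$fast[i], slow = pred$slow[i],
                                panel = 1L, flagged = m$flagged)
  }
  out <- dplyr::bind_rows(rows)
  out <- out[!is.na(out$I), ]
  structure(out, class = c("sfx_reflections", class(out)))
}
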