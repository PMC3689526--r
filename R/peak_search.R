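#' Find Bragg peaks in a background-subtracted frame
#'
#' Peaks are 8-connected clusters of unmasked pixels above `threshold`. A
#' cluster qualifies when its pixel count lies in `[min_pix, max_pix]` (the
#' lower bound rejects single-pixel outliers, the upper bound diffuse ice
#' blobs) and its signal-to-noise ratio reaches `min_snr`. The SNR numerator
#' is the mean above-threshold intensity per peak pixel; the denominator is
#' the standard deviation of the pixels in a `local_box` window around the
#' centroid, omitting pixels belonging to any peak, so the criterion is
#' independent of peak size and adapts to local noise (e.g. on the water
#' ring).
#'
#' @param frame a background-subtracted [sfx_frame()].
#' @param threshold intensity threshold in detector units; default 4 x the
#'   robust frame sigma (MAD of unmasked pixels).
#' @param min_pix,max_pix allowed connected-pixel counts (defaults 2 and 40).
#' @param min_snr minimum local signal-to-noise ratio (default 6).
#' @param local_box window edge (pixels) for the local noise estimate
#'   (default 5, matching the median-filter box).
#' @param beam_centre optional (fast, slow) beam position used to attach each
#'   peak's radius; taken from `geom` if supplied there instead.
#' @return tibble with columns `fast`, `slow` (intensity-weighted centroid,
#'   0-based pixels), `n_pixels`, `intensity`, `snr`,
#'   `radius` (px from beam centre, `NA` when no centre given).
#' @export
find_peaks <- function(frame, threshold = NULL, min_pix = 2, max_pix = 40,
                       min_snr = 6, local_box = 5, beam_centre = NULL) {
  stopifnot(min_pix <= max_pix)
  if (is.null(threshold)) {
    threshold <- 4 * stats::mad(frame$data[!frame$mask])
    if (!is.finite(threshold)) threshold <- 0
  }
  lab <- label_peaks_cpp(frame$data, frame$mask, threshold)
  n <- length(lab$n_pixels)
  empty <- tibble::tibble(fast = numeric(), slow = numeric(),
                          n_pixels = integer(), intensity = numeric(),
                          snr = numeric(), radius = numeric())
  if (n == 0) return(empty)
  keep <- lab$n_pixels >= min_pix & lab$n_pixels <= max_pix
  if (!any(keep)) return(empty)
  labels <- lab$labels
  half <- local_box %/% 2
  nr <- nrow(frame$data); nc <- ncol(frame$data)
  snr <- rep(NA_real_, n)
  for (i in which(keep)) {
    cf <- round(lab$fast[i]) + 1      # to 1-based matrix indices
    cs <- round(lab$slow[i]) + 1
    ri <- max(1, cf - half):min(nr, cf + half)
    ci <- max(1, cs - half):min(nc, cs + half)
    win_v <- frame$data[ri, ci, drop = FALSE]
    win_l <- labels[ri, ci, drop = FALSE]
    win_m <- frame$mask[ri, ci, drop = FALSE]
    bgpx <- win_v[win_l == 0 & !win_m]
    noise <- if (length(bgpx) >= 2) stats::sd(bgpx) else NA_real_
    mean_peak <- lab$intensity[i] / lab$n_pixels[i]
    snr[i] <- if (is.na(noise)) Inf else if (noise == 0) Inf else mean_peak / noise
  }
  keep <- keep & snr >= min_snr
  out <- tibble::tibble(fast = lab$fast[keep], slow = lab$slow[keep],
                        n_pixels = as.integer(lab$n_pixels[keep]),
                        intensity = lab$intensity[keep], snr = snr[keep],
                        radius = NA_real_)
  centre <- beam_centre
  if (!is.null(centre))
    out$radius <- sqrt((out$fast - centre[1])^2 + (out$slow - centre[2])^2)
  out[order(-out$intensity), ]
}

#' Classify a pattern as a hit
#'
#' A frame is retained as a crystal hit when at least `min_peaks` Bragg peaks
#' were found; 25 peaks is the standard compromise between keeping indexable
#' patterns and discarding blanks.
#'
#' @param peaks peak tibble from [find_peaks()] (or anything with `nrow()`).
#' @param min_peaks minimum peak count (default 25).
#' @return logical scalar.
#' @export
classify_hit <- function(peaks, min_peaks = 25) {
  stopifnot(min_peaks >= 1)
  nrow(peaks) >= min_peaks
}

#' Hit rate over consecutive frame blocks
#'
#' The running hit fraction, averaged over blocks of `block` frames (3600
#' frames is 30 s at a 120 Hz repetition rate). A final partial block is
#' reported with its own denominator.
#'
#' @param hit_records data frame with logical column `is_hit`, one row per
#'   frame in acquisition order.
#' @param block frames per block (default 3600).
#' @return tibble with `block`, `n_frames`, `n_hits`, `hit_rate`.
#' @export
hit_rate_series <- function(hit_records, block = 3600) {
  stopifnot(block >= 1)
  hits <- hit_records$is_hit
  idx <- (seq_along(hits) - 1) %/% block
  tibble::tibble(block = sort(unique(idx)) + 1L) |>
    dplyr::mutate(n_frames = as.integer(tabulate(idx + 1L)),
                  n_hits = as.integer(vapply(sort(unique(idx)),
                                             function(b) sum(hits[idx == b]), 1L)),
                  hit_rate = .data$n_hits / .data$n_frames)
}

#' Pattern resolution from the 80% peak radius
#'
#' The spatial frequency (1/d) at the radius of the circle, centred on the
#' beam position, containing 80% of the found Bragg peaks (ceiling-rank
#' convention: the smallest radius containing at least 80% of peaks).
#'
#' @param peaks peak tibble; radii are taken from its `radius` column or
#'   recomputed from `geom`'s beam centre.
#' @param geom an [detector_geometry()].
#' @param wavelength wavelength in angstroms.
#' @return spatial frequency in 1/angstrom.
#' @export
pattern_resolution_80 <- function(peaks, geom, wavelength) {
  if (nrow(peaks) == 0) stop("no peaks: resolution estimate undefined", call. = FALSE)
  centre <- geom$beam_centre
  r <- sqrt((peaks$fast - centre[1])^2 + (peaks$slow - centre[2])^2)
  r80 <- sort(r)[ceiling(0.8 * length(r))]
  px <- geom$panels[[1]]$pixel_size
  two_theta <- atan2(r80 * px, geom$camera_length)
  2 * sin(two_theta / 2) / wavelength
}

#' Run peak finding and hit classification over a frame stack
#'
#' @param frames list of prepared frames (or an iterator from
#'   [read_frames()]).
#' @param geom optional geometry (attaches radii / resolution estimates).
#' @param wavelength wavelength in angstroms (needed with `geom`).
#' @param min_peaks hit threshold, see [classify_hit()].
#' @param ... passed to [find_peaks()].
#' @return list with `hits` (tibble: `frame_id`, `n_peaks`, `is_hit`,
#'   `resolution_invA`) and `peaks` (tibble of all peaks with `frame_id`).
#' @export
find_hits <- function(frames, geom = NULL, wavelength = NULL, min_peaks = 25, ...) {
  nxt <- if (is.function(frames)) frames else {
    i <- 0L
    function() { i <<- i + 1L; if (i > length(frames)) NULL else frames[[i]] }
  }
  hit_rows <- list(); peak_rows <- list()
  centre <- if (!is.null(geom)) geom$beam_centre else NULL
  repeat {
    fr <- nxt()
    if (is.null(fr)) break
    pk <- find_peaks(fr, beam_centre = centre, ...)
    res <- if (!is.null(geom) && !is.null(wavelength) && nrow(pk) > 0)
      pattern_resolution_80(pk, geom, wavelength) else NA_real_
    hit_rows[[length(hit_rows) + 1L]] <-
      tibble::tibble(frame_id = fr$id, n_peaks = nrow(pk),
                     is_hit = classify_hit(pk, min_peaks),
                     resolution_invA = res)
    if (nrow(pk) > 0)
      peak_rows[[length(peak_rows) + 1L]] <- dplyr::mutate(pk, frame_id = fr$id,
                                                           .before = 1)
  }
  list(hits = dplyr::bind_rows(hit_rows), peaks = dplyr::bind_rows(peak_rows))
}

#' Fast-feedback histograms of hit statistics
#'
#' Histograms of the number of patterns versus total peak count and versus
#' the 80%-radius resolution estimate, the two running diagnostics used to
#' monitor crystal quality during data collection.
#'
#' @param hits hit tibble from [find_hits()].
#' @param bins number of bins per histogram (default 20).
#' @return tibble with `statistic` (`"n_peaks"` or `"resolution_invA"`),
#'   `mid` (bin centre) and `count`; each histogram sums to the total frame
#'   count (frames without an estimate land in an `NA`-mid bin).
#' @export
hit_histograms <- function(hits, bins = 20) {
  one <- function(values, statistic) {
    ok <- is.finite(values)
    if (!any(ok)) {
      return(tibble::tibble(statistic = statistic, mid = NA_real_,
                            count = length(values)))
    }
    rng <- range(values[ok])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = bins + 1)
    cnt <- tabulate(findInterval(values[ok], br, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = bins)
    out <- tibble::tibble(statistic = statistic,
                          mid = (br[-1] + br[-(bins + 1)]) / 2, count = cnt)
    if (any(!ok)) {
      out <- dplyr::bind_rows(out, tibble::tibble(statistic = statistic,
                                                  mid = NA_real_,
                                                  count = sum(!ok)))
    }
    out
  }
  dplyr::bind_rows(one(as.numeric(hits$n_peaks), "n_peaks"),
                   one(hits$resolution_invA, "resolution_invA"))
}
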