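#' Detector frame
#'
#' A single detector readout: the pixel data plus a per-pixel segment label
#' (which read-out unit each pixel belongs to) and a bad-pixel mask. Masked
#' pixels are excluded from every statistic computed by the pipeline.
#'
#' @param data numeric matrix of detector intensity units
#'   (rows = fast coordinate, columns = slow coordinate).
#' @param segment_map integer matrix of segment labels, same shape as `data`;
#'   defaults to a single segment.
#' @param mask logical matrix, `TRUE` marks bad pixels; defaults to all good.
#' @param id frame identifier.
#' @return An object of class `sfx_frame`.
#' @export
sfx_frame <- function(data, segment_map = NULL, mask = NULL, id = NA_integer_) {
  data <- as.matrix(data)
  if (is.null(segment_map)) segment_map <- matrix(1L, nrow(data), ncol(data))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(data), ncol(data))
  stopifnot(all(dim(segment_map) == dim(data)), all(dim(mask) == dim(data)))
  structure(list(data = data, segment_map = segment_map, mask = mask, id = id),
            class = "sfx_frame")
}

#' @export
print.sfx_frame <- function(x, ...) {
  cat(sprintf("<sfx_frame> id=%s  %d x %d px, %d segment(s), %d masked px\n",
              as.character(x$id), nrow(x$data), ncol(x$data),
              length(unique(as.integer(x$segment_map))), sum(x$mask)))
  invisible(x)
}

#' Build a dark model from dark frames
#'
#' Static detector offsets are estimated from frames recorded without X-rays:
#' the model holds the per-pixel mean (offset) and per-pixel standard
#' deviation (spread, zero for a single frame).
#'
#' @param dark_frames list of [sfx_frame()] objects with congruent shapes.
#' @return list of class `sfx_dark` with matrices `offset` and `spread`.
#' @export
build_dark_model <- function(dark_frames) {
  if (length(dark_frames) < 1) stop("need at least one dark frame", call. = FALSE)
  dims <- dim(dark_frames[[1]]$data)
  for (f in dark_frames)
    if (!all(dim(f$data) == dims)) stop("dark frames have differing shapes", call. = FALSE)
  stack <- vapply(dark_frames, function(f) f$data, dark_frames[[1]]$data)
  n <- length(dark_frames)
  offset <- apply(stack, c(1, 2), mean)
  spread <- if (n == 1) matrix(0, dims[1], dims[2]) else apply(stack, c(1, 2), stats::sd)
  structure(list(offset = offset, spread = spread, n_frames = n), class = "sfx_dark")
}

#' Subtract the dark offset from a frame
#'
#' @param frame an [sfx_frame()].
#' @param dark an [build_dark_model()] result with matching shape.
#' @return The corrected frame (mask and segment map propagated).
#' @export
subtract_dark <- function(frame, dark) {
  if (!all(dim(frame$data) == dim(dark$offset)))
    stop("frame and dark model shapes differ", call. = FALSE)
  frame$data <- frame$data - dark$offset
  frame
}

#' Correct per-segment common-mode offsets
#'
#' Shot-to-shot fluctuations between detector segments (common mode) and
#' offsets coupled to the total segment signal are removed together by one
#' robust per-frame, per-segment estimate: the median of this frame's
#' signal-free pixels in each segment, where "signal-free" means below
#' `signal_threshold`. Segments with fewer than 16 usable pixels are left
#' unchanged (offset 0) with a warning.
#'
#' @param frame a dark-subtracted [sfx_frame()].
#' @param dark optional dark model; when given the default threshold is
#'   3 x the median dark spread.
#' @param signal_threshold detector-unit threshold below which a pixel is
#'   treated as signal-free; default `3 * median(dark$spread)` or, without a
#'   dark model, 3 x the robust frame sigma (MAD).
#' @return The corrected frame; the applied per-segment offsets are attached
#'   as attribute `"segment_offsets"` (named numeric vector).
#' @export
correct_segment_offsets <- function(frame, dark = NULL, signal_threshold = NULL) {
  if (is.null(signal_threshold)) {
    signal_threshold <- if (!is.null(dark)) {
      3 * stats::median(dark$spread[!frame$mask])
    } else {
      3 * stats::mad(frame$data[!frame$mask])
    }
  }
  segs <- sort(unique(as.integer(frame$segment_map)))
  offsets <- stats::setNames(numeric(length(segs)), segs)
  for (i in seq_along(segs)) {
    in_seg <- frame$segment_map == segs[i] & !frame$mask
    if (sum(in_seg) < 16) {
      warning(sprintf("segment %d has <16 unmasked pixels; offset left at 0", segs[i]),
              call. = FALSE)
      next
    }
    vals <- frame$data[in_seg]
    quiet <- vals[vals <= signal_threshold]
    if (!length(quiet)) quiet <- vals   # all pixels bright: fall back to all
    offsets[i] <- stats::median(quiet)
    frame$data[in_seg] <- frame$data[in_seg] - offsets[i]
  }
  attr(frame, "segment_offsets") <- offsets
  frame
}

#' Flag stuck pixels
#'
#' Marks pixels at or above `saturation` or at or below `floor` (both bounds
#' inclusive) and unions them with the existing mask.
#'
#' @param frame an [sfx_frame()].
#' @param saturation upper stuck-value threshold (default 65534, one below a
#'   16-bit container maximum).
#' @param floor lower stuck-value threshold (default -500 detector units).
#' @return The frame with its mask updated.
#' @export
flag_bad_pixels <- function(frame, saturation = 65534, floor = -500) {
  stopifnot(is.finite(saturation), is.finite(floor), floor < saturation)
  frame$mask <- frame$mask | frame$data >= saturation | frame$data <= floor
  frame
}

#' Pixel-wise median background
#'
#' Estimates the local background at each pixel as the median of the unmasked
#' pixels in a `box` x `box` neighbourhood (truncated at the frame edges) and
#' subtracts it. Because Bragg peaks are small compared to the box, the
#' median is dominated by background pixels: a 2-pixel-diameter peak inside a
#' 5x5 box leaves about 21 background pixels to fix the median, so peaks
#' survive the subtraction while the water ring and residual detector
#' structure are removed.
#'
#' @param frame an [sfx_frame()].
#' @param box odd box edge length in pixels, >= 3 (default 5).
#' @return list with `background` (matrix) and `frame` (the subtracted
#'   [sfx_frame()]).
#' @export
local_median_background <- function(frame, box = 5) {
  if (box < 3 || box %% 2 != 1) stop("box must be odd and >= 3", call. = FALSE)
  bg <- median_filter_cpp(frame$data, frame$mask, as.integer(box))
  bg[is.na(bg)] <- 0
  out <- frame
  out$data <- frame$data - bg
  list(background = bg, frame = out)
}

#' One-call frame preparation
#'
#' Dark subtraction, per-segment offset correction, bad-pixel flagging and
#' median background subtraction in the standard order.
#'
#' @param frame raw [sfx_frame()].
#' @param dark optional dark model.
#' @param box median-filter box (odd, default 5).
#' @param saturation,floor bad-pixel thresholds, see [flag_bad_pixels()].
#' @return The background-subtracted frame ready for peak finding.
#' @export
prepare_frame <- function(frame, dark = NULL, box = 5,
                          saturation = 65534, floor = -500) {
  if (!is.null(dark)) frame <- subtract_dark(frame, dark)
  frame <- flag_bad_pixels(frame, saturation, floor)
  frame <- correct_segment_offsets(frame, dark = dark)
  local_median_background(frame, box = box)$frame
}
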