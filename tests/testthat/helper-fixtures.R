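# shared fixtures: the reference simulation geometry/beam and small frames

ref_geom <- function() detector_geometry(768, 768, pixel_size = 0.1, camera_length = 70)
ref_wavelength <- function() 12398.42 / 9000

flat_frame <- function(value = 0, n = 32, segments = 1) {
  seg <- matrix(rep(seq_len(segments), each = ceiling(n / segments))[1:n],
                n, n, byrow = TRUE)
  sfx_frame(matrix(value, n, n), segment_map = seg)
}

# brute-force masked median filter (independent oracle for the C++ kernel)
median_filter_oracle <- function(data, mask, box) {
  h <- box %/% 2
  out <- matrix(NA_real_, nrow(data), ncol(data))
  for (i in seq_len(nrow(data))) {
    for (j in seq_len(ncol(data))) {
      ri <- max(1, i - h):min(nrow(data), i + h)
      ci <- max(1, j - h):min(ncol(data), j + h)
      v <- data[ri, ci][!mask[ri, ci]]
      out[i, j] <- if (length(v)) stats::median(v) else NA_real_
    }
  }
  out
}

# reciprocal peak positions of a synthetic still pattern (no pixels involved)
pattern_points <- function(setup, rot, geom, wavelength, max_peaks = Inf) {
  obs <- simulate_pattern(rot, setup = setup)
  obs <- obs[order(-obs$I_partial), ]
  if (nrow(obs) > max_peaks) obs <- obs[seq_len(max_peaks), ]
  map_peaks_to_ewald(obs, geom, wavelength)
}

sim_setup_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config()
      withr::with_seed(101, {
        ints <- synthetic_intensities(cfg$cell, cfg$d_min, pg = cfg$point_group)
        cache <<- serialx:::partiality_setup(cfg, ints)
      })
    }
    cache
  }
})
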