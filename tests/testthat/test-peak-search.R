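test_that("connected-component peak finding applies the size gates", {
  fr <- flat_frame(0, n = 32)
  fr$data[10:11, 10:11] <- 100           # 2x2 blob
  pk <- find_peaks(fr, threshold = 10, min_pix = 2, min_snr = 0)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$n_pixels, 4L)
  expect_equal(pk$intensity, 400)
  expect_equal(c(pk$fast, pk$slow), c(9.5, 9.5))  # 0-based centroid
  # single-pixel outlier rejected by min_pix
  fr2 <- flat_frame(0, n = 32); fr2$data[5, 5] <- 1000
  expect_equal(nrow(find_peaks(fr2, threshold = 10, min_pix = 2, min_snr = 0)), 0L)
  # oversized diffuse blob rejected by max_pix
  fr3 <- flat_frame(0, n = 40)
  fr3$data[5:34, 5:34] <- 50
  expect_equal(nrow(find_peaks(fr3, threshold = 10, min_pix = 2, max_pix = 20,
                               min_snr = 0)), 0L)
  # 8-connectivity: a diagonal pair is one component
  fr4 <- flat_frame(0, n = 16)
  fr4$data[4, 4] <- 60; fr4$data[5, 5] <- 60
  pk4 <- find_peaks(fr4, threshold = 10, min_pix = 2, min_snr = 0)
  expect_equal(nrow(pk4), 1L)
  expect_equal(pk4$n_pixels, 2L)
})

test_that("local signal-to-noise gate rejects weak blobs", {
  withr::with_seed(8, {
    fr <- sfx_frame(matrix(rnorm(48 * 48, 0, 1), 48, 48))
  })
  fr$data[20:21, 20:21] <- 3          # ~3 sigma blob
  pk <- find_peaks(fr, threshold = 2, min_pix = 2, min_snr = 6, local_box = 9)
  expect_false(any(pk$n_pixels >= 4 & abs(pk$fast - 19.5) < 2))
  fr$data[30:31, 30:31] <- 30         # 30 sigma blob passes
  pk2 <- find_peaks(fr, threshold = 2, min_pix = 2, min_snr = 6, local_box = 9)
  expect_true(any(abs(pk2$fast - 29.5) < 1 & abs(pk2$slow - 29.5) < 1))
})

test_that("peak finding is translation-equivariant and threshold-monotone", {
  withr::with_seed(9, {
    base <- matrix(pmax(rnorm(64 * 64, 0, 1), 0), 64, 64)
  })
  for (ij in list(c(10, 12), c(30, 31), c(44, 20))) {
    base[ij[1] + 0:1, ij[2] + 0:1] <- 40
  }
  shift <- 3
  shifted <- matrix(0, 64, 64)
  shifted[(1 + shift):64, ] <- base[1:(64 - shift), ]
  p1 <- find_peaks(sfx_frame(base), threshold = 5, min_snr = 0)
  p2 <- find_peaks(sfx_frame(shifted), threshold = 5, min_snr = 0)
  inner <- p1$fast < 60 - shift
  expect_equal(sort(p2$fast), sort(p1$fast[inner] + shift), tolerance = 1e-9)
  # raising threshold or min_snr never increases the count
  for (thr in c(1, 5, 20, 45)) {
    n_lo <- nrow(find_peaks(sfx_frame(base), threshold = thr, min_snr = 0))
    n_hi <- nrow(find_peaks(sfx_frame(base), threshold = thr + 5, min_snr = 0))
    expect_gte(n_lo, n_hi)
  }
  n_snr <- vapply(c(0, 3, 10, 100), function(s)
    nrow(find_peaks(sfx_frame(base), threshold = 5, min_snr = s)), 0L)
  expect_true(all(diff(n_snr) <= 0))
})

test_that("hit classification uses the 25-peak rule with a sharp boundary", {
  mk <- function(n) tibble::tibble(fast = seq_len(n))
  expect_true(classify_hit(mk(25)))
  expect_false(classify_hit(mk(24)))
  expect_false(classify_hit(mk(0)))
  expect_true(classify_hit(mk(3), min_peaks = 3))
})

test_that("hit rate is averaged over frame blocks with partial-block denominators", {
  rec <- tibble::tibble(is_hit = rep(c(TRUE, rep(FALSE, 9)), 360))
  hr <- hit_rate_series(rec, block = 3600)
  expect_equal(hr$hit_rate, 0.1)
  hr2 <- hit_rate_series(tibble::tibble(is_hit = rep(TRUE, 7200)), block = 3600)
  expect_equal(hr2$hit_rate, c(1, 1))
  hr3 <- hit_rate_series(tibble::tibble(is_hit = rep(c(TRUE, FALSE), 50)),
                         block = 3600)
  expect_equal(hr3$n_frames, 100L)
  expect_equal(hr3$hit_rate, 0.5)
  hr4 <- hit_rate_series(tibble::tibble(is_hit = rep(TRUE, 5000)), block = 3600)
  expect_equal(hr4$n_frames, c(3600L, 1400L))
})

test_that("80%-radius resolution estimate follows the ceiling-rank convention", {
  geom <- ref_geom(); wl <- ref_wavelength()
  mk <- function(radii) tibble::tibble(
    fast = geom$beam_centre[1] + radii, slow = rep(geom$beam_centre[2], length(radii)))
  # all peaks at one radius: the estimate is the frequency at that radius
  est <- pattern_resolution_80(mk(rep(200, 5)), geom, wl)
  expect_equal(est, 1 / resolution_at_pixel(geom, wl, geom$beam_centre[1] + 200,
                                            geom$beam_centre[2]))
  # radii 10..100: ceil(0.8*10) = 8th radius defines it
  est2 <- pattern_resolution_80(mk(seq(10, 100, by = 10)), geom, wl)
  expect_equal(est2, 1 / resolution_at_pixel(geom, wl, geom$beam_centre[1] + 80,
                                             geom$beam_centre[2]))
  expect_error(pattern_resolution_80(mk(numeric()), geom, wl), "no peaks")
})

test_that("peaks in synthetic frames are recovered with high recall and precision", {
  cfg <- synth_config()
  withr::with_seed(10, {
    fs <- generate_frame_set(6, config = cfg, max_spots = 60)
  })
  prepped <- lapply(fs$frames, function(f) local_median_background(f, 5)$frame)
  res <- find_hits(prepped, geom = cfg$geom,
                   wavelength = cfg$beam$wavelength, min_peaks = 25)
  expect_true(all(res$hits$is_hit))
  # per-frame matching of found peaks to rendered truth
  bg_sd <- sqrt(70)   # Poisson noise scale of the background plateau
  recall_n <- 0; recall_d <- 0; prec_n <- 0; prec_d <- 0
  for (id in seq_along(fs$frames)) {
    tr <- fs$truth[fs$truth$frame_id == id, ]
    # expected SNR of a rendered spot: central-pixel fraction over local noise
    tr$snr <- tr$I * 0.2 / bg_sd
    strong <- tr[tr$snr >= 8, ]
    pk <- res$peaks[res$peaks$frame_id == id, ]
    d2 <- outer(strong$fast, pk$fast, "-")^2 + outer(strong$slow, pk$slow, "-")^2
    recall_n <- recall_n + sum(apply(d2, 1, min) < 2^2)
    recall_d <- recall_d + nrow(strong)
    # precision against all rendered spots
    d2p <- outer(pk$fast, tr$fast, "-")^2 + outer(pk$slow, tr$slow, "-")^2
    prec_n <- prec_n + sum(apply(d2p, 1, min) < 2^2)
    prec_d <- prec_d + nrow(pk)
  }
  expect_gte(recall_n / recall_d, 0.9)
  expect_gte(prec_n / prec_d, 0.9)
})

test_that("hit-statistic histograms account for every frame", {
  withr::with_seed(11, {
    hits <- tibble::tibble(frame_id = 1:30,
                           n_peaks = c(rep(0L, 10), rpois(20, 40)),
                           is_hit = n_peaks >= 25,
                           resolution_invA = c(rep(NA_real_, 10),
                                               runif(20, 0.2, 0.45)))
  })
  h <- hit_histograms(hits, bins = 8)
  sums <- tapply(h$count, h$statistic, sum)
  expect_true(all(sums == 30))
  expect_equal(sum(h$count[h$statistic == "resolution_invA" & is.na(h$mid)]), 10)
})
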