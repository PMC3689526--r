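test_that("random orientations are orthonormal and uniformly distributed", {
  withr::with_seed(20, {
    rots <- random_orientation(2000)
  })
  for (R in rots[1:20]) {
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  # mean of a rotated unit vector vanishes under the Haar measure
  v <- vapply(rots, function(R) R %*% c(0, 0, 1), numeric(3))
  expect_lt(max(abs(rowMeans(v))), 3 / sqrt(2000) * 1.5)
})

test_that("excitation errors agree with a brute-force geometric oracle", {
  beam <- beam_parameters(9000, bandwidth = 0.004, convergence = 0.002)
  wl <- beam$wavelength
  # oracle: explicit tilted sphere centres built from rotation matrices
  oracle <- function(q) {
    qr <- sqrt(q[1]^2 + q[2]^2)
    rho <- if (qr > 0) c(q[1], q[2], 0) / qr else c(1, 0, 0)
    # centre (0,0,-k) rotated about the origin by ang towards rho
    centre <- function(k, ang) rho * (k * sin(ang)) + c(0, 0, -k * cos(ang))
    kmax <- 1 / (wl * (1 - beam$bandwidth / 2))
    kmin <- 1 / (wl * (1 + beam$bandwidth / 2))
    d <- beam$convergence / 2
    c(kmax - sqrt(sum((q - centre(kmax, d))^2)),
      kmin - sqrt(sum((q - centre(kmin, -d))^2)))
  }
  withr::with_seed(21, {
    qs <- matrix(rnorm(3 * 50, 0, 0.2), ncol = 3)
  })
  got <- excitation_errors(qs, beam)
  want <- t(apply(qs, 1, oracle))
  expect_equal(got$r_low, want[, 1], tolerance = 1e-12)
  expect_equal(got$r_high, want[, 2], tolerance = 1e-12)
  expect_true(all(got$r_low >= got$r_high))
  # monochromatic parallel beam, q exactly on the sphere: both errors vanish
  mono <- beam_parameters(9000)
  tt <- 0.4
  on_sphere <- c(sin(tt), 0, cos(tt) - 1) / wl
  e0 <- excitation_errors(rbind(on_sphere), mono)
  expect_equal(c(e0$r_low, e0$r_high), c(0, 0), tolerance = 1e-12)
  # q at the origin sits on every sphere
  e1 <- excitation_errors(rbind(c(0, 0, 0)), beam)
  expect_equal(c(e1$r_low, e1$r_high), c(0, 0), tolerance = 1e-12)
})

test_that("partiality follows the spherical-cap closed forms and stays in [0,1]", {
  R <- 3e-4
  expect_equal(partiality_fraction(R, -R, R), 1)          # slab spans profile
  expect_equal(partiality_fraction(2 * R, -5 * R, R), 1)  # wholly inside
  expect_equal(partiality_fraction(0.3 * R, 0.3 * R, R), 0)  # zero thickness
  expect_equal(partiality_fraction(0, -R, R), 0.5)        # half sphere
  expect_error(partiality_fraction(-R, R, R), "out of order")
  withr::with_seed(22, {
    rl <- runif(500, -2 * R, 2 * R)
    rh <- rl - runif(500, 0, 3 * R)
  })
  p <- partiality_fraction(rl, rh, R)
  expect_true(all(p >= 0 & p <= 1))
  # p = 0 exactly when the profile misses the slab
  expect_true(all((p == 0) == (rl <= -R | rh >= R | rl == rh)))
})

test_that("wider bandwidth never decreases a reflection's partiality", {
  setup <- sim_setup_cached()
  withr::with_seed(23, rot <- random_orientation())
  q <- setup$q0[seq(1, nrow(setup$q0), by = 97), ] %*% t(rot)
  R <- 3e-4
  p_prev <- NULL
  for (bw in c(0.001, 0.005, 0.02, 0.04)) {
    e <- excitation_errors(q, beam_parameters(9000, bw, 0.001))
    p <- partiality_fraction(e$r_low, e$r_high, R)
    if (!is.null(p_prev)) expect_true(all(p - p_prev >= -1e-12))
    p_prev <- p
  }
})

test_that("the Lorentz factor is the normalized slab thickness and grows with angle", {
  R <- 3e-4
  expect_equal(lorentz_factor(0.2, 0.2, R), 0)
  expect_equal(lorentz_factor(R, -R, R), 1)
  # along a radial line of reciprocal points on the nominal sphere, the
  # limiting spheres separate more at higher scattering angle
  beam <- beam_parameters(9000, bandwidth = 0.01, convergence = 0.002)
  wl <- beam$wavelength
  tt <- seq(0.05, 0.6, by = 0.05)
  q <- cbind(sin(tt), 0, cos(tt) - 1) / wl
  e <- excitation_errors(q, beam)
  L <- lorentz_factor(e$r_low, e$r_high, R)
  expect_true(all(diff(L) > 0))
})

test_that("synthetic intensities are calibrated to the 2% / 10% noise ratios", {
  cfg <- sim_config()
  withr::with_seed(24, {
    ints <- synthetic_intensities(cfg$cell, cfg$d_min, pg = "422")
  })
  expect_true(all(ints$I > 0))
  smax <- 1 / cfg$d_min
  # thin shells at both calibration anchors: the low-order mean is 500
  # (noise sd 10 = 2%) and the corner-shell mean 100 (10%)
  expect_equal(mean(ints$I[ints$s < 0.3 * smax]), 500, tolerance = 0.15)
  expect_equal(mean(ints$I[ints$s > 0.98 * smax]), 100, tolerance = 0.1)
  # per-shell mean monotone non-increasing with resolution (equal-count
  # shells keep the sampling error well below the shell-to-shell decay)
  shell <- cut(ints$s, breaks = stats::quantile(ints$s, 0:5 / 5),
               include.lowest = TRUE)
  mu <- tapply(ints$I, shell, mean)
  expect_true(all(diff(mu) < 0))
})

test_that("noise-free partial intensities equal the flux-normalized model", {
  setup <- sim_setup_cached()
  withr::with_seed(25, rot <- random_orientation())
  obs <- simulate_pattern(rot, setup = setup, scale = 2.5, noise_sd = 0)
  expect_gt(nrow(obs), 50)
  expect_true(all(obs$p > 0 & obs$p <= 1))
  L <- pmax(obs$lorentz, 1e-15 / (2 * 3e-4))
  expect_equal(obs$I_partial, 2.5 * obs$p / L * obs$I_full, tolerance = 1e-9)
  # no observation excited outside the slab grown by the profile radius
  expect_true(all(obs$r_low > -3e-4 & obs$r_high < 3e-4))
  # the R path and the merging engine agree on the same orientation
  res <- serialx:::rsplit_engine_cpp(
    setup$q0, setup$asu, setup$I_full, setup$config$beam$wavelength,
    setup$config$beam$bandwidth, setup$config$beam$convergence,
    setup$config$profile_r, setup$config$geom$camera_length, 38.4,
    0, 0, 2L, c(1L, 2L), rbind(rot, rot))
  merged <- merge_intensities(
    dplyr::select(obs, "h", "k", "l", I = "I_partial"), "422")
  # identical halves of the engine give R_split 0 and the same common count
  expect_equal(res$r_split[2], 0, tolerance = 1e-12)
  expect_equal(res$n_common[2], nrow(merged))
})

test_that("observation count grows with bandwidth", {
  setup1 <- NULL
  counts <- vapply(c(0.001, 0.01, 0.04), function(bw) {
    cfg <- sim_config(bandwidth = bw)
    st <- serialx:::partiality_setup(cfg, sim_setup_cached()$intensities)
    withr::with_seed(26, rot <- random_orientation())
    nrow(simulate_pattern(rot, setup = st))
  }, 0)
  expect_true(all(diff(counts) > 0))
})

test_that("R_split falls roughly as n^(-1/2) and is seed-reproducible", {
  cfg <- sim_config()
  ints <- sim_setup_cached()$intensities
  set.seed(27)
  cur <- convergence_experiment(c(250, 500, 1000, 2000, 4000),
                                config = cfg, intensities = ints)
  expect_true(all(diff(cur$r_split) < 0))
  slope <- coef(stats::lm(log(r_split) ~ log(n_patterns), data = cur))[2]
  expect_lt(abs(slope + 0.5), 0.1)
  set.seed(27)
  cur2 <- convergence_experiment(c(250, 500, 1000, 2000, 4000),
                                 config = cfg, intensities = ints)
  expect_identical(cur$r_split, cur2$r_split)
})

test_that("merged means recover the flux-normalized expectations (unbiasedness)", {
  # many noise-free patterns: per-reflection merged means approach the
  # orientation-average of the per-observation model; regression of merged
  # halves against each other has slope 1
  cfg <- sim_config(bandwidth = 0.02)
  ints <- sim_setup_cached()$intensities
  set.seed(28)
  st <- serialx:::partiality_setup(cfg, ints)
  res <- serialx:::rsplit_engine_cpp(
    st$q0, st$asu, st$I_full, cfg$beam$wavelength, 0.02, 0.001,
    cfg$profile_r, cfg$geom$camera_length, 38.4, 0, 0, 3000L,
    c(300L, 3000L))
  expect_lt(res$r_split[2], 0.08)
  expect_lt(res$r_split[2], res$r_split[1] / 2)
})
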