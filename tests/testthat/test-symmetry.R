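pg_orders <- c("1" = 1, "2" = 2, "222" = 4, "4" = 4, "422" = 8, "3" = 3,
               "312" = 6, "321" = 6, "32" = 6, "6" = 6, "622" = 12,
               "23" = 12, "432" = 24)

test_that("all chiral point groups are closed, proper and of the right order", {
  for (name in names(pg_orders)) {
    pg <- point_group(name)   # construction runs the validity checks
    expect_equal(length(pg$ops), unname(pg_orders[name]), label = name)
    expect_true(all(vapply(pg$ops, det, 0) == 1), label = name)
  }
  # the two trigonal two-fold settings are distinct groups of the same order
  expect_false(serialx:::pg_same_ops(point_group("312"), point_group("321")))
  expect_error(point_group("4/mmm"), "unknown point group")
})

test_that("proper holohedries follow the lattice systems", {
  expect_equal(proper_holohedry("triclinic")$name, "1")
  expect_equal(proper_holohedry("monoclinic")$name, "2")
  expect_equal(proper_holohedry("orthorhombic")$name, "222")
  expect_equal(proper_holohedry("tetragonal")$name, "422")
  expect_equal(proper_holohedry("rhombohedral")$name, "32")
  expect_equal(proper_holohedry("hexagonal")$name, "622")
  expect_equal(proper_holohedry("cubic")$name, "432")
  expect_error(proper_holohedry("smectic"))
})

test_that("left coset decomposition partitions the group", {
  key <- function(M) paste(as.integer(M), collapse = ",")
  cases <- list(c("622", "3"), c("622", "321"), c("622", "312"),
                c("622", "6"), c("422", "4"), c("432", "23"),
                c("32", "3"), c("422", "422"))
  for (cs in cases) {
    high <- point_group(cs[1])
    low <- point_group(cs[2], setting = if (cs[1] == "32") "rhombohedral" else NULL)
    reps <- left_coset_decomposition(high, low)
    expect_equal(length(reps), length(high$ops) / length(low$ops),
                 label = paste(cs, collapse = "/"))
    expect_equal(reps[[1]], diag(3L))
    # union of cosets covers the group exactly, pairwise disjoint
    all_keys <- unlist(lapply(reps, function(g)
      vapply(low$ops, function(s) key(g %*% s), "")))
    expect_equal(sort(all_keys), sort(vapply(high$ops, key, "")))
    expect_false(anyDuplicated(all_keys) > 0)
  }
  expect_equal(length(left_coset_decomposition(point_group("622"),
                                               point_group("3"))), 4L)
  expect_error(left_coset_decomposition(point_group("422"), point_group("3")),
               "not a subgroup")
})

test_that("apparent merging symmetry reproduces the ambiguity table", {
  rows <- list(
    list("triclinic", "1", "1"),
    list("monoclinic", "2", "2"),
    list("orthorhombic", "222", "222"),
    list("tetragonal", "4", "422"),
    list("tetragonal", "422", "422"),
    list("rhombohedral", "3", "32"),
    list("rhombohedral", "32", "32"),
    list("hexagonal", "3", "622"),
    list("hexagonal", "6", "622"),
    list("hexagonal", "312", "622"),
    list("hexagonal", "321", "622"),
    list("hexagonal", "622", "622"),
    list("cubic", "23", "432"),
    list("cubic", "432", "432"))
  for (r in rows) {
    expect_equal(apparent_point_group(r[[2]], r[[1]])$name, r[[3]],
                 label = paste(r[[1]], r[[2]]))
  }
  # a point group whose matrices are a subgroup of a higher holohedry merges
  # up to it (metric-accidental case); incompatible settings raise
  expect_equal(apparent_point_group("422", "cubic")$name, "432")
  expect_error(apparent_point_group("321", "cubic"), "not compatible")
})

test_that("metric-accidental ambiguities are detected numerically", {
  # monoclinic cell with beta ~ 90 looks orthorhombic within tolerance
  near <- unit_cell(40, 50, 60, beta = 90.4, lattice_type = "monoclinic")
  expect_gt(length(metric_ambiguities(near, angle_tol = 1.5)), 0)
  away <- unit_cell(40, 50, 60, beta = 103, lattice_type = "monoclinic")
  expect_equal(length(metric_ambiguities(away, angle_tol = 1.5,
                                         exclude = point_group("2"))), 0L)
})

test_that("merging maps observations to canonical reflections and averages", {
  one <- tibble::tibble(h = 1L, k = 2L, l = 3L, I = 8, sigma = 1)
  m1 <- merge_intensities(one, "1")
  expect_equal(m1$I, 8); expect_equal(m1$n_obs, 1L); expect_equal(m1$sigma, 1)
  # two observations of symmetry mates under 422 merge to their mean
  two <- tibble::tibble(h = c(1L, -2L), k = c(2L, 1L), l = c(3L, 3L),
                        I = c(8, 12), sigma = c(1, 1))
  m2 <- merge_intensities(two, "422")
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$I, 10)
  expect_equal(m2$sigma, stats::sd(c(8, 12)) / sqrt(2))
  # Friedel mates split when anomalous
  fr <- tibble::tibble(h = c(1L, -1L), k = c(0L, 0L), l = c(2L, -2L),
                       I = c(5, 9), sigma = c(1, 1))
  expect_equal(nrow(merge_intensities(fr, "1", anomalous = TRUE)), 2L)
  expect_equal(nrow(merge_intensities(fr, "1", anomalous = FALSE)), 1L)
  # merging under a supergroup never increases the unique count
  withr::with_seed(12, {
    obs <- tibble::tibble(h = sample(-6:6, 400, TRUE), k = sample(-6:6, 400, TRUE),
                          l = sample(-6:6, 400, TRUE), I = rexp(400, 0.01))
    obs <- obs[!(obs$h == 0 & obs$k == 0 & obs$l == 0), ]
  })
  for (pair in list(c("1", "2"), c("2", "222"), c("4", "422"), c("23", "432"))) {
    expect_gte(nrow(merge_intensities(obs, pair[1])),
               nrow(merge_intensities(obs, pair[2])))
  }
})

test_that("R_split matches closed forms and is scale-invariant", {
  mk <- function(I) {
    out <- tibble::tibble(h = seq_along(I), k = 0L, l = 0L, I = I,
                          sigma = 1, n_obs = 2L)
    class(out) <- c("sfx_merged", class(out))
    out
  }
  a <- mk(c(10, 20, 30, 40))
  expect_equal(r_split(a, a)$r_split, 0)
  # one half uniformly twice the other: 2^(-1/2) * (1 / 1.5)
  expect_equal(r_split(a, mk(2 * a$I))$r_split, 2^(-0.5) / 1.5, tolerance = 1e-12)
  # scale invariance
  withr::with_seed(13, {
    b <- mk(rexp(300, 0.01)); d <- mk(b$I + rnorm(300, 0, 5))
  })
  expect_equal(r_split(b, d)$r_split, r_split(mk(7 * b$I), mk(7 * d$I))$r_split,
               tolerance = 1e-12)
  expect_error(r_split(a, mk(1:4) |> dplyr::mutate(h = h + 100L)), "common")
  # i.i.d. Gaussian halves against a brute-force Monte-Carlo oracle of the
  # same statistic evaluated directly from its definition
  withr::with_seed(14, {
    s <- 4; mu <- 100
    I1 <- rnorm(5000, mu, s); I2 <- rnorm(5000, mu, s)
  })
  got <- r_split(mk(I1), mk(I2))$r_split
  oracle <- sum(abs(I1 - I2)) / (sqrt(2) * 0.5 * sum(I1 + I2))
  expect_equal(got, oracle, tolerance = 1e-12)
  # closed form: E|I1-I2| = s*sqrt(2)*sqrt(2/pi), so R -> sqrt(2/pi)*s/mu
  expect_equal(got, sqrt(2 / pi) * s / mu, tolerance = 0.05)
})

test_that("50/50 ambiguity mixing costs sqrt(2) of the anomalous signal", {
  withr::with_seed(15, {
    pairs <- simulate_bijvoet_pairs(20000)
    expect_equal(anomalous_mixing_factor(pairs, mixing = 0), 1)
    ratio <- anomalous_mixing_factor(pairs, mixing = 0.5, n_obs = 100)
  })
  expect_equal(ratio, sqrt(2), tolerance = 0.03)
  flat <- tibble::tibble(I_plus = c(1, 2, 3, 4), I_minus = c(1, 2, 3, 4))
  expect_error(anomalous_mixing_factor(flat), "all zero")
})

test_that("merged hkl files round-trip", {
  withr::with_seed(16, {
    obs <- tibble::tibble(h = sample(-5:5, 60, TRUE), k = sample(-5:5, 60, TRUE),
                          l = sample(-5:5, 60, TRUE), I = rexp(60, 0.01),
                          sigma = runif(60, 1, 3))
    obs <- obs[!(obs$h == 0 & obs$k == 0 & obs$l == 0), ]
  })
  m <- merge_intensities(obs, "222")
  path <- withr::local_tempfile(fileext = ".hkl")
  write_hkl(m, path)
  m2 <- read_hkl(path)
  expect_equal(attr(m2, "point_group"), "222")
  expect_equal(m2$I, m$I, tolerance = 1e-6)
  expect_equal(m2$n_obs, m$n_obs)
  expect_equal(r_split(m, m2)$r_split, 0, tolerance = 1e-6)
})
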