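#' Map found peaks onto the Ewald sphere
#'
#' Converts a peak list to exact reciprocal-space positions under the
#' still-pattern assumption: nominal wavelength, zero convergence and zero
#' mosaicity.
#'
#' @param peaks tibble with `fast`, `slow` centroid columns.
#' @param geom an [detector_geometry()].
#' @param wavelength wavelength in angstroms.
#' @return numeric matrix (n x 3) of reciprocal vectors (1/angstrom).
#' @export
map_peaks_to_ewald <- function(peaks, geom, wavelength) {
  q <- map_pixel_to_reciprocal(geom, wavelength, peaks$fast, peaks$slow)
  cbind(qx = q$qx, qy = q$qy, qz = q$qz)
}

# quasi-uniform directions on the upper hemisphere (Fibonacci spiral)
hemisphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Known-cell reciprocal-vector search
#'
#' Samples quasi-uniform directions on a hemisphere; for each direction the
#' reciprocal peak positions are projected onto it and the magnitude
#' spectrum of the projected density is evaluated over real-space
#' periodicities within `length_tol` of the reference axis lengths (the
#' spectrum peaks at length |a| when the direction aligns with the
#' real-space axis a). The best periodicity per direction and axis window
#' becomes a candidate real-space lattice vector with the spectral magnitude
#' as its figure of merit.
#'
#' @param points reciprocal peak positions (n x 3 matrix, 1/angstrom); at
#'   least 5 required (an empty candidate list is returned otherwise).
#' @param reference known [unit_cell()].
#' @param length_tol relative length tolerance of the search windows
#'   (default 0.10).
#' @param n_directions hemisphere sampling density (default 7300, roughly
#'   1.7-degree spacing; the subsequent refinement recovers sub-sample
#'   accuracy).
#' @param step length-sweep step within each window, angstrom (default 0.25).
#' @param n_keep candidates retained for polishing (by figure of merit,
#'   default 150; squashing reduces them afterwards).
#' @return tibble: `vx`, `vy`, `vz` (real-space vector, angstrom), `length`,
#'   `fom`, `n_supporting` (NA until refinement).
#' @export
fft_vector_search <- function(points, reference, length_tol = 0.10,
                              n_directions = 7300, step = 0.25, n_keep = 150) {
  empty <- tibble::tibble(vx = numeric(), vy = numeric(), vz = numeric(),
                          length = numeric(), fom = numeric(),
                          n_supporting = integer())
  points <- as.matrix(points)
  if (nrow(points) < 5) return(empty)
  lens <- sort(unique(round(cell_lengths(reference), 4)))
  windows <- cbind(lens * (1 - length_tol), lens * (1 + length_tol))
  dirs <- hemisphere_directions(n_directions)
  res <- dft_search_cpp(points, dirs, windows, step)
  cand <- tibble::tibble(
    dir = rep(seq_len(n_directions), times = length(lens)),
    window = rep(seq_along(lens), each = n_directions),
    length = as.vector(res$length),
    fom = as.vector(res$fom))
  cand <- cand[order(-cand$fom), ][seq_len(min(n_keep, nrow(cand))), ]
  U <- dirs[cand$dir, , drop = FALSE]
  # local direction polish: the coarse grid spacing (~sqrt(2*pi/n) rad) is
  # marginal for long axes, whose spectral peak decoheres within ~1/(q_span*L)
  # radians of the true direction; two shrinking 5x5 tangent-grid rounds
  # around each kept candidate recover the peak
  spacing <- sqrt(2 * pi / n_directions)
  offsets <- as.matrix(expand.grid(a = -2:2, b = -2:2))
  for (delta in c(0.5, 0.12) * spacing) {
    for (i in seq_len(nrow(cand))) {
      u <- U[i, ]
      t1 <- c(-u[2], u[1], 0)
      if (sum(t1^2) < 1e-12) t1 <- c(1, 0, 0)
      t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(u[2] * t1[3] - u[3] * t1[2],
              u[3] * t1[1] - u[1] * t1[3],
              u[1] * t1[2] - u[2] * t1[1])
      local_dirs <- t(apply(offsets, 1, function(ab)
        u + delta * (ab[1] * t1 + ab[2] * t2)))
      local_dirs <- local_dirs / sqrt(rowSums(local_dirs^2))
      w <- cand$window[i]
      r <- dft_search_cpp(points, local_dirs,
                          windows[w, , drop = FALSE], step)
      best <- which.max(r$fom[, 1])
      if (r$fom[best, 1] > cand$fom[i]) {
        cand$fom[i] <- r$fom[best, 1]
        cand$length[i] <- r$length[best, 1]
        U[i, ] <- local_dirs[best, ]
      }
    }
  }
  tibble::tibble(vx = U[, 1] * cand$length,
                 vy = U[, 2] * cand$length,
                 vz = U[, 3] * cand$length,
                 length = cand$length, fom = cand$fom,
                 n_supporting = NA_integer_)
}

candidate_vectors <- function(cand) {
  cbind(cand$vx, cand$vy, cand$vz)
}

#' Squash a candidate-vector list
#'
#' Greedy de-duplication by descending figure of merit: a candidate is
#' discarded when it lies within `angle_tol` and `length_tol` of an already
#' kept one, treating `v` and `-v` as equal (the projection spectrum cannot
#' distinguish them).
#'
#' @param candidates candidate tibble (see [fft_vector_search()]).
#' @param angle_tol angular tolerance in degrees (default 3).
#' @param length_tol relative length tolerance (default 0.03).
#' @return the surviving candidates, ordered by descending figure of merit.
#' @export
squash_candidates <- function(candidates, angle_tol = 3, length_tol = 0.03) {
  if (nrow(candidates) <= 1) return(candidates)
  candidates <- candidates[order(-candidates$fom), ]
  V <- candidate_vectors(candidates)
  len <- sqrt(rowSums(V^2))
  U <- V / len
  keep <- logical(nrow(candidates))
  cosmax <- cos(angle_tol * pi / 180)
  for (i in seq_len(nrow(candidates))) {
    ki <- which(keep)
    if (!length(ki)) { keep[i] <- TRUE; next }
    cosang <- abs(U[ki, , drop = FALSE] %*% U[i, ])
    close <- cosang >= cosmax & abs(len[ki] - len[i]) <= length_tol * len[ki]
    keep[i] <- !any(close)
  }
  candidates[keep, ]
}

#' Refine a candidate lattice vector against the peak positions
#'
#' Iterative single-step refinement: peaks whose projection onto the current
#' vector lies within `inlier_tol` of an integer are selected as inliers and
#' the vector is updated by the least-squares fit of those projections to
#' their nearest integers (normal equations), repeating until the inlier set
#' is stable or `max_iter` iterations. Inlier gating keeps spurious peaks
#' out of the fit.
#'
#' @param v real-space lattice vector (length-3 numeric, angstrom).
#' @param points reciprocal peak positions (n x 3, 1/angstrom).
#' @param inlier_tol maximum distance of a projection from an integer, as a
#'   fraction of the spacing (default 0.2).
#' @param max_iter iteration cap (default 10).
#' @return list with `v` (refined vector), `n_supporting` (final inliers)
#'   and `refined` (FALSE when fewer than 3 inliers stopped refinement).
#' @export
refine_vector <- function(v, points, inlier_tol = 0.2, max_iter = 10) {
  stopifnot(sum(v^2) > 0)
  points <- as.matrix(points)
  len0 <- sqrt(sum(v^2))
  pass <- function(v, tol) {
    prev <- integer(0)
    for (it in seq_len(max_iter)) {
      t <- as.vector(points %*% v)
      m <- round(t)
      inl <- which(abs(t - m) <= tol)
      # need projections onto several distinct lattice planes, otherwise the
      # fit is degenerate (e.g. all m = 0 collapses v towards zero)
      if (length(inl) < 3 || length(unique(m[inl])) < 3)
        return(list(v = v, n = length(inl), ok = FALSE))
      P <- points[inl, , drop = FALSE]
      G <- crossprod(P)
      if (abs(det(G)) < 1e-12 * max(abs(G))^3)
        return(list(v = v, n = length(inl), ok = FALSE))
      v_new <- solve(G, crossprod(P, m[inl]))[, 1]
      if (sqrt(sum(v_new^2)) < 0.5 * len0)
        return(list(v = v, n = length(inl), ok = FALSE))
      stable <- identical(inl, prev)
      prev <- inl
      v <- v_new
      if (stable) break
    }
    t <- as.vector(points %*% v)
    list(v = v, n = sum(abs(t - round(t)) <= tol), ok = TRUE)
  }
  # anneal the inlier gate: tighter passes drop spurious peaks that slipped
  # inside the looser gate once the genuine peaks have pulled v into place
  r <- pass(v, inlier_tol)
  if (!r$ok) return(list(v = r$v, n_supporting = r$n, refined = FALSE))
  for (shrink in c(2, 4)) {
    r2 <- pass(r$v, inlier_tol / shrink)
    if (!r2$ok) break
    r <- r2
  }
  t <- as.vector(points %*% r$v)
  list(v = r$v, n_supporting = sum(abs(t - round(t)) <= inlier_tol),
       refined = TRUE)
}

# indexing residual bookkeeping for a real-space basis A (columns a, b, c)
count_indexed <- function(A, points, frac_tol = 0.25) {
  frac <- points %*% A           # h_i = a . q_i
  err <- abs(frac - round(frac))
  idx <- apply(err, 1, max) <= frac_tol
  list(n = sum(idx), residual = sum(err[idx, ]))
}

#' Assemble candidate vectors into an indexing solution
#'
#' Tries triples of candidate vectors (both signs each: the search cannot
#' tell `v` from `-v`) whose pairwise interaxial angles match the reference
#' cell within `angle_tol` and lengths within `length_tol`; left-handed
#' triples are rejected. Among acceptable triples the one indexing the most
#' peaks wins (a peak is indexed when its fractional Miller indices are all
#' within 0.25 of integers); ties break on the lowest summed residual.
#'
#' @param candidates (refined) candidate tibble.
#' @param reference known [unit_cell()].
#' @param points reciprocal peak positions (n x 3).
#' @param angle_tol interaxial-angle tolerance in degrees (default 1.5).
#' @param length_tol relative length tolerance (default 0.05).
#' @param max_candidates cap on candidates tried (default 12, by FOM).
#' @return An `sfx_solution`: list with `success`, reciprocal `basis`
#'   (columns a*, b*, c*, 1/angstrom), found `cell`, `n_indexed`, `n_peaks`.
#' @export
assemble_cell <- function(candidates, reference, points,
                          angle_tol = 1.5, length_tol = 0.05,
                          max_candidates = 12) {
  failed <- structure(list(success = FALSE, basis = NULL, cell = NULL,
                           n_indexed = 0L, n_peaks = nrow(points)),
                      class = "sfx_solution")
  if (nrow(candidates) < 3) return(failed)
  candidates <- candidates[order(-candidates$fom), ]
  candidates <- candidates[seq_len(min(max_candidates, nrow(candidates))), ]
  V <- candidate_vectors(candidates)
  nc <- nrow(V)
  best <- NULL
  for (i in 1:(nc - 2)) for (j in (i + 1):(nc - 1)) for (k in (j + 1):nc) {
    for (s in 0:7) {
      A <- cbind(V[i, ] * (1 - 2 * bitwAnd(s, 1)),
                 V[j, ] * (1 - 2 * (bitwAnd(s, 2) / 2)),
                 V[k, ] * (1 - 2 * (bitwAnd(s, 4) / 4)))
      lens2 <- colSums(A^2)
      if (any(lens2 < 1e-6)) next
      # normalized determinant = sqrt of the reduced metric determinant;
      # near-coplanar triples make a degenerate cell whose parameter
      # reconstruction is numerically meaningless
      if (det(A) / prod(sqrt(lens2)) <= 0.05) next
      cand_cell <- basis_to_cell(A)
      cmp <- compare_cell(cand_cell, reference,
                          length_tol = length_tol, angle_tol = angle_tol)
      if (!cmp$matches) next
      A_ord <- A %*% cmp$transform
      if (det(A_ord) <= 0) next
      cnt <- count_indexed(A_ord, points)
      if (is.null(best) || cnt$n > best$n ||
          (cnt$n == best$n && cnt$residual < best$residual)) {
        best <- list(A = A_ord, n = cnt$n, residual = cnt$residual)
      }
    }
  }
  if (is.null(best)) return(failed)
  structure(list(success = TRUE,
                 basis = t(solve(best$A)),
                 cell = basis_to_cell(best$A,
                                      lattice_type = reference$lattice_type),
                 n_indexed = as.integer(best$n),
                 n_peaks = nrow(points)),
            class = "sfx_solution")
}

#' @export
print.sfx_solution <- function(x, ...) {
  if (!x$success) {
    cat(sprintf("<sfx_solution> FAILED (%d peaks)\n", x$n_peaks))
  } else {
    cat(sprintf("<sfx_solution> indexed %d / %d peaks\n", x$n_indexed, x$n_peaks))
    print(x$cell)
  }
  invisible(x)
}

#' Indexing configuration
#'
#' @param length_tol search-window / assembly relative length tolerance.
#' @param angle_tol interaxial angle tolerance, degrees.
#' @param n_directions hemisphere sampling density of the vector search.
#' @param step length-sweep step, angstrom.
#' @param inlier_tol refinement inlier gate (fraction of a spacing).
#' @param min_peaks minimum peaks required to attempt indexing.
#' @param min_indexed_frac fraction of peaks that must be indexed for
#'   success (default 0.5).
#' @return list of settings for [index_pattern()].
#' @export
index_config <- function(length_tol = 0.10, angle_tol = 1.5,
                         n_directions = 7300, step = 0.25,
                         inlier_tol = 0.2, min_peaks = 10,
                         min_indexed_frac = 0.5) {
  list(length_tol = length_tol, angle_tol = angle_tol,
       n_directions = n_directions, step = step, inlier_tol = inlier_tol,
       min_peaks = min_peaks, min_indexed_frac = min_indexed_frac)
}

#' Index one still pattern against a known cell
#'
#' Composes the full autoindexing chain: Ewald mapping, direction search,
#' squashing, iterative refinement, and cell assembly. Success additionally
#' requires the found cell to match the reference
#' (enforced during assembly) and at least `min_indexed_frac` of the peaks
#' to be indexed.
#'
#' @param peaks peak tibble (`fast`, `slow`) or an n x 3 matrix of
#'   reciprocal positions.
#' @param geom,beam geometry and beam (ignored when `peaks` is already in
#'   reciprocal space).
#' @param reference known [unit_cell()].
#' @param config settings from [index_config()].
#' @return An `sfx_solution`.
#' @export
index_pattern <- function(peaks, geom = NULL, beam = NULL, reference,
                          config = index_config()) {
  points <- if (is.matrix(peaks)) peaks
            else map_peaks_to_ewald(peaks, geom, beam$wavelength)
  failed <- structure(list(success = FALSE, basis = NULL, cell = NULL,
                           n_indexed = 0L, n_peaks = nrow(points)),
                      class = "sfx_solution")
  if (nrow(points) < config$min_peaks) return(failed)
  cand <- fft_vector_search(points, reference,
                            length_tol = config$length_tol,
                            n_directions = config$n_directions,
                            step = config$step)
  if (nrow(cand) == 0) return(failed)
  cand <- squash_candidates(cand)
  ref <- purrr::map(seq_len(nrow(cand)), function(i) {
    refine_vector(c(cand$vx[i], cand$vy[i], cand$vz[i]), points,
                  inlier_tol = config$inlier_tol)
  })
  cand$vx <- vapply(ref, function(r) r$v[1], 0)
  cand$vy <- vapply(ref, function(r) r$v[2], 0)
  cand$vz <- vapply(ref, function(r) r$v[3], 0)
  cand$length <- sqrt(cand$vx^2 + cand$vy^2 + cand$vz^2)
  cand$n_supporting <- vapply(ref, function(r) as.integer(r$n_supporting), 0L)
  cand$refined <- vapply(ref, function(r) isTRUE(r$refined), TRUE)
  lens <- cell_lengths(reference)
  keep <- cand$refined &
    cand$length >= (1 - 2 * config$length_tol) * min(lens) &
    cand$length <= (1 + 2 * config$length_tol) * max(lens)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(failed)
  cand <- squash_candidates(cand)
  sol <- assemble_cell(cand, reference, points,
                       angle_tol = config$angle_tol,
                       length_tol = config$length_tol)
  if (sol$success && sol$n_indexed < config$min_indexed_frac * nrow(points)) {
    sol$success <- FALSE
  }
  sol
}

#' Indexing yield
#'
#' @param solutions list of `sfx_solution` objects.
#' @return fraction of patterns successfully indexed.
#' @export
indexing_yield <- function(solutions) {
  if (!length(solutions)) stop("no patterns: yield undefined", call. = FALSE)
  mean(vapply(solutions, function(s) isTRUE(s$success), TRUE))
}

#' Histograms of recovered lattice parameters
#'
#' Cell-parameter histograms over the successfully indexed patterns; the
#' sharpness of each histogram (fraction of solutions in the modal bin) is
#' the standard diagnostic for the accuracy of the experimental geometry.
#'
#' @param solutions list of `sfx_solution` objects.
#' @param bins number of bins (default 30).
#' @return tibble with `parameter`, `mid`, `count`; modal-bin fractions in
#'   attribute `"mode_fraction"`.
#' @export
cell_parameter_histograms <- function(solutions, bins = 30) {
  ok <- purrr::keep(solutions, function(s) isTRUE(s$success))
  if (!length(ok)) stop("no successful solutions", call. = FALSE)
  vals <- purrr::map_dfr(ok, function(s) {
    tibble::tibble(parameter = c("a", "b", "c", "alpha", "beta", "gamma"),
                   value = c(cell_lengths(s$cell), cell_angles(s$cell)))
  })
  out <- vals |>
    dplyr::group_by(.data$parameter) |>
    dplyr::reframe({
      v <- .data$value
      rng <- range(v)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(1e-3, abs(rng[1]) * 1e-3)
      br <- seq(rng[1], rng[2], length.out = bins + 1)
      cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                                   all.inside = TRUE), nbins = bins)
      tibble::tibble(mid = (br[-1] + br[-(bins + 1)]) / 2, count = cnt)
    })
  mode_frac <- out |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(frac = max(.data$count) / sum(.data$count)) |>
    tibble::deframe()
  attr(out, "mode_fraction") <- mode_frac
  out
}
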