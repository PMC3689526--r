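#' Chiral point groups
#'
#' Integer rotation-matrix representations, in the conventional lattice
#' basis, of the chiral (rotation-only) point groups relevant to biological
#' crystallography: 1, 2, 222, 4, 422, 3, 312, 321, 32, 6, 622, 23 and 432.
#' Trigonal groups exist in two settings: `"3"` defaults to hexagonal axes
#' and `"32"` to rhombohedral axes; pass `setting` to override. Every group
#' is generated from its generators and verified closed, identity-containing
#' and of determinant +1 at construction.
#'
#' @param name Hermann-Mauguin symbol as a string.
#' @param setting `"hexagonal"` or `"rhombohedral"` for the trigonal groups;
#'   ignored otherwise.
#' @return An object of class `sfx_point_group`: list with `name`, `setting`
#'   and `ops` (list of integer 3x3 matrices; identity first).
#' @examples
#' point_group("422")
#' @export
point_group <- function(name, setting = NULL) {
  m <- function(...) matrix(as.integer(c(...)), 3, byrow = TRUE)
  Rz4 <- m(0, -1, 0, 1, 0, 0, 0, 0, 1)          # 4-fold about c
  R3h <- m(0, -1, 0, 1, -1, 0, 0, 0, 1)          # 3-fold, hexagonal axes
  R6h <- m(1, -1, 0, 1, 0, 0, 0, 0, 1)           # 6-fold, hexagonal axes
  two_a_hex <- m(1, -1, 0, 0, -1, 0, 0, 0, -1)   # 2-fold along a (hex)
  two_ab_hex <- m(0, -1, 0, -1, 0, 0, 0, 0, -1)  # 2-fold perpendicular setting
  cyc <- m(0, 0, 1, 1, 0, 0, 0, 1, 0)            # 3-fold along [111]
  two_r <- m(0, -1, 0, -1, 0, 0, 0, 0, -1)       # 2-fold, rhombohedral axes
  trigonal <- name %in% c("3", "32")
  if (is.null(setting)) setting <- if (name == "32") "rhombohedral" else "hexagonal"
  if (trigonal) setting <- match.arg(setting, c("hexagonal", "rhombohedral"))
  gens <- switch(name,
    "1"   = list(),
    "2"   = list(diag(c(-1L, 1L, -1L))),
    "222" = list(diag(c(-1L, -1L, 1L)), diag(c(1L, -1L, -1L))),
    "4"   = list(Rz4),
    "422" = list(Rz4, diag(c(1L, -1L, -1L))),
    "3"   = if (setting == "hexagonal") list(R3h) else list(cyc),
    "312" = list(R3h, two_ab_hex),
    "321" = list(R3h, two_a_hex),
    "32"  = if (setting == "rhombohedral") list(cyc, two_r) else list(R3h, two_a_hex),
    "6"   = list(R6h),
    "622" = list(R6h, two_a_hex),
    "23"  = list(diag(c(-1L, -1L, 1L)), cyc),
    "432" = list(diag(c(-1L, -1L, 1L)), cyc, Rz4),
    stop("unknown point group: ", name, call. = FALSE))
  ops <- close_group(gens)
  pg <- structure(list(name = name,
                       setting = if (trigonal || name %in% c("312", "321")) setting else NA_character_,
                       ops = ops),
                  class = "sfx_point_group")
  validate_point_group(pg)
  pg
}

# generate the closure of a generator list under matrix multiplication
close_group <- function(gens) {
  key <- function(M) paste(as.integer(M), collapse = ",")
  ops <- list(diag(3L))
  seen <- key(ops[[1]])
  queue <- gens
  while (length(queue)) {
    M <- queue[[1]]; queue <- queue[-1]
    if (key(M) %in% seen) next
    ops[[length(ops) + 1]] <- M
    seen <- c(seen, key(M))
    for (N in ops) {
      queue <- c(queue, list(M %*% N), list(N %*% M))
    }
  }
  ops
}

validate_point_group <- function(pg) {
  key <- function(M) paste(as.integer(M), collapse = ",")
  keys <- vapply(pg$ops, key, "")
  if (anyDuplicated(keys)) stop("duplicate operations in point group", call. = FALSE)
  if (!key(diag(3L)) %in% keys) stop("point group lacks identity", call. = FALSE)
  for (M in pg$ops) {
    if (abs(det(M) - 1) > 1e-9)
      stop("point-group operation with determinant != +1", call. = FALSE)
  }
  for (M in pg$ops) for (N in pg$ops) {
    if (!key(M %*% N) %in% keys)
      stop("point group not closed under multiplication", call. = FALSE)
  }
  invisible(pg)
}

#' @export
print.sfx_point_group <- function(x, ...) {
  set <- if (!is.na(x$setting)) paste0(" (", x$setting, " axes)") else ""
  cat(sprintf("<sfx_point_group> %s%s, order %d\n", x$name, set, length(x$ops)))
  invisible(x)
}

pg_order <- function(pg) length(pg$ops)

pg_contains <- function(high, low) {
  key <- function(M) paste(as.integer(M), collapse = ",")
  all(vapply(low$ops, key, "") %in% vapply(high$ops, key, ""))
}

pg_same_ops <- function(a, b) pg_order(a) == pg_order(b) && pg_contains(a, b)

#' Proper holohedry of a lattice type
#'
#' The rotational (chiral) part of the full lattice symmetry: the point group
#' an orientation-blind indexer cannot see beyond, and hence the merging
#' symmetry that appears when an indexing ambiguity goes unresolved.
#'
#' @param lattice_type lattice system name (see [unit_cell()]).
#' @return An [point_group()].
#' @export
proper_holohedry <- function(lattice_type) {
  name <- switch(match.arg(lattice_type, sfx_lattice_types()),
                 triclinic = "1", monoclinic = "2", orthorhombic = "222",
                 tetragonal = "422", rhombohedral = "32", hexagonal = "622",
                 cubic = "432")
  setting <- if (name == "32") "rhombohedral" else if (name == "622") "hexagonal" else NULL
  point_group(name, setting = setting)
}

#' Left coset decomposition
#'
#' Decomposes `high` into left cosets of its subgroup `low`; the non-identity
#' coset representatives are the indexing-ambiguity (apparent twin)
#' operators.
#'
#' @param high,low [point_group()] objects; `low` must be a subgroup of
#'   `high` (verified).
#' @return list of integer 3x3 representative matrices, identity first, of
#'   length `order(high) / order(low)`.
#' @export
left_coset_decomposition <- function(high, low) {
  if (!pg_contains(high, low))
    stop(sprintf("%s is not a subgroup of %s", low$name, high$name), call. = FALSE)
  key <- function(M) paste(as.integer(M), collapse = ",")
  assigned <- character(0)
  reps <- list()
  # identity first, then remaining ops in stored order
  ord <- c(which(vapply(high$ops, function(M) all(M == diag(3L)), TRUE)),
           seq_along(high$ops))
  for (i in unique(ord)) {
    g <- high$ops[[i]]
    if (key(g) %in% assigned) next
    reps[[length(reps) + 1]] <- g
    coset <- lapply(low$ops, function(s) g %*% s)
    assigned <- c(assigned, vapply(coset, key, ""))
  }
  if (length(reps) * pg_order(low) != pg_order(high))
    stop("coset decomposition failed to partition the group", call. = FALSE)
  reps
}

#' Apparent merging point group under indexing ambiguity
#'
#' For a structure with true point group `true_pg` on a lattice of type
#' `lattice_type`, unresolved indexing ambiguities make the merged data
#' appear to have the symmetry of the lattice's proper holohedry whenever
#' the true group is a proper subgroup of it; otherwise no exact ambiguity
#' exists and the apparent group equals the true group.
#'
#' @param true_pg a [point_group()] or a Hermann-Mauguin name (built in the
#'   lattice-appropriate setting when a name is given).
#' @param lattice_type lattice system name.
#' @return An [point_group()]: the symmetry to merge under.
#' @examples
#' apparent_point_group("321", "hexagonal")$name   # "622"
#' @export
apparent_point_group <- function(true_pg, lattice_type) {
  lattice_type <- match.arg(lattice_type, sfx_lattice_types())
  if (is.character(true_pg)) {
    setting <- if (lattice_type == "rhombohedral") "rhombohedral"
               else if (lattice_type == "hexagonal") "hexagonal" else NULL
    true_pg <- point_group(true_pg, setting = setting)
  }
  holo <- proper_holohedry(lattice_type)
  if (!pg_contains(holo, true_pg))
    stop(sprintf("point group %s is not compatible with a %s lattice",
                 true_pg$name, lattice_type), call. = FALSE)
  if (pg_order(true_pg) < pg_order(holo)) holo else true_pg
}

#' Lattice rotations that map a metric tensor onto itself
#'
#' Detects approximate (metric-accidental) indexing ambiguities: a proper
#' signed axis permutation is admitted when it maps the cell's metric tensor
#' to itself within the given tolerances, even though it is not an operation
#' of the structure's point group. Exact ambiguities come from the group
#' tables ([apparent_point_group()]); this check catches cells that only
#' accidentally look more symmetric (e.g. a monoclinic cell with beta near
#' 90 degrees).
#'
#' @param cell an [unit_cell()].
#' @param length_tol relative tolerance on lengths (default 0.05).
#' @param angle_tol tolerance on angles in degrees (default 1.5).
#' @param exclude optional [point_group()] whose operations (the structure's
#'   own symmetry, which trivially preserves the metric) are not reported.
#' @return list of integer 3x3 matrices (identity excluded).
#' @export
metric_ambiguities <- function(cell, length_tol = 0.05, angle_tol = 1.5,
                               exclude = NULL) {
  A <- cell_basis(cell)
  key <- function(M) paste(as.integer(M), collapse = ",")
  skip <- if (!is.null(exclude)) vapply(exclude$ops, key, "") else character()
  out <- list()
  for (M in proper_axis_transforms()) {
    if (all(M == diag(3)) || key(round(M)) %in% skip) next
    cand <- basis_to_cell(A %*% M)
    if (all(abs(cell_lengths(cand) - cell_lengths(cell)) <=
            length_tol * cell_lengths(cell)) &&
        all(abs(cell_angles(cand) - cell_angles(cell)) <= angle_tol))
      out[[length(out) + 1]] <- round(M)
  }
  out
}

# canonical representative of the orbit of each (h,k,l) under a point group:
# the lexicographically greatest image (h first, then k, then l), with the
# Friedel-expanded orbit when `friedel` is TRUE.
canonical_hkl <- function(h, k, l, pg, friedel = TRUE) {
  K <- 4096
  enc <- function(h, k, l) ((h + 2048) * K + (k + 2048)) * K + (l + 2048)
  ops <- pg$ops
  best <- rep(-Inf, length(h))
  hkl <- cbind(h, k, l)
  for (M in ops) {
    img <- hkl %*% t(M)
    best <- pmax(best, enc(img[, 1], img[, 2], img[, 3]))
    if (friedel) best <- pmax(best, enc(-img[, 1], -img[, 2], -img[, 3]))
  }
  l2 <- best %% K; rest <- (best - l2) / K
  k2 <- rest %% K; h2 <- (rest - k2) / K
  cbind(h = h2 - 2048, k = k2 - 2048, l = l2 - 2048)
}

#' Monte-Carlo merge of reflection intensities
#'
#' Maps every observation to the canonical symmetrically unique reflection
#' under `pg` (Friedel mates merged unless `anomalous`) and takes the mean of
#' all observations of each unique reflection. The standard error of the
#' mean is the sample SD over sqrt(n) when n >= 2, else the observation's own
#' sigma.
#'
#' @param reflections a reflection tibble (columns `h`, `k`, `l`, `I` and
#'   optionally `sigma`) or a list of such tibbles (one per pattern).
#' @param pg a [point_group()] or Hermann-Mauguin name.
#' @param anomalous keep Friedel mates separate? (default FALSE)
#' @return tibble of class `sfx_merged` with columns `h`, `k`, `l`, `I`,
#'   `sigma`, `n_obs`; attributes `point_group` and `anomalous`.
#' @export
merge_intensities <- function(reflections, pg, anomalous = FALSE) {
  if (is.character(pg)) pg <- point_group(pg)
  if (is.data.frame(reflections)) reflections <- list(reflections)
  if (!length(reflections)) stop("no reflection lists to merge", call. = FALSE)
  obs <- dplyr::bind_rows(reflections)
  if (!"sigma" %in% names(obs)) obs$sigma <- NA_real_
  can <- canonical_hkl(obs$h, obs$k, obs$l, pg, friedel = !anomalous)
  obs$h <- can[, 1]; obs$k <- can[, 2]; obs$l <- can[, 3]
  out <- obs |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(
      sigma = ifelse(dplyr::n() >= 2,
                     stats::sd(.data$I) / sqrt(dplyr::n()),
                     .data$sigma[1]),
      I = mean(.data$I),
      n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::select("h", "k", "l", "I", "sigma", "n_obs")
  attr(out, "point_group") <- pg$name
  attr(out, "anomalous") <- anomalous
  class(out) <- c("sfx_merged", class(out))
  out
}

#' Half-data-set agreement statistic R_split
#'
#' Agreement between intensities merged from the odd- and even-numbered
#' halves of a data set:
#' `R_split = 2^(-1/2) * sum |I1 - I2| / (0.5 * sum (I1 + I2))`
#' over the unique reflections common to both halves.
#'
#' @param half1,half2 merged-intensity tibbles (see [merge_intensities()]).
#' @return one-row tibble with `r_split` (fraction) and `n_common`.
#' @export
r_split <- function(half1, half2) {
  common <- dplyr::inner_join(
    tibble::as_tibble(half1)[, c("h", "k", "l", "I")],
    tibble::as_tibble(half2)[, c("h", "k", "l", "I")],
    by = c("h", "k", "l"), suffix = c("1", "2"))
  if (nrow(common) == 0)
    stop("no unique reflections common to both halves", call. = FALSE)
  tibble::tibble(
    r_split = sum(abs(common$I1 - common$I2)) /
      (sqrt(2) * 0.5 * sum(common$I1 + common$I2)),
    n_common = nrow(common))
}

#' Simulate Bijvoet pairs with anomalous differences
#'
#' Convenience generator for [anomalous_mixing_factor()]: mean intensities
#' are exponential (Wilson-like) and each pair's anomalous difference is
#' Gaussian with RMS `anom_frac` times the mean intensity.
#'
#' @param n_pairs number of Bijvoet pairs.
#' @param mean_I mean intensity (arbitrary units).
#' @param anom_frac RMS anomalous difference as a fraction of `mean_I`.
#' @return tibble with columns `I_plus`, `I_minus`.
#' @export
simulate_bijvoet_pairs <- function(n_pairs, mean_I = 500, anom_frac = 0.05) {
  base <- stats::rexp(n_pairs, rate = 1 / mean_I)
  d <- stats::rnorm(n_pairs, 0, anom_frac * mean_I)
  tibble::tibble(I_plus = base + d / 2, I_minus = base - d / 2)
}

#' Anomalous-signal loss under indexing-ambiguity mixing
#'
#' When an unresolved two-fold indexing ambiguity mixes each reflection with
#' an unrelated partner, a pattern indexed in the wrong orientation
#' contributes the partner's Bijvoet intensities in place of the true ones
#' (never the Friedel opposite: ambiguities cannot invert hands). Merging
#' many patterns, each wrongly oriented with probability `mixing`, averages
#' the two pairs' anomalous differences; at 50/50 mixing the RMS anomalous
#' difference drops by a factor of sqrt(2).
#'
#' @param pairs tibble with `I_plus`, `I_minus` (see
#'   [simulate_bijvoet_pairs()]); consecutive rows are ambiguity partners.
#' @param mixing probability a pattern is indexed in the wrong orientation.
#' @param n_obs patterns merged per reflection (default 100).
#' @return ratio of the RMS true anomalous difference to the RMS merged
#'   anomalous difference (>= 1; sqrt(2) at `mixing = 0.5`).
#' @export
anomalous_mixing_factor <- function(pairs, mixing = 0.5, n_obs = 100) {
  n <- nrow(pairs)
  if (n < 2) stop("need at least two Bijvoet pairs", call. = FALSE)
  if (n %% 2 == 1) { pairs <- pairs[-n, ]; n <- n - 1 }
  d <- pairs$I_plus - pairs$I_minus
  if (all(d == 0))
    stop("anomalous differences are all zero: ratio undefined", call. = FALSE)
  partner <- as.vector(rbind(seq(2, n, 2), seq(1, n, 2)))  # 1<->2, 3<->4, ...
  m <- stats::rbinom(n, n_obs, mixing)
  d_merged <- ((n_obs - m) * d + m * d[partner]) / n_obs
  sqrt(mean(d^2) / mean(d_merged^2))
}
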