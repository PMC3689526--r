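#' Unit cell
#'
#' A crystallographic unit cell with optional lattice-type tag. Lengths in
#' angstroms, angles in degrees.
#'
#' @param a,b,c axis lengths (angstrom), all positive.
#' @param alpha,beta,gamma interaxial angles (degrees), each in (0, 180).
#' @param lattice_type one of `"triclinic"`, `"monoclinic"`, `"orthorhombic"`,
#'   `"tetragonal"`, `"rhombohedral"`, `"hexagonal"`, `"cubic"`.
#' @return An object of class `sfx_cell`.
#' @examples
#' unit_cell(68.17, 68.17, 108.26, lattice_type = "tetragonal")
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90,
                      lattice_type = "triclinic") {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180, gamma > 0, gamma < 180)
  d <- pi / 180
  ca <- cos(alpha * d); cb <- cos(beta * d); cg <- cos(gamma * d)
  if (1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg <= 0)
    stop("angle triple does not describe a realizable (non-degenerate) cell",
         call. = FALSE)
  lattice_type <- match.arg(lattice_type, sfx_lattice_types())
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
                 lattice_type = lattice_type), class = "sfx_cell")
}

sfx_lattice_types <- function() {
  c("triclinic", "monoclinic", "orthorhombic", "tetragonal",
    "rhombohedral", "hexagonal", "cubic")
}

#' @export
print.sfx_cell <- function(x, ...) {
  cat(sprintf("<sfx_cell> %s  a=%.3f b=%.3f c=%.3f A  al=%.2f be=%.2f ga=%.2f deg\n",
              x$lattice_type, x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Real-space basis matrix of a cell (columns a, b, c; angstrom)
#'
#' Standard orientation: a along x, b in the xy plane. The basis is
#' right-handed (positive determinant).
#'
#' @param cell an [unit_cell()].
#' @return 3x3 numeric matrix with the axis vectors as columns.
#' @export
cell_basis <- function(cell) {
  d <- pi / 180
  ca <- cos(cell$alpha * d); cb <- cos(cell$beta * d); cg <- cos(cell$gamma * d)
  sg <- sin(cell$gamma * d)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg),
         nrow = 3)
}

#' Reciprocal basis of a cell (columns a*, b*, c*; 1/angstrom)
#'
#' Crystallographic convention without 2*pi: `t(A) %*% reciprocal_basis(cell)`
#' is the identity for `A = cell_basis(cell)`.
#'
#' @inheritParams cell_basis
#' @return 3x3 numeric matrix.
#' @export
reciprocal_basis <- function(cell) {
  t(solve(cell_basis(cell)))
}

#' Cell parameters from a real-space basis matrix
#'
#' @param A 3x3 matrix with real-space axis vectors as columns (angstrom).
#' @param lattice_type optional tag for the returned cell.
#' @return An [unit_cell()].
#' @export
basis_to_cell <- function(A, lattice_type = "triclinic") {
  len <- sqrt(colSums(A^2))
  ang <- function(u, v) acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  unit_cell(len[1], len[2], len[3],
            alpha = ang(A[, 2], A[, 3]),
            beta  = ang(A[, 1], A[, 3]),
            gamma = ang(A[, 1], A[, 2]),
            lattice_type = lattice_type)
}

cell_lengths <- function(cell) c(cell$a, cell$b, cell$c)
cell_angles <- function(cell) c(cell$alpha, cell$beta, cell$gamma)

# the 24 proper (det = +1) signed axis permutations
proper_axis_transforms <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    P <- diag(3)[, p]
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      M <- P %*% diag(c(s1, s2, s3))
      if (det(M) > 0) out[[length(out) + 1]] <- M
    }
  }
  out
}

#' Compare a found cell against reference parameters
#'
#' Tries the identity and every proper signed axis permutation; the cells
#' match if some transform brings all three lengths within `length_tol`
#' (relative) and all angles within `angle_tol` degrees of the reference.
#'
#' @param found,reference [unit_cell()] objects.
#' @param length_tol relative length tolerance (default 0.05).
#' @param angle_tol angle tolerance in degrees (default 1.5).
#' @return list with `matches` (logical) and `transform` (integer 3x3 matrix
#'   mapping found axes to reference order, or `NULL` when no match).
#' @export
compare_cell <- function(found, reference, length_tol = 0.05, angle_tol = 1.5) {
  A <- cell_basis(found)
  ref_len <- cell_lengths(reference)
  ref_ang <- cell_angles(reference)
  for (M in proper_axis_transforms()) {
    cand <- basis_to_cell(A %*% M)
    if (all(abs(cell_lengths(cand) - ref_len) <= length_tol * ref_len) &&
        all(abs(cell_angles(cand) - ref_ang) <= angle_tol)) {
      return(list(matches = TRUE, transform = round(M)))
    }
  }
  list(matches = FALSE, transform = NULL)
}

#' Read a reference cell from a one-line text file
#'
#' Format: `a b c alpha beta gamma lattice_type` (whitespace separated;
#' comment lines starting with `#` ignored).
#'
#' @param path file path.
#' @return An [unit_cell()].
#' @export
read_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  if (!length(lines)) stop("no cell record in ", path, call. = FALSE)
  tok <- strsplit(lines[[1]], "\\s+")[[1]]
  if (length(tok) < 7) stop("cell line needs 'a b c alpha beta gamma lattice_type'",
                            call. = FALSE)
  unit_cell(as.numeric(tok[1]), as.numeric(tok[2]), as.numeric(tok[3]),
            as.numeric(tok[4]), as.numeric(tok[5]), as.numeric(tok[6]),
            lattice_type = tok[7])
}

#' @param cell cell to write.
#' @rdname read_cell
#' @export
write_cell <- function(cell, path) {
  writeLines(sprintf("%.6f %.6f %.6f %.4f %.4f %.4f %s",
                     cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                     cell$lattice_type), path)
  invisible(path)
}
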