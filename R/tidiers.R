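#' Tidy an indexing solution
#'
#' One row per reciprocal basis vector with its components and length.
#'
#' @param x an `sfx_solution`.
#' @param ... unused.
#' @return tibble with `vector`, `qx`, `qy`, `qz`, `length_invA`.
#' @exportS3Method generics::tidy
tidy.sfx_solution <- function(x, ...) {
  if (!isTRUE(x$success)) {
    return(tibble::tibble(vector = character(), qx = numeric(),
                          qy = numeric(), qz = numeric(),
                          length_invA = numeric()))
  }
  B <- x$basis
  tibble::tibble(vector = c("a*", "b*", "c*"),
                 qx = B[1, ], qy = B[2, ], qz = B[3, ],
                 length_invA = sqrt(colSums(B^2)))
}

#' @rdname tidy.sfx_solution
#' @return `glance()`: one-row tibble with the found cell parameters,
#'   `n_indexed`, `n_peaks` and `success`.
#' @exportS3Method generics::glance
glance.sfx_solution <- function(x, ...) {
  if (!isTRUE(x$success)) {
    return(tibble::tibble(a = NA_real_, b = NA_real_, c = NA_real_,
                          alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                          n_indexed = x$n_indexed, n_peaks = x$n_peaks,
                          success = FALSE))
  }
  tibble::tibble(a = x$cell$a, b = x$cell$b, c = x$cell$c,
                 alpha = x$cell$alpha, beta = x$cell$beta,
                 gamma = x$cell$gamma,
                 n_indexed = x$n_indexed, n_peaks = x$n_peaks,
                 success = TRUE)
}

#' Tidy merged intensities
#'
#' @param x an `sfx_merged` tibble.
#' @param ... unused.
#' @return the underlying tibble (h, k, l, I, sigma, n_obs).
#' @exportS3Method generics::tidy
tidy.sfx_merged <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "sfx_merged")
  out
}

#' @rdname tidy.sfx_merged
#' @return `glance()`: one-row summary (unique reflections, observations,
#'   mean multiplicity, merging point group).
#' @exportS3Method generics::glance
glance.sfx_merged <- function(x, ...) {
  tibble::tibble(n_unique = nrow(x),
                 n_obs = sum(x$n_obs),
                 multiplicity = mean(x$n_obs),
                 point_group = attr(x, "point_group") %||% NA_character_,
                 anomalous = isTRUE(attr(x, "anomalous")))
}
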