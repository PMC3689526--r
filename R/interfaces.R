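#' Run configuration
#'
#' A validated bag of pipeline parameters with provenance: every value is
#' tagged as a default or user-set, unknown keys are rejected, and the whole
#' configuration is echoed into the headers of output files so any result
#' can be reproduced from its own header.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `sfx_config` with attributes `provenance`.
#' @export
run_config <- function(...) {
  defaults <- list(
    median_box = 5, saturation = 65534, floor = -500,
    peak_threshold = NA_real_, min_pix = 2, max_pix = 40, min_snr = 6,
    min_peaks = 25, hit_block = 3600,
    length_tol = 0.10, angle_tol = 1.5, n_directions = 7300,
    inlier_tol = 0.2, min_indexed_frac = 0.5,
    r_peak = 3, r_gap = 4, r_bg = 5, gain = 1,
    profile_r = 3e-4, point_group = "422", anomalous = FALSE,
    seed = 1L)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  prov <- ifelse(names(cfg) %in% names(user), "user", "default")
  names(prov) <- names(cfg)
  structure(cfg, provenance = prov, class = "sfx_config")
}

config_header_lines <- function(cfg) {
  prov <- attr(cfg, "provenance")
  vapply(names(unclass(cfg)), function(k) {
    sprintf("config: %s = %s [%s]", k, format(cfg[[k]]), prov[[k]])
  }, "")
}

#' @export
print.sfx_config <- function(x, ...) {
  cat("<sfx_config>\n")
  cat(paste0("  ", config_header_lines(x)), sep = "\n")
  invisible(x)
}

#' Write / read a frame stack
#'
#' On-disk container for detector frames: a directory holding one serialized
#' record per frame plus a JSON manifest (`meta.json`) with the stack shape.
#' The reader streams frame by frame, so arbitrarily long stacks are
#' processed with bounded memory.
#'
#' @param frames list of [sfx_frame()] objects.
#' @param path directory to create/read.
#' @return `write_frame_stack()` returns `path` invisibly.
#' @export
write_frame_stack <- function(frames, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(frames[[1]]$data)
  meta <- list(n_frames = length(frames), n_fast = d[1], n_slow = d[2],
               format = "serialx-frame-stack-v1")
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  for (i in seq_along(frames)) {
    saveRDS(frames[[i]], file.path(path, sprintf("frame_%06d.rds", i)))
  }
  invisible(path)
}

#' @param max_resident contract check: the iterator holds at most this many
#'   frames in memory (informational; the implementation holds one).
#' @rdname write_frame_stack
#' @return `read_frames()` returns a zero-argument function; each call
#'   yields the next [sfx_frame()] or `NULL` after the last.
#' @export
read_frames <- function(path, max_resident = 2) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a frame stack: missing meta.json in ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path)
  if (is.null(meta$n_frames) || !identical(meta$format, "serialx-frame-stack-v1"))
    stop("frame-stack manifest missing required fields (n_frames, format)",
         call. = FALSE)
  n <- meta$n_frames
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > n) return(NULL)
    f <- file.path(path, sprintf("frame_%06d.rds", i))
    if (!file.exists(f))
      stop("frame stack truncated: missing record ", basename(f), call. = FALSE)
    readRDS(f)
  }
}

#' Write / read a reflection list
#'
#' Plain-text tab-separated reflection format: `#`-prefixed header lines
#' (free-form, typically the run configuration and geometry echo), one
#' column-name line, then rows `h k l I sigma N fast slow panel`. Numeric
#' formatting is locale-independent.
#'
#' @param reflections reflection tibble (see [integrate_pattern()]).
#' @param path file path.
#' @param header character vector of header lines (without the leading
#'   `"# "`).
#' @return `write_reflections()` returns `path` invisibly;
#'   `read_reflections()` returns the reflection tibble with the header in
#'   attribute `"header"`.
#' @export
write_reflections <- function(reflections, path, header = character()) {
  cols <- c("h", "k", "l", "I", "sigma", "N", "fast", "slow", "panel")
  for (c in setdiff(cols, names(reflections)))
    reflections[[c]] <- if (c %in% c("N", "panel")) NA_integer_ else NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(reflections)) {
    rows <- sprintf("%d\t%d\t%d\t%.8g\t%.8g\t%d\t%.4f\t%.4f\t%d",
                    reflections$h, reflections$k, reflections$l,
                    reflections$I, reflections$sigma, reflections$N,
                    reflections$fast, reflections$slow, reflections$panel)
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_reflections
#' @export
read_reflections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_header <- grepl("^#", lines)
  header <- sub("^#\\s?", "", lines[is_header])
  body <- lines[!is_header]
  if (!length(body)) stop("no column line in ", path, call. = FALSE)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  out <- if (!length(rows)) {
    stats::setNames(as.data.frame(matrix(numeric(), 0, length(cols))), cols)
  } else {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != length(cols))
    if (length(bad)) {
      line_no <- which(!is_header)[-1][bad[1]]
      stop(sprintf("malformed reflection row at line %d of %s", line_no, path),
           call. = FALSE)
    }
    m <- do.call(rbind, parts)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- cols
    for (c in cols) {
      v <- suppressWarnings(as.numeric(df[[c]]))
      if (any(is.na(v) & nzchar(df[[c]]) & df[[c]] != "NA")) {
        line_no <- which(!is_header)[-1][which(is.na(v))[1]]
        stop(sprintf("non-numeric value in column %s at line %d of %s",
                     c, line_no, path), call. = FALSE)
      }
      df[[c]] <- if (c %in% c("h", "k", "l", "N", "panel")) as.integer(v) else v
    }
    df
  }
  out <- tibble::as_tibble(out)
  attr(out, "header") <- header
  out
}

#' Write / read merged intensities
#'
#' Text hkl format: header lines name the merging point group, then rows
#' `h k l I sigma nmeas`.
#'
#' @param merged an `sfx_merged` tibble (see [merge_intensities()]).
#' @param path file path.
#' @return `write_hkl()` returns `path` invisibly; `read_hkl()` the merged
#'   tibble.
#' @export
write_hkl <- function(merged, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# point_group:", attr(merged, "point_group")),
               paste("# anomalous:", isTRUE(attr(merged, "anomalous"))),
               "h\tk\tl\tI\tsigma\tnmeas"), con)
  if (nrow(merged))
    writeLines(sprintf("%d\t%d\t%d\t%.8g\t%.8g\t%d",
                       merged$h, merged$k, merged$l, merged$I,
                       ifelse(is.na(merged$sigma), 0, merged$sigma),
                       merged$n_obs), con)
  invisible(path)
}

#' @rdname write_hkl
#' @export
read_hkl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  pg <- sub("^# point_group:\\s*", "", lines[grepl("^# point_group:", lines)])
  body <- lines[!hdr]
  cols <- strsplit(body[1], "\t")[[1]]
  rows <- body[-1]
  out <- if (length(rows)) {
    m <- do.call(rbind, strsplit(rows, "\t"))
    tibble::tibble(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                   l = as.integer(m[, 3]), I = as.numeric(m[, 4]),
                   sigma = as.numeric(m[, 5]), n_obs = as.integer(m[, 6]))
  } else {
    tibble::tibble(h = integer(), k = integer(), l = integer(),
                   I = numeric(), sigma = numeric(), n_obs = integer())
  }
  attr(out, "point_group") <- if (length(pg)) pg else NA_character_
  class(out) <- c("sfx_merged", class(out))
  out
}

# --- command-line interface ------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: serialx <command> [options]",
    "commands:",
    "  synth       --n N --seed S --out DIR [--spots K]",
    "  prep        --frames DIR --out DIR [--box B]",
    "  hits        --frames DIR --out FILE [--min-peaks N] [--geometry G] [--energy EV]",
    "  index       --peaks FILE --cell FILE --geometry FILE --energy EV [--out FILE]",
    "  integrate   --frames DIR --cell FILE --geometry FILE --energy EV --out FILE",
    "  merge       --refl FILE[,FILE...] --pg PG --out FILE [--anomalous]",
    "  rsplit      --half1 FILE --half2 FILE",
    "  ambiguities --pg PG --lattice TYPE",
    "  simulate    --bandwidth B --convergence C --n N --seed S --out FILE",
    sep = "\n")
}

cli_parse_args <- function(argv) {
  out <- list(flags = character())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i < length(argv) && !grepl("^--", argv[i + 1])) {
        out[[key]] <- argv[i + 1]
        i <- i + 2L
      } else {
        out$flags <- c(out$flags, key)
        i <- i + 1L
      }
    } else {
      stop("unexpected argument: ", a, call. = FALSE)
    }
  }
  out
}

cli_require <- function(args, keys) {
  miss <- setdiff(keys, names(args))
  if (length(miss))
    stop("missing required option(s): ", paste0("--", miss, collapse = ", "),
         call. = FALSE)
}

#' Command-line entry point
#'
#' Dispatches the `serialx` subcommands (see `exec/serialx`). Returns an
#' exit code instead of quitting so it is testable in-process: 0 on success,
#' 2 for usage errors, 1 for runtime failures.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(argv = character()) {
  if (!length(argv)) {
    message(cli_usage())
    return(invisible(2L))
  }
  cmd <- argv[1]
  known <- c("synth", "prep", "hits", "index", "integrate", "merge",
             "rsplit", "ambiguities", "simulate")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd, "\n", cli_usage())
    return(invisible(2L))
  }
  args <- tryCatch(cli_parse_args(argv[-1]), error = function(e) e)
  if (inherits(args, "error")) {
    message(conditionMessage(args), "\n", cli_usage())
    return(invisible(2L))
  }
  res <- tryCatch({
    switch(cmd,
      ambiguities = cli_ambiguities(args),
      rsplit = cli_rsplit(args),
      merge = cli_merge(args),
      synth = cli_synth(args),
      prep = cli_prep(args),
      hits = cli_hits(args),
      index = cli_index(args),
      integrate = cli_integrate(args),
      simulate = cli_simulate(args))
    0L
  },
  usage_error = function(e) { message(conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(res)
}

cli_num <- function(args, key, default = NULL) {
  if (!is.null(args[[key]])) as.numeric(args[[key]])
  else if (!is.null(default)) default
  else stop(structure(class = c("usage_error", "error", "condition"),
                      list(message = paste0("missing --", key), call = NULL)))
}

cli_str <- function(args, key, default = NULL) {
  if (!is.null(args[[key]])) args[[key]]
  else if (!is.null(default)) default
  else stop(structure(class = c("usage_error", "error", "condition"),
                      list(message = paste0("missing --", key), call = NULL)))
}

cli_ambiguities <- function(args) {
  pg <- cli_str(args, "pg")
  lattice <- cli_str(args, "lattice")
  app <- apparent_point_group(pg, lattice)
  true_pg <- if (is.character(pg)) {
    setting <- if (lattice == "rhombohedral") "rhombohedral"
               else if (lattice == "hexagonal") "hexagonal" else NULL
    point_group(pg, setting = setting)
  } else pg
  reps <- left_coset_decomposition(app, true_pg)
  cat(sprintf("true point group: %s\napparent point group: %s\n",
              true_pg$name, app$name))
  cat(sprintf("ambiguity operators (%d coset(s)):\n", length(reps)))
  for (i in seq_along(reps)) {
    cat(sprintf("  [%d] %s\n", i,
                paste(apply(reps[[i]], 1, paste, collapse = " "),
                      collapse = " / ")))
  }
  invisible(NULL)
}

cli_rsplit <- function(args) {
  h1 <- read_hkl(cli_str(args, "half1"))
  h2 <- read_hkl(cli_str(args, "half2"))
  rs <- r_split(h1, h2)
  cat(sprintf("R_split = %.4f%% over %d common reflections\n",
              100 * rs$r_split, rs$n_common))
  invisible(NULL)
}

cli_merge <- function(args) {
  files <- strsplit(cli_str(args, "refl"), ",", fixed = TRUE)[[1]]
  lists <- lapply(files, read_reflections)
  merged <- merge_intensities(lists, cli_str(args, "pg"),
                              anomalous = "anomalous" %in% args$flags)
  write_hkl(merged, cli_str(args, "out"))
  cat(sprintf("merged %d observations into %d unique reflections\n",
              sum(merged$n_obs), nrow(merged)))
  invisible(NULL)
}

cli_synth <- function(args) {
  set.seed(as.integer(cli_num(args, "seed", 1)))
  n <- as.integer(cli_num(args, "n"))
  spots <- as.integer(cli_num(args, "spots", 80))
  fs <- generate_frame_set(n, max_spots = spots)
  out <- cli_str(args, "out")
  write_frame_stack(fs$frames, out)
  utils::write.table(fs$truth, file.path(out, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("wrote %d synthetic frames to %s\n", n, out))
  invisible(NULL)
}

cli_prep <- function(args) {
  it <- read_frames(cli_str(args, "frames"))
  box <- as.integer(cli_num(args, "box", 5))
  out <- list()
  repeat {
    fr <- it()
    if (is.null(fr)) break
    out[[length(out) + 1]] <- prepare_frame(fr, box = box)
  }
  write_frame_stack(out, cli_str(args, "out"))
  cat(sprintf("prepared %d frames\n", length(out)))
  invisible(NULL)
}

cli_hits_geom <- function(args) {
  if (!is.null(args$geometry)) read_geometry(args$geometry)
  else synth_config()$geom
}

cli_hits <- function(args) {
  it <- read_frames(cli_str(args, "frames"))
  geom <- cli_hits_geom(args)
  wl <- 12398.42 / cli_num(args, "energy", 9000)
  res <- find_hits(it, geom = geom, wavelength = wl,
                   min_peaks = as.integer(cli_num(args, "min-peaks", 25)))
  utils::write.table(res$hits, cli_str(args, "out"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  peaks_out <- sub("(\\.[^.]*)?$", "_peaks.tsv", cli_str(args, "out"))
  utils::write.table(res$peaks, peaks_out, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cat(sprintf("%d / %d frames are hits\n", sum(res$hits$is_hit),
              nrow(res$hits)))
  invisible(NULL)
}

cli_index <- function(args) {
  peaks <- utils::read.delim(cli_str(args, "peaks"))
  cell <- read_cell(cli_str(args, "cell"))
  geom <- cli_hits_geom(args)
  beam <- beam_parameters(cli_num(args, "energy", 9000))
  ids <- unique(peaks$frame_id)
  sols <- lapply(ids, function(id) {
    index_pattern(peaks[peaks$frame_id == id, ], geom, beam, cell)
  })
  for (i in seq_along(ids)) {
    s <- sols[[i]]
    if (s$success) {
      cat(sprintf("frame %s: indexed %d/%d peaks, cell %.2f %.2f %.2f A\n",
                  ids[i], s$n_indexed, s$n_peaks, s$cell$a, s$cell$b, s$cell$c))
    } else {
      cat(sprintf("frame %s: indexing failed\n", ids[i]))
    }
  }
  cat(sprintf("indexing yield: %.3f\n", indexing_yield(sols)))
  invisible(NULL)
}

cli_integrate <- function(args) {
  it <- read_frames(cli_str(args, "frames"))
  cell <- read_cell(cli_str(args, "cell"))
  geom <- cli_hits_geom(args)
  beam <- beam_parameters(cli_num(args, "energy", 9000),
                          bandwidth = cli_num(args, "bandwidth", 0.02),
                          convergence = cli_num(args, "convergence", 0.001))
  out_dir <- cli_str(args, "out")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rr <- as.numeric(strsplit(cli_str(args, "rings", "3 4 5"), "\\s+")[[1]])
  rings <- integration_rings(rr[1], rr[2], rr[3])
  gain <- cli_num(args, "gain", 1)
  idx_cfg <- index_config(n_directions = as.integer(cli_num(args, "directions", 3000)))
  n <- 0L; n_ok <- 0L
  repeat {
    fr <- it()
    if (is.null(fr)) break
    n <- n + 1L
    pk <- find_peaks(fr, beam_centre = geom$beam_centre)
    if (!classify_hit(pk, min_peaks = as.integer(cli_num(args, "min-peaks", 25))))
      next
    sol <- index_pattern(pk, geom, beam, cell, config = idx_cfg)
    if (!sol$success) next
    n_ok <- n_ok + 1L
    refl <- integrate_pattern(fr, sol, beam, geom, rings = rings, gain = gain,
                              profile_r = cli_num(args, "profile", 3e-4))
    hdr <- c(sprintf("frame: %s", fr$id),
             sprintf("cell: %.4f %.4f %.4f %.3f %.3f %.3f",
                     sol$cell$a, sol$cell$b, sol$cell$c,
                     sol$cell$alpha, sol$cell$beta, sol$cell$gamma),
             geometry_header_lines(geom),
             sprintf("rings: %g %g %g  gain: %g", rr[1], rr[2], rr[3], gain))
    write_reflections(refl, file.path(out_dir, sprintf("refl_%06d.refl", n)),
                      header = hdr)
  }
  cat(sprintf("indexed and integrated %d / %d frames\n", n_ok, n))
  invisible(NULL)
}

cli_simulate <- function(args) {
  set.seed(as.integer(cli_num(args, "seed", 1)))
  cfg <- sim_config(bandwidth = cli_num(args, "bandwidth", 0.001),
                    convergence = cli_num(args, "convergence", 0.001))
  n <- as.integer(cli_num(args, "n"))
  curve <- convergence_experiment(n, bandwidth_grid = cfg$beam$bandwidth,
                                  convergence_grid = cfg$beam$convergence,
                                  config = cfg)
  utils::write.table(curve, cli_str(args, "out"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cat(sprintf("R_split = %.4f%% at %d patterns\n",
              100 * curve$r_split[nrow(curve)], max(curve$n_patterns)))
  invisible(NULL)
}
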