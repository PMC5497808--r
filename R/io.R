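# Plain-text interchange formats. All tables are comma-delimited UTF-8 with
# '.' decimals, a header row, and '#'-prefixed metadata lines (units,
# provenance) before it; numbers are written with 17 significant digits so
# every writer/reader pair round-trips losslessly at double precision.

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  gsub(" ", "", out)
}

#' Write and read model-parameter configs
#'
#' Model parameters serialise to a flat YAML file with keys `omega0`, `k`,
#' `sigma` (frequency profile), `v0`, `q` (velocity profile), `x0`, `x1`,
#' `eta`, `tbar` (length dynamics), `epsilon`, `t0`; units (um, min, rad)
#' are documented in the file's comment header.
#'
#' @param mp a [model_parameters()].
#' @param path file path.
#' @return `read_params` returns a [model_parameters()];
#'   `write_params` returns `path` invisibly.
#' @export
write_params <- function(mp, path) {
  stopifnot(inherits(mp, "model_parameters"))
  header <- c(
    "# segwave model parameters",
    "# units: omega0 rad/min; v0 um/min; epsilon um^2/min;",
    "#        x0, x1 um; eta 1/min; tbar, t0 min; k, sigma, q dimensionless")
  writeLines(c(header, yaml::as.yaml(params_to_list(mp))), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  params_from_list(yaml::read_yaml(path))
}

#' Write and read tabular series
#'
#' Generic writer/reader for the package's tabular data (length series,
#' boundary tracks, observable series, segment records): CSV with a header
#' row and '#'-prefixed metadata lines.
#'
#' @param df a data frame.
#' @param path file path.
#' @param metadata character vector of metadata lines (written '#'-prefixed).
#' @return `read_series` returns the data frame (metadata in attribute
#'   `"metadata"`); `write_series` returns `path` invisibly.
#' @export
write_series <- function(df, path, metadata = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(metadata)) writeLines(paste("#", metadata), con)
  writeLines(paste(names(df), collapse = ","), con)
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt_num(col) else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- sub("^# ?", "", lines[startsWith(lines, "#")])
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  attr(df, "metadata") <- meta
  df
}

#' Write and read kymographs
#'
#' Kymographs (time-by-position grids of phase, in radians) serialise to a
#' plain-text table: after the '#' metadata lines, the first row carries the
#' position grid (first field empty), and every following row carries the
#' frame time followed by the row's values. Rows are times (increasing);
#' columns are positions with the posterior tip `x = 0` leftmost. The
#' round-trip is lossless at double precision.
#'
#' @param kymo a `"kymograph"` (list with `x`, `t`, `values`).
#' @param path file path.
#' @param metadata character vector of extra metadata lines.
#' @return `read_kymograph` returns a `"kymograph"`; `write_kymograph`
#'   returns `path` invisibly.
#' @export
write_kymograph <- function(kymo, path, metadata = character()) {
  stopifnot(all(c("x", "t", "values") %in% names(kymo)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c("segwave kymograph: rows = time (min), columns = position (um), cells = phase (rad)",
            metadata)
  writeLines(paste("#", meta), con)
  writeLines(paste(c("", fmt_num(kymo$x)), collapse = ","), con)
  body <- vapply(seq_along(kymo$t), function(i) {
    paste(c(fmt_num(kymo$t[i]), fmt_num(kymo$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  x <- as.numeric(header[-1])
  body <- do.call(rbind, lapply(strsplit(lines[-1], ",", fixed = TRUE),
                                as.numeric))
  structure(list(x = x, t = body[, 1], values = body[, -1, drop = FALSE],
                 what = "psi"),
            class = "kymograph")
}

#' Write and read a phase-field run directory
#'
#' A solved run serialises to a directory of plain-text files: the phase
#' kymograph (`phi.csv`), the PSM-length trajectory (`xbar.csv`), the model
#' parameters (`params.yml`) and a small run manifest (`manifest.yml`:
#' grid, realised time step, stability bound). The round-trip reconstructs
#' the `phase_field` losslessly at double precision.
#'
#' @param pf a `phase_field`.
#' @param dir directory path (created if needed).
#' @return `read_phase_field` returns a `phase_field`; `write_phase_field`
#'   returns `dir` invisibly.
#' @export
write_phase_field <- function(pf, dir) {
  stopifnot(inherits(pf, "phase_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_kymograph(list(x = pf$x, t = pf$t, values = pf$phi),
                  file.path(dir, "phi.csv"))
  write_series(data.frame(t = pf$t, xbar = pf$xbar,
                          xbar_rate = pf$xbar_rate),
               file.path(dir, "xbar.csv"),
               metadata = "PSM length (um) and analytic rate (um/min) at the output times")
  write_params(pf$params, file.path(dir, "params.yml"))
  sc <- pf$config
  manifest <- list(dx = sc$dx, L = sc$L, dt = sc$dt,
                   t0 = sc$t0, t_end = sc$t_end,
                   output_stride = sc$output_stride,
                   coupling_beyond_psm = sc$coupling_beyond_psm,
                   dt_stability_bound = cfl_dt(sc$dx, pf$params$vel$v0,
                                               pf$params$epsilon))
  writeLines(c("# segwave run manifest", yaml::as.yaml(manifest)),
             file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname write_phase_field
#' @export
read_phase_field <- function(dir) {
  kymo <- read_kymograph(file.path(dir, "phi.csv"))
  xb <- read_series(file.path(dir, "xbar.csv"))
  mp <- read_params(file.path(dir, "params.yml"))
  man <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  sc <- simulation_config(t_end = man$t_end, t0 = man$t0, dx = man$dx,
                          L = man$L, dt = man$dt,
                          output_stride = man$output_stride,
                          coupling_beyond_psm = man$coupling_beyond_psm)
  structure(list(x = kymo$x, t = kymo$t, phi = kymo$values,
                 xbar = xb$xbar, xbar_rate = xb$xbar_rate,
                 params = mp, config = sc),
            class = "phase_field")
}
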