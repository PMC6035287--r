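# File I/O. Conventions: axial positions in nm with 0 at the left profile
# edge; kymograph rows = time increasing downward; profiles oriented with
# the lattice at lower x. Profiles and trajectories are CSV, kymographs
# single-channel TIFF with a JSON sidecar carrying metadata (pixel size,
# frame interval, intensity scale, time-axis orientation), configs YAML.

#' Write / read an intensity profile as CSV
#'
#' Columns `x_nm,intensity`; the pixel size is stored in a
#' `# pixel_size_nm:` header comment and is required on read.
#'
#' @param profile an [intensity_profile()].
#' @param path file path.
#' @return `read_profile_csv` returns an [intensity_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_nm: %.10g", profile$pixel_size), con)
  write.csv(data.frame(x_nm = profile$x, intensity = profile$intensity),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*pixel_size_nm:", first))
    stop("profile CSV is missing the '# pixel_size_nm:' metadata header")
  px <- as.numeric(sub("^#\\s*pixel_size_nm:\\s*", "", first))
  if (!is.finite(px) || px <= 0) stop("invalid pixel_size_nm in header")
  d <- read.csv(path, comment.char = "#")
  if (!all(c("x_nm", "intensity") %in% names(d)))
    stop("profile CSV must have columns x_nm,intensity")
  intensity_profile(d$x_nm, d$intensity, px)
}

#' Write / read a tip trajectory as CSV
#'
#' Columns `t_s,length_nm` (plus `true_length_nm`, `phase` when available).
#'
#' @param traj an `mt_trajectory`.
#' @param path file path.
#' @return `read_trajectory_csv` returns an `mt_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "mt_trajectory"))
  d <- data.frame(t_s = traj$times, length_nm = traj$observed_lengths,
                  true_length_nm = traj$true_lengths)
  if (!is.null(traj$phases)) d$phase <- traj$phases
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("t_s", "length_nm") %in% names(d)))
    stop("trajectory CSV must have columns t_s,length_nm")
  new_trajectory(d$t_s,
                 if ("true_length_nm" %in% names(d)) d$true_length_nm
                 else d$length_nm,
                 d$length_nm,
                 phases = if ("phase" %in% names(d)) d$phase else NULL)
}

#' Write / read a kymograph as single-channel TIFF with JSON sidecar
#'
#' The matrix (rows = time by convention) is stored as 32-bit TIFF scaled
#' into [0, 1]; the scale, pixel size, frame interval and time-axis
#' orientation go into `<path>.json`. On read the sidecar restores the
#' intensity scale and transposes column-major time if the sidecar says so
#' (the orientation is declared, never guessed).
#'
#' @param kymo numeric matrix, rows = time.
#' @param path TIFF path (sidecar written at `paste0(path, ".json")`).
#' @param pixel_size pixel size (nm).
#' @param dt frame interval (s).
#' @param time_axis `"rows"` (default) or `"columns"` - how time is laid
#'   out in the stored image.
#' @return `read_kymograph_tiff` returns a matrix with rows = time and
#'   attributes `pixel_size` and `dt`.
#' @export
write_kymograph_tiff <- function(kymo, path, pixel_size, dt,
                                 time_axis = c("rows", "columns")) {
  time_axis <- match.arg(time_axis)
  stopifnot(is.matrix(kymo), pixel_size > 0, dt > 0)
  img <- if (time_axis == "rows") kymo else t(kymo)
  offset <- min(img)
  scale <- max(img) - offset
  if (scale <= 0) scale <- 1
  tiff::writeTIFF((img - offset) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_nm = pixel_size, dt_s = dt, time_axis = time_axis,
         intensity_offset = offset, intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph_tiff
#' @export
read_kymograph_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("kymograph sidecar metadata not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  img <- img * meta$intensity_scale + meta$intensity_offset
  if (identical(meta$time_axis, "columns")) img <- t(img)
  attr(img, "pixel_size") <- meta$pixel_size_nm
  attr(img, "dt") <- meta$dt_s
  img
}

#' Write / read an event table as CSV
#'
#' Segments with ISO-like column names (`t_start_s`, `t_end_s`,
#' `slope_nm_per_s`, `phase`).
#'
#' @param events an `event_table`.
#' @param path file path.
#' @return `read_events_csv` returns the segments data frame (re-classify
#'   with [classify_events()] to recover counts).
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  seg <- events$segments
  write.csv(data.frame(t_start_s = seg$t_start, t_end_s = seg$t_end,
                       slope_nm_per_s = seg$slope, phase = seg$phase),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  d <- read.csv(path)
  need <- c("t_start_s", "t_end_s", "slope_nm_per_s")
  if (!all(need %in% names(d)))
    stop("events CSV must have columns ", paste(need, collapse = ","))
  out <- data.frame(t_start = d$t_start_s, t_end = d$t_end_s,
                    slope = d$slope_nm_per_s,
                    phase = if ("phase" %in% names(d)) d$phase
                    else NA_character_)
  class(out) <- c("phase_segments", class(out))
  out
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip losslessly; every stochastic stage's seed is
#' derived from the `seed` field.
#'
#' @param config named list (must contain `seed`).
#' @param path YAML path.
#' @return `read_run_config` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(config$seed))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  if (is.null(config$seed)) stop("run config must contain a 'seed' field")
  config
}

#' Load a typed input file
#'
#' Dispatches on `kind` and returns the validated domain object; schema
#' violations raise an error naming the offending column or metadata field.
#'
#' @param path file path.
#' @param kind one of `"kymograph_tiff"`, `"profile_csv"`,
#'   `"trajectory_csv"`, `"events_csv"`.
#' @return the loaded object.
#' @export
load_inputs <- function(path, kind = c("kymograph_tiff", "profile_csv",
                                       "trajectory_csv", "events_csv")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(kind,
         kymograph_tiff = read_kymograph_tiff(path),
         profile_csv = read_profile_csv(path),
         trajectory_csv = read_trajectory_csv(path),
         events_csv = read_events_csv(path))
}
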