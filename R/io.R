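# File formats: multi-page TIFF movies with JSON sidecars, CSV traces,
# YAML configuration.

protocol_to_list <- function(p) {
  list(onset_s = p$onset_s, frequency_hz = p$frequency_hz,
       n_pulses = p$n_pulses, pulse_width_us = p$pulse_width_us,
       current_uA = p$current_uA)
}

protocol_from_list <- function(l) {
  make_stimulus_protocol(l$frequency_hz, l$n_pulses, l$onset_s,
                         l$pulse_width_us, l$current_uA)
}

#' Write a movie as a multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled to `[0, 1]`; the
#' intensity scale, frame rate, pixel size, region label and stimulus
#' protocol are written to `<path>.json`. Values are therefore preserved
#' to single-precision accuracy.
#'
#' @param movie An `"ffn_movie"`.
#' @param path Output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "ffn_movie"))
  d <- dim(movie$frames)
  scale <- max(movie$frames, 1e-12)
  pages <- lapply(seq_len(d[1]), function(k) movie$frames[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- list(
    n_frames = d[1], height_px = d[2], width_px = d[3],
    frame_rate_hz = movie$frame_rate_hz,
    pixel_size_um = movie$pixel_size_um,
    region_label = movie$region_label,
    intensity_scale = scale,
    protocol = protocol_to_list(movie$protocol))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' Validates the TIFF stack against its JSON sidecar (page count, frame
#' shape) and restores intensities and metadata.
#'
#' @param path TIFF path with a `<path>.json` sidecar.
#' @return An `"ffn_movie"`.
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop_invalid("movie file not found: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop_invalid("missing metadata sidecar: ", sidecar_path)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_frames) {
    stop_invalid(sprintf(
      "%s: sidecar declares %d frames but file has %d pages",
      path, meta$n_frames, length(pages)))
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != meta$height_px) || any(dims[2, ] != meta$width_px)) {
    bad <- which(dims[1, ] != meta$height_px |
                 dims[2, ] != meta$width_px)[1]
    stop_invalid(sprintf("%s: page %d has a non-conforming frame shape",
                         path, bad))
  }
  frames <- array(0, dim = c(length(pages), meta$height_px, meta$width_px))
  for (k in seq_along(pages)) {
    frames[k, , ] <- pages[[k]] * meta$intensity_scale
  }
  structure(list(frames = frames, frame_rate_hz = meta$frame_rate_hz,
                 pixel_size_um = meta$pixel_size_um,
                 region_label = meta$region_label,
                 protocol = protocol_from_list(meta$protocol)),
            class = "ffn_movie")
}

#' Write an edge mask as a single-page TIFF
#'
#' Edge pixels are written as 255, background as 0 (8-bit).
#'
#' @param mask An `"edge_mask"`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "edge_mask"))
  tiff::writeTIFF(mask$pixels * 1.0, path, bits.per.sample = 8)
  invisible(path)
}

#' Write traces to CSV
#'
#' Wide layout: a `time_s` column followed by one value column per trace;
#' `#`-prefixed header lines carry the frame rate and protocol.
#'
#' @param traces A single trace or list of `"raw_trace"`/`"dff_trace"`
#'   objects sharing one time base.
#' @param path Output CSV path.
#' @param ids Optional column names, one per trace.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, ids = NULL) {
  if (inherits(traces, c("raw_trace", "dff_trace"))) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  t0 <- traces[[1]]$times_s
  if (is.null(ids)) ids <- sprintf("trace%03d", seq_along(traces))
  header <- c(
    sprintf("# frame_rate_hz: %.10g", traces[[1]]$frame_rate_hz))
  prot <- traces[[1]]$protocol
  if (!is.null(prot)) {
    header <- c(header, sprintf(
      "# protocol: onset_s=%.10g frequency_hz=%.10g n_pulses=%d",
      prot$onset_s, prot$frequency_hz, prot$n_pulses))
  }
  df <- data.frame(time_s = t0)
  for (i in seq_along(traces)) df[[ids[i]]] <- traces[[i]]$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read traces from CSV
#'
#' Reads the wide layout written by [write_traces()] (time column plus one
#' column per trace; `#` comment header). A long layout with columns
#' `time_s`, `id`, `value` is also accepted. The time column must be
#' strictly increasing and uniformly spaced.
#'
#' @param path CSV path.
#' @param layout `"wide"` (default) or `"long"`.
#' @param time_col,value_col,id_col Column names for the long layout (and
#'   `time_col` for wide), a mapping hook for externally produced files.
#' @return Named list of `"raw_trace"` objects.
#' @export
read_traces <- function(path, layout = c("wide", "long"),
                        time_col = "time_s", value_col = "value",
                        id_col = "id") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_invalid("trace file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  frame_rate <- NA_real_
  fr <- grep("frame_rate_hz:", meta_lines, value = TRUE)
  if (length(fr)) frame_rate <- as.numeric(sub(".*frame_rate_hz:", "", fr[1]))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        check.names = FALSE)
  if (!time_col %in% names(df)) {
    stop_invalid(sprintf("no `%s` column in %s", time_col, path))
  }
  if (layout == "long") {
    if (!all(c(value_col, id_col) %in% names(df))) {
      stop_invalid("long layout needs time, id and value columns")
    }
    split_df <- split(df, df[[id_col]])
    traces <- lapply(split_df, function(d) {
      make_trace_from_columns(d[[time_col]], d[[value_col]], frame_rate)
    })
    return(traces)
  }
  value_cols <- setdiff(names(df), time_col)
  if (length(value_cols) == 0L) stop_invalid("no value columns in ", path)
  traces <- lapply(value_cols, function(cn) {
    make_trace_from_columns(df[[time_col]], df[[cn]], frame_rate)
  })
  names(traces) <- value_cols
  traces
}

make_trace_from_columns <- function(times, values, frame_rate) {
  if (any(diff(times) <= 0)) {
    stop_invalid("time column must be strictly increasing")
  }
  dt <- diff(times)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop_invalid("time column is not uniformly sampled")
  }
  if (is.na(frame_rate)) frame_rate <- 1 / stats::median(dt)
  raw_trace(times, values, frame_rate)
}

#' Read a pipeline configuration file
#'
#' Plain-text YAML `key: value` configuration collecting every analysis
#' constant in one auditable place. Missing keys take the documented
#' defaults; see [default_config()].
#'
#' @param path YAML file path.
#' @return A validated `"pipeline_config"` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
}

#' Default pipeline configuration
#'
#' Defaults mirror the standard acquisition and analysis settings:
#' 10 Hz imaging, 0.5 s pre-stimulus baseline fit, AUC over the stimulus
#' window in seconds, Canny thresholds 0.08/0.2 with 1.4 px smoothing,
#' decay floor at 10 percent of peak.
#'
#' @return A `"pipeline_config"` list.
#' @export
default_config <- function() {
  validate_config(list(
    frame_rate_hz = 10,
    baseline_window_s = 0.5,
    auc_window_s = NULL,          # NULL: pipeline uses onset + 0-300 ms
    auc_abscissa = "seconds",
    canny_low = 0.08,
    canny_high = 0.2,
    canny_sigma_px = 1.4,
    decay_floor_fraction = 0.10,
    onset_s = 1,
    n_pulses = 10,
    frequency_hz = 10,
    duration_s = 8,
    n_fovs = 12,
    n_trials_per_fov = 4,
    noise_sd = 0.5,
    seed = 1L))
}

validate_config <- function(cfg) {
  check_scalar(cfg$frame_rate_hz, "frame_rate_hz", lower = 0,
               strict_lower = TRUE)
  check_scalar(cfg$baseline_window_s, "baseline_window_s", lower = 0,
               strict_lower = TRUE)
  if (!is.null(cfg$auc_window_s)) {
    if (length(cfg$auc_window_s) != 2L ||
        cfg$auc_window_s[1] >= cfg$auc_window_s[2]) {
      stop_invalid("`auc_window_s` must be c(start, end), start < end")
    }
  }
  if (!cfg$auc_abscissa %in% c("seconds", "frames")) {
    stop_invalid("`auc_abscissa` must be 'seconds' or 'frames'")
  }
  check_scalar(cfg$canny_low, "canny_low", lower = 0, upper = 1)
  check_scalar(cfg$canny_high, "canny_high", lower = 0, upper = 1)
  if (cfg$canny_low >= cfg$canny_high) {
    stop_invalid("`canny_low` must be smaller than `canny_high`")
  }
  check_scalar(cfg$decay_floor_fraction, "decay_floor_fraction",
               lower = 0, upper = 1, strict_lower = TRUE)
  structure(cfg, class = "pipeline_config")
}
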