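PULSE_LOG_COLUMNS <- c("index", "phase", "pressure_MPa", "sc_linear",
                       "ic_linear", "sc_db", "ic_db", "in_band", "ic_event")

#' Load a configuration file
#'
#' Reads a YAML or JSON configuration and validates it against the type
#' invariants via the corresponding constructor. Unknown keys are
#' rejected with an error naming the field.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @param type `"sonication"` for a [sonication_config()], `"plant"` for
#'   [plant_params()].
#' @return The validated configuration object.
#' @export
load_config <- function(path, type = c("sonication", "plant")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a mapping of fields", call. = FALSE)
  ctor <- switch(type, sonication = sonication_config, plant = plant_params)
  known <- names(formals(ctor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(ctor, raw)
}

#' Save a configuration file
#'
#' @param cfg A `sonication_config` or `plant_params` object.
#' @param path Output path; format chosen by extension (`.yaml` or `.json`).
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else
    writeLines(yaml::as.yaml(x, precision = 17), path)
  invisible(path)
}

#' Write a pulse log as CSV
#'
#' One row per pulse with exactly the columns
#' `index, phase, pressure_MPa, sc_linear, ic_linear, sc_db, ic_db,
#' in_band, ic_event`. Floats are serialized at round-trip precision
#' (17 significant digits) so that write-then-read is the identity.
#'
#' @param log A `treatment_log` or a records data.frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_pulse_log <- function(log, path) {
  rec <- if (inherits(log, "treatment_log")) log$records else log
  if (nrow(rec) == 0) {
    writeLines(paste(PULSE_LOG_COLUMNS, collapse = ","), path)
    return(invisible(path))
  }
  missing <- setdiff(PULSE_LOG_COLUMNS, names(rec))
  if (length(missing) > 0)
    stop("pulse log missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rec <- rec[, PULSE_LOG_COLUMNS]
  fmt <- function(x) {
    if (is.double(x)) sprintf("%.17g", x)
    else if (is.logical(x)) ifelse(x, "TRUE", "FALSE")
    else as.character(x)
  }
  out <- do.call(cbind, lapply(rec, fmt))
  lines <- c(paste(PULSE_LOG_COLUMNS, collapse = ","),
             apply(out, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pulse log CSV
#'
#' @param path CSV written by [write_pulse_log()].
#' @return A records data.frame with the standard pulse-log columns.
#' @export
read_pulse_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PULSE_LOG_COLUMNS, names(df))
  if (length(missing) > 0)
    stop("pulse log missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, PULSE_LOG_COLUMNS]
  df$index <- as.integer(df$index)
  df$phase <- as.character(df$phase)
  for (col in c("pressure_MPa", "sc_linear", "ic_linear", "sc_db", "ic_db"))
    df[[col]] <- as.numeric(df[[col]])
  df$in_band <- as.logical(df$in_band)
  df$ic_event <- as.logical(df$ic_event)
  df
}

#' Per-TCL group summary of session metrics
#'
#' Groups per-session metrics by TCL and reports the arithmetic mean and
#' sample standard deviation of each metric, mirroring the mean +/- sd
#' bar-plot reporting of controller stability, IC probability and
#' opening volume. Inferential statistics are out of scope.
#'
#' @param metrics A data.frame with a `tcl_db` column and one column per
#'   numeric metric (e.g. `good_pulse_rate_pct`, `ic_probability_pct`,
#'   `opening_volume_mm3`).
#' @return A data.frame with one row per TCL group: `tcl_db`, `n`, and
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @export
summarize_sessions <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0)
    stop("metrics must be a non-empty data.frame", call. = FALSE)
  if (!"tcl_db" %in% names(metrics))
    stop("metrics must contain a tcl_db column", call. = FALSE)
  mcols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                   "tcl_db")
  groups <- sort(unique(metrics$tcl_db))
  rows <- lapply(groups, function(g) {
    sub <- metrics[metrics$tcl_db == g, , drop = FALSE]
    row <- data.frame(tcl_db = g, n = nrow(sub))
    for (m in mcols) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]])
      row[[paste0(m, "_sd")]] <- if (nrow(sub) > 1) stats::sd(sub[[m]]) else 0
    }
    row
  })
  do.call(rbind, rows)
}

#' Format a group summary as a plain-text table
#' @param summary Output of [summarize_sessions()].
#' @return Character vector of lines.
#' @export
format_summary_table <- function(summary) {
  utils::capture.output(print(summary, row.names = FALSE))
}

#' Session manifest for reproducible reruns
#'
#' Records config file paths with their MD5 hashes, the seeds, package
#' version and a timestamp. Re-running a deterministic command with an
#' identical manifest reproduces all numeric outputs bit-identically.
#'
#' @param config_paths Named character vector of config file paths.
#' @param seeds Named or unnamed integer vector of seeds.
#' @return A list of class `session_manifest`.
#' @export
session_manifest <- function(config_paths = character(), seeds = integer()) {
  hashes <- if (length(config_paths) > 0)
    as.vector(tools::md5sum(config_paths)) else character()
  structure(list(
    config_paths = as.list(config_paths),
    config_md5 = as.list(hashes),
    seeds = as.list(seeds),
    package_version = as.character(utils::packageVersion("fuscontrol")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "session_manifest")
}

#' @rdname session_manifest
#' @param manifest A `session_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- minimal NIfTI-1 I/O ---------------------------------------------------
# No NIfTI reader is available in the target environment, so a minimal
# single-file NIfTI-1 (.nii / .nii.gz) codec is provided for 3-D scalar
# volumes: little-endian, float32/float64/int16/uint8, no extensions,
# spacing carried in pixdim.

nifti_dtypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                     `4` = list(what = "integer", size = 2, signed = TRUE),
                     `8` = list(what = "integer", size = 4, signed = TRUE),
                     `16` = list(what = "double", size = 4, signed = TRUE),
                     `64` = list(what = "double", size = 8, signed = TRUE))

#' Write an image volume as NIfTI-1
#'
#' Minimal NIfTI-1 writer for 3-D scalar volumes (single-file `.nii`,
#' gzipped when the path ends in `.gz`): little-endian float64 data, voxel
#' spacing stored in `pixdim`, no extensions.
#'
#' @param volume An [image_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$intensities)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  wi(348L, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(64L, 2); wi(64L, 2)           # datatype float64, bitpix
  wi(0L, 2)                        # slice_start
  wf(c(1, volume$spacing, 1, 1, 1, 1))  # pixdim[8]
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc("", 1); wc("", 1)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc("fuscontrol", 80); wc("", 24) # descrip, aux_file
  wi(c(0L, 0L), 2)                 # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))          # quatern, qoffset
  wf(c(volume$spacing[1], 0, 0, 0))  # srow_x
  wf(c(0, volume$spacing[2], 0, 0))  # srow_y
  wf(c(0, 0, volume$spacing[3], 0))  # srow_z
  wc("", 16); wc("n+1", 4)         # intent_name, magic
  writeBin(raw(4), con)            # extension indicator
  writeBin(as.numeric(volume$intensities), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Minimal single-file NIfTI-1 reader for 3-D scalar volumes
#' (little-endian; uint8/int16/int32/float32/float64; `scl_slope`
#' honored).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header", call. = FALSE)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L)
    stop("unsupported NIfTI file (not little-endian NIfTI-1)", call. = FALSE)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file", call. = FALSE)
  dims <- ri(40, 2, 8)
  nd <- dims[1]
  if (nd < 3) stop("expected a 3-D volume", call. = FALSE)
  d <- dims[2:4]
  if (nd > 3 && any(dims[5:(nd + 1)] > 1))
    stop("only 3-D scalar volumes are supported", call. = FALSE)
  datatype <- ri(70, 2)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112)
  scl_inter <- rf(116)
  skip <- round(vox_offset) - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = "little")
  if (length(vals) < n) stop("truncated NIfTI data section", call. = FALSE)
  vals <- as.numeric(vals)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  image_volume(array(vals, dim = d), spacing = pixdim[2:4])
}

#' Read an RGB image (PNG)
#'
#' @param path PNG file path.
#' @return Numeric h x w x 3 array in `[0, 1]` (alpha dropped). A
#'   grayscale PNG raises an error: the red-pixel quantifier needs color.
#' @export
read_rgb_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("image must have three color channels (grayscale not supported)",
         call. = FALSE)
  img[, , 1:3, drop = FALSE]
}

#' Write an RGB image (PNG)
#' @param image Numeric h x w x 3 array in `[0, 1]`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
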