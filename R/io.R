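# File formats: TIFF stacks in, CSV tables and JSON configuration out.
# CSV numbers are written with full (17 significant digit) precision so
# that write/read round-trips are lossless.

#' Read a TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into a [frame_stack()].
#' Integer sample values are kept as-is (bit depth is not rescaled).
#'
#' @param path TIFF file path.
#' @param pixel_size um per pixel recorded in the stack (default 0.65).
#' @param frame_interval_s Seconds between pages (default 60).
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, pixel_size = 0.65, frame_interval_s = 60) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) != 2L) {
      stop(sprintf("page %d is not 2-D grayscale (dims: %s)", i,
                   paste(dim(p), collapse = "x")), call. = FALSE)
    }
    storage.mode(p) <- "double"
    p
  })
  frame_stack(frames, pixel_size = pixel_size,
              frame_interval_s = frame_interval_s)
}

#' Write a frame stack to a 16-bit TIFF
#'
#' Intensities are clipped to \[0, 1\] and stored as 16-bit samples; a
#' stack read back with [read_stack()] contains the integer sample values
#' (0..65535).
#'
#' @param stack A [frame_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  imgs <- lapply(stack$frames, function(f) {
    f <- pmin(pmax(f, 0), 1)
    round(f * 65535) / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

write_table_precise <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

TRACKS_COLUMNS <- c("track_id", "frame", "time_s", "x_px", "y_px",
                    "x_um", "y_um", "area_um2", "major_axis_um",
                    "stop_reason")

#' Write and read track tables
#'
#' CSV schema: `track_id, frame, time_s, x_px, y_px, x_um, y_um, area_um2,
#' major_axis_um, stop_reason` (stop reason populated on each track's last
#' row). Numeric values round-trip losslessly.
#'
#' @param tracks List of `cell_track` or a data frame already in the
#'   schema.
#' @param path CSV path.
#' @return `write_tracks()` returns the path invisibly; `read_tracks()`
#'   returns a list of `cell_track`.
#' @export
write_tracks <- function(tracks, path) {
  df <- if (is.data.frame(tracks)) tracks else tracks_to_table(tracks)
  require_columns(df, TRACKS_COLUMNS, "tracks table")
  write_table_precise(df[, TRACKS_COLUMNS], path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(stop_reason = "character"))
  require_columns(df, TRACKS_COLUMNS, basename(path))
  df$stop_reason[!nzchar(df$stop_reason) | is.na(df$stop_reason)] <-
    NA_character_
  table_to_tracks(df)
}

features_columns <- function() {
  c("cell_id", "group", motility_parameters(),
    "quiescent_frac", "track_duration_h")
}

#' Write and read feature tables
#'
#' CSV schema: `cell_id, group`, the ten motility parameters, and
#' `quiescent_frac, track_duration_h`. Missing migration-distance values
#' (cells with no qualifying turn) are preserved as empty fields.
#'
#' @param features Feature data frame (e.g. from [profile_tracks()] with a
#'   group label).
#' @param path CSV path.
#' @return `write_features()` returns the path invisibly;
#'   `read_features()` returns the data frame.
#' @export
write_features <- function(features, path) {
  if (!"group" %in% names(features)) features$group <- NA_character_
  require_columns(features, features_columns(), "feature table")
  write_table_precise(features[, features_columns()], path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, features_columns(), basename(path))
  df
}

#' Run configuration
#'
#' Bundles acquisition metadata and the per-stage configurations, with a
#' JSON round-trip for provenance. Unknown keys in a JSON file are
#' rejected.
#'
#' @param pixel_size um per pixel.
#' @param frame_interval_s Seconds between frames.
#' @param segmentation A [seg_config()].
#' @param tracking A [trk_config()].
#' @param turn_thresholds_deg Angular thresholds for the turn parameters.
#' @param normalization_hours Observation window the duration-dependent
#'   parameters are normalized to.
#' @param cv_k,cv_seed Cross-validation settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size = 0.65, frame_interval_s = 60,
                       segmentation = seg_config(edge_threshold = 0.2),
                       tracking = trk_config(),
                       turn_thresholds_deg = c(90, 60, 30),
                       normalization_hours = 30,
                       cv_k = 10, cv_seed = 0) {
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  structure(list(pixel_size = pixel_size,
                 frame_interval_s = frame_interval_s,
                 segmentation = unclass(segmentation),
                 tracking = unclass(tracking),
                 turn_thresholds_deg = turn_thresholds_deg,
                 normalization_hours = normalization_hours,
                 cv_k = cv_k, cv_seed = cv_seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- run_config()
  unknown <- setdiff(names(raw), names(template))
  if (length(unknown)) {
    stop("unknown key(s) in run config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seg_keys <- setdiff(names(raw$segmentation), names(template$segmentation))
  trk_keys <- setdiff(names(raw$tracking), names(template$tracking))
  if (length(seg_keys) || length(trk_keys)) {
    stop("unknown key(s) in run config: ",
         paste(c(seg_keys, trk_keys), collapse = ", "), call. = FALSE)
  }
  merged <- utils::modifyList(unclass(template), raw)
  cfg <- run_config(
    pixel_size = merged$pixel_size,
    frame_interval_s = merged$frame_interval_s,
    segmentation = do.call(seg_config, merged$segmentation),
    tracking = do.call(trk_config, merged$tracking),
    turn_thresholds_deg = merged$turn_thresholds_deg,
    normalization_hours = merged$normalization_hours,
    cv_k = merged$cv_k, cv_seed = merged$cv_seed)
  cfg
}

#' Write a provenance record
#'
#' Machine-readable JSON describing a run: package version, timestamp,
#' seed, and the configuration or parameters used. Written alongside every
#' CLI output.
#'
#' @param path Output JSON path.
#' @param params Named list of run parameters.
#' @param seed Seed used (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, params, seed = NULL) {
  rec <- list(
    package = "motrack",
    version = as.character(utils::packageVersion("motrack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = params)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
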