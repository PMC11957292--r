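# ROI-based single-cell tracking: each cell is re-segmented inside a moving
# square window derived from its previous centroid and major axis. Tracking
# stops on loss (no centroid), division/contact (two centroids or an area
# jump), or at the end of the stack.

#' Tracking configuration
#'
#' @param roi_scale Square ROI side as a multiple of the cell's major-axis
#'   length (default 2.0; must be > 1 so the cell fits with margin).
#' @param min_track_duration_min Minimum track duration in minutes; tracks
#'   are kept only if strictly longer (default 60).
#' @param frame_interval_s Acquisition interval in seconds (default 60).
#' @param merge_area_factor A single matched region whose area exceeds this
#'   multiple of the previous area is treated as a cell-cell merge and stops
#'   the track (default 1.8).
#' @return An object of class `trk_config`.
#' @export
trk_config <- function(roi_scale = 2.0,
                       min_track_duration_min = 60,
                       frame_interval_s = 60,
                       merge_area_factor = 1.8) {
  if (roi_scale <= 1) stop("`roi_scale` must be > 1", call. = FALSE)
  if (frame_interval_s <= 0) stop("`frame_interval_s` must be > 0", call. = FALSE)
  if (merge_area_factor <= 1) stop("`merge_area_factor` must be > 1", call. = FALSE)
  structure(
    list(roi_scale = roi_scale,
         min_track_duration_min = min_track_duration_min,
         frame_interval_s = frame_interval_s,
         merge_area_factor = merge_area_factor),
    class = "trk_config"
  )
}

#' Frame stack container
#'
#' @param frames List of numeric matrices (grayscale frames, identical
#'   extents, page order = time order).
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval_s Seconds between frames.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size = 0.65, frame_interval_s = 60) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
               logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical extent",
                     call. = FALSE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval_s = frame_interval_s),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %.3g um/px, %gs interval\n",
              length(x$frames), ncol(x$frames[[1]]), nrow(x$frames[[1]]),
              x$pixel_size, x$frame_interval_s))
  invisible(x)
}

new_track <- function(track_id, point) {
  structure(list(track_id = as.integer(track_id),
                 points = point,
                 stop_reason = NA_character_),
            class = "cell_track")
}

track_point <- function(frame_index, frame_interval_s, region) {
  data.frame(frame = as.integer(frame_index),
             time_s = frame_index * frame_interval_s,
             x_px = region$centroid_px[["x"]],
             y_px = region$centroid_px[["y"]],
             x_um = region$centroid_um[["x"]],
             y_um = region$centroid_um[["y"]],
             area_um2 = region$area_um2,
             major_axis_um = region$major_axis_length_um)
}

#' Seed tracks from the first frame
#'
#' One track per segmented region of frame 0.
#'
#' @param first_frame_regions List of `cell_region` from [segment_frame()]
#'   applied to the full first frame.
#' @param frame_interval_s Seconds between frames.
#' @return List of `cell_track` objects (empty, with a warning, if no
#'   regions were found).
#' @export
initialize_tracks <- function(first_frame_regions, frame_interval_s = 60) {
  if (length(first_frame_regions) == 0L) {
    warning("no regions in the first frame; no tracks seeded")
    return(list())
  }
  lapply(seq_along(first_frame_regions), function(i) {
    new_track(i, track_point(0L, frame_interval_s, first_frame_regions[[i]]))
  })
}

#' Square ROI around a centroid
#'
#' Side = `ceiling(roi_scale * major_axis_len_px)`, centered on the
#' centroid, translated (not shrunk) to stay inside the frame where
#' possible; clipped to the frame if the side exceeds a frame dimension.
#'
#' @param centroid_px Numeric `c(x, y)`, 0-based pixel coordinates.
#' @param major_axis_len_px Major-axis length in pixels (> 0).
#' @param roi_scale ROI side multiplier.
#' @param frame_shape Integer `c(width, height)` in pixels.
#' @return List with `origin` (`c(x, y)`, 0-based) and `side`
#'   (`c(x, y)` extents).
#' @export
make_roi <- function(centroid_px, major_axis_len_px, roi_scale, frame_shape) {
  if (!is.finite(major_axis_len_px) || major_axis_len_px <= 0) {
    stop2("roi_degenerate", "non-positive major-axis length")
  }
  side <- ceiling(roi_scale * major_axis_len_px)
  sx <- min(side, frame_shape[1]); sy <- min(side, frame_shape[2])
  ox <- floor(centroid_px[[1]]) - floor(sx / 2)
  oy <- floor(centroid_px[[2]]) - floor(sy / 2)
  ox <- min(max(ox, 0), frame_shape[1] - sx)
  oy <- min(max(oy, 0), frame_shape[2] - sy)
  list(origin = c(x = ox, y = oy), side = c(x = sx, y = sy))
}

#' Advance a track by one frame
#'
#' Builds the ROI from the track's last point, segments inside it, and
#' appends the matched region's centroid or stops the track:
#' zero qualifying regions stop it with `no_centroid`, two or more with
#' `multiple_centroids`; a single region is accepted only if its centroid
#' lies within half the ROI side of the previous centroid and its area has
#' not jumped by more than `merge_area_factor` (a jump indicates contact
#' with another cell and also stops with `multiple_centroids`). Only points
#' collected before the stop event are retained.
#'
#' @param track A live `cell_track`.
#' @param next_frame A [frame_image()] for the following frame.
#' @param seg_config A [seg_config()].
#' @param config A [trk_config()].
#' @return The updated `cell_track`.
#' @export
step_track <- function(track, next_frame, seg_config, config) {
  stopifnot(inherits(track, "cell_track"))
  if (!is.na(track$stop_reason)) {
    stop("track has already stopped; cannot advance", call. = FALSE)
  }
  last <- track$points[nrow(track$points), ]
  ps <- next_frame$pixel_size
  axis_px <- last$major_axis_um / ps
  fs <- c(ncol(next_frame$pixels), nrow(next_frame$pixels))
  roi <- tryCatch(make_roi(c(last$x_px, last$y_px), axis_px,
                           config$roi_scale, fs),
                  roi_degenerate = function(e) NULL)
  if (is.null(roi)) {
    track$stop_reason <- "roi_degenerate"
    return(track)
  }
  crop <- next_frame$pixels[seq_len(roi$side[["y"]]) + roi$origin[["y"]],
                            seq_len(roi$side[["x"]]) + roi$origin[["x"]],
                            drop = FALSE]
  sub <- frame_image(pad_to_min(crop), pixel_size = ps,
                     frame_index = next_frame$frame_index)
  regions <- segment_frame(sub, seg_config)
  if (length(regions) == 0L) {
    track$stop_reason <- "no_centroid"
    return(track)
  }
  if (length(regions) >= 2L) {
    track$stop_reason <- "multiple_centroids"
    return(track)
  }
  r <- regions[[1]]
  gx <- r$centroid_px[["x"]] + roi$origin[["x"]]
  gy <- r$centroid_px[["y"]] + roi$origin[["y"]]
  # sanity guard: the match must stay near the previous centroid
  if (sqrt((gx - last$x_px)^2 + (gy - last$y_px)^2) >
      max(roi$side) / 2) {
    track$stop_reason <- "no_centroid"
    return(track)
  }
  if (r$area_um2 > config$merge_area_factor * last$area_um2) {
    track$stop_reason <- "multiple_centroids"  # suspected merge/contact
    return(track)
  }
  r$centroid_px <- c(x = gx, y = gy)
  r$centroid_um <- c(x = gx * ps, y = gy * ps)
  track$points <- rbind(track$points,
                        track_point(next_frame$frame_index,
                                    config$frame_interval_s, r))
  track
}

# segmentation needs a minimum extent; pad a small ROI crop by edge
# replication on the right/bottom (does not move coordinates)
pad_to_min <- function(m, min_dim = 16L) {
  ny <- nrow(m); nx <- ncol(m)
  if (ny >= min_dim && nx >= min_dim) return(m)
  m[c(seq_len(ny), rep(ny, max(0L, min_dim - ny))),
    c(seq_len(nx), rep(nx, max(0L, min_dim - nx))), drop = FALSE]
}

#' Track every cell through a stack
#'
#' Seeds tracks from a full segmentation of the first frame and advances
#' each frame by frame until it stops or the stack ends. Deterministic for
#' a given stack and configuration.
#'
#' @param stack A [frame_stack()].
#' @param seg_config A [seg_config()].
#' @param config A [trk_config()].
#' @param verbose Log per-track stop events via `message()`.
#' @return List of `cell_track` objects.
#' @export
track_all <- function(stack, seg_config, config = trk_config(),
                      verbose = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(stack$frames) < 2L) {
    stop("tracking needs at least 2 frames", call. = FALSE)
  }
  f0 <- frame_image(stack$frames[[1]], stack$pixel_size, 0L)
  regions <- segment_frame(f0, seg_config)
  tracks <- initialize_tracks(regions, config$frame_interval_s)
  if (length(tracks) == 0L) return(tracks)
  active <- rep(TRUE, length(tracks))
  for (fi in seq_along(stack$frames)[-1]) {
    if (!any(active)) break
    fr <- frame_image(stack$frames[[fi]], stack$pixel_size, fi - 1L)
    for (ti in which(active)) {
      tracks[[ti]] <- step_track(tracks[[ti]], fr, seg_config, config)
      if (!is.na(tracks[[ti]]$stop_reason)) {
        active[ti] <- FALSE
        if (verbose) {
          message(sprintf("track %d stopped at frame %d: %s",
                          tracks[[ti]]$track_id, fi - 1L,
                          tracks[[ti]]$stop_reason))
        }
      }
    }
  }
  for (ti in which(active)) tracks[[ti]]$stop_reason <- "end_of_stack"
  tracks
}

#' Filter tracks by duration
#'
#' Keeps tracks whose duration (last time minus first time) is strictly
#' greater than `min_track_duration_min`. A track spanning exactly the
#' threshold is excluded.
#'
#' @param tracks List of `cell_track`.
#' @param min_track_duration_min Minutes (default 60).
#' @return Filtered list.
#' @export
filter_tracks <- function(tracks, min_track_duration_min = 60) {
  keep <- vapply(tracks, function(tr) {
    dur_s <- tr$points$time_s[nrow(tr$points)] - tr$points$time_s[1]
    dur_s / 60 > min_track_duration_min
  }, logical(1))
  tracks[keep]
}

#' Convert a track to a trajectory
#'
#' @param track A `cell_track`.
#' @return A [trajectory()] of the track's centroid positions in
#'   micrometres.
#' @export
track_to_trajectory <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  trajectory(cbind(track$points$x_um, track$points$y_um),
             track$points$time_s, cell_id = track$track_id)
}

#' Tabulate tracks
#'
#' @param tracks List of `cell_track`.
#' @return Data frame with columns `track_id`, `frame`, `time_s`, `x_px`,
#'   `y_px`, `x_um`, `y_um`, `area_um2`, `major_axis_um`, `stop_reason`
#'   (populated on each track's last row, `NA` elsewhere).
#' @export
tracks_to_table <- function(tracks) {
  if (length(tracks) == 0L) {
    return(data.frame(track_id = integer(), frame = integer(),
                      time_s = numeric(), x_px = numeric(), y_px = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), major_axis_um = numeric(),
                      stop_reason = character()))
  }
  do.call(rbind, lapply(tracks, function(tr) {
    df <- tr$points
    df$track_id <- tr$track_id
    df$stop_reason <- c(rep(NA_character_, nrow(df) - 1L), tr$stop_reason)
    df[, c("track_id", "frame", "time_s", "x_px", "y_px", "x_um", "y_um",
           "area_um2", "major_axis_um", "stop_reason")]
  }))
}

#' Rebuild track objects from a track table
#'
#' @param df Data frame in the [tracks_to_table()] schema.
#' @return List of `cell_track`.
#' @export
table_to_tracks <- function(df) {
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    tr <- new_track(d$track_id[1],
                    d[, c("frame", "time_s", "x_px", "y_px", "x_um", "y_um",
                          "area_um2", "major_axis_um")])
    rownames(tr$points) <- NULL
    sr <- d$stop_reason[nrow(d)]
    tr$stop_reason <- if (is.null(sr)) NA_character_ else sr
    tr
  })
}
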