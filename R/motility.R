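# Trajectory motility parameters. Ten parameters per cell: migration speed,
# frequency of turns below 90/60/30 degrees, migration distance between
# turns below 90/60/30 degrees, sum of turn angles, quiescent time, and
# total migration length. Duration-dependent parameters (turn frequencies,
# sum of angles, total length) are normalized to a 30-h observation window.

NORMALIZATION_HOURS <- 30

#' Construct a trajectory
#'
#' @param positions_um n x 2 matrix of (x, y) centroid positions in
#'   micrometres.
#' @param times_s Strictly increasing times in seconds with uniform spacing.
#' @param cell_id Identifier carried through to feature tables.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(positions_um, times_s, cell_id = "cell") {
  positions_um <- as.matrix(positions_um)
  if (ncol(positions_um) != 2L) stop("positions must be n x 2", call. = FALSE)
  n <- nrow(positions_um)
  if (length(times_s) != n) stop("times and positions differ in length",
                                 call. = FALSE)
  if (n >= 2L) {
    dt <- diff(times_s)
    if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
    if (diff(range(dt)) > 1e-6 * dt[1]) {
      stop("time spacing must be uniform", call. = FALSE)
    }
  }
  structure(list(positions_um = unname(positions_um),
                 times_s = as.numeric(times_s),
                 cell_id = cell_id),
            class = "trajectory")
}

traj_dt <- function(traj) traj$times_s[2] - traj$times_s[1]
traj_duration_s <- function(traj) {
  traj$times_s[length(traj$times_s)] - traj$times_s[1]
}

#' Step displacements and speeds
#'
#' @param traj A [trajectory()] with at least 2 positions.
#' @return Data frame with one row per step: `dx_um`, `dy_um`, `dist_um`,
#'   `speed_um_s`.
#' @export
step_displacements <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$positions_um)
  if (n < 2L) stop2("insufficient_data", "need >= 2 positions for displacements")
  d <- diff(traj$positions_um)
  dist <- sqrt(rowSums(d^2))
  data.frame(dx_um = d[, 1], dy_um = d[, 2], dist_um = dist,
             speed_um_s = dist / traj_dt(traj))
}

#' Turn angles along a trajectory
#'
#' The turn angle at an interior point is the angle between the incoming
#' and outgoing displacement vectors, in \[0, 180\] degrees. When either
#' displacement is the zero vector (no centroid movement over one
#' interval), the angle is set to 0 and flagged `zero_step`; such angles
#' are excluded from turn counts but contribute 0 to the angle sum.
#'
#' @param traj A [trajectory()] with at least 3 positions.
#' @return Data frame with `angle_deg` and logical `zero_step`.
#' @export
turn_angles <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$positions_um)
  if (n < 3L) stop2("insufficient_data", "need >= 3 positions for turn angles")
  d <- diff(traj$positions_um)
  a <- d[-nrow(d), , drop = FALSE]
  b <- d[-1, , drop = FALSE]
  dot <- rowSums(a * b)
  crs <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  ang <- atan2(abs(crs), dot) * 180 / pi
  zero <- rowSums(a^2) == 0 | rowSums(b^2) == 0
  ang[zero] <- 0
  data.frame(angle_deg = ang, zero_step = zero)
}

per_30h <- function(raw, traj) {
  dur_h <- traj_duration_s(traj) / 3600
  if (dur_h <= 0) stop2("insufficient_data", "zero-duration trajectory")
  raw / dur_h * NORMALIZATION_HOURS
}

#' Frequency of turns below an angular threshold
#'
#' Counts interior turn angles strictly below the threshold, excluding
#' zero-displacement steps, and normalizes the count to a 30-h window
#' (hourly rate times 30).
#'
#' @param traj A [trajectory()].
#' @param threshold_deg Angular threshold in degrees (90, 60, or 30 in the
#'   standard parameter set; any positive value is accepted).
#' @return List with `raw` (count) and `per_30h`.
#' @export
freq_turns_below <- function(traj, threshold_deg) {
  ta <- turn_angles(traj)
  raw <- sum(ta$angle_deg < threshold_deg & !ta$zero_step)
  list(raw = raw, per_30h = per_30h(raw, traj))
}

#' Migration distance between turns below a threshold
#'
#' Total path length divided by the number of qualifying (below-threshold,
#' non-zero-step) turns: the mean distance migrated per direction change
#' sharper than the threshold. Undefined (NA) when no turn qualifies; such
#' cells are dropped from fits that use this parameter.
#'
#' @inheritParams freq_turns_below
#' @return Distance in micrometres, or `NA` if no turn qualifies.
#' @export
md_between_turns <- function(traj, threshold_deg) {
  cnt <- freq_turns_below(traj, threshold_deg)$raw
  if (cnt == 0L) return(NA_real_)
  sum(step_displacements(traj)$dist_um) / cnt
}

#' Sum of turn angles
#'
#' Cumulative polarity change: the sum of all interior turn angles
#' (zero-displacement steps contribute 0), normalized per 30 h.
#'
#' @param traj A [trajectory()].
#' @return List with `raw` (degrees) and `per_30h`.
#' @export
sum_turn_angles <- function(traj) {
  ta <- turn_angles(traj)
  raw <- sum(ta$angle_deg)
  list(raw = raw, per_30h = per_30h(raw, traj))
}

#' Quiescent time
#'
#' Cumulative duration with instantaneous speed strictly below the cell's
#' own mean step speed.
#'
#' @param traj A [trajectory()].
#' @return List with `seconds` and `fraction` (of the track duration).
#' @export
quiescent_time <- function(traj) {
  sp <- step_displacements(traj)$speed_um_s
  thr <- mean(sp)
  secs <- traj_dt(traj) * sum(sp < thr)
  list(seconds = secs, fraction = secs / traj_duration_s(traj))
}

#' Total migration length
#'
#' Sum of step displacements, normalized per 30 h.
#'
#' @param traj A [trajectory()].
#' @return List with `raw_um` and `per_30h`.
#' @export
total_migration_length <- function(traj) {
  raw <- sum(step_displacements(traj)$dist_um)
  list(raw_um = raw, per_30h = per_30h(raw, traj))
}

#' Names of the ten motility parameters
#'
#' Canonical column names of the per-cell feature table, in the order used
#' throughout: migration speed (um/s), turn frequencies below 90/60/30
#' degrees (per 30 h), migration distances between turns below 90/60/30
#' degrees (um), sum of turn angles (degrees per 30 h), quiescent time (s),
#' total migration length (um per 30 h).
#'
#' @return Character vector of length 10.
#' @export
motility_parameters <- function() {
  c("mean_speed_um_s",
    "freq_below_90", "freq_below_60", "freq_below_30",
    "md_below_90", "md_below_60", "md_below_30",
    "sum_turn_angles", "quiescent_time_s", "total_length")
}

#' Motility profile of one trajectory
#'
#' Computes the ten motility parameters plus the quiescent fraction and
#' track duration.
#'
#' @param traj A [trajectory()] with at least 3 positions (and typically
#'   more than 1 h of data; see [filter_tracks()]).
#' @return One-row data frame: `cell_id`, the columns of
#'   [motility_parameters()], `quiescent_frac`, `track_duration_h`.
#' @export
motility_profile <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sp <- step_displacements(traj)
  tot <- total_migration_length(traj)
  q <- quiescent_time(traj)
  data.frame(
    cell_id = traj$cell_id,
    mean_speed_um_s = mean(sp$speed_um_s),
    freq_below_90 = freq_turns_below(traj, 90)$per_30h,
    freq_below_60 = freq_turns_below(traj, 60)$per_30h,
    freq_below_30 = freq_turns_below(traj, 30)$per_30h,
    md_below_90 = md_between_turns(traj, 90),
    md_below_60 = md_between_turns(traj, 60),
    md_below_30 = md_between_turns(traj, 30),
    sum_turn_angles = sum_turn_angles(traj)$per_30h,
    quiescent_time_s = q$seconds,
    total_length = tot$per_30h,
    quiescent_frac = q$fraction,
    track_duration_h = traj_duration_s(traj) / 3600,
    stringsAsFactors = FALSE
  )
}

#' Motility profiles for a list of tracks
#'
#' Applies the >1 h duration filter, converts surviving tracks to
#' trajectories, and stacks their profiles into a feature table.
#'
#' @param tracks List of `cell_track` from [track_all()].
#' @param group Optional group label recorded for every row.
#' @param min_track_duration_min Duration filter passed to
#'   [filter_tracks()] (default 60).
#' @return Data frame of motility profiles (possibly 0 rows), with a
#'   `group` column if `group` is given.
#' @export
profile_tracks <- function(tracks, group = NULL,
                           min_track_duration_min = 60) {
  kept <- filter_tracks(tracks, min_track_duration_min)
  if (length(kept) == 0L) {
    out <- motility_profile(trajectory(rbind(c(0, 0), c(1, 0), c(2, 0)),
                                       c(0, 60, 120)))[0, ]
  } else {
    out <- do.call(rbind, lapply(kept, function(tr) {
      motility_profile(track_to_trajectory(tr))
    }))
  }
  if (!is.null(group)) out$group <- rep(group, nrow(out))
  rownames(out) <- NULL
  out
}
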