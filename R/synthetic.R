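# Ground-truthed synthetic data: persistent-random-walk trajectories with a
# one- or two-state speed process, and rendered phase-contrast-like image
# stacks (dark-ish elliptical cell body, bright halo rim, optional faint
# protrusions, additive Gaussian noise).
#
# The trajectory model is the package's own: headings evolve by
# wrapped-normal increments with concentration kappa (variance 1/kappa),
# which reproduces the two phenotypes used for validation -- a directional
# population with transient high-speed bursts, and a temporally homogeneous
# slow population.

#' Speed-process specifications
#'
#' `speed_two_state()` describes a two-state Markov speed process
#' (transient high-speed bursts against a slow baseline);
#' `speed_constant()` a homogeneous speed with Gaussian jitter (truncated
#' at zero).
#'
#' @param v_high,v_low High/low state speeds in um/s (`v_high > v_low >= 0`).
#' @param p_high_to_low,p_low_to_high Per-step switch probabilities.
#' @param v Mean speed in um/s.
#' @param sd Speed jitter standard deviation in um/s.
#' @return A speed-model specification list.
#' @export
speed_two_state <- function(v_high, v_low, p_high_to_low, p_low_to_high) {
  if (!(v_high > v_low && v_low >= 0)) {
    stop("need v_high > v_low >= 0", call. = FALSE)
  }
  p <- c(p_high_to_low, p_low_to_high)
  if (any(p < 0 | p > 1)) stop("switch probabilities must be in [0, 1]",
                               call. = FALSE)
  list(type = "two_state", v_high = v_high, v_low = v_low,
       p_high_to_low = p_high_to_low, p_low_to_high = p_low_to_high)
}

#' @rdname speed_two_state
#' @export
speed_constant <- function(v, sd = 0) {
  if (v < 0 || sd < 0) stop("need v >= 0 and sd >= 0", call. = FALSE)
  list(type = "constant", v = v, sd = sd)
}

#' Population specification for trajectory simulation
#'
#' @param n_cells Number of cells.
#' @param duration_min Track duration in minutes.
#' @param dt_s Time step in seconds (default 60, the standard acquisition
#'   interval).
#' @param speed_model A [speed_two_state()] or [speed_constant()].
#' @param kappa Heading persistence: heading increments are wrapped-normal
#'   with variance `1/kappa` (radians^2). `kappa = 0` means uniform
#'   headings (no persistence); large `kappa` means nearly straight paths.
#' @param seed Default seed for [simulate_population()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells, duration_min, dt_s = 60,
                            speed_model = speed_constant(0.015, 0.004),
                            kappa = 2, seed = 1) {
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (duration_min <= 0 || dt_s <= 0) {
    stop("duration and time step must be positive", call. = FALSE)
  }
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (!speed_model$type %in% c("two_state", "constant")) {
    stop("unknown speed model", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells),
                 duration_min = duration_min, dt_s = dt_s,
                 speed_model = speed_model, kappa = kappa,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Preset population specifications
#'
#' Two ready-made phenotypes: `"cancerlike"` is a directional
#' two-speed-mode population (high-speed bursts of ~0.05 um/s against a
#' 0.008 um/s baseline, heading concentration kappa = 8); in
#' `"fibroblastlike"` speed is temporally homogeneous around 0.015 um/s and
#' headings are less persistent (kappa = 2). Speeds bracket the typical
#' single-cell values observed for the two reference cell types (around
#' 0.02 and 0.015 um/s), with burst spacing well under 100 min.
#'
#' @param preset `"cancerlike"` or `"fibroblastlike"`.
#' @param n_cells,duration_min,seed Passed to [population_spec()].
#' @return A `population_spec`.
#' @export
preset_population_spec <- function(preset = c("cancerlike", "fibroblastlike"),
                                   n_cells = 50, duration_min = 200,
                                   seed = 1) {
  preset <- match.arg(preset)
  if (preset == "cancerlike") {
    population_spec(n_cells, duration_min, dt_s = 60,
                    speed_model = speed_two_state(0.05, 0.008, 0.12, 0.06),
                    kappa = 8, seed = seed)
  } else {
    population_spec(n_cells, duration_min, dt_s = 60,
                    speed_model = speed_constant(0.015, 0.004),
                    kappa = 2, seed = seed)
  }
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Simulate one trajectory
#'
#' Persistent random walk: the heading gains a wrapped-normal increment of
#' variance `1/kappa` each step (uniform when `kappa = 0`); the step length
#' is the current speed times the time step. The speed follows the spec's
#' speed model.
#'
#' @param spec A [population_spec()].
#' @param seed Seed for this trajectory; `NULL` draws from the current RNG
#'   stream.
#' @param cell_id Identifier for the trajectory.
#' @return List with `trajectory` (a [trajectory()] starting at the
#'   origin) and `truth` (per-step `speeds_um_s`, `headings_rad`,
#'   realized `mean_speed_um_s`, and the spec's `kappa`).
#' @export
simulate_trajectory <- function(spec, seed = NULL, cell_id = "sim") {
  stopifnot(inherits(spec, "population_spec"))
  run <- function() {
    n <- max(2L, as.integer(round(spec$duration_min * 60 / spec$dt_s)))
    sm <- spec$speed_model
    if (sm$type == "constant") {
      v <- pmax(0, stats::rnorm(n, sm$v, sm$sd))
    } else {
      p_stat_high <- {
        s <- sm$p_high_to_low + sm$p_low_to_high
        if (s > 0) sm$p_low_to_high / s else 0
      }
      state <- logical(n)  # TRUE = high
      state[1] <- stats::runif(1) < p_stat_high
      if (n > 1) {
        u <- stats::runif(n - 1)
        for (i in seq.int(2L, n)) {
          state[i] <- if (state[i - 1L]) u[i - 1L] >= sm$p_high_to_low
                      else u[i - 1L] < sm$p_low_to_high
        }
      }
      v <- ifelse(state, sm$v_high, sm$v_low)
    }
    inc <- if (spec$kappa > 0) {
      wrap_angle(stats::rnorm(n - 1L, 0, 1 / sqrt(spec$kappa)))
    } else {
      stats::runif(n - 1L, -pi, pi)
    }
    heading <- cumsum(c(stats::runif(1, -pi, pi), inc))
    steps <- cbind(v * spec$dt_s * cos(heading),
                   v * spec$dt_s * sin(heading))
    pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
    list(trajectory = trajectory(pos, seq.int(0L, n) * spec$dt_s,
                                 cell_id = cell_id),
         truth = list(speeds_um_s = v, headings_rad = heading,
                      mean_speed_um_s = mean(v), kappa = spec$kappa))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate two labeled populations into a feature table
#'
#' Generates trajectories for both specs, profiles each with the motility
#' module, and returns the stacked, labeled feature table.
#'
#' @param spec_a,spec_b [population_spec()]s for the two groups.
#' @param label_a,label_b Group labels (`label_a` is the conventional
#'   positive class).
#' @param seed Master seed; `NULL` uses each spec's own seed. All per-cell
#'   randomness derives from it.
#' @return Data frame of motility profiles with a `group` column, plus a
#'   `"truth"` attribute holding per-cell generator records.
#' @export
simulate_population <- function(spec_a, spec_b, label_a = "A", label_b = "B",
                                seed = NULL) {
  base <- if (is.null(seed)) spec_a$seed else seed
  run_group <- function(spec, label, offset) {
    lapply(seq_len(spec$n_cells), function(i) {
      sim <- simulate_trajectory(spec, seed = base + offset + i,
                                 cell_id = paste0(label, "_", i))
      prof <- motility_profile(sim$trajectory)
      prof$group <- label
      list(profile = prof, truth = sim$truth)
    })
  }
  a <- run_group(spec_a, label_a, 0L)
  b <- run_group(spec_b, label_b, 500000L)
  out <- do.call(rbind, lapply(c(a, b), `[[`, "profile"))
  rownames(out) <- NULL
  attr(out, "truth") <- lapply(c(a, b), `[[`, "truth")
  out
}

#' Scene specification for rendering
#'
#' Describes how cells are drawn into phase-contrast-like frames: an
#' elliptical cell body at a small negative offset from the background, a
#' bright Gaussian halo rim along the boundary, optional faint radial
#' protrusions, and additive Gaussian noise. Default geometry gives a
#' spread-cell area near 1900 um^2 (semi-axes 30 x 20 um).
#'
#' @param frame_shape Integer `c(width, height)` in pixels.
#' @param pixel_size um per pixel (default 0.65).
#' @param semi_axes_um Ellipse semi-axes `c(a, b)` in um.
#' @param interior_offset Intensity offset of the cell body relative to
#'   background (negative = darker).
#' @param halo_amplitude Peak added intensity of the halo rim.
#' @param halo_width_px Gaussian sigma of the rim in pixels.
#' @param n_protrusions Number of thin radial protrusions per cell.
#' @param protrusion_contrast Added intensity of protrusion pixels.
#' @param protrusion_length_um Protrusion length beyond the rim, in um.
#' @param background Background intensity level.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Seed for orientations, protrusion angles and noise.
#' @param orientations_rad Optional fixed ellipse orientations, one per
#'   rendered cell (recycled); `NULL` (default) draws them from the seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(frame_shape = c(256L, 256L), pixel_size = 0.65,
                       semi_axes_um = c(30, 20), interior_offset = -0.06,
                       halo_amplitude = 0.35, halo_width_px = 2,
                       n_protrusions = 2, protrusion_contrast = 0.05,
                       protrusion_length_um = 15, background = 0.5,
                       noise_sd = 0.01, seed = 1,
                       orientations_rad = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (any(semi_axes_um <= 0)) stop("semi-axes must be positive", call. = FALSE)
  structure(list(frame_shape = as.integer(frame_shape),
                 pixel_size = pixel_size, semi_axes_um = semi_axes_um,
                 interior_offset = interior_offset,
                 halo_amplitude = halo_amplitude,
                 halo_width_px = halo_width_px,
                 n_protrusions = as.integer(n_protrusions),
                 protrusion_contrast = protrusion_contrast,
                 protrusion_length_um = protrusion_length_um,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 orientations_rad = orientations_rad),
            class = "scene_spec")
}

#' Shift a trajectory
#'
#' @param traj A [trajectory()].
#' @param offset_um Numeric `c(x, y)` in um added to every position.
#' @return The shifted [trajectory()].
#' @export
shift_trajectory <- function(traj, offset_um) {
  trajectory(sweep(traj$positions_um, 2, -offset_um), traj$times_s,
             traj$cell_id)
}

# draw one cell into `img` (modified copy returned); center in px
draw_cell <- function(img, cx, cy, a_px, b_px, phi, scene, prot_angles) {
  ny <- nrow(img); nx <- ncol(img)
  halo_reach <- 4 * scene$halo_width_px
  prot_px <- scene$protrusion_length_um / scene$pixel_size
  rad <- ceiling(max(a_px, b_px) + halo_reach + prot_px + 2)
  x0 <- max(0, floor(cx - rad)); x1 <- min(nx - 1, ceiling(cx + rad))
  y0 <- max(0, floor(cy - rad)); y1 <- min(ny - 1, ceiling(cy + rad))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
  X <- matrix(rep(xs, each = length(ys)), nrow = length(ys)) - cx
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys)) - cy
  xr <- cos(phi) * X + sin(phi) * Y
  yr <- -sin(phi) * X + cos(phi) * Y
  e <- sqrt((xr / a_px)^2 + (yr / b_px)^2)
  patch <- img[ys + 1L, xs + 1L, drop = FALSE]
  patch <- patch + scene$interior_offset * (e <= 1)
  patch <- patch + scene$halo_amplitude *
    exp(-0.5 * ((e - 1) * b_px / scene$halo_width_px)^2)
  img[ys + 1L, xs + 1L] <- patch
  # faint protrusions: 1-px-wide rays from the rim outward
  if (scene$n_protrusions > 0 && scene$protrusion_contrast != 0) {
    for (psi in prot_angles) {
      # boundary radius of the rotated ellipse along direction psi
      ca <- cos(psi - phi); sa <- sin(psi - phi)
      rb <- 1 / sqrt((ca / a_px)^2 + (sa / b_px)^2)
      tt <- seq(rb, rb + prot_px, by = 0.5)
      pxs <- round(cx + tt * cos(psi)); pys <- round(cy + tt * sin(psi))
      ok <- pxs >= 0 & pxs < nx & pys >= 0 & pys < ny
      idx <- unique(cbind(pys[ok] + 1L, pxs[ok] + 1L))
      if (nrow(idx)) img[idx] <- img[idx] + scene$protrusion_contrast
    }
  }
  img
}

#' Render trajectories into a phase-contrast-like stack
#'
#' Each trajectory becomes a cell drawn frame by frame at its centroid
#' position: elliptical body, bright halo rim, optional protrusions, plus
#' Gaussian noise. Cells keep a fixed (seeded) orientation. Trajectories
#' may have different lengths; a cell disappears from the scene after its
#' last point (the stack length is the longest trajectory unless
#' `n_frames` is given).
#'
#' @param trajectories List of [trajectory()]s with positions in um (frame
#'   coordinates, x right / y down, origin at the top-left pixel center).
#' @param scene A [scene_spec()].
#' @param n_frames Optional stack length override.
#' @return List with `stack` (a [frame_stack()]) and `truth` (data frame
#'   `frame`, `cell_id`, `x_px`, `y_px` of true centers).
#' @export
render_scene <- function(trajectories, scene, n_frames = NULL) {
  stopifnot(inherits(scene, "scene_spec"))
  if (length(trajectories) == 0L) stop("no trajectories", call. = FALSE)
  ps <- scene$pixel_size
  a_px <- scene$semi_axes_um[1] / ps
  b_px <- scene$semi_axes_um[2] / ps
  nx <- scene$frame_shape[1]; ny <- scene$frame_shape[2]
  dt <- traj_dt(trajectories[[1]])
  margin <- max(a_px, b_px)
  for (tr in trajectories) {
    p <- tr$positions_um / ps
    if (any(p[, 1] < margin | p[, 1] > nx - 1 - margin |
            p[, 2] < margin | p[, 2] > ny - 1 - margin)) {
      stop("trajectory leaves the frame (cell body must fit inside)",
           call. = FALSE)
    }
  }
  lens <- vapply(trajectories, function(tr) nrow(tr$positions_um), integer(1))
  nf <- if (is.null(n_frames)) max(lens) else n_frames
  with_seed(scene$seed, {
    phis <- if (is.null(scene$orientations_rad)) {
      stats::runif(length(trajectories), -pi, pi)
    } else {
      rep_len(scene$orientations_rad, length(trajectories))
    }
    prot <- lapply(seq_along(trajectories), function(i) {
      stats::runif(scene$n_protrusions, -pi, pi)
    })
    frames <- vector("list", nf)
    truth <- list()
    for (f in seq_len(nf)) {
      img <- matrix(scene$background, ny, nx)
      for (i in seq_along(trajectories)) {
        if (lens[i] < f) next
        cpx <- trajectories[[i]]$positions_um[f, ] / ps
        img <- draw_cell(img, cpx[1], cpx[2], a_px, b_px, phis[i], scene,
                         prot[[i]])
        truth[[length(truth) + 1L]] <- data.frame(
          frame = f - 1L, cell_id = trajectories[[i]]$cell_id,
          x_px = cpx[1], y_px = cpx[2])
      }
      if (scene$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(ny * nx, 0, scene$noise_sd), ny, nx)
      }
      frames[[f]] <- img
    }
    list(stack = frame_stack(frames, pixel_size = ps, frame_interval_s = dt),
         truth = do.call(rbind, truth))
  })
}

#' Lay trajectories out on a grid
#'
#' Shifts each trajectory so that cells sit on a regular grid with enough
#' pitch that non-interacting cells never approach each other, and sizes
#' the frame to fit. Used by the simulate command to render whole
#' populations. The default clearance keeps neighbours outside a tracking
#' ROI of twice the cell's major axis.
#'
#' @param trajectories List of [trajectory()]s (any origin).
#' @param scene A [scene_spec()] providing cell geometry; its
#'   `frame_shape` is replaced in the returned scene.
#' @param pad_um Extra clearance per grid cell in um (default 60).
#' @return List with shifted `trajectories` and a resized `scene`.
#' @export
arrange_scene <- function(trajectories, scene, pad_um = 60) {
  ps <- scene$pixel_size
  n <- length(trajectories)
  spans <- vapply(trajectories, function(tr) {
    max(apply(tr$positions_um, 2, function(v) diff(range(v))))
  }, numeric(1))
  pitch_um <- max(spans) + 2 * (max(scene$semi_axes_um) + pad_um)
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  shifted <- lapply(seq_len(n), function(i) {
    r <- (i - 1L) %/% ncols; c <- (i - 1L) %% ncols
    tr <- trajectories[[i]]
    # center the trajectory's bounding box on its grid node
    mid <- colMeans(apply(tr$positions_um, 2, range))
    target <- c((c + 0.5) * pitch_um, (r + 0.5) * pitch_um)
    shift_trajectory(tr, target - mid)
  })
  scene$frame_shape <- as.integer(ceiling(
    c(ncols, nrows) * pitch_um / ps))
  list(trajectories = shifted, scene = scene)
}
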