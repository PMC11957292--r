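# Independent reference implementations (deliberately naive; loops and
# enumeration) used to validate the vectorized pipeline.

# --- image oracles ---------------------------------------------------------

# Sobel magnitude by explicit double-loop convolution, edge replication
sobel_oracle <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # [dy+2, dx+2]
  ky <- t(kx)
  out <- matrix(0, ny, nx)
  at <- function(y, x) m[min(max(y, 1), ny), min(max(x, 1), nx)]
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      gx <- 0; gy <- 0
      for (dy in -1:1) for (dx in -1:1) {
        v <- at(y + dy, x + dx)
        gx <- gx + kx[dy + 2, dx + 2] * v
        gy <- gy + ky[dy + 2, dx + 2] * v
      }
      out[y, x] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

kernel_offsets <- function(kern) {
  r <- (nrow(kern) - 1L) / 2L
  idx <- which(kern > 0, arr.ind = TRUE)
  cbind(dy = idx[, 1] - r - 1L, dx = idx[, 2] - r - 1L)
}

shift_logical <- function(m, dy, dx, fill) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

# dilation: out-of-bounds treated as background
dilate_oracle <- function(mask, kern) {
  off <- kernel_offsets(kern)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_logical(mask, off[i, "dy"], off[i, "dx"], FALSE)
  }
  out
}

# erosion: out-of-bounds treated as foreground
erode_oracle <- function(mask, kern) {
  off <- kernel_offsets(kern)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_logical(mask, -off[i, "dy"], -off[i, "dx"], TRUE)
  }
  out
}

# hole filling: flood the background from the border with 4-connectivity;
# anything not reached becomes foreground
fill_oracle <- function(mask) {
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  border <- matrix(FALSE, nrow(mask), ncol(mask))
  border[1, ] <- TRUE; border[nrow(bg), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(bg)] <- TRUE
  reach <- bg & border
  repeat {
    grown <- reach
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      grown <- grown | shift_logical(reach, d[1], d[2], FALSE)
    }
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | !reach
}

refine_oracle <- function(edge_mask, cfg) {
  m <- dilate_oracle(edge_mask, octagon_kernel(cfg$dilation_radius_px))
  m <- fill_oracle(m)
  for (i in seq_len(cfg$erosion_repeats)) {
    m <- erode_oracle(m, diamond_kernel(cfg$erosion_radius_px))
  }
  m
}

# 8-connected labeling by breadth-first search
bfs_label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lbl <- matrix(0L, ny, nx)
  cur <- 0L
  for (start in which(mask)) {
    if (lbl[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lbl[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      y <- (p - 1L) %% ny + 1L; x <- (p - 1L) %/% ny + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
        if (mask[yy, xx] && lbl[yy, xx] == 0L) {
          lbl[yy, xx] <- cur
          queue <- c(queue, (xx - 1L) * ny + yy)
        }
      }
    }
  }
  lbl
}

# even-odd ray-crossing point-in-polygon (boundary-inclusive within tol)
point_in_poly_eo <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- min(max(t, 0), 1)
      if ((px - (xi + t * dx))^2 + (py - (yi + t * dy))^2 < tol) return(TRUE)
    } else if ((px - xi)^2 + (py - yi)^2 < tol) return(TRUE)
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# random test frame: a few bright-rimmed ellipses on noise
rand_frame <- function(seed, n = 128L) {
  set.seed(seed)
  img <- matrix(0.5, n, n)
  for (k in seq_len(sample(2:3, 1))) {
    cx <- runif(1, 30, n - 30); cy <- runif(1, 30, n - 30)
    a <- runif(1, 14, 20); b <- runif(1, 10, 14); phi <- runif(1, -pi, pi)
    X <- matrix(rep(0:(n - 1), each = n), n) - cx
    Y <- matrix(rep(0:(n - 1), times = n), n) - cy
    xr <- cos(phi) * X + sin(phi) * Y; yr <- -sin(phi) * X + cos(phi) * Y
    e <- sqrt((xr / a)^2 + (yr / b)^2)
    img <- img - 0.05 * (e <= 1) + 0.3 * exp(-0.5 * ((e - 1) * b / 1.5)^2)
  }
  img + matrix(rnorm(n * n, 0, 0.01), n)
}

rand_blob_mask <- function(seed, n = 40L) {
  set.seed(seed)
  cx <- runif(1, 12, n - 12); cy <- runif(1, 12, n - 12)
  a <- runif(1, 5, 9); b <- runif(1, 4, 7); phi <- runif(1, -pi, pi)
  X <- matrix(rep(0:(n - 1), each = n), n) - cx
  Y <- matrix(rep(0:(n - 1), times = n), n) - cy
  xr <- cos(phi) * X + sin(phi) * Y; yr <- -sin(phi) * X + cos(phi) * Y
  (xr / a)^2 + (yr / b)^2 <= 1
}

# --- trajectory oracles ----------------------------------------------------

rand_traj <- function(seed, n = 20L, dt = 60) {
  set.seed(seed)
  trajectory(cbind(cumsum(rnorm(n)), cumsum(rnorm(n))),
             seq_len(n) * dt - dt, cell_id = paste0("r", seed))
}

angles_oracle <- function(traj) {
  p <- traj$positions_um
  n <- nrow(p)
  ang <- numeric(n - 2L); zero <- logical(n - 2L)
  for (i in seq_len(n - 2L)) {
    a <- p[i + 1L, ] - p[i, ]; b <- p[i + 2L, ] - p[i + 1L, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) { ang[i] <- 0; zero[i] <- TRUE; next }
    u <- sum(a * b) / (na * nb)
    ang[i] <- acos(min(max(u, -1), 1)) * 180 / pi
  }
  list(angle_deg = ang, zero_step = zero)
}

profile_oracle <- function(traj) {
  p <- traj$positions_um
  dt <- traj$times_s[2] - traj$times_s[1]
  dur_s <- traj$times_s[length(traj$times_s)] - traj$times_s[1]
  steps <- sqrt(rowSums(diff(p)^2))
  ao <- angles_oracle(traj)
  norm30 <- function(raw) raw / (dur_s / 3600) * 30
  fb <- function(th) sum(ao$angle_deg < th & !ao$zero_step)
  md <- function(th) if (fb(th) == 0) NA_real_ else sum(steps) / fb(th)
  sp <- steps / dt
  list(mean_speed_um_s = mean(sp),
       freq_below_90 = norm30(fb(90)),
       freq_below_60 = norm30(fb(60)),
       freq_below_30 = norm30(fb(30)),
       md_below_90 = md(90), md_below_60 = md(60), md_below_30 = md(30),
       sum_turn_angles = norm30(sum(ao$angle_deg)),
       quiescent_time_s = dt * sum(sp < mean(sp)),
       total_length = norm30(sum(steps)))
}

# small rendered scene helpers used by several test files
static_cell_scene <- function(center_um = c(52, 52), n_frames = 11L,
                              noise_sd = 0.005, seed = 3) {
  tr <- trajectory(matrix(rep(center_um, n_frames), ncol = 2, byrow = TRUE),
                   seq_len(n_frames) * 60 - 60, "c1")
  render_scene(list(tr), scene_spec(frame_shape = c(160L, 160L),
                                    noise_sd = noise_sd, seed = seed))
}
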