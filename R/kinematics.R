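#' Larval centroid trajectory
#'
#' A regularly sampled 2-D centroid track of one larva: positions in mm at a
#' fixed frame interval `dt` (0.5 s at the 2 frames/s recording rate). A full
#' 50-min recording has 6000 frames.
#'
#' @param x,y Centroid coordinates (mm), equal length, at least 2 frames.
#' @param dt Frame interval in seconds (default 0.5).
#' @param larva_id Identifier label.
#' @param t0 Time of the first frame (s).
#' @return An object of class `larva_trajectory` with elements `times`,
#'   `positions` (n x 2 matrix), `dt`, `larva_id`.
#' @export
#' @examples
#' tr <- trajectory(x = c(0, 1, 2), y = c(0, 0, 1))
trajectory <- function(x, y, dt = 0.5, larva_id = "larva_1", t0 = 0) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y), dt > 0)
  if (length(x) < 2) stop("a trajectory needs at least 2 frames", call. = FALSE)
  structure(list(times = t0 + (seq_along(x) - 1) * dt,
                 positions = cbind(x = as.numeric(x), y = as.numeric(y)),
                 dt = dt, larva_id = larva_id),
            class = "larva_trajectory")
}

#' @export
print.larva_trajectory <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("<larva_trajectory> '%s': %d frames, dt = %g s (%.1f min)\n",
              x$larva_id, n, x$dt, (n - 1) * x$dt / 60))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$positions)

#' Read and write tracker-style centroid CSV
#'
#' The tracker dialect is one row per frame with columns `larva_id`, `frame`
#' (0-based), `x_mm`, `y_mm`. Several larvae may share a file.
#'
#' @param path CSV file path.
#' @param dt Frame interval (s) to attach to the trajectories.
#' @return `read_tracker_csv()` returns a named list of `larva_trajectory`
#'   objects (one per larva, in order of first appearance).
#' @export
read_tracker_csv <- function(path, dt = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "frame", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("tracker CSV must have columns larva_id, frame, x_mm, y_mm",
         call. = FALSE)
  ids <- unique(df$larva_id)
  out <- lapply(ids, function(id) {
    d <- df[df$larva_id == id, ]
    d <- d[order(d$frame), ]
    trajectory(d$x_mm, d$y_mm, dt = dt, larva_id = as.character(id))
  })
  names(out) <- ids
  out
}

#' @rdname read_tracker_csv
#' @param trajs A `larva_trajectory` or a list of them.
#' @export
write_tracker_csv <- function(trajs, path) {
  if (inherits(trajs, "larva_trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(larva_id = tr$larva_id,
               frame = seq_len(n_frames(tr)) - 1L,
               x_mm = tr$positions[, 1], y_mm = tr$positions[, 2])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Kalman smoothing of a centroid track
#'
#' Applies a constant-velocity linear-Gaussian Kalman filter independently to
#' each larva's (x, y) coordinates to suppress centroid jitter before
#' kinematic analysis. State is (x, y, vx, vy); process noise enters the
#' velocity components, measurement noise the observed positions. With
#' `measurement_sd` going to zero the output converges to the input. An
#' optional Rauch-Tung-Striebel pass gives the forward-backward smoother.
#'
#' @param traj A [trajectory()].
#' @param process_sd Process-noise standard deviation on velocity
#'   (mm/s per step), default 0.05.
#' @param measurement_sd Measurement-noise standard deviation (mm),
#'   default 0.1.
#' @param smoother If TRUE, run the RTS backward pass as well.
#' @return A `larva_trajectory` of the same length with filtered positions.
#' @export
kalman_smooth <- function(traj, process_sd = 0.05, measurement_sd = 0.1,
                          smoother = FALSE) {
  stopifnot(inherits(traj, "larva_trajectory"))
  z <- traj$positions
  bad <- which(!is.finite(z[, 1]) | !is.finite(z[, 2]))
  if (length(bad) > 0)
    stop(sprintf("non-finite coordinates at frames: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  dt <- traj$dt
  n <- nrow(z)
  FF <- rbind(c(1, 0, dt, 0),
              c(0, 1, 0, dt),
              c(0, 0, 1, 0),
              c(0, 0, 0, 1))
  Q <- diag(c(0, 0, process_sd^2, process_sd^2))
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  R <- diag(max(measurement_sd^2, 1e-12), 2)
  xf <- matrix(0, n, 4)          # filtered means
  Pf <- array(0, c(4, 4, n))     # filtered covariances
  xp <- matrix(0, n, 4)          # one-step predictions (for RTS)
  Pp <- array(0, c(4, 4, n))
  x <- c(z[1, 1], z[1, 2], 0, 0)
  P <- diag(c(measurement_sd^2, measurement_sd^2, 1, 1))
  xf[1, ] <- x; Pf[, , 1] <- P; xp[1, ] <- x; Pp[, , 1] <- P
  for (j in 2:n) {
    x <- FF %*% x
    P <- FF %*% P %*% t(FF) + Q
    xp[j, ] <- x; Pp[, , j] <- P
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (z[j, ] - H %*% x)
    P <- (diag(4) - K %*% H) %*% P
    xf[j, ] <- x; Pf[, , j] <- P
  }
  out <- xf
  if (smoother) {
    xs <- xf; Ps <- Pf
    for (j in (n - 1):1) {
      G <- Pf[, , j] %*% t(FF) %*% solve(Pp[, , j + 1])
      xs[j, ] <- xf[j, ] + G %*% (xs[j + 1, ] - xp[j + 1, ])
      Ps[, , j] <- Pf[, , j] +
        G %*% (Ps[, , j + 1] - Pp[, , j + 1]) %*% t(G)
    }
    out <- xs
  }
  trajectory(out[, 1], out[, 2], dt = dt, larva_id = traj$larva_id,
             t0 = traj$times[1])
}

#' Per-frame kinematics of a trajectory
#'
#' Computes, by backward differences, velocity V(t_j) = (R(t_j) -
#' R(t_{j-1})) / dt, scalar speed s = ||V||, unit heading H = V / s, and the
#' instantaneous turn rate arccos(H(t_{j-1}) . H(t_j)) / dt in
#' \[0, pi/dt\] rad/s. The first frame carries no velocity (NA). At frames
#' with zero displacement the heading is undefined (flagged); the last
#' defined heading is propagated for turn-rate purposes only and the turn
#' rate at such frames is reported as 0 and flagged.
#'
#' @param traj A [trajectory()] with at least 3 frames for turn rates.
#' @return A tibble with columns `t`, `x`, `y`, `vx`, `vy`, `speed`,
#'   `heading_x`, `heading_y`, `turn_rate`, `zero_speed` (flag).
#' @export
kinematics <- function(traj) {
  stopifnot(inherits(traj, "larva_trajectory"))
  n <- n_frames(traj)
  if (n < 3) stop("turn rate needs at least 3 frames", call. = FALSE)
  dt <- traj$dt
  p <- traj$positions
  vx <- c(NA, diff(p[, 1]) / dt)
  vy <- c(NA, diff(p[, 2]) / dt)
  speed <- sqrt(vx^2 + vy^2)
  zero <- !is.na(speed) & speed == 0
  hx <- ifelse(zero, NA, vx / speed)
  hy <- ifelse(zero, NA, vy / speed)
  # headings with zero-speed gaps filled by the last defined heading,
  # used only to evaluate the turn rate
  fill_last <- function(v) {
    for (j in seq_along(v)[-1]) if (is.na(v[j])) v[j] <- v[j - 1]
    v
  }
  fhx <- fill_last(hx)
  fhy <- fill_last(hy)
  dotp <- fhx[-n] * fhx[-1] + fhy[-n] * fhy[-1]
  dotp <- pmin(1, pmax(-1, dotp))
  tr <- c(NA, acos(dotp) / dt)
  tr[1:2] <- c(NA, NA)  # needs two headings, defined from frame 3 on
  if (n >= 3) tr[2] <- NA
  tr[zero] <- 0
  tibble::tibble(t = traj$times, x = p[, 1], y = p[, 2],
                 vx = vx, vy = vy, speed = speed,
                 heading_x = hx, heading_y = hy,
                 turn_rate = tr, zero_speed = zero)
}
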