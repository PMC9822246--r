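#' Fraction of time spent inside food patches
#'
#' Fraction of frames whose centroid lies inside the closed disc of any
#' patch — the food-exploitation measure of the patchy-arena analysis.
#'
#' @param traj A [trajectory()].
#' @param layout A [patch_layout()].
#' @return A ratio in \[0, 1\].
#' @export
fraction_time_inside <- function(traj, layout) {
  stopifnot(inherits(traj, "larva_trajectory"),
            inherits(layout, "patch_layout"))
  if (n_frames(traj) == 0) stop("empty trajectory", call. = FALSE)
  mean(inside_any_patch(layout, traj$positions))
}

#' Fraction of non-source patches visited
#'
#' Number of distinct patches, other than the source patch the larva started
#' in, that contain at least one frame of the trajectory, divided by
#' (number of patches - 1). Defined as 0 (with a warning) for single-patch
#' layouts.
#'
#' @param traj A [trajectory()].
#' @param layout A [patch_layout()] with at least 2 patches.
#' @param source_patch Index (1-based) of the starting patch.
#' @return A ratio in \[0, 1\].
#' @export
fraction_visited <- function(traj, layout, source_patch) {
  stopifnot(inherits(traj, "larva_trajectory"),
            inherits(layout, "patch_layout"))
  np <- n_patches(layout)
  if (source_patch < 1 || source_patch > np)
    stop("source_patch out of range", call. = FALSE)
  if (np < 2) {
    warning("fraction_visited undefined for a single patch; returning 0")
    return(0)
  }
  pm <- patch_matrix(layout)
  xy <- traj$positions
  visited <- vapply(seq_len(np), function(i)
    any((xy[, 1] - pm$centers[i, 1])^2 + (xy[, 2] - pm$centers[i, 2])^2 <=
          pm$radii[i]^2), logical(1))
  sum(visited[-source_patch]) / (np - 1)
}

#' Total distance traveled
#'
#' Sum of consecutive inter-frame Euclidean displacements.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @return Distance in mm.
#' @export
distance_traveled <- function(traj) {
  stopifnot(inherits(traj, "larva_trajectory"))
  p <- traj$positions
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

#' Fraction of pause frames
#'
#' For recorded-style tracks, the fraction of frames with scalar speed below
#' a threshold (the recordings themselves carry no state labels; the 0.1 mm/s
#' default is a package choice, configurable). For simulated data prefer
#' [pause_fraction_states()] on the ground-truth state log.
#'
#' @param traj A [trajectory()].
#' @param speed_threshold Speed below which a frame counts as paused (mm/s).
#' @return A ratio in \[0, 1\] over the frames with defined speed.
#' @export
pause_fraction <- function(traj, speed_threshold = 0.1) {
  stopifnot(speed_threshold >= 0)
  kin <- kinematics(traj)
  s <- kin$speed[!is.na(kin$speed)]
  mean(s < speed_threshold)
}

#' @rdname pause_fraction
#' @param states Ground-truth state vector of a `sim_result`.
#' @export
pause_fraction_states <- function(states) {
  mean(states == "pause")
}

#' Residence and exploration summary for a set of tracks
#'
#' Per-larva residence metrics in long format, one row per larva, averaged
#' with equal weight per larva by downstream summaries.
#'
#' @param trajs List of [trajectory()] objects.
#' @param layout A [patch_layout()].
#' @param source_patches Optional integer vector of source-patch indices
#'   (enables `fraction_visited`).
#' @param speed_threshold Passed to [pause_fraction()].
#' @return A tibble with columns `larva_id`, `fraction_inside`,
#'   `fraction_visited` (NA when sources unknown), `distance_mm`,
#'   `pause_fraction`.
#' @export
residence_summary <- function(trajs, layout, source_patches = NULL,
                              speed_threshold = 0.1) {
  if (inherits(trajs, "larva_trajectory")) trajs <- list(trajs)
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    fv <- if (!is.null(source_patches) && n_patches(layout) >= 2)
      fraction_visited(tr, layout, source_patches[i]) else NA_real_
    tibble::tibble(larva_id = tr$larva_id,
                   fraction_inside = fraction_time_inside(tr, layout),
                   fraction_visited = fv,
                   distance_mm = distance_traveled(tr),
                   pause_fraction = pause_fraction(tr, speed_threshold))
  })
  do.call(rbind, rows)
}
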