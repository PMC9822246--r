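#' Generate a tracker-style synthetic recording with ground truth
#'
#' Builds a piecewise-ballistic centroid track with the statistical structure
#' of the crawl/turn/pause model — crawl bouts at a constant per-bout speed
#' drawn from the substrate's truncated normal, instantaneous heading changes
#' at turn events drawn from the larva's von Mises model, frozen position
#' during pauses — then adds isotropic Gaussian centroid jitter, emulating a
#' tracking pipeline's measurement noise. The complete ground truth (turn
#' frames and angles, pause intervals, bout speeds, true handedness) is
#' returned alongside, so every analysis stage can be validated without real
#' recordings.
#'
#' Unlike [simulate_larva()] the generator is unconstrained by arena walls
#' (tracks start at the arena center and the default frame counts keep them
#' well inside); it is an independent construction used to test the analysis
#' pipeline, not a second simulator.
#'
#' @param params A [substrate_params()].
#' @param turn_model A [turn_angle_model()].
#' @param n_frames Number of frames (6000 = 50 min at 2 frames/s).
#' @param dt Frame interval (s).
#' @param jitter_sd Centroid jitter standard deviation (mm), default 0.1.
#' @param start Numeric (x, y) start position (mm).
#' @param heading0 Initial heading (radians); uniform draw when NULL.
#' @param larva_id Track label.
#' @param layout Optional [patch_layout()] stored in the ground truth.
#' @return A list with elements `trajectory` (a [trajectory()]) and
#'   `ground_truth`: list with `turn_frames` (1-based frame of each heading
#'   change), `turn_angles`, `pause_intervals` (2-column matrix of frame
#'   ranges), `segment_speeds`, `handedness_true`, `layout`.
#' @export
#' @examples
#' set.seed(7)
#' rec <- generate_recording(substrate_params(0.84, 0.13, 0.02, 0.01),
#'                           turn_angle_model(0.2, 2), n_frames = 600,
#'                           jitter_sd = 0)
#' rec$ground_truth$handedness_true
generate_recording <- function(params, turn_model, n_frames = 6000,
                               dt = 0.5, jitter_sd = 0.1,
                               start = c(120, 120), heading0 = NULL,
                               larva_id = "synthetic_1", layout = NULL) {
  stopifnot(inherits(params, "substrate_params"),
            inherits(turn_model, "turn_angle_model"),
            n_frames >= 2, jitter_sd >= 0)
  check_params_dt(params, dt)
  states <- step_state(params, dt, n = n_frames - 1)
  angles_at <- which(states == "turn")
  turn_angles <- if (length(angles_at) > 0)
    sample_turn_angle(turn_model, length(angles_at)) else numeric(0)
  x <- numeric(n_frames); y <- numeric(n_frames)
  x[1] <- start[1]; y[1] <- start[2]
  if (is.null(heading0)) heading0 <- stats::runif(1, -pi, pi)
  h <- heading0
  v <- sample_speed(params)          # speed of the current crawl bout
  seg_speeds <- v
  ti <- 0L
  for (j in seq_len(n_frames - 1)) {
    s <- states[j]
    if (s == "turn") {
      ti <- ti + 1L
      h <- h + turn_angles[ti]
      v <- sample_speed(params)      # new bout begins after the turn
      seg_speeds <- c(seg_speeds, v)
      x[j + 1] <- x[j]; y[j + 1] <- y[j]
    } else if (s == "pause") {
      x[j + 1] <- x[j]; y[j + 1] <- y[j]
    } else {
      x[j + 1] <- x[j] + cos(h) * v * dt
      y[j + 1] <- y[j] + sin(h) * v * dt
    }
  }
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(n_frames, 0, jitter_sd)
    y <- y + stats::rnorm(n_frames, 0, jitter_sd)
  }
  pause_iv <- run_intervals(states == "pause")
  # the corner position is first occupied at the turn-step frame itself
  # (the position is frozen during the turn step)
  gt <- list(turn_frames = angles_at,
             turn_angles = turn_angles,
             pause_intervals = pause_iv,
             segment_speeds = seg_speeds,
             handedness_true = handedness(turn_angles)$H,
             layout = layout)
  list(trajectory = trajectory(x, y, dt = dt, larva_id = larva_id),
       ground_truth = gt)
}

# start/end frame pairs of the TRUE runs in a logical vector
run_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Generate a scripted synthetic track
#'
#' A fully deterministic piecewise-ballistic track (apart from optional
#' jitter): straight crawl segments of `spacing` frames at constant `speed`,
#' with prescribed heading changes between them. Ideal for exact round-trip
#' tests of the turn-detection pipeline.
#'
#' @param turn_angles Signed heading changes (radians), one per turn.
#' @param spacing Frames per straight segment (so segments are
#'   `spacing * speed * dt` mm long).
#' @param speed Constant crawling speed (mm/s).
#' @param dt Frame interval (s).
#' @param jitter_sd Optional centroid jitter SD (mm).
#' @param start,heading0,larva_id As in [generate_recording()].
#' @return As [generate_recording()].
#' @export
#' @examples
#' rec <- scripted_recording(c(pi / 2, -pi / 2, pi / 2))
#' rec$ground_truth$turn_frames
scripted_recording <- function(turn_angles, spacing = 60, speed = 0.84,
                               dt = 0.5, jitter_sd = 0, start = c(120, 120),
                               heading0 = 0, larva_id = "scripted_1") {
  stopifnot(spacing >= 2, speed > 0)
  n_seg <- length(turn_angles) + 1
  n_frames <- n_seg * spacing + 1
  x <- numeric(n_frames); y <- numeric(n_frames)
  x[1] <- start[1]; y[1] <- start[2]
  h <- heading0
  turn_frames <- integer(0)
  j <- 1L
  for (seg in seq_len(n_seg)) {
    for (i in seq_len(spacing)) {
      x[j + 1] <- x[j] + cos(h) * speed * dt
      y[j + 1] <- y[j] + sin(h) * speed * dt
      j <- j + 1L
    }
    if (seg < n_seg) {
      h <- h + turn_angles[seg]
      turn_frames <- c(turn_frames, j)
    }
  }
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(n_frames, 0, jitter_sd)
    y <- y + stats::rnorm(n_frames, 0, jitter_sd)
  }
  gt <- list(turn_frames = turn_frames, turn_angles = turn_angles,
             pause_intervals = run_intervals(logical(n_frames)),
             segment_speeds = rep(speed, n_seg),
             handedness_true = handedness(turn_angles)$H,
             layout = NULL)
  list(trajectory = trajectory(x, y, dt = dt, larva_id = larva_id),
       ground_truth = gt)
}

#' Write a deterministic fixture suite
#'
#' Generates a reproducible set of tracker CSV files with JSON ground-truth
#' sidecars covering the homogeneous substrate conditions (sitter parameters
#' on agar, sucrose, yeast), a two-patch and an eight-patch layout, and edge
#' cases (all-pause, straight line, wall-hugging). All files are produced at
#' call time from the given seed; the same seed yields byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_frames Frames per fixture track.
#' @return Invisibly, a character vector of the written file paths; a
#'   `manifest.json` in `dir` records the seed and file list.
#' @export
make_fixture_suite <- function(dir, seed = 1, n_frames = 2000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- character(0)
  save_one <- function(name, rec) {
    csv <- file.path(dir, paste0(name, ".csv"))
    write_tracker_csv(rec$trajectory, csv)
    gt <- rec$ground_truth
    gt$pause_intervals <- apply(gt$pause_intervals, 1, as.list)
    gt$layout <- NULL
    jsonlite::write_json(gt, file.path(dir, paste0(name, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    files <<- c(files, csv, file.path(dir, paste0(name, "_truth.json")))
  }
  for (sub in c("agar", "sucrose", "yeast")) {
    rec <- generate_recording(get_motor_params("sitter", sub),
                              draw_turn_model(), n_frames = n_frames,
                              jitter_sd = 0.1,
                              larva_id = paste0("sitter_", sub))
    save_one(paste0("homogeneous_", sub, "_sitter"), rec)
  }
  # patchy layouts, stored alongside as JSON
  lay2 <- two_patch_layout("yeast")
  write_layout(lay2, file.path(dir, "layout_two_patch.json"))
  lay8 <- random_layout(arena_spec(), 8, fragment_radius(total_food_area(25), 8),
                        substrate = "yeast")
  write_layout(lay8, file.path(dir, "layout_eight_patch.json"))
  files <- c(files, file.path(dir, c("layout_two_patch.json",
                                     "layout_eight_patch.json")))
  # edge cases
  save_one("edge_all_pause",
           generate_recording(substrate_params(0.5, 0.1, 0, 2),
                              turn_angle_model(), n_frames = 200,
                              dt = 0.5, jitter_sd = 0,
                              larva_id = "all_pause"))
  save_one("edge_straight_line",
           scripted_recording(numeric(0), spacing = 199,
                              larva_id = "straight"))
  wall <- trajectory(x = seq(0, 100, length.out = 200), y = rep(0, 200),
                     larva_id = "wall_hugger")
  write_tracker_csv(wall, file.path(dir, "edge_wall_hugging.csv"))
  files <- c(files, file.path(dir, "edge_wall_hugging.csv"))
  jsonlite::write_json(list(seed = seed, n_frames = n_frames,
                            files = basename(files)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(files)
}
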