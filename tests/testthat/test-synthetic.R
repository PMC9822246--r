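test_that("noiseless scripted tracks round-trip exactly through the pipeline", {
  rec <- scripted_recording(c(pi / 2, -pi / 2, pi / 2), spacing = 30,
                            speed = 0.84, jitter_sd = 0)
  sp <- rdp_simplify(rec$trajectory, 2.5)
  # interior vertices exactly at the scripted turn frames
  expect_equal(sp$frame_indices[-c(1, length(sp$frame_indices))],
               rec$ground_truth$turn_frames)
  expect_equal(turning_angles(sp), c(pi / 2, -pi / 2, pi / 2),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a 30 CCW / 10 CW scripted larva recovers H = 0.75 exactly", {
  set.seed(40)
  angles <- sample(c(rep(1, 30), rep(-1, 10))) * runif(40, pi / 5, pi / 2)
  expect_equal(handedness(angles)$H, 0.75)
  rec <- scripted_recording(angles, spacing = 25, speed = 0.9, jitter_sd = 0)
  ev <- detect_turns(rec$trajectory, epsilon = 2.5)
  expect_equal(handedness(ev$angle_rad)$H, 0.75)
  expect_equal(ev$angle_rad, angles, tolerance = 1e-9)
})

test_that("stochastic recordings carry consistent ground truth", {
  set.seed(41)
  rec <- generate_recording(get_motor_params("sitter", "yeast"),
                            turn_angle_model(0.2, 1), n_frames = 4000,
                            jitter_sd = 0)
  gt <- rec$ground_truth
  expect_equal(length(gt$turn_frames), length(gt$turn_angles))
  expect_true(all(diff(gt$turn_frames) > 0))
  expect_true(all(gt$turn_angles > -pi & gt$turn_angles <= pi))
  # pause intervals are disjoint
  if (nrow(gt$pause_intervals) > 1) {
    expect_true(all(gt$pause_intervals[-1, "start"] >
                      gt$pause_intervals[-nrow(gt$pause_intervals), "end"]))
  }
  # frozen exactly during pauses
  for (r in seq_len(min(5, nrow(gt$pause_intervals)))) {
    s <- gt$pause_intervals[r, "start"]
    e <- gt$pause_intervals[r, "end"]
    seg <- rec$trajectory$positions[s:(e + 1), , drop = FALSE]
    expect_equal(max(dist(seg)), 0)
  }
  # bout speeds drawn from the substrate distribution (truncated normal)
  expect_true(all(gt$segment_speeds > 0))
})

test_that("turn recovery from jittered tracks is high and degrades with noise", {
  # tracks with well-separated turns of at least 30 degrees: a hit is a
  # detected event within +-2 frames of a true turn with a matching sign
  recover_rate <- function(jitter_sd, seed) {
    set.seed(seed)
    hits <- 0; total <- 0
    for (r in 1:6) {
      angles <- sample(c(-1, 1), 40, replace = TRUE) *
        runif(40, pi / 6, 2 * pi / 3)
      rec <- scripted_recording(angles, spacing = 40, speed = 0.84,
                                jitter_sd = jitter_sd)
      gt_fr <- rec$ground_truth$turn_frames
      ev <- detect_turns(rec$trajectory, epsilon = 2.5)
      for (i in seq_along(gt_fr)) {
        total <- total + 1
        near <- abs(ev$frame - gt_fr[i]) <= 2
        if (any(near & sign(ev$angle_rad) == sign(angles[i]))) hits <- hits + 1
      }
    }
    hits / total
  }
  r0 <- recover_rate(0, 42)
  r02 <- recover_rate(0.2, 42)
  r15 <- recover_rate(1.5, 42)
  expect_equal(r0, 1.0)       # noiseless recovery is exact
  expect_gte(r02, 0.9)        # >= 90% at tracking-level jitter
  expect_gte(r0, r02)         # non-increasing in jitter
  expect_gt(r02, r15)         # and clearly degraded under heavy noise
})

test_that("fixture suites are deterministic and match their parameters", {
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  unlink(d1, recursive = TRUE); unlink(d2, recursive = TRUE)
  f1 <- make_fixture_suite(d1, seed = 9, n_frames = 1500)
  f2 <- make_fixture_suite(d2, seed = 9, n_frames = 1500)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  # yeast fixture: mean bout speed within 3 SE of the sitter-yeast mean
  tr <- read_tracker_csv(file.path(d1, "homogeneous_yeast_sitter.csv"))[[1]]
  gt <- jsonlite::read_json(file.path(d1, "homogeneous_yeast_sitter_truth.json"),
                            simplifyVector = TRUE)
  v <- gt$segment_speeds
  expect_lt(abs(mean(v) - 0.31), 3 * 0.11 / sqrt(length(v)) + 0.005)
  # straight-line fixture has no turns: handedness undefined
  straight <- read_tracker_csv(file.path(d1, "edge_straight_line.csv"))[[1]]
  ev <- detect_turns(straight, epsilon = 2.5)
  expect_true(is.na(handedness(ev$angle_rad)$H))
  # all-pause fixture never moves
  ap <- read_tracker_csv(file.path(d1, "edge_all_pause.csv"))[[1]]
  expect_equal(distance_traveled(ap), 0)
})
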