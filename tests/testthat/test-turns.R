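test_that("RDP keeps corners, drops collinear runs, and matches the reference", {
  # 100 collinear points reduce to the endpoints
  tr <- trajectory(seq(0, 99), rep(0, 100))
  sp <- rdp_simplify(tr, 2.5)
  expect_equal(sp$frame_indices, c(1, 100))

  # L-shaped path sampled at 1 mm: the corner survives
  xs <- c(seq(0, 50), rep(50, 50))
  ys <- c(rep(0, 51), seq(1, 50))
  sp <- rdp_simplify(trajectory(xs, ys), 2.5)
  expect_equal(nrow(sp$vertices), 3)
  expect_equal(sp$vertices[2, ], c(x = 50, y = 0))

  # vertex sets identical to an independent recursive reference
  set.seed(7)
  for (rep in 1:110) {
    n <- sample(10:60, 1)
    pts <- random_walk_pts(n, step = runif(1, 0.5, 3))
    eps <- runif(1, 0.5, 5)
    got <- rdp_simplify(pts, eps)$frame_indices
    expect_equal(got, ref_rdp_indices(pts, eps))
  }
  expect_error(rdp_simplify(trajectory(c(0, 1), c(0, 1)), -1), "epsilon")
})

test_that("RDP is invariant under rigid motions of the input", {
  set.seed(8)
  pts <- random_walk_pts(200)
  idx0 <- rdp_simplify(pts, 2)$frame_indices
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  pts2 <- t(R %*% t(pts)) + matrix(c(31, 17), nrow(pts), 2, byrow = TRUE)
  expect_equal(rdp_simplify(pts2, 2)$frame_indices, idx0)
})

test_that("turning angles are signed CCW-positive and match rotations", {
  expect_equal(turning_angles(rbind(c(0, 0), c(1, 0), c(1, 1)))[1], pi / 2)
  expect_equal(turning_angles(rbind(c(0, 0), c(1, 0), c(2, 0)))[1], 0)
  expect_equal(turning_angles(rbind(c(0, 0), c(1, 0), c(1, -1)))[1], -pi / 2)
  set.seed(9)
  for (rep in 1:300) {
    p1 <- runif(2, -5, 5); p2 <- runif(2, -5, 5); p3 <- runif(2, -5, 5)
    if (all(p1 == p2) || all(p2 == p3)) next
    got <- turning_angles(rbind(p1, p2, p3))[1]
    expect_equal(got, ref_turning_angle(p1, p2, p3), tolerance = 1e-12)
  }
  # zero-length middle segment is flagged, not computed
  a <- turning_angles(rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 1)))
  expect_true(all(is.na(a)))
  expect_equal(attr(a, "degenerate"), c(1, 2))
})

test_that("handedness counts CCW fraction and flags empty input", {
  h <- handedness(c(0.5, 1.0, 0.2, -0.3))
  expect_equal(h$H, 0.75)
  expect_equal(handedness(c(1, 2, 0.1))$H, 1.0)
  expect_equal(handedness(c(1, -1, 2, -2))$H, 0.5)
  expect_true(is.na(handedness(c(0, 0))$H))
  expect_true(is.na(handedness(numeric(0))$H))
  set.seed(10)
  ang <- runif(1000, -pi, pi)
  expect_equal(handedness(ang)$H, sum(ang > 0) / sum(ang != 0))
})

test_that("turns per minute averages rolling 120-frame window sums", {
  ind <- integer(6000)
  ind[seq(60, 6000, by = 60)] <- 1L   # one turn every 30 s
  expect_equal(turns_per_minute(ind), 2.0)
  expect_equal(turns_per_minute(integer(500)), 0)
  set.seed(11)
  ind <- rbinom(700, 1, 0.03)
  expect_equal(turns_per_minute(ind), ref_turns_per_minute(ind))
  expect_error(turns_per_minute(integer(50), window = 120), "shorter")
})

test_that("inward/outward classification follows the two-angle rule", {
  lay <- patch_layout(arena_spec(480, 480),
                      list(patch(240, 240, 25, "yeast")))
  # work in coordinates relative to the patch center at (240, 240)
  mk <- function(a, b, c) {
    structure(list(vertices = rbind(a, b, c) +
                     matrix(240, 3, 2), frame_indices = 1:3, epsilon = 2.5),
              class = "simplified_path")
  }
  # heading away from the center, then turning perpendicular: inward
  expect_equal(classify_turn(mk(c(30, 0), c(35, 0), c(35, 5)), 2, lay),
               "inward")
  # slight deflection from the radial escape: still inward
  expect_equal(classify_turn(mk(c(30, 0), c(35, 0), c(40, 1)), 2, lay),
               "inward")
  # exactly radial continuation: theta2 == theta1, tie goes outward
  expect_equal(classify_turn(mk(c(30, 0), c(35, 0), c(41, 0)), 2, lay),
               "outward")
  # turn ending pointed exactly at the center: theta2 = 0, inward
  expect_equal(classify_turn(mk(c(30, 5), c(35, 0), c(20, 0)), 2, lay),
               "inward")
  # random instances against the direct evaluation
  set.seed(12)
  for (rep in 1:120) {
    v <- matrix(runif(6, 100, 380), 3, 2)
    sp <- structure(list(vertices = v, frame_indices = 1:3, epsilon = 2.5),
                    class = "simplified_path")
    expect_equal(classify_turn(sp, 2, lay),
                 ref_classify(v[1, ], v[2, ], v[3, ], c(240, 240)))
  }
})

test_that("mirroring flips handedness but preserves inward/outward labels", {
  set.seed(13)
  rec <- generate_recording(substrate_params(0.8, 0.1, 0.03, 0.01),
                            turn_angle_model(0.4, 2), n_frames = 2000,
                            jitter_sd = 0, start = c(120, 120))
  tr <- rec$trajectory
  lay <- two_patch_layout("sucrose")
  ev <- detect_turns(tr, epsilon = 2.5, layout = lay)
  # mirror about the arena midline y = 120: layout maps onto itself
  tr_m <- trajectory(tr$positions[, 1], 240 - tr$positions[, 2])
  ev_m <- detect_turns(tr_m, epsilon = 2.5, layout = lay)
  expect_equal(ev_m$angle_rad, -ev$angle_rad, tolerance = 1e-9)
  h <- handedness(ev$angle_rad)$H
  expect_equal(handedness(ev_m$angle_rad)$H, 1 - h, tolerance = 1e-12)
  expect_equal(ev_m$orientation, ev$orientation)
  expect_equal(ev_m$dist_mm, ev$dist_mm, tolerance = 1e-9)
})

test_that("inward fractions bin by half-open 10 mm distance bins", {
  mk_events <- function(d, orient) {
    tibble::tibble(larva_id = "x", vertex = seq_along(d),
                   frame = seq_along(d), x = 0, y = 0, angle_rad = 0.1,
                   direction = "CCW", orientation = orient, dist_mm = d)
  }
  tab <- inward_fraction_by_distance(mk_events(rep(22, 5), rep("inward", 5)))
  expect_equal(tab$fraction_inward[tab$bin_lo == 20], 1.0)
  expect_equal(tab$n[tab$bin_lo == 20], 5)
  expect_true(all(is.na(tab$fraction_inward[tab$bin_lo != 20])))
  # boundary event at exactly 30 mm goes to [30, 40)
  tab <- inward_fraction_by_distance(mk_events(30, "inward"))
  expect_equal(tab$n[tab$bin_lo == 30], 1)
  expect_equal(tab$n[tab$bin_lo == 20], 0)
  # events beyond the 60 mm cap are excluded
  tab <- inward_fraction_by_distance(mk_events(c(65, 22), c("inward", "outward")))
  expect_equal(sum(tab$n), 1)
  # binomial recovery of per-bin probabilities, n = 10000
  set.seed(14)
  p_by_bin <- c(0.5, 0.55, 0.8, 0.75, 0.7, 0.65)
  d <- runif(10000, 0, 60)
  b <- findInterval(d, seq(0, 60, 10))
  orient <- ifelse(rbinom(10000, 1, p_by_bin[b]) == 1, "inward", "outward")
  tab <- inward_fraction_by_distance(mk_events(d, orient))
  for (i in seq_len(6)) {
    se <- sqrt(p_by_bin[i] * (1 - p_by_bin[i]) / tab$n[i])
    expect_lt(abs(tab$fraction_inward[i] - p_by_bin[i]), 3 * se)
  }
})
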