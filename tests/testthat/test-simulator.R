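rover_agar <- substrate_params(0.84, 0.13, 0.044, 0.0083)

test_that("motor-state draws have the configured per-step probabilities", {
  set.seed(20)
  expect_true(all(step_state(substrate_params(1, 0.1, 0, 0), n = 100) ==
                    "crawl"))
  expect_true(all(step_state(substrate_params(1, 0.1, 0, 2), dt = 0.5,
                             n = 100) == "pause"))
  s <- step_state(rover_agar, dt = 0.5, n = 1e6)
  p_hat <- mean(s == "turn")
  se <- sqrt(0.022 * (1 - 0.022) / 1e6)
  expect_lt(abs(p_hat - 0.022), 3 * se)
  p_pause <- mean(s == "pause")
  se <- sqrt(0.00415 * (1 - 0.00415) / 1e6)
  expect_lt(abs(p_pause - 0.00415), 3 * se)
  expect_error(step_state(substrate_params(1, 0, 1.5, 1.5), dt = 1), "exceeds")
})

test_that("crawl speeds are positive truncated-normal draws", {
  set.seed(21)
  expect_equal(sample_speed(substrate_params(0.5, 0, 0, 0), 10), rep(0.5, 10))
  v <- sample_speed(rover_agar, 1e5)
  expect_true(all(v > 0))
  # truncation shift is < 1e-3 at mean/sd ~ 6.5, so the plain mean applies
  expect_lt(abs(mean(v) - 0.84), 3 * 0.13 / sqrt(1e5))
})

test_that("turning angles follow the von Mises model", {
  set.seed(22)
  # degenerate concentration limit collapses onto mu
  a <- sample_turn_angle(turn_angle_model(0.7, 1e6), 1000)
  expect_lt(max(abs(a - 0.7)), 0.01)
  # kappa = 0 is circular uniform: Rayleigh statistic stays small
  a <- sample_turn_angle(turn_angle_model(0, 0), 1e4)
  expect_true(all(a > -pi & a <= pi))
  Rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  expect_lt(2 * 1e4 * Rbar^2, qchisq(0.999, df = 2))
  # circular mean and resultant length match theory at mu 0.5, kappa 2
  n <- 1e5
  a <- sample_turn_angle(turn_angle_model(0.5, 2), n)
  A1 <- besselI(2, 1) / besselI(2, 0)
  mean_dir <- atan2(mean(sin(a)), mean(cos(a)))
  se_dir <- 1 / sqrt(n * 2 * A1)  # asymptotic SE of the mean direction
  expect_lt(abs(mean_dir - 0.5), 3 * se_dir)
  Rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  expect_lt(abs(Rbar - A1), 0.01)
})

test_that("bias profiles validate and rescale with patch radius", {
  pr <- bias_profile(seq(0, 60, 10), c(0.5, 0.55, 0.8, 0.75, 0.7, 0.65))
  expect_identical(scale_bias_profile(pr, 25, 25), pr)
  half <- scale_bias_profile(pr, 12.5, 25)
  expect_equal(half$bin_edges, seq(0, 30, 5))
  expect_equal(half$bin_edges[3:4], c(10, 15))   # the [20,30) bin halves
  expect_equal(half$cutoff, 30)
  expect_equal(half$p_bias, pr$p_bias)
  expect_error(bias_profile(c(0, 10), 1.2), "0, 1")
  expect_error(bias_profile(c(10, 0), 0.5), "increasing")
})

test_that("deterministic configurations give exact trajectories", {
  lay <- patch_layout(arena_spec(), list())
  par0 <- substrate_params(0.8, 0, 0, 0)   # fixed speed, never turn or pause
  set.seed(23)
  sim <- simulate_larva(lay, par0, turn_angle_model(0, 1), n_steps = 100,
                        start = "point", start_point = c(20, 120),
                        heading0 = 0)
  expect_equal(unname(sim$trajectory$positions[101, ]), c(20 + 0.8 * 0.5 * 100, 120))
  expect_true(all(sim$states == "crawl"))
  expect_equal(distance_traveled(sim$trajectory), 0.8 * 0.5 * 100)
  # pause-only: frozen for the whole run
  parp <- substrate_params(0.8, 0.1, 0, 2)
  sim <- simulate_larva(lay, parp, turn_angle_model(0, 1), n_steps = 50,
                        start = "point", start_point = c(100, 100))
  expect_true(all(sim$states == "pause"))
  expect_equal(max(abs(sweep(sim$trajectory$positions, 2, c(100, 100)))), 0)
})

test_that("simulations are seed-reproducible and wall-bounded", {
  lay <- two_patch_layout("yeast")
  pars <- list(yeast = substrate_params(0.31, 0.11, 0.028, 0.25),
               agar = substrate_params(0.96, 0.13, 0.046, 0.0063))
  run <- function() {
    set.seed(24)
    simulate_larva(lay, pars, turn_angle_model(0.2, 1), n_steps = 3000)
  }
  a <- run(); b <- run()
  expect_identical(a$trajectory$positions, b$trajectory$positions)
  expect_identical(a$states, b$states)
  expect_identical(a$turn_log, b$turn_log)
  # wall-heavy configuration stays strictly inside the arena
  small <- patch_layout(arena_spec(40, 40), list())
  set.seed(25)
  sim <- simulate_larva(small, substrate_params(15, 3, 0.02, 0),
                        turn_angle_model(0, 0), n_steps = 4000,
                        start = "point", start_point = c(2, 2))
  expect_true(all(sim$trajectory$positions >= 0 &
                    sim$trajectory$positions <= 40))
})

test_that("long-run state fractions converge to the step probabilities", {
  set.seed(26)
  sim <- simulate_larva(NULL, rover_agar, turn_angle_model(0.1, 1),
                        n_steps = 1e5)
  p_turn <- 0.044 * 0.5
  p_pause <- 0.0083 * 0.5
  expect_lt(abs(mean(sim$states == "turn") - p_turn),
            3 * sqrt(p_turn * (1 - p_turn) / 1e5))
  expect_lt(abs(mean(sim$states == "pause") - p_pause),
            3 * sqrt(p_pause * (1 - p_pause) / 1e5))
  # ground-truth turn log agrees with the state log
  expect_equal(nrow(sim$turn_log), sum(sim$states == "turn"))
})

test_that("the realized inward fraction at a biased turn equals Pbias", {
  lay <- patch_layout(arena_spec(), list(patch(120, 120, 25, "sucrose")))
  pars <- list(sucrose = substrate_params(0.68, 0.092, 0.3, 0),
               agar = substrate_params(0.84, 0.13, 0.3, 0))
  pr <- bias_profile(c(0, 60), 0.8, cutoff = 60)
  set.seed(27)
  logs <- list()
  for (r in 1:30) {
    sim <- simulate_larva(lay, pars, turn_angle_model(0, 1), bias = pr,
                          n_steps = 2000)
    logs[[r]] <- sim$turn_log
  }
  tl <- do.call(rbind, logs)
  tl <- tl[tl$biased, ]
  expect_gt(nrow(tl), 5000)
  se <- sqrt(0.8 * 0.2 / nrow(tl))
  expect_lt(abs(mean(tl$inward) - 0.8), 3 * se)
  # a zero profile applies no bias at all
  set.seed(28)
  sim0 <- simulate_larva(lay, pars, turn_angle_model(0.3, 1),
                         bias = bias_profile(c(0, 60), 0, cutoff = 60),
                         n_steps = 2000)
  expect_true(all(!sim0$turn_log$biased))
})

test_that("border-elevated bias increases patch residence on paired seeds", {
  lay <- two_patch_layout("sucrose")
  pars <- list(sucrose = substrate_params(0.68, 0.092, 0.041, 0.012),
               agar = substrate_params(0.84, 0.13, 0.044, 0.0083))
  pr <- bias_profile(seq(0, 60, 10), c(0.5, 0.55, 0.8, 0.75, 0.7, 0.65))
  frac <- function(bias, seed) {
    set.seed(seed)
    out <- numeric(12)
    for (r in seq_along(out)) {
      sim <- simulate_larva(lay, pars, turn_angle_model(0.1, 1), bias = bias,
                            n_steps = 6000)
      out[r] <- fraction_time_inside(sim$trajectory, lay)
    }
    mean(out)
  }
  f0 <- frac(NULL, 29)
  f1 <- frac(pr, 29)
  expect_gt(f1, f0)
})

test_that("residence falls with fragmentation at fixed food area", {
  pr <- bias_profile(seq(0, 60, 10), c(0.5, 0.55, 0.8, 0.75, 0.7, 0.65))
  set.seed(30)
  res <- fragmentation_experiment("sitter", "yeast",
                                  n_patches_grid = c(1, 8, 64),
                                  n_larvae = 8, n_runs = 4,
                                  n_steps = 3000, bias = pr)
  expect_true(all(diff(res$mean_fraction_inside) < 0))
})
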