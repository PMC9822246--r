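#' Von Mises turning-angle model
#'
#' Each larva draws its turning angles from a von Mises distribution with its
#' own mean `mu` (the individual handedness bias: positive mu favors CCW
#' turns) and concentration `kappa` (kappa = 0 is the circular uniform).
#'
#' @param mu Mean direction in radians.
#' @param kappa Concentration, non-negative.
#' @return An object of class `turn_angle_model`.
#' @export
turn_angle_model <- function(mu = 0, kappa = 1) {
  stopifnot(is.numeric(mu), is.numeric(kappa), length(mu) == 1,
            length(kappa) == 1)
  if (kappa < 0) stop("kappa must be non-negative", call. = FALSE)
  structure(list(mu = mu, kappa = kappa), class = "turn_angle_model")
}

#' Sample signed turning angles
#'
#' Von Mises draws wrapped to (-pi, pi\], via the Best-Fisher rejection
#' sampler; kappa = 0 gives the circular uniform.
#'
#' @param model A [turn_angle_model()].
#' @param n Number of draws.
#' @return Numeric vector of signed angles in radians.
#' @export
sample_turn_angle <- function(model, n = 1) {
  stopifnot(inherits(model, "turn_angle_model"))
  rvonmises_cpp(as.integer(n), model$mu, model$kappa)
}

#' Sample crawling speeds
#'
#' Normal(mean_v, sd_v) truncated to positive values by resampling.
#'
#' @param params A [substrate_params()].
#' @param n Number of draws.
#' @return Positive speeds in mm/s.
#' @export
sample_speed <- function(params, n = 1) {
  stopifnot(inherits(params, "substrate_params"))
  rtruncnorm_pos_cpp(as.integer(n), params$mean_v, params$sd_v)
}

#' Draw per-step motor states
#'
#' One mutually exclusive draw per step: turn with probability
#' `p_turn_per_s * dt`, pause with `p_pause_per_s * dt`, crawl otherwise.
#'
#' @param params A [substrate_params()].
#' @param dt Time step in seconds.
#' @param n Number of draws.
#' @return Character vector of `"crawl"`, `"turn"`, `"pause"`.
#' @export
step_state <- function(params, dt = 0.5, n = 1) {
  stopifnot(inherits(params, "substrate_params"))
  check_params_dt(params, dt)
  c("crawl", "turn", "pause")[
    step_state_cpp(as.integer(n), params$p_turn_per_s * dt,
                   params$p_pause_per_s * dt) + 1L]
}

#' Distance-dependent inward-turn bias profile
#'
#' The probability that a simulated turn is taken toward the nearest patch
#' center, as a piecewise-constant function of the distance to that center
#' over half-open bins \[edge_i, edge_{i+1}). Beyond the cutoff (default
#' 60 mm) no bias is applied; bins with `p_bias = 0` also leave the turn
#' unbiased, so the zero profile reproduces the unbiased model exactly.
#'
#' @param bin_edges Increasing distance bin edges (mm), length nbins + 1.
#' @param p_bias Per-bin inward probabilities in \[0, 1\], length nbins.
#' @param cutoff No-bias cutoff distance (mm), default 60.
#' @return An object of class `bias_profile`.
#' @seealso [scale_bias_profile()], [read_bias_profile()]
#' @export
bias_profile <- function(bin_edges, p_bias, cutoff = 60) {
  stopifnot(is.numeric(bin_edges), is.numeric(p_bias),
            length(bin_edges) == length(p_bias) + 1)
  if (any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  if (any(p_bias < 0 | p_bias > 1))
    stop("p_bias values must lie in [0, 1]", call. = FALSE)
  stopifnot(cutoff > 0)
  structure(list(bin_edges = as.numeric(bin_edges),
                 p_bias = as.numeric(p_bias), cutoff = cutoff),
            class = "bias_profile")
}

#' @export
print.bias_profile <- function(x, ...) {
  cat(sprintf("<bias_profile> %d bins, cutoff %g mm\n",
              length(x$p_bias), x$cutoff))
  for (i in seq_along(x$p_bias))
    cat(sprintf("  [%g, %g) mm : %g\n", x$bin_edges[i], x$bin_edges[i + 1],
                x$p_bias[i]))
  invisible(x)
}

#' Rescale a bias profile for fragmented patches
#'
#' When the food area is redistributed into more, smaller patches, the
#' distance bins of the bias profile shrink with the patch radius: all bin
#' edges and the cutoff are multiplied by `r_new / r_ref`. Probabilities are
#' unchanged.
#'
#' @param bias A [bias_profile()].
#' @param r_new New patch radius (mm).
#' @param r_ref Reference patch radius (mm), default 25.
#' @return A rescaled [bias_profile()].
#' @export
#' @examples
#' pr <- bias_profile(c(0, 10, 20, 30), c(0.5, 0.6, 0.8))
#' scale_bias_profile(pr, r_new = 12.5)  # eight-patch rescaling, factor 0.5
scale_bias_profile <- function(bias, r_new, r_ref = 25) {
  stopifnot(inherits(bias, "bias_profile"), r_new > 0, r_ref > 0)
  f <- r_new / r_ref
  bias_profile(bias$bin_edges * f, bias$p_bias, cutoff = bias$cutoff * f)
}

#' Read a bias profile from YAML
#'
#' Reads `{bin_edges, p_bias, cutoff}`. The package ships an illustrative
#' synthetic profile at
#' `system.file("extdata", "bias_profile_synthetic.yaml", package = "larvaforage")`;
#' the experimentally measured profiles were published only graphically, so
#' users supply their own numbers.
#'
#' @param path YAML file path.
#' @return A [bias_profile()].
#' @export
read_bias_profile <- function(path) {
  obj <- yaml::read_yaml(path)
  bias_profile(unlist(obj$bin_edges), unlist(obj$p_bias),
               cutoff = if (is.null(obj$cutoff)) 60 else obj$cutoff)
}

#' Simulate one larva
#'
#' Runs the crawl/turn/pause agent model for `n_steps` time steps of length
#' `dt`. At each step the motor parameters are looked up at the current
#' position (patch substrate inside patches, outside substrate elsewhere).
#' On a crawl step the larva advances by heading * v * dt with v freshly
#' drawn from the local truncated-normal speed distribution; on a turn step
#' the heading rotates by a von Mises draw (optionally redirected toward the
#' nearest patch center by a [bias_profile()]) with no translation; on a
#' pause step nothing moves. Crawl steps that would exit the arena are
#' truncated at the rigid wall and the heading is redrawn uniformly into the
#' interior. All randomness comes from R's RNG: call `set.seed()` for a
#' fully reproducible run.
#'
#' @param layout A [patch_layout()]; use a layout with no patches (or
#'   `params` as a single [substrate_params()] with `layout = NULL`) for a
#'   homogeneous arena.
#' @param params Named list mapping substrate labels to [substrate_params()]
#'   (must cover every patch substrate and the outside substrate), or a
#'   single `substrate_params` used everywhere.
#' @param turn_model A [turn_angle_model()] for this larva.
#' @param bias Optional [bias_profile()] for inward-turn bias.
#' @param n_steps Number of time steps (6000 = 50 min at dt 0.5 s).
#' @param dt Step length in seconds.
#' @param start `"patch"` starts uniformly inside a uniformly chosen patch
#'   (uniform in the arena when there are none); `"point"` uses
#'   `start_point`.
#' @param start_point Numeric (x, y) start when `start = "point"`.
#' @param heading0 Initial heading in radians; uniform when `NULL`.
#' @param larva_id Label for the resulting trajectory.
#' @return An object of class `sim_result`: list with `trajectory` (a
#'   [trajectory()] of n_steps + 1 frames including the start), `states`
#'   (character, length n_steps), and `turn_log` (tibble of ground-truth
#'   turns: `step`, `x`, `y`, `angle_rad`, `dist_mm`, `biased` — whether the
#'   bias rule was applied — and `inward` — whether the inward option was
#'   chosen, NA for unbiased turns).
#' @export
#' @examples
#' set.seed(1)
#' res <- simulate_larva(two_patch_layout("yeast"),
#'                       params = list(yeast = get_motor_params("sitter", "yeast"),
#'                                     agar = get_motor_params("sitter", "agar")),
#'                       turn_model = turn_angle_model(0.1, 1),
#'                       n_steps = 200)
simulate_larva <- function(layout, params, turn_model = turn_angle_model(),
                           bias = NULL, n_steps = 6000, dt = 0.5,
                           start = c("patch", "point"), start_point = NULL,
                           heading0 = NULL, larva_id = "sim_1") {
  start <- match.arg(start)
  if (is.null(layout)) layout <- patch_layout(arena_spec(), list())
  stopifnot(inherits(layout, "patch_layout"),
            inherits(turn_model, "turn_angle_model"),
            n_steps >= 1, dt > 0)
  pm <- patch_matrix(layout)
  if (inherits(params, "substrate_params")) {
    labels <- unique(c(pm$substrates, layout$outside_substrate))
    params <- stats::setNames(rep(list(params), length(labels)), labels)
  }
  need <- unique(c(pm$substrates, layout$outside_substrate))
  missing <- setdiff(need, names(params))
  if (length(missing) > 0)
    stop(sprintf("params missing for substrate(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (p in params) {
    stopifnot(inherits(p, "substrate_params"))
    check_params_dt(p, dt)
  }
  pmat <- t(vapply(params, function(p)
    c(p$mean_v, p$sd_v, p$p_turn_per_s, p$p_pause_per_s), numeric(4)))
  patch_idx <- match(pm$substrates, names(params)) - 1L
  outside_idx <- match(layout$outside_substrate, names(params)) - 1L

  if (start == "point") {
    if (is.null(start_point) || length(start_point) != 2)
      stop("start_point (x, y) required when start = 'point'", call. = FALSE)
    x0 <- start_point[1]; y0 <- start_point[2]
    if (x0 < 0 || x0 > layout$arena$width || y0 < 0 ||
        y0 > layout$arena$height)
      stop("start_point lies outside the arena", call. = FALSE)
  } else if (n_patches(layout) > 0) {
    i <- sample.int(n_patches(layout), 1)
    p <- layout$patches[[i]]
    r <- p$radius * sqrt(stats::runif(1))
    a <- stats::runif(1, -pi, pi)
    x0 <- p$cx + r * cos(a); y0 <- p$cy + r * sin(a)
  } else {
    x0 <- stats::runif(1, 0, layout$arena$width)
    y0 <- stats::runif(1, 0, layout$arena$height)
  }
  if (is.null(heading0)) heading0 <- stats::runif(1, -pi, pi)

  use_bias <- !is.null(bias)
  if (use_bias) stopifnot(inherits(bias, "bias_profile"))
  res <- simulate_cpp(as.integer(n_steps), dt,
                      layout$arena$width, layout$arena$height,
                      pm$centers, pm$radii, patch_idx, outside_idx,
                      pmat, turn_model$mu, turn_model$kappa,
                      use_bias,
                      if (use_bias) bias$bin_edges else numeric(2),
                      if (use_bias) bias$p_bias else numeric(1),
                      if (use_bias) bias$cutoff else 0,
                      x0, y0, heading0)
  traj <- trajectory(res$positions[, 1], res$positions[, 2], dt = dt,
                     larva_id = larva_id)
  structure(list(
    trajectory = traj,
    states = c("crawl", "turn", "pause")[res$states + 1L],
    turn_log = tibble::tibble(step = res$turn_step, x = res$turn_x,
                              y = res$turn_y, angle_rad = res$turn_angle,
                              dist_mm = res$turn_dist,
                              biased = res$turn_biased == 1L,
                              inward = as.logical(res$turn_inward)),
    layout = layout, dt = dt, n_steps = n_steps),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  tab <- table(factor(x$states, levels = c("crawl", "turn", "pause")))
  cat(sprintf("<sim_result> %d steps (dt %g s): %d crawl / %d turn / %d pause\n",
              x$n_steps, x$dt, tab[["crawl"]], tab[["turn"]], tab[["pause"]]))
  invisible(x)
}

#' Draw a per-larva turning-angle model
#'
#' The study's per-larva von Mises parameters were fitted to individual
#' recorded larvae and are not published; the package's default stand-in
#' draws each larva's mean direction mu from Uniform(-0.3, 0.3) rad (an
#' individual handedness bias of either sign) with a common kappa = 1.
#'
#' @param mu_range Length-2 range for the uniform mu draw.
#' @param kappa Common concentration.
#' @return A [turn_angle_model()].
#' @export
draw_turn_model <- function(mu_range = c(-0.3, 0.3), kappa = 1) {
  turn_angle_model(stats::runif(1, mu_range[1], mu_range[2]), kappa)
}
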