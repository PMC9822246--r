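#' Patch-residence simulation experiment
#'
#' The study-condition wrapper used throughout the package: simulates a
#' cohort of larvae of one genotype in a patchy arena and reports, per larva,
#' the fraction of time spent inside patches averaged over repeated runs.
#' The predictive (unbiased) model uses the homogeneous-substrate motor
#' parameters: the patch substrate's parameters inside patches, the
#' genotype's agar parameters outside, and the agar-derived turning-angle
#' model everywhere. Each larva gets its own von Mises mean drawn by
#' [draw_turn_model()]; each run starts inside a uniformly chosen patch.
#'
#' @param genotype `"rover"` or `"sitter"`.
#' @param patch_substrate Substrate inside the patches (`"agar"` gives the
#'   no-food control with identical parameters everywhere).
#' @param layout A [patch_layout()]; default the reference two-patch layout.
#' @param n_larvae Number of simulated larvae (default 30).
#' @param n_runs Runs per larva (default 30).
#' @param n_steps Steps per run (default 6000 = 50 min at dt 0.5 s).
#' @param dt Step length (s).
#' @param bias Optional [bias_profile()].
#' @param mu_range,kappa Per-larva turning-angle stand-in, see
#'   [draw_turn_model()].
#' @return A tibble with one row per larva: `larva`, `mu`,
#'   `fraction_inside` (mean over runs), `fraction_visited` (mean over runs;
#'   NA for layouts with fewer than 2 patches), `pause_fraction` and
#'   `distance_mm` (means over runs, from the ground-truth state log and the
#'   ideal positions). The condition mean of `fraction_inside` is the
#'   quantity reported as "fraction of time inside patches".
#' @export
#' @examples
#' set.seed(42)
#' res <- patch_residence_experiment("sitter", "yeast",
#'                                   n_larvae = 2, n_runs = 2, n_steps = 500)
#' mean(res$fraction_inside)
patch_residence_experiment <- function(genotype, patch_substrate,
                                       layout = two_patch_layout(patch_substrate),
                                       n_larvae = 30, n_runs = 30,
                                       n_steps = 6000, dt = 0.5,
                                       bias = NULL,
                                       mu_range = c(-0.3, 0.3), kappa = 1) {
  params <- list(get_motor_params(genotype, "agar"))
  names(params) <- "agar"
  if (patch_substrate != "agar")
    params[[patch_substrate]] <- get_motor_params(genotype, patch_substrate)
  np <- n_patches(layout)
  rows <- lapply(seq_len(n_larvae), function(l) {
    tm <- draw_turn_model(mu_range, kappa)
    fi <- fv <- pf <- dist <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      # choose the start patch here so the source is known for
      # fraction_visited
      src <- if (np > 0) sample.int(np, 1) else NA_integer_
      sp <- NULL
      if (!is.na(src)) {
        p <- layout$patches[[src]]
        rad <- p$radius * sqrt(stats::runif(1))
        a <- stats::runif(1, -pi, pi)
        sp <- c(p$cx + rad * cos(a), p$cy + rad * sin(a))
      }
      sim <- simulate_larva(layout, params, tm, bias = bias,
                            n_steps = n_steps, dt = dt,
                            start = if (is.null(sp)) "patch" else "point",
                            start_point = sp,
                            larva_id = sprintf("%s_%s_l%02d_r%02d",
                                               genotype, patch_substrate,
                                               l, r))
      fi[r] <- fraction_time_inside(sim$trajectory, layout)
      fv[r] <- if (np >= 2)
        fraction_visited(sim$trajectory, layout, src) else NA_real_
      pf[r] <- pause_fraction_states(sim$states)
      dist[r] <- distance_traveled(sim$trajectory)
    }
    tibble::tibble(larva = l, mu = tm$mu,
                   fraction_inside = mean(fi),
                   fraction_visited = mean(fv),
                   pause_fraction = mean(pf),
                   distance_mm = mean(dist))
  })
  out <- do.call(rbind, rows)
  attr(out, "condition") <- list(genotype = genotype,
                                 patch_substrate = patch_substrate,
                                 n_runs = n_runs, n_steps = n_steps, dt = dt,
                                 biased = !is.null(bias))
  out
}

#' Patch-fragmentation simulation experiment
#'
#' Holds the total food area fixed at the two-patch reference design
#' (S = 2 pi R^2, R = 25 mm) while splitting it into `n_patches` randomly
#' placed patches of radius R' = sqrt(S / (n_patches pi)); any bias profile
#' is rescaled by R'/R. Returns the mean residence and visitation fractions
#' per patch number.
#'
#' @inheritParams patch_residence_experiment
#' @param n_patches_grid Integer vector of patch numbers to test.
#' @param reference_radius Reference patch radius (mm), default 25.
#' @param arena An [arena_spec()].
#' @return A tibble with one row per patch number: `n_patches`, `radius_mm`,
#'   `mean_fraction_inside`, `sd_fraction_inside`, `mean_fraction_visited`.
#' @export
fragmentation_experiment <- function(genotype, patch_substrate,
                                     n_patches_grid = c(1, 2, 4, 8, 16, 32, 64),
                                     n_larvae = 30, n_runs = 30,
                                     n_steps = 6000, dt = 0.5,
                                     bias = NULL,
                                     reference_radius = 25,
                                     arena = arena_spec(),
                                     mu_range = c(-0.3, 0.3), kappa = 1) {
  S <- total_food_area(reference_radius, 2)
  rows <- lapply(n_patches_grid, function(np) {
    r <- fragment_radius(S, np)
    layout <- random_layout(arena, np, r, substrate = patch_substrate)
    b <- if (is.null(bias)) NULL else
      scale_bias_profile(bias, r_new = r, r_ref = reference_radius)
    res <- patch_residence_experiment(genotype, patch_substrate,
                                      layout = layout,
                                      n_larvae = n_larvae, n_runs = n_runs,
                                      n_steps = n_steps, dt = dt, bias = b,
                                      mu_range = mu_range, kappa = kappa)
    tibble::tibble(n_patches = np, radius_mm = r,
                   mean_fraction_inside = mean(res$fraction_inside),
                   sd_fraction_inside = stats::sd(res$fraction_inside),
                   mean_fraction_visited = mean(res$fraction_visited))
  })
  do.call(rbind, rows)
}
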