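#' Substrate motor parameters
#'
#' The per-substrate motor parameters of the crawl/turn/pause model: crawling
#' speed is Normal(mean_v, sd_v) truncated to positive values; at each time
#' step of length dt the larva turns with probability `p_turn_per_s * dt` and
#' pauses with probability `p_pause_per_s * dt` (crawling otherwise).
#'
#' @param mean_v Mean crawling speed (mm/s), positive.
#' @param sd_v Speed standard deviation (mm/s), non-negative.
#' @param p_turn_per_s Turn probability per second.
#' @param p_pause_per_s Pause probability per second.
#' @return An object of class `substrate_params`.
#' @export
#' @examples
#' substrate_params(0.84, 0.13, 0.044, 0.0083)  # rover on agar
substrate_params <- function(mean_v, sd_v, p_turn_per_s, p_pause_per_s) {
  stopifnot(is.numeric(mean_v), is.numeric(sd_v), is.numeric(p_turn_per_s),
            is.numeric(p_pause_per_s))
  if (mean_v <= 0) stop("mean_v must be positive", call. = FALSE)
  if (sd_v < 0) stop("sd_v must be non-negative", call. = FALSE)
  if (p_turn_per_s < 0 || p_pause_per_s < 0)
    stop("probabilities must be non-negative", call. = FALSE)
  structure(list(mean_v = mean_v, sd_v = sd_v, p_turn_per_s = p_turn_per_s,
                 p_pause_per_s = p_pause_per_s),
            class = "substrate_params")
}

#' @export
print.substrate_params <- function(x, ...) {
  cat(sprintf(
    "<substrate_params> v ~ N+(%g, %g) mm/s, P_turn %g /s, P_pause %g /s\n",
    x$mean_v, x$sd_v, x$p_turn_per_s, x$p_pause_per_s))
  invisible(x)
}

# Per-step probabilities must leave room for the crawl state.
check_params_dt <- function(params, dt) {
  if ((params$p_turn_per_s + params$p_pause_per_s) * dt > 1)
    stop(sprintf("p_turn + p_pause exceeds 1 per step at dt = %g", dt),
         call. = FALSE)
  invisible(params)
}

#' Packaged motor-parameter tables
#'
#' Loads the motor parameters shipped with the package: `"homogeneous"` for
#' the per-(genotype, substrate) parameters fitted on homogeneous substrates
#' (these drive the predictive patchy-substrate model), `"patchy"` for the
#' corrected parameters fitted inside/outside patches in patchy arenas.
#'
#' @param set `"homogeneous"` or `"patchy"`.
#' @return A tibble, one row per parameter set.
#' @export
#' @examples
#' motor_params_table("homogeneous")
motor_params_table <- function(set = c("homogeneous", "patchy")) {
  set <- match.arg(set)
  path <- system.file("extdata",
                      paste0("motor_params_", set, ".yaml"),
                      package = "larvaforage", mustWork = TRUE)
  obj <- yaml::read_yaml(path)
  rows <- lapply(obj$parameters, function(p) tibble::as_tibble(p))
  do.call(rbind, rows)
}

#' Look up one packaged parameter set
#'
#' @param genotype `"rover"` or `"sitter"`.
#' @param substrate Substrate label.
#' @param set Which table to use, see [motor_params_table()].
#' @param region For the patchy table, `"inside"` or `"outside"`.
#' @return A [substrate_params()] object.
#' @export
#' @examples
#' get_motor_params("rover", "agar")
get_motor_params <- function(genotype, substrate,
                             set = c("homogeneous", "patchy"),
                             region = NULL) {
  set <- match.arg(set)
  tab <- motor_params_table(set)
  keep <- tab$genotype == genotype & tab$substrate == substrate
  if (set == "patchy") {
    if (is.null(region)) stop("region required for the patchy table",
                              call. = FALSE)
    keep <- keep & tab$region == region
  }
  row <- tab[keep, ]
  if (nrow(row) != 1)
    stop(sprintf("no parameter set for genotype '%s', substrate '%s'",
                 genotype, substrate), call. = FALSE)
  substrate_params(row$mean_v, row$sd_v, row$p_turn_per_s, row$p_pause_per_s)
}
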