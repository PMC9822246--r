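#' Ramer-Douglas-Peucker trajectory simplification
#'
#' Simplifies the point sequence of a trajectory with the standard recursive
#' RDP algorithm: between two anchor points, the point with the largest
#' perpendicular distance to the anchor chord is retained if that distance
#' exceeds `epsilon`, and the procedure recurses on both halves. The retained
#' interior vertices are the salient turning points of the track. Defaults
#' used in larval analysis: epsilon 2.5 mm on agar, sucrose and apple juice,
#' 1.25 mm on yeast (see [rdp_epsilon()]).
#'
#' @param traj A [trajectory()] or an n x 2 numeric matrix of points.
#' @param epsilon Maximum allowed deviation (mm), positive.
#' @return An object of class `simplified_path`: list with `vertices`
#'   (m x 2 matrix), `frame_indices` (1-based indices into the input), and
#'   `epsilon`.
#' @export
#' @examples
#' tr <- trajectory(x = c(0, 10, 20, 20, 20), y = c(0, 0, 0, 10, 20))
#' rdp_simplify(tr, 2.5)$frame_indices   # endpoints and the corner
rdp_simplify <- function(traj, epsilon) {
  if (inherits(traj, "larva_trajectory")) {
    pts <- traj$positions
  } else {
    pts <- as.matrix(traj)
  }
  stopifnot(ncol(pts) == 2, nrow(pts) >= 2)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("epsilon must be a positive number", call. = FALSE)
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  # iterative stack version of the recursion (deep recursion on long tracks)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    idx <- (i + 1):(j - 1)
    d <- point_line_distance(pts[idx, , drop = FALSE], pts[i, ], pts[j, ])
    m <- which.max(d)
    if (d[m] > epsilon) {
      k <- idx[m]
      keep[k] <- TRUE
      stack[[length(stack) + 1]] <- c(i, k)
      stack[[length(stack) + 1]] <- c(k, j)
    }
  }
  fi <- which(keep)
  structure(list(vertices = pts[fi, , drop = FALSE],
                 frame_indices = fi, epsilon = epsilon),
            class = "simplified_path")
}

# Perpendicular distance from points (m x 2) to the line through a and b;
# plain Euclidean distance to a when the chord is degenerate.
point_line_distance <- function(p, a, b) {
  ab <- b - a
  L <- sqrt(sum(ab^2))
  if (L == 0) return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  abs(ab[1] * (a[2] - p[, 2]) - ab[2] * (a[1] - p[, 1])) / L
}

#' @export
print.simplified_path <- function(x, ...) {
  cat(sprintf("<simplified_path> %d vertices (epsilon = %g mm)\n",
              nrow(x$vertices), x$epsilon))
  invisible(x)
}

#' Default RDP epsilon by substrate
#'
#' @param substrate Substrate label; yeast gets 1.25 mm, everything else
#'   2.5 mm.
#' @return Epsilon in mm.
#' @export
rdp_epsilon <- function(substrate) {
  ifelse(substrate == "yeast", 1.25, 2.5)
}

#' Signed turning angles of a simplified path
#'
#' For each interior vertex, the signed angle from the incoming to the
#' outgoing segment direction, computed as atan2 of the 2-D cross and dot
#' products, in \[-pi, pi\]. Positive angles are counter-clockwise (CCW)
#' turns, negative are clockwise (CW). Vertices adjacent to a zero-length
#' segment yield NA (flagged via the `degenerate` attribute).
#'
#' @param path A `simplified_path` (or an m x 2 matrix of vertices) with at
#'   least 3 vertices.
#' @return Numeric vector of length m - 2 of signed angles in radians, with
#'   attribute `degenerate` marking skipped vertices.
#' @export
#' @examples
#' turning_angles(rbind(c(0, 0), c(1, 0), c(1, 1)))  # +pi/2, a CCW turn
turning_angles <- function(path) {
  v <- if (inherits(path, "simplified_path")) path$vertices else as.matrix(path)
  if (nrow(v) < 3) stop("need at least 3 vertices", call. = FALSE)
  d <- diff(v)                      # segment vectors
  a <- d[-nrow(d), , drop = FALSE]  # incoming
  b <- d[-1, , drop = FALSE]        # outgoing
  cross <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  dotp <- a[, 1] * b[, 1] + a[, 2] * b[, 2]
  ang <- unname(atan2(cross, dotp))
  degen <- (a[, 1] == 0 & a[, 2] == 0) | (b[, 1] == 0 & b[, 2] == 0)
  ang[degen] <- NA
  attr(ang, "degenerate") <- which(degen)
  ang
}

#' Handedness score
#'
#' H = N_CCW / (N_CCW + N_CW), the fraction of counter-clockwise turns among
#' all turns of a larva. H > 0.5 means a CCW bias, H < 0.5 a CW bias. Turns
#' with angle exactly 0 (and NA angles) count as neither.
#'
#' @param angles Signed turning angles in radians.
#' @return An object of class `handedness_score`: list with `H` (NA when no
#'   nonzero turns), `n_ccw`, `n_cw`.
#' @export
#' @examples
#' handedness(c(0.5, 1, 0.2, -0.3))$H   # 0.75
handedness <- function(angles) {
  angles <- angles[!is.na(angles)]
  n_ccw <- sum(angles > 0)
  n_cw <- sum(angles < 0)
  H <- if (n_ccw + n_cw == 0) NA_real_ else n_ccw / (n_ccw + n_cw)
  structure(list(H = H, n_ccw = n_ccw, n_cw = n_cw),
            class = "handedness_score")
}

#' @export
print.handedness_score <- function(x, ...) {
  cat(sprintf("<handedness> H = %s (%d CCW / %d CW)\n",
              ifelse(is.na(x$H), "undefined", format(x$H)), x$n_ccw, x$n_cw))
  invisible(x)
}

#' Average turns per minute from a turn indicator
#'
#' Applies a rolling window (default 120 frames = 1 min at 2 frames/s) to a
#' per-frame 0/1 turn indicator, sums within each full window, and returns
#' the mean of the window sums: the average number of turns per minute.
#'
#' @param turn_frames Binary (0/1 or logical) per-frame indicator vector.
#' @param window Window length in frames, default 120.
#' @return Mean turns per window (turns per minute at the default window).
#' @export
turns_per_minute <- function(turn_frames, window = 120) {
  x <- as.numeric(turn_frames)
  n <- length(x)
  if (window > n)
    stop(sprintf("indicator (%d frames) shorter than window (%d)", n, window),
         call. = FALSE)
  cs <- c(0, cumsum(x))
  sums <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
  mean(sums)
}

#' Per-frame turn indicator of a simplified path
#'
#' 1 at the frames of the interior RDP vertices (the detected turns),
#' 0 elsewhere.
#'
#' @param path A `simplified_path`.
#' @param n_frames Length of the source trajectory.
#' @return Integer 0/1 vector of length `n_frames`.
#' @export
turn_indicator <- function(path, n_frames) {
  stopifnot(inherits(path, "simplified_path"))
  ind <- integer(n_frames)
  fi <- path$frame_indices
  interior <- fi[-c(1, length(fi))]
  ind[interior] <- 1L
  ind
}

#' Classify one turn as inward or outward
#'
#' At interior vertex k of the simplified path, with V1 the incoming segment,
#' V2 the outgoing segment and U the vector from the vertex to the nearest
#' patch center, the turn is inward when the outgoing segment points more
#' toward the center than the incoming one: theta2 < theta1, where
#' theta_i = angle(V_i, U). Exact ties (within 1e-12) are labelled outward,
#' the conservative choice.
#'
#' @param path A `simplified_path` with at least 3 vertices.
#' @param k Interior vertex index (2 .. m-1 in vertex numbering).
#' @param layout A [patch_layout()] with at least one patch.
#' @return `"inward"`, `"outward"`, or `NA` when any of V1, V2, U is
#'   zero-length (unclassifiable).
#' @export
classify_turn <- function(path, k, layout) {
  stopifnot(inherits(path, "simplified_path"))
  v <- path$vertices
  m <- nrow(v)
  if (k < 2 || k > m - 1) stop("k must be an interior vertex index",
                               call. = FALSE)
  np <- nearest_patch(layout, v[k, ])
  u <- c(np$patch$cx, np$patch$cy) - v[k, ]
  v1 <- v[k, ] - v[k - 1, ]
  v2 <- v[k + 1, ] - v[k, ]
  nu <- sqrt(sum(u^2)); n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (nu == 0 || n1 == 0 || n2 == 0) return(NA_character_)
  th1 <- acos(pmin(1, pmax(-1, sum(v1 * u) / (n1 * nu))))
  th2 <- acos(pmin(1, pmax(-1, sum(v2 * u) / (n2 * nu))))
  if (th2 < th1 - 1e-12) "inward" else "outward"
}

#' Detect and characterize turns in a trajectory
#'
#' The full turn-analysis pipeline for one track: RDP simplification, signed
#' turning angles and CW/CCW direction at each retained interior vertex, and
#' (when a layout is given) the inward/outward label and the distance to the
#' nearest patch center.
#'
#' @param traj A [trajectory()].
#' @param epsilon RDP epsilon (mm); defaults to [rdp_epsilon()] of the
#'   layout's patch substrate, or 2.5 mm without a layout.
#' @param layout Optional [patch_layout()] for orientation labels.
#' @return A tibble of turn events: `larva_id`, `vertex`, `frame`, `x`, `y`,
#'   `angle_rad`, `direction` ("CCW", "CW", or "none" for exactly 0),
#'   `orientation` ("inward"/"outward"/NA), `dist_mm` (NA without layout).
#' @export
detect_turns <- function(traj, epsilon = NULL, layout = NULL) {
  stopifnot(inherits(traj, "larva_trajectory"))
  if (is.null(epsilon)) {
    epsilon <- if (!is.null(layout) && n_patches(layout) > 0)
      rdp_epsilon(layout$patches[[1]]$substrate) else 2.5
  }
  sp <- rdp_simplify(traj, epsilon)
  m <- nrow(sp$vertices)
  if (m < 3) {
    return(tibble::tibble(larva_id = character(0), vertex = integer(0),
                          frame = integer(0), x = numeric(0), y = numeric(0),
                          angle_rad = numeric(0), direction = character(0),
                          orientation = character(0), dist_mm = numeric(0)))
  }
  ang <- as.vector(turning_angles(sp))
  ks <- 2:(m - 1)
  direction <- ifelse(is.na(ang), NA_character_,
                      ifelse(ang > 0, "CCW", ifelse(ang < 0, "CW", "none")))
  if (!is.null(layout) && n_patches(layout) > 0) {
    orientation <- vapply(ks, function(k) classify_turn(sp, k, layout),
                          character(1))
    dist_mm <- vapply(ks, function(k)
      nearest_patch(layout, sp$vertices[k, ])$distance, numeric(1))
  } else {
    orientation <- rep(NA_character_, length(ks))
    dist_mm <- rep(NA_real_, length(ks))
  }
  tibble::tibble(larva_id = traj$larva_id, vertex = ks,
                 frame = sp$frame_indices[ks],
                 x = sp$vertices[ks, 1], y = sp$vertices[ks, 2],
                 angle_rad = ang, direction = direction,
                 orientation = orientation, dist_mm = dist_mm)
}

#' Fraction of inward turns by distance to the patch center
#'
#' Bins classified turn events into half-open distance bins \[a, b) from the
#' nearest patch center (default 10-mm bins up to 60 mm, beyond which events
#' are excluded) and reports the inward fraction per bin. With the 25 mm
#' reference patches the patch border falls in the 20-30 mm bin.
#'
#' @param events A turn-event tibble from [detect_turns()] (needs
#'   `orientation` and `dist_mm`).
#' @param bin_width Bin width in mm, default 10.
#' @param max_distance Upper cap in mm, default 60.
#' @return A tibble with `bin_lo`, `bin_hi`, `n_inward`, `n_outward`, `n`,
#'   `fraction_inward` (NA for empty bins).
#' @export
inward_fraction_by_distance <- function(events, bin_width = 10,
                                        max_distance = 60) {
  stopifnot(bin_width > 0, max_distance > 0)
  lo <- seq(0, max_distance - bin_width, by = bin_width)
  hi <- lo + bin_width
  ev <- events[!is.na(events$orientation) & !is.na(events$dist_mm) &
                 events$dist_mm < max_distance, ]
  bin <- findInterval(ev$dist_mm, c(lo, max_distance),
                      rightmost.closed = FALSE)
  n_in <- n_out <- integer(length(lo))
  for (b in seq_along(lo)) {
    n_in[b] <- sum(bin == b & ev$orientation == "inward")
    n_out[b] <- sum(bin == b & ev$orientation == "outward")
  }
  n <- n_in + n_out
  tibble::tibble(bin_lo = lo, bin_hi = hi, n_inward = n_in,
                 n_outward = n_out, n = n,
                 fraction_inward = ifelse(n == 0, NA_real_, n_in / n))
}
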