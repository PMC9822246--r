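#' Arena specification
#'
#' Rectangular crawling arena with rigid boundaries. The coordinate frame has
#' its origin at the lower-left corner, x to the right, y up, units mm. The
#' default 240 x 240 mm matches the behavioral arenas.
#'
#' @param width,height Arena dimensions in mm; both must be positive.
#' @return An object of class `arena_spec`.
#' @export
#' @examples
#' arena_spec()
#' arena_spec(100, 150)
arena_spec <- function(width = 240, height = 240) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1,
            length(height) == 1, is.finite(width), is.finite(height))
  if (width <= 0 || height <= 0)
    stop("arena width and height must be positive", call. = FALSE)
  structure(list(width = width, height = height), class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g mm\n", x$width, x$height))
  invisible(x)
}

#' Circular food patch
#'
#' @param cx,cy Patch center coordinates (mm).
#' @param radius Patch radius (mm), positive. The patch is a closed disc:
#'   points at distance exactly `radius` from the center count as inside.
#' @param substrate Substrate label, e.g. "agar", "sucrose", "yeast",
#'   "apple_juice".
#' @return An object of class `patch`.
#' @export
patch <- function(cx, cy, radius, substrate = "yeast") {
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(radius),
            is.character(substrate), length(substrate) == 1)
  if (!is.finite(radius) || radius <= 0)
    stop("patch radius must be positive and finite", call. = FALSE)
  structure(list(cx = cx, cy = cy, radius = radius, substrate = substrate),
            class = "patch")
}

#' Arena layout with circular food patches
#'
#' Combines an arena with an ordered list of patches and the substrate label
#' for the area outside every patch. Each patch disc must lie entirely within
#' the arena. If user-supplied patches overlap, the first patch in list order
#' wins for point-in-patch queries.
#'
#' @param arena An [arena_spec()].
#' @param patches A list of [patch()] objects (possibly empty).
#' @param outside_substrate Label of the substrate outside all patches.
#' @return An object of class `patch_layout`.
#' @export
patch_layout <- function(arena = arena_spec(), patches = list(),
                         outside_substrate = "agar") {
  stopifnot(inherits(arena, "arena_spec"), is.list(patches))
  for (p in patches) {
    if (!inherits(p, "patch")) stop("patches must be patch objects", call. = FALSE)
    if (p$cx - p$radius < 0 || p$cx + p$radius > arena$width ||
        p$cy - p$radius < 0 || p$cy + p$radius > arena$height)
      stop(sprintf("patch at (%g, %g) with radius %g extends outside the arena",
                   p$cx, p$cy, p$radius), call. = FALSE)
  }
  structure(list(arena = arena, patches = patches,
                 outside_substrate = outside_substrate),
            class = "patch_layout")
}

#' @export
print.patch_layout <- function(x, ...) {
  cat(sprintf("<patch_layout> %g x %g mm arena, %d patch(es), outside: %s\n",
              x$arena$width, x$arena$height, length(x$patches),
              x$outside_substrate))
  for (p in x$patches)
    cat(sprintf("  (%g, %g) r = %g mm  [%s]\n", p$cx, p$cy, p$radius,
                p$substrate))
  invisible(x)
}

n_patches <- function(layout) length(layout$patches)

# Patch centers as an n x 2 matrix (0 rows when empty) and radii vector;
# internal plumbing shared with the simulator.
patch_matrix <- function(layout) {
  if (n_patches(layout) == 0)
    return(list(centers = matrix(numeric(0), 0, 2), radii = numeric(0),
                substrates = character(0)))
  list(centers = t(vapply(layout$patches, function(p) c(p$cx, p$cy),
                          numeric(2))),
       radii = vapply(layout$patches, function(p) p$radius, numeric(1)),
       substrates = vapply(layout$patches, function(p) p$substrate,
                           character(1)))
}

#' Total food area of the reference patch design
#'
#' The reference experiments distribute food over `n_reference` patches of a
#' given radius; the conserved quantity when fragmenting the food into more
#' patches is the total surface area S = n_reference * pi * radius^2 (with the
#' default two 25-mm patches, S = 2 * pi * R^2).
#'
#' @param radius Reference patch radius (mm), positive.
#' @param n_reference Number of reference patches (default 2).
#' @return Total food area in mm^2.
#' @seealso [fragment_radius()]
#' @export
#' @examples
#' total_food_area(25)             # 1250 * pi
total_food_area <- function(radius, n_reference = 2) {
  stopifnot(is.numeric(radius), length(radius) == 1)
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be positive", call. = FALSE)
  stopifnot(n_reference >= 1)
  n_reference * pi * radius^2
}

#' Patch radius after fragmentation at fixed total food area
#'
#' Redistributing a fixed total food area S into `n_patches` equal circular
#' patches gives each patch radius R' = sqrt(S / (n_patches * pi)), so that
#' the combined patch area is exactly S for any patch number.
#'
#' @param total_area Total food area (mm^2), positive.
#' @param n_patches Number of patches, at least 1.
#' @return The per-patch radius R' in mm.
#' @seealso [total_food_area()]
#' @export
#' @examples
#' fragment_radius(total_food_area(25), 8)   # 12.5 mm
#' fragment_radius(total_food_area(25), 2)   # 25 mm round-trip
fragment_radius <- function(total_area, n_patches) {
  stopifnot(is.numeric(total_area), length(total_area) == 1)
  if (!is.finite(total_area) || total_area <= 0)
    stop("total_area must be positive", call. = FALSE)
  if (length(n_patches) != 1 || n_patches < 1 || n_patches != round(n_patches))
    stop("n_patches must be a positive integer", call. = FALSE)
  sqrt(total_area / (n_patches * pi))
}

#' Random non-overlapping patch layout
#'
#' Places `n_patches` disjoint discs of equal radius uniformly at random fully
#' inside the arena by rejection sampling (at most 10000 attempts per patch).
#'
#' @param arena An [arena_spec()].
#' @param n_patches Number of patches to place.
#' @param radius Common patch radius (mm).
#' @param substrate Substrate label for every patch.
#' @param seed Optional integer seed for reproducible placement; when `NULL`
#'   the current RNG stream is used.
#' @param outside_substrate Label outside the patches.
#' @param max_attempts Rejection-sampling cap per patch.
#' @return A [patch_layout()].
#' @export
random_layout <- function(arena, n_patches, radius, substrate = "yeast",
                          seed = NULL, outside_substrate = "agar",
                          max_attempts = 10000) {
  stopifnot(inherits(arena, "arena_spec"), n_patches >= 1, radius > 0)
  if (!is.null(seed)) set.seed(seed)
  if (2 * radius > arena$width || 2 * radius > arena$height)
    stop("packing failure: a single patch does not fit in the arena",
         call. = FALSE)
  cx <- numeric(0); cy <- numeric(0)
  for (i in seq_len(n_patches)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      x <- stats::runif(1, radius, arena$width - radius)
      y <- stats::runif(1, radius, arena$height - radius)
      if (i == 1 || all((x - cx)^2 + (y - cy)^2 > (2 * radius)^2)) {
        cx <- c(cx, x); cy <- c(cy, y); placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(paste0("packing failure: could not place patch %d of %d ",
                          "after %d attempts"), i, n_patches, max_attempts),
           call. = FALSE)
  }
  patch_layout(arena,
               patches = lapply(seq_len(n_patches), function(i)
                 patch(cx[i], cy[i], radius, substrate)),
               outside_substrate = outside_substrate)
}

#' Reference two-patch layout
#'
#' The two-patch design of the patchy-arena experiments: two patches of equal
#' radius placed symmetrically on the horizontal midline of the arena. The
#' exact experimental center coordinates were not published; the 120 mm
#' default separation is a configurable stand-in.
#'
#' @param substrate Patch substrate label.
#' @param radius Patch radius (mm), default 25.
#' @param separation Center-to-center distance (mm), default 120.
#' @param arena An [arena_spec()].
#' @param outside_substrate Label outside the patches.
#' @return A [patch_layout()] with two patches.
#' @export
#' @examples
#' two_patch_layout("yeast")
two_patch_layout <- function(substrate = "yeast", radius = 25,
                             separation = 120, arena = arena_spec(),
                             outside_substrate = "agar") {
  ymid <- arena$height / 2
  x1 <- arena$width / 2 - separation / 2
  x2 <- arena$width / 2 + separation / 2
  patch_layout(arena,
               patches = list(patch(x1, ymid, radius, substrate),
                              patch(x2, ymid, radius, substrate)),
               outside_substrate = outside_substrate)
}

#' Substrate label at a point
#'
#' Returns the substrate of the first patch (in list order) whose closed disc
#' contains the point, or the outside substrate if no patch does.
#'
#' @param layout A [patch_layout()].
#' @param point Numeric length-2 vector (x, y) in mm; must lie in the arena.
#' @return A substrate label (character scalar).
#' @export
substrate_at <- function(layout, point) {
  stopifnot(inherits(layout, "patch_layout"), is.numeric(point),
            length(point) == 2)
  if (point[1] < 0 || point[1] > layout$arena$width ||
      point[2] < 0 || point[2] > layout$arena$height)
    stop(sprintf("point (%g, %g) is outside the arena", point[1], point[2]),
         call. = FALSE)
  for (p in layout$patches) {
    if ((point[1] - p$cx)^2 + (point[2] - p$cy)^2 <= p$radius^2)
      return(p$substrate)
  }
  layout$outside_substrate
}

#' Nearest patch to a point
#'
#' The patch whose center minimizes the Euclidean distance to the point;
#' ties go to the lowest-index patch.
#'
#' @param layout A [patch_layout()] with at least one patch.
#' @param point Numeric length-2 vector (x, y) in mm.
#' @return A list with elements `patch`, `index`, and `distance` (mm,
#'   point-to-center).
#' @export
nearest_patch <- function(layout, point) {
  stopifnot(inherits(layout, "patch_layout"), is.numeric(point),
            length(point) == 2)
  if (n_patches(layout) == 0)
    stop("layout has no patches", call. = FALSE)
  pm <- patch_matrix(layout)
  d <- sqrt((pm$centers[, 1] - point[1])^2 + (pm$centers[, 2] - point[2])^2)
  i <- which.min(d)  # which.min returns the first minimum: lowest index wins
  list(patch = layout$patches[[i]], index = i, distance = d[i])
}

#' Frames per frame matrix of points inside any patch
#'
#' Vectorized point-in-patch test used by the residence metrics.
#'
#' @param layout A [patch_layout()].
#' @param xy An n x 2 matrix of points.
#' @return Logical vector of length n: TRUE where the point lies inside the
#'   closed disc of at least one patch.
#' @keywords internal
inside_any_patch <- function(layout, xy) {
  pm <- patch_matrix(layout)
  inside <- rep(FALSE, nrow(xy))
  for (i in seq_along(pm$radii)) {
    inside <- inside |
      ((xy[, 1] - pm$centers[i, 1])^2 + (xy[, 2] - pm$centers[i, 2])^2 <=
         pm$radii[i]^2)
  }
  inside
}

#' Read or write a patch layout
#'
#' Layouts serialize to JSON or YAML with fields
#' `{arena: {width, height}, patches: [{cx, cy, r, substrate}], outside: label}`.
#' The format is chosen from the file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param layout A [patch_layout()].
#' @param path File path.
#' @return `write_layout()` returns `path` invisibly; `read_layout()` returns
#'   a [patch_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "patch_layout"))
  obj <- list(
    arena = list(width = layout$arena$width, height = layout$arena$height),
    patches = lapply(layout$patches, function(p)
      list(cx = p$cx, cy = p$cy, r = p$radius, substrate = p$substrate)),
    outside = layout$outside_substrate)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  patch_layout(arena_spec(obj$arena$width, obj$arena$height),
               patches = lapply(obj$patches, function(p)
                 patch(p$cx, p$cy, p$r, p$substrate)),
               outside_substrate = obj$outside)
}
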