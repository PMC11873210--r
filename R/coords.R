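#' Interaural-polar coordinates
#'
#' The model works in the interaural-polar convention: the lateral angle is
#' the angle from the midsagittal plane (positive toward the left ear,
#' range \[-90, 90\] degrees) and the polar angle is the position on the
#' cone of confusion (0 = front horizontal, 90 = up, 180 = rear horizontal,
#' range \[-90, 270)).  Internally directions are unit vectors with x =
#' front, y = left, z = up, so `lateral = asin(y)` and
#' `polar = atan2(z, x)`.
#'
#' @param v Unit 3-vector, or an n x 3 matrix of unit row vectors.
#' @return `interaural_polar()`: list with `lateral_deg` and `polar_deg`
#'   (vectors).  `interaural_polar_inverse()`: n x 3 matrix of unit
#'   vectors.
#' @examples
#' interaural_polar(c(1, 0, 0))   # lateral 0, polar 0 (straight ahead)
#' interaural_polar(c(0, 0, 1))   # polar 90 (straight up)
#' @export
interaural_polar <- function(v) {
  if (is.vector(v)) v <- matrix(v, nrow = 1)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("zero vector has no direction")
  v <- v / nrm
  lat <- asin(pmin(pmax(v[, 2], -1), 1)) * 180 / pi
  pol <- atan2(v[, 3], v[, 1]) * 180 / pi
  pol[pol < -90] <- pol[pol < -90] + 360          # map to [-90, 270)
  pol[abs(abs(lat) - 90) < 1e-9] <- 0             # poles: polar undefined
  list(lateral_deg = lat, polar_deg = pol)
}

#' @rdname interaural_polar
#' @param lateral_deg,polar_deg Angles in degrees.
#' @export
interaural_polar_inverse <- function(lateral_deg, polar_deg) {
  lat <- lateral_deg * pi / 180
  pol <- polar_deg * pi / 180
  cbind(x = cos(lat) * cos(pol), y = sin(lat), z = cos(lat) * sin(pol))
}

#' Direction grids on the sphere
#'
#' A `direction_grid` stores unit direction vectors together with their
#' interaural-polar (lateral/polar) and elevation angles.
#'
#' @param vectors n x 3 matrix of direction vectors (normalized on input).
#' @return An object of class `direction_grid` with fields `unit_vectors`,
#'   `lateral_deg`, `polar_deg`, `elevation_deg`, `n`.
#' @export
direction_grid <- function(vectors) {
  if (is.vector(vectors)) vectors <- matrix(vectors, nrow = 1)
  stopifnot(ncol(vectors) == 3)
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm < 1e-12)) stop("zero vector in grid")
  v <- vectors / nrm
  if (nrow(v) > 1) {
    # duplicate check on rounded coordinates
    key <- apply(round(v, 9), 1, paste, collapse = ",")
    if (anyDuplicated(key)) stop("duplicate directions in grid")
  }
  ip <- interaural_polar(v)
  structure(list(unit_vectors = v,
                 lateral_deg = ip$lateral_deg,
                 polar_deg = ip$polar_deg,
                 elevation_deg = asin(pmin(pmax(v[, 3], -1), 1)) * 180 / pi,
                 n = nrow(v)),
            class = "direction_grid")
}

#' @export
print.direction_grid <- function(x, ...) {
  cat(sprintf("direction grid: %d directions\n", x$n))
  invisible(x)
}

#' @rdname direction_grid
#' @param grid A `direction_grid`.
#' @param idx Integer or logical index of directions to keep.
#' @export
grid_subset <- function(grid, idx) {
  stopifnot(inherits(grid, "direction_grid"))
  structure(list(unit_vectors = grid$unit_vectors[idx, , drop = FALSE],
                 lateral_deg = grid$lateral_deg[idx],
                 polar_deg = grid$polar_deg[idx],
                 elevation_deg = grid$elevation_deg[idx],
                 n = nrow(grid$unit_vectors[idx, , drop = FALSE])),
            class = "direction_grid")
}

#' Approximately uniform grid of directions on the sphere
#'
#' Generates `n` directions distributed approximately uniformly over the
#' sphere.  The default Fibonacci lattice is deterministic; the
#' `"random"` method samples i.i.d. uniform directions given `seed`.
#'
#' @param n Number of directions (>= 1).
#' @param method `"fibonacci"` (default) or `"random"`.
#' @param seed RNG seed for the random method.
#' @return A [direction_grid()].
#' @export
uniform_sphere_grid <- function(n, method = c("fibonacci", "random"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(n >= 1)
  if (method == "fibonacci") {
    i <- seq_len(n) - 1
    z <- 1 - (2 * i + 1) / n
    phi <- 2 * pi * i * (sqrt(5) - 1) / 2
    r <- sqrt(pmax(1 - z^2, 0))
    v <- cbind(r * cos(phi), r * sin(phi), z)
  } else {
    v <- with_seed(seed, {
      z <- runif(n, -1, 1)
      phi <- runif(n, 0, 2 * pi)
      r <- sqrt(pmax(1 - z^2, 0))
      cbind(r * cos(phi), r * sin(phi), z)
    })
  }
  direction_grid(v)
}

#' Filter a grid by minimum elevation
#'
#' Retains exactly the directions with elevation at or above
#' `min_elevation_deg`, preserving order.  Used to emulate HRTF
#' measurement setups that leave the lower cone unmeasured: cutting a
#' 2000-direction uniform grid at -45 degrees retains about
#' `(1 + sin 45) / 2` of the sphere, i.e. ~1708 directions.
#'
#' @param grid A [direction_grid()].
#' @param min_elevation_deg Cut in degrees.
#' @return The filtered `direction_grid`; errors if nothing survives.
#' @export
filter_grid <- function(grid, min_elevation_deg) {
  stopifnot(inherits(grid, "direction_grid"))
  keep <- grid$elevation_deg >= min_elevation_deg
  if (!any(keep)) stop("elevation filter removed every direction")
  grid_subset(grid, keep)
}

#' Mask of directions near the midsagittal plane
#'
#' Boolean mask selecting the benchmark response region: directions within
#' `max_lateral_deg` of the midsagittal plane and within
#' `max_polar_band_deg` above and below the horizontal plane, in both the
#' front and rear hemifields.  The default band is expressed in polar
#' angle (front: polar in \[-60, 60\]; rear: polar in \[120, 240\]), which
#' reproduces the 599-direction count of the reference grid; an
#' elevation-based band is available via `mode`.
#'
#' @param grid A [direction_grid()].
#' @param max_lateral_deg Maximum |lateral| in degrees.
#' @param max_polar_band_deg Half-width of the band around the horizontal
#'   plane, degrees.
#' @param mode `"polar"` (default) or `"elevation"`.
#' @return Logical vector of length `grid$n`.
#' @export
region_mask <- function(grid, max_lateral_deg = 30, max_polar_band_deg = 60,
                        mode = c("polar", "elevation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "direction_grid"))
  lat_ok <- abs(grid$lateral_deg) <= max_lateral_deg
  if (mode == "polar") {
    p <- grid$polar_deg
    band <- (p >= -max_polar_band_deg & p <= max_polar_band_deg) |
      (p >= 180 - max_polar_band_deg & p <= 180 + max_polar_band_deg)
  } else {
    band <- abs(grid$elevation_deg) <= max_polar_band_deg
  }
  lat_ok & band
}

#' Angular separation between grid directions
#'
#' Great-circle (angular) distance in degrees between the directions at
#' indices `i` and `j` of a grid; vectorized over pairs.
#'
#' @param i,j Direction indices (recycled to common length).
#' @param grid A [direction_grid()].
#' @return Numeric vector of angles in degrees.
#' @export
great_circle_error <- function(i, j, grid) {
  stopifnot(inherits(grid, "direction_grid"))
  n <- max(length(i), length(j))
  i <- rep_len(i, n); j <- rep_len(j, n)
  vi <- grid$unit_vectors[i, , drop = FALSE]
  vj <- grid$unit_vectors[j, , drop = FALSE]
  d <- rowSums(vi * vj)
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}
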