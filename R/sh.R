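#' Real spherical-harmonics basis
#'
#' Evaluates the orthonormal real spherical harmonics up to degree
#' `order` at the directions of a grid.  Columns are ordered by degree l
#' and, within a degree, by m = -l..l (sine terms for m < 0, the zonal
#' term at m = 0, cosine terms for m > 0).
#'
#' @param grid A [direction_grid()].
#' @param order Maximum degree L (>= 0).
#' @return Matrix of size `grid$n` x `(order + 1)^2`.
#' @export
real_sh_basis <- function(grid, order) {
  stopifnot(inherits(grid, "direction_grid"), order >= 0)
  v <- grid$unit_vectors
  ct <- pmin(pmax(v[, 3], -1), 1)                  # cos(colatitude)
  phi <- atan2(v[, 2], v[, 1])
  n <- nrow(v)
  G <- matrix(0, n, (order + 1)^2)
  col <- 1L
  for (l in 0:order) {
    P <- pracma::legendre(l, ct)                   # (l+1) x n, rows m = 0..l
    if (is.vector(P)) P <- matrix(P, nrow = 1)
    for (m in (-l):l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi)) *
        exp(0.5 * (lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- nrm * P[am + 1, ]
      G[, col] <- if (m < 0) sqrt(2) * base * sin(am * phi)
      else if (m == 0) base
      else sqrt(2) * base * cos(am * phi)
      col <- col + 1L
    }
  }
  G
}

#' Spherical-harmonics resampling of an HRTF set
#'
#' Fits each frequency channel of both ears (and the ITD) with real
#' spherical harmonics up to `order` by Tikhonov-regularized least
#' squares, then evaluates the fit on a target grid.  This is the
#' standard way to interpolate sparsely measured HRTFs onto a dense
#' uniform grid before template matching.
#'
#' @param hrtf An [hrtf_set()].
#' @param target A [direction_grid()] to evaluate on.
#' @param order Maximum spherical-harmonic degree; the source grid must
#'   contain at least `(order + 1)^2` directions.
#' @param tikhonov_lambda Ridge penalty added to the normal equations
#'   (>= 0).  With 0 the fit is plain least squares and errors out on a
#'   rank-deficient system.
#' @return An [hrtf_set()] on `target`.
#' @export
sh_resample <- function(hrtf, target, order = 15, tikhonov_lambda = 1e-4) {
  stopifnot(inherits(hrtf, "hrtf_set"), inherits(target, "direction_grid"))
  ncoef <- (order + 1)^2
  if (hrtf$grid$n < ncoef)
    stop(sprintf("source grid has %d directions; order %d needs at least %d",
                 hrtf$grid$n, order, ncoef))
  G <- real_sh_basis(hrtf$grid, order)
  Y <- cbind(hrtf$logmag_left, hrtf$logmag_right, hrtf$itd_us)
  A <- crossprod(G) + diag(tikhonov_lambda, ncoef)
  coef <- tryCatch(solve(A, crossprod(G, Y)), error = function(e)
    stop("spherical-harmonics system is rank deficient; ",
         "set tikhonov_lambda > 0 (", conditionMessage(e), ")"))
  Gt <- real_sh_basis(target, order)
  Z <- Gt %*% coef
  N <- hrtf$fb$n_channels
  hrtf_set(target, Z[, 1:N, drop = FALSE], Z[, (N + 1):(2 * N), drop = FALSE],
           Z[, 2 * N + 1], hrtf$fb, subject_id = hrtf$subject_id)
}
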