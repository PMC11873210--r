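#' ITD just-noticeable-difference transform
#'
#' The interaural time difference enters the model in jnd units so that
#' measurement noise on it has input-independent (unit) variance.  Human
#' ITD discrimination thresholds grow with |ITD|, so the transform is a
#' compressive odd function: the default tabulated curve is calibrated so
#' that 1 jnd corresponds to 20 microseconds near zero and widens linearly
#' to 60 microseconds per jnd at |ITD| = 600 microseconds (and stays at 60
#' beyond).  Any monotone (ITD, jnd) table measured psychoacoustically can
#' be substituted via `curve`.
#'
#' @param itd_us ITD in microseconds (positive = left ear leads);
#'   vectorized, any finite value.
#' @param curve A two-column matrix/data.frame `(itd_us, jnd)` describing
#'   the transform for non-negative ITDs, first row (0, 0); defaults to
#'   [default_itd_jnd_curve()].
#' @return ITD in jnd units (odd, strictly increasing in `itd_us`).
#' @examples
#' itd_to_jnd(0)    # 0
#' itd_to_jnd(20)   # 1
#' @export
itd_to_jnd <- function(itd_us, curve = default_itd_jnd_curve()) {
  curve <- as.matrix(curve)
  stopifnot(ncol(curve) == 2, curve[1, 1] == 0, curve[1, 2] == 0,
            all(diff(curve[, 1]) > 0), all(diff(curve[, 2]) > 0))
  a <- abs(itd_us)
  last_slope <- (curve[nrow(curve), 2] - curve[nrow(curve) - 1, 2]) /
    (curve[nrow(curve), 1] - curve[nrow(curve) - 1, 1])
  j <- approx(curve[, 1], curve[, 2], xout = pmin(a, curve[nrow(curve), 1]),
              method = "linear", ties = "ordered")$y
  over <- a > curve[nrow(curve), 1]
  j[over] <- curve[nrow(curve), 2] + (a[over] - curve[nrow(curve), 1]) * last_slope
  sign(itd_us) * j
}

#' @rdname itd_to_jnd
#' @param width_0_us,width_600_us jnd widths (microseconds per jnd) at ITD
#'   0 and at 600 microseconds.
#' @param max_itd_us Largest tabulated ITD; the curve extrapolates
#'   linearly beyond it.
#' @export
default_itd_jnd_curve <- function(width_0_us = 20, width_600_us = 60,
                                  max_itd_us = 1000) {
  itd <- 0; jnd <- 0
  repeat {
    cur <- itd[length(itd)]
    w <- width_0_us + (width_600_us - width_0_us) * min(cur, 600) / 600
    itd <- c(itd, cur + w)
    jnd <- c(jnd, jnd[length(jnd)] + 1)
    if (cur + w >= max_itd_us) break
  }
  cbind(itd_us = itd, jnd = jnd)
}
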