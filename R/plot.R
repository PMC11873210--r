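#' Heat map of a source-prior covariance
#'
#' Covariance matrix as an image with the mean spectrum underneath, the
#' usual way corpus priors are inspected.
#'
#' @param p A [source_prior()].
#' @param main Title.
#' @export
plot_prior_covariance <- function(p, main = NULL) {
  stopifnot(inherits(p, "source_prior"))
  n <- length(p$mean)
  old <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  image(1:n, 1:n, p$cov, col = hcl.colors(64, "viridis"),
        xlab = "channel", ylab = "channel",
        main = main %||% sprintf("%s covariance (%s)", p$representation,
                                 p$provenance))
  plot(1:n, p$mean, type = "l", xlab = "channel",
       ylab = sprintf("mean (%s)", if (p$representation == "SG") "dB/ERB" else "dB"))
  invisible(p)
}

#' Error-rate curves across ripple conditions
#'
#' Plots the pooled polar error rate against one ripple parameter, one
#' curve per representation (the usual benchmark summary figure).
#'
#' @param summary Data frame from [run_ripple_experiment()].
#' @param x One of `"density"`, `"depth_db"`, `"phase"`.
#' @param log_x Use a log x-axis (natural for ripple density).
#' @export
plot_error_rate_curves <- function(summary, x = "density", log_x = (x == "density")) {
  reps <- unique(summary$representation)
  xs <- sort(unique(summary[[x]]))
  Y <- sapply(reps, function(r) {
    s <- summary[summary$representation == r, ]
    s$error_rate[match(xs, s[[x]])]
  })
  matplot(xs, Y, type = "b", pch = 16, lty = 1, log = if (log_x) "x" else "",
          xlab = x, ylab = "polar error rate", ylim = c(0, max(Y, na.rm = TRUE)))
  legend("topright", legend = reps, col = seq_along(reps), lty = 1, pch = 16,
         bty = "n")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
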