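# Base-graphics diagnostics.

#' @export
plot.progress_curve <- function(x, fit = NULL, ...) {
  plot(x$time_s, x$signal, xlab = "time (s)", ylab = "product signal",
       pch = 16, cex = 0.6, ...)
  if (!is.null(fit))
    graphics::lines(x$time_s, closed_form_progress(fit$v0$value,
                                                   fit$kobs$value,
                                                   x$time_s), col = 2)
  invisible(x)
}

#' @export
plot.titration_series <- function(x, si = NULL, ...) {
  plot(x$ratio, x$residual_activity, xlab = "[serpin]:[protease]",
       ylab = "residual activity", pch = 16, ...)
  if (!is.null(si))
    graphics::abline(a = si$extra$intercept, b = si$extra$slope, col = 2)
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  species <- c("E", "EI", "E_inh", "I", "I_clv")
  graphics::matplot(x$time_s, as.matrix(x[species]), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "concentration (M)", ...)
  graphics::legend("right", legend = species, col = seq_along(species),
                   lty = 1, bty = "n")
  invisible(x)
}
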