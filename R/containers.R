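# Lightweight S3 containers for assay data and fitted quantities.

#' Progress curve: product signal vs time at one assay condition
#'
#' @param time_s Time points (s); strictly increasing from 0.
#' @param signal Product signal (M or absorbance units); finite.
#' @param inhibitor_M Serpin concentration during the assay (M).
#' @param substrate_M Chromogenic substrate concentration (M).
#' @param metadata Named list of provenance (ground truth, units, warnings).
#' @return A data frame of class `progress_curve` with columns `time_s`,
#'   `signal`; condition and metadata stored as attributes.
#' @export
progress_curve <- function(time_s, signal, inhibitor_M = 0, substrate_M = 0,
                           metadata = list()) {
  if (length(time_s) != length(signal))
    stop("time_s and signal must have equal length")
  if (time_s[1L] != 0 || any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing from 0")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (inhibitor_M < 0 || substrate_M < 0)
    stop("inhibitor_M and substrate_M must be >= 0")
  structure(data.frame(time_s = time_s, signal = signal),
            class = c("progress_curve", "data.frame"),
            inhibitor_M = inhibitor_M, substrate_M = substrate_M,
            metadata = metadata)
}

#' Titration series: residual protease activity vs serpin:protease ratio
#'
#' @param ratio Inhibitor:enzyme molar ratios (>= 0).
#' @param residual_activity Residual activity fractions (>= 0; 1 = uninhibited).
#' @param metadata Named list of provenance.
#' @return A data frame of class `titration_series` with columns `ratio`,
#'   `residual_activity`.
#' @export
titration_series <- function(ratio, residual_activity, metadata = list()) {
  if (length(ratio) != length(residual_activity))
    stop("ratio and residual_activity must have equal length")
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop("ratios must be finite and >= 0")
  if (any(!is.finite(residual_activity)) || any(residual_activity < 0))
    stop("residual activities must be finite and >= 0")
  structure(data.frame(ratio = ratio,
                       residual_activity = residual_activity),
            class = c("titration_series", "data.frame"),
            metadata = metadata)
}

#' Set of progress curves at several inhibitor concentrations
#'
#' @param curves List of [progress_curve] objects.
#' @param substrate_M Common substrate concentration (M).
#' @param Km_M Michaelis constant of the substrate (M), used downstream for
#'   the competition correction.
#' @param metadata Named list of provenance.
#' @return An object of class `progress_set`.
#' @export
progress_set <- function(curves, substrate_M, Km_M = NA_real_,
                         metadata = list()) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1L), "progress_curve")))
  structure(curves, class = "progress_set",
            substrate_M = substrate_M, Km_M = Km_M, metadata = metadata)
}

#' @export
print.progress_set <- function(x, ...) {
  I <- vapply(x, attr, numeric(1L), "inhibitor_M")
  cat(sprintf("Progress set: %d curves, [I] = %s M, [S] = %g M, Km = %g M\n",
              length(x), paste(signif(I, 4), collapse = ", "),
              attr(x, "substrate_M"), attr(x, "Km_M")))
  invisible(x)
}

#' Fitted kinetic quantity with diagnostics
#'
#' @param quantity One of `"v0"`, `"kobs"`, `"kunc"`, `"kass"`, `"Km"`,
#'   `"Vmax"`, `"SI"`.
#' @param value Point estimate; must be finite.
#' @param se Standard error (NA for exact/derived fits).
#' @param rss Residual sum of squares of the underlying fit.
#' @param n Number of data points used.
#' @param extra Named list of fit diagnostics (e.g. intercepts, stages).
#' @return An object of class `kinetic_estimate`.
#' @export
kinetic_estimate <- function(quantity, value, se = NA_real_, rss = NA_real_,
                             n = NA_integer_, extra = list()) {
  quantity <- match.arg(quantity,
                        c("v0", "kobs", "kunc", "kass", "Km", "Vmax", "SI"))
  if (!is.finite(value)) stop("estimate value must be finite")
  if (!is.na(se) && se < 0) stop("standard error must be >= 0")
  structure(list(quantity = quantity, value = value, se = se, rss = rss,
                 n = n, extra = extra),
            class = "kinetic_estimate")
}

#' @export
print.kinetic_estimate <- function(x, ...) {
  unit <- switch(x$quantity,
                 v0 = "signal/s", kobs = "s^-1",
                 kunc = "M^-1 s^-1", kass = "M^-1 s^-1",
                 Km = "M", Vmax = "signal/s", SI = "mol/mol")
  se <- if (is.na(x$se)) "" else sprintf(" +/- %.3g", x$se)
  cat(sprintf("%s = %.6g%s %s  (n = %s)\n", x$quantity, x$value, se, unit,
              ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}
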