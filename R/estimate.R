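# Estimator chain: progress-curve fit -> k_unc slope -> k_ass correction,
# plus SI x-intercept, Lineweaver-Burk / direct Michaelis-Menten fits, and
# stability summarization.

#' Fit the hyperbolic progress-curve model
#'
#' Nonlinear least-squares fit of
#' `P(t) = v0/kobs (1 - exp(-kobs t))`
#' to a progress curve, returning the initial velocity `v0` and the
#' pseudo-first-order inactivation rate `kobs`.
#'
#' Initialization: `v0` from the OLS slope of the first 10% of points;
#' `kobs` from `ln 2` over the time at half-plateau when a plateau is
#' visible, otherwise from a logarithmic restart grid spanning
#' 1e-5 to 1 s^-1. A curve whose fitted `kobs` implies less than ~10%
#' curvature over the observation window (`kobs * t_max < 0.1`) is rejected
#' as effectively linear.
#'
#' @param curve A [progress_curve] (or data frame with `time_s`, `signal`).
#' @return A list of class `progress_fit` with elements `v0` and `kobs`
#'   (both [kinetic_estimate]), plus `rss` and `fitted`.
#' @export
fit_progress_curve <- function(curve) {
  d <- data.frame(t = curve$time_s, P = curve$signal)
  n <- nrow(d)
  if (n < 5L) stop("progress-curve fit needs at least 5 points")
  if (any(diff(d$t) <= 0)) stop("time points must be strictly increasing")

  k0 <- max(3L, ceiling(0.1 * n))
  v0_init <- unname(stats::coef(stats::lm(P ~ t, data = d[seq_len(k0), ]))[2L])
  if (!is.finite(v0_init) || v0_init <= 0)
    v0_init <- max(d$P) / max(d$t[n], 1)
  Pmax <- max(d$P)
  tail_flat <- Pmax > 0 &&
    (Pmax - d$P[n - 1L]) < 0.05 * Pmax  # plateau visible near the end
  kobs_starts <- if (tail_flat) {
    t_half <- d$t[which(d$P >= Pmax / 2)[1L]]
    log(2) / max(t_half, d$t[2L])
  } else numeric(0)
  kobs_starts <- unique(c(kobs_starts, 10^seq(-5, 0, length.out = 11)))

  best <- NULL
  for (k_start in kobs_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(P ~ v0 / kobs * (1 - exp(-kobs * t)), data = d,
                        start = list(v0 = v0_init, kobs = k_start),
                        lower = c(0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    if (rss <= max(1e-20, 1e-12 * sum(d$P^2))) break  # essentially exact
  }
  if (is.null(best))
    stop("progress-curve fit did not converge over the restart grid")
  co <- stats::coef(best$fit)
  if (co[["kobs"]] * d$t[n] < 0.1)
    stop("no curvature: fitted kobs (", signif(co[["kobs"]], 3),
         " s^-1) implies an effectively linear curve over the window")
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(v0 = NA_real_, kobs = NA_real_))
  structure(list(
    v0 = kinetic_estimate("v0", co[["v0"]], se = unname(se[["v0"]]),
                          rss = best$rss, n = n),
    kobs = kinetic_estimate("kobs", co[["kobs"]], se = unname(se[["kobs"]]),
                            rss = best$rss, n = n),
    rss = best$rss,
    fitted = stats::fitted(best$fit)
  ), class = "progress_fit")
}

#' Uncorrected second-order rate from the k_obs vs [I] line
#'
#' Ordinary least-squares slope of the pseudo-first-order rate `kobs`
#' against inhibitor concentration: `kunc = d(kobs)/d[I]`. The intercept is
#' retained as a diagnostic (it should be near zero).
#'
#' @param points Data frame with columns `inhibitor_M` and `kobs` (at least
#'   3 distinct inhibitor concentrations).
#' @return A [kinetic_estimate] for `kunc`; `extra$intercept` holds the
#'   fitted intercept.
#' @export
fit_kunc <- function(points) {
  if (!all(c("inhibitor_M", "kobs") %in% names(points)))
    stop("points must have columns inhibitor_M and kobs")
  if (nrow(points) < 3L) stop("need at least 3 (I, kobs) points")
  if (length(unique(points$inhibitor_M)) < 2L)
    stop("all inhibitor concentrations are identical")
  fit <- stats::lm(kobs ~ inhibitor_M, data = points)
  # exact (zero-residual) fits are routine on noise-free data; the
  # perfect-fit warning from summary.lm is expected there
  co <- suppressWarnings(summary(fit)$coefficients)
  kinetic_estimate("kunc", co["inhibitor_M", "Estimate"],
                   se = co["inhibitor_M", "Std. Error"],
                   rss = sum(stats::resid(fit)^2), n = nrow(points),
                   extra = list(intercept = co["(Intercept)", "Estimate"]))
}

#' Substrate-competition correction of k_unc
#'
#' Because the serpin and the chromogenic substrate compete for the enzyme,
#' the observed slope `kunc` underestimates the association constant; the
#' corrected second-order rate is
#' `kass = kunc * (1 + S/Km)`. The standard error scales by the same factor.
#'
#' @param kunc A [kinetic_estimate] for `kunc`, or a bare number.
#' @param S Substrate concentration during the assay (M), >= 0.
#' @param Km Michaelis constant of the substrate (M), > 0.
#' @return A [kinetic_estimate] for `kass`.
#' @export
correct_kass <- function(kunc, S, Km) {
  if (!is.finite(Km) || Km <= 0) stop("Km must be > 0")
  if (!is.finite(S) || S < 0) stop("S must be >= 0")
  if (is.numeric(kunc)) kunc <- kinetic_estimate("kunc", kunc)
  stopifnot(inherits(kunc, "kinetic_estimate"), kunc$quantity == "kunc")
  f <- 1 + S / Km
  kinetic_estimate("kass", kunc$value * f,
                   se = if (is.na(kunc$se)) NA_real_ else kunc$se * f,
                   rss = kunc$rss, n = kunc$n,
                   extra = c(kunc$extra,
                             list(kunc = kunc$value, S_M = S, Km_M = Km,
                                  correction_factor = f)))
}

#' Stoichiometry of inhibition from a titration line
#'
#' Fits an OLS line through residual activity versus inhibitor:enzyme molar
#' ratio and reports the x-intercept as the SI: the ratio at which the line
#' predicts complete inhibition. Points at the activity floor (below
#' `floor`, default 0.05) are excluded — the underlying relation is
#' piecewise linear with a floor at zero past the equivalence point, and the
#' linear extrapolation presumes the pre-floor segment. The intercept is fit
#' freely (not forced through activity 1 at ratio 0) and reported.
#'
#' @param titration A [titration_series] (or data frame with `ratio`,
#'   `residual_activity`).
#' @param floor Activity level below which points are excluded (default
#'   0.05).
#' @return A [kinetic_estimate] for `SI` with a delta-method standard error;
#'   `extra` holds slope, intercept and number of excluded points.
#' @export
estimate_si <- function(titration, floor = 0.05) {
  d <- data.frame(r = titration$ratio, a = titration$residual_activity)
  if (!any(d$r == 0))
    warning("titration has no ratio-0 point; the intercept is extrapolated")
  keep <- d$a >= floor
  if (sum(keep) == 0L) stop("all titration points are at the activity floor")
  d <- d[keep, ]
  if (nrow(d) < 3L)
    stop("need at least 3 titration points above the activity floor")
  fit <- stats::lm(a ~ r, data = d)
  b <- stats::coef(fit)
  if (b[["r"]] >= -1e-8)  # tolerance absorbs round-off on flat data
    stop("no inhibition detected: titration slope is non-negative")
  si <- -b[["(Intercept)"]] / b[["r"]]
  V <- suppressWarnings(stats::vcov(fit))
  g <- c(-1 / b[["r"]], b[["(Intercept)"]] / b[["r"]]^2)  # d(SI)/d(b0,b1)
  se <- sqrt(max(0, drop(t(g) %*% V %*% g)))
  kinetic_estimate("SI", si, se = se, rss = sum(stats::resid(fit)^2),
                   n = nrow(d),
                   extra = list(slope = unname(b[["r"]]),
                                intercept = unname(b[["(Intercept)"]]),
                                n_excluded = sum(!keep), floor = floor))
}

#' Michaelis constant and Vmax from initial rates
#'
#' Double-reciprocal (Lineweaver-Burk) estimation: unweighted OLS of `1/v`
#' on `1/S`, giving `Km = slope/intercept` and `Vmax = 1/intercept`. A
#' direct nonlinear Michaelis-Menten fit (`method = "direct"`) is provided
#' as a cross-check, since the reciprocal transform distorts noise.
#'
#' @param mm_table Data frame with columns `substrate_M` and `rate`, at
#'   least 3 points, all positive.
#' @param method `"lineweaver"` (default) or `"direct"`.
#' @return A list with elements `Km` and `Vmax` (both [kinetic_estimate]).
#' @export
fit_km <- function(mm_table, method = c("lineweaver", "direct")) {
  method <- match.arg(method)
  if (!all(c("substrate_M", "rate") %in% names(mm_table)))
    stop("mm_table must have columns substrate_M and rate")
  S <- mm_table$substrate_M; v <- mm_table$rate
  if (length(S) < 3L) stop("need at least 3 initial-rate points")
  if (any(S <= 0)) stop("all substrate concentrations must be > 0")
  if (any(v <= 0)) stop("all rates must be > 0 (non-saturating or ",
                        "degenerate data)")
  n <- length(S)
  if (method == "lineweaver") {
    d <- data.frame(x = 1 / S, y = 1 / v)
    fit <- stats::lm(y ~ x, data = d)
    b <- stats::coef(fit)
    if (b[["(Intercept)"]] <= 0)
      stop("non-positive 1/Vmax intercept: data do not saturate")
    Km <- b[["x"]] / b[["(Intercept)"]]
    Vmax <- 1 / b[["(Intercept)"]]
    V <- suppressWarnings(stats::vcov(fit))
    gK <- c(-b[["x"]] / b[["(Intercept)"]]^2, 1 / b[["(Intercept)"]])
    seK <- sqrt(max(0, drop(t(gK) %*% V %*% gK)))
    seV <- sqrt(V[1L, 1L]) / b[["(Intercept)"]]^2
    rss <- sum(stats::resid(fit)^2)
    list(Km = kinetic_estimate("Km", Km, se = seK, rss = rss, n = n),
         Vmax = kinetic_estimate("Vmax", Vmax, se = seV, rss = rss, n = n))
  } else {
    start <- list(Vmax = max(v) * 1.2,
                  Km = S[which.min(abs(v - max(v) / 2))])
    fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                             data = data.frame(S = S, v = v), start = start,
                             lower = c(1e-12, 1e-15))
    co <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(Vmax = NA_real_, Km = NA_real_))
    rss <- sum(stats::resid(fit)^2)
    list(Km = kinetic_estimate("Km", co[["Km"]], se = unname(se[["Km"]]),
                               rss = rss, n = n),
         Vmax = kinetic_estimate("Vmax", co[["Vmax"]],
                                 se = unname(se[["Vmax"]]), rss = rss, n = n))
  }
}

#' @rdname fit_km
#' @export
fit_km_lineweaver <- function(mm_table) fit_km(mm_table, "lineweaver")

#' End-to-end k_ass from a set of progress curves
#'
#' Chains the three estimator stages: fit every progress curve for `kobs`
#' ([fit_progress_curve]), regress `kobs` on inhibitor concentration
#' ([fit_kunc]), and apply the substrate-competition correction
#' ([correct_kass]).
#'
#' @param pset A [progress_set] with at least 3 curves at distinct
#'   inhibitor concentrations.
#' @param S Substrate concentration (M); defaults to the set's.
#' @param Km Michaelis constant (M); defaults to the set's.
#' @return A [kinetic_estimate] for `kass`; `extra$kobs_points` holds the
#'   per-curve fits and `extra$kunc` the intermediate slope.
#' @export
run_kass_pipeline <- function(pset, S = attr(pset, "substrate_M"),
                              Km = attr(pset, "Km_M")) {
  stopifnot(inherits(pset, "progress_set"))
  I <- vapply(pset, attr, numeric(1L), "inhibitor_M")
  if (length(unique(I)) < 3L)
    stop("insufficient concentrations: k_ass needs at least 3 curves at ",
         "distinct inhibitor concentrations")
  fits <- lapply(seq_along(pset), function(i)
    tryCatch(fit_progress_curve(pset[[i]]),
             error = function(e)
               stop("stage fit_progress_curve[", i, "] ([I] = ",
                    signif(I[i], 4), " M): ", conditionMessage(e),
                    call. = FALSE)))
  points <- data.frame(
    inhibitor_M = I,
    kobs = vapply(fits, function(f) f$kobs$value, numeric(1L)))
  kunc <- tryCatch(fit_kunc(points), error = function(e)
    stop("stage fit_kunc: ", conditionMessage(e), call. = FALSE))
  kass <- tryCatch(correct_kass(kunc, S = S, Km = Km), error = function(e)
    stop("stage correct_kass: ", conditionMessage(e), call. = FALSE))
  kass$extra$kobs_points <- points
  kass
}

#' Summarize a stability profile against a retention threshold
#'
#' Finds the maximal contiguous run of grid conditions whose residual
#' activity is at or above `threshold`, plus the minimum and maximum
#' retained activity. Activities are fractions of the uninhibited reaction
#' rate (no-serpin control = 100%).
#'
#' @param profile A `stability_profile` (or data frame with
#'   `condition_value`, `residual_activity`), sorted by condition value.
#' @param threshold Retention threshold as a fraction (default 0.90).
#' @return A list of class `stability_summary` with `range` (condition
#'   bounds of the longest qualifying run; `c(NA, NA)` if none),
#'   `n_in_range`, `min_retained`, `max_retained`, `threshold`.
#' @export
summarize_stability <- function(profile, threshold = 0.90) {
  if (nrow(profile) == 0L) stop("empty stability profile")
  x <- profile$condition_value; a <- profile$residual_activity
  if (any(diff(x) <= 0)) stop("profile must be sorted by condition value")
  ok <- a >= threshold
  rng <- c(NA_real_, NA_real_); len <- 0L
  r <- rle(ok); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    if (r$lengths[i] > len) {
      len <- r$lengths[i]
      rng <- c(x[starts[i]], x[ends[i]])
    }
  }
  structure(list(range = rng, n_in_range = len,
                 min_retained = min(a), max_retained = max(a),
                 threshold = threshold),
            class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  if (is.na(x$range[1L]))
    cat(sprintf("No conditions retain >= %.0f%% activity.\n",
                100 * x$threshold))
  else
    cat(sprintf(
      "Activity >= %.0f%% retained over %g-%g (%d grid points);\n",
      100 * x$threshold, x$range[1L], x$range[2L], x$n_in_range),
      sprintf("retained activity spans %.3f-%.3f.\n",
              x$min_retained, x$max_retained))
  invisible(x)
}
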