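# Seeded generators of synthetic assay datasets. Every generator embeds its
# ground truth in the object metadata so recovery tests need no bookkeeping.

#' Additive-normal noise model for generated assay signals
#'
#' Noise is additive normal on the measured signal, truncated at zero
#' (absorbance readings cannot be negative). `sd = 0` gives exact,
#' noise-free data. Identical seed and parameters yield bit-identical
#' datasets.
#'
#' @param sd Standard deviation, in signal units. Default 0 (no noise).
#' @param seed Integer RNG seed, or NULL to use the current RNG state.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 0, seed = NULL) {
  if (!is.finite(sd) || sd < 0) stop("noise sd must be finite and >= 0")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed) || seed < 0) stop("seed must be a non-negative integer")
  }
  structure(list(kind = "additive-normal", sd = sd, seed = seed),
            class = "noise_model")
}

seed_noise <- function(noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
}

apply_noise <- function(x, noise) {
  if (noise$sd == 0) return(x)
  pmax(x + stats::rnorm(length(x), 0, noise$sd), 0)
}

#' Generate a set of noisy progress curves
#'
#' Builds one hyperbolic progress curve per inhibitor concentration from the
#' closed form `P(t) = v0/kobs (1 - exp(-kobs t))` with
#' `kobs = kunc * [I]`, where `kunc` is either given directly or derived
#' from a mechanistic [rate_constants] object via [effective_observables()]
#' (`kunc = kass / (1 + S/Km)`). Noise is applied per point.
#'
#' If a curve has fewer than 4 time points before its plateau (t < 1/kobs) a
#' warning flag is recorded in the curve metadata: such a grid poorly
#' constrains `kobs`.
#'
#' @param I_list Inhibitor concentrations (M), non-empty, positive.
#' @param S Substrate concentration during the assay (M).
#' @param Km Michaelis constant of the substrate (M).
#' @param kunc Uncorrected second-order rate (M^-1 s^-1); give this or
#'   `rates`.
#' @param rates Optional [rate_constants]; used instead of `kunc`.
#' @param v0 Initial velocity, identical across curves (signal/s).
#' @param t_grid Time points (s), shared by all curves.
#' @param noise A [noise_model].
#' @return A [progress_set]; metadata records the generating truth.
#' @export
gen_progress_set <- function(I_list, S, Km, kunc = NULL, rates = NULL,
                             v0 = 2e-3, t_grid = seq(0, 600, by = 5),
                             noise = noise_model()) {
  if (length(I_list) == 0L || any(I_list <= 0))
    stop("I_list must be non-empty and positive")
  if (is.null(kunc) == is.null(rates))
    stop("supply exactly one of kunc or rates")
  if (!is.null(rates)) {
    obs <- effective_observables(rates, S = S, Km = Km)
    kunc <- obs$kass_true / obs$competition_factor
  }
  stopifnot(kunc > 0, v0 >= 0)
  seed_noise(noise)
  curves <- lapply(I_list, function(I) {
    kobs <- kunc * I
    sig <- apply_noise(closed_form_progress(v0, kobs, t_grid), noise)
    md <- list(kobs_true = kobs, v0_true = v0)
    if (sum(t_grid < 1 / kobs) < 4L)
      md$warning <- "t_grid has fewer than 4 points before the plateau"
    progress_curve(t_grid, sig, inhibitor_M = I, substrate_M = S,
                   metadata = md)
  })
  progress_set(curves, substrate_M = S, Km_M = Km,
               metadata = list(kunc_true = kunc, v0_true = v0,
                               noise_sd = noise$sd, seed = noise$seed))
}

#' Generate a noisy SI titration
#'
#' Residual activity follows the ideal suicide-inhibition titration line
#' `max(0, 1 - r/SI)`: linear decay hitting zero at the stoichiometry of
#' inhibition, with a floor at zero beyond it (as in real assays; exclusion
#' of floor points is the estimator's job, not the generator's).
#'
#' @param SI_true True stoichiometry of inhibition (> 0).
#' @param ratios Inhibitor:enzyme molar ratios; default 0 to 35 as in a
#'   typical titration layout.
#' @param noise A [noise_model].
#' @return A [titration_series]; metadata records `SI_true`.
#' @export
gen_titration <- function(SI_true, ratios = 0:35, noise = noise_model()) {
  if (!is.finite(SI_true) || SI_true <= 0) stop("SI_true must be > 0")
  if (length(ratios) == 0L) stop("ratios must be non-empty")
  seed_noise(noise)
  resid <- apply_noise(pmax(0, 1 - ratios / SI_true), noise)
  titration_series(ratios, resid,
                   metadata = list(SI_true = SI_true, noise_sd = noise$sd,
                                   seed = noise$seed, source = "closed-form"))
}

#' Generate a Michaelis-Menten initial-rate dataset
#'
#' @param Km Michaelis constant (M), > 0.
#' @param Vmax Maximal rate (signal/s), > 0.
#' @param S_grid Substrate concentrations (M), positive.
#' @param noise A [noise_model].
#' @return A data frame of class `mm_table` with columns `substrate_M`,
#'   `rate`; metadata records the truth.
#' @export
gen_mm_dataset <- function(Km, Vmax, S_grid, noise = noise_model()) {
  stopifnot(is.finite(Km), Km > 0, is.finite(Vmax), Vmax > 0,
            length(S_grid) >= 1L, all(S_grid > 0))
  seed_noise(noise)
  v <- apply_noise(Vmax * S_grid / (Km + S_grid), noise)
  structure(data.frame(substrate_M = S_grid, rate = v),
            class = c("mm_table", "data.frame"),
            metadata = list(Km_true = Km, Vmax_true = Vmax,
                            noise_sd = noise$sd, seed = noise$seed))
}

#' Piecewise stability-profile shape
#'
#' Residual inhibitory activity as a function of an incubation condition
#' (temperature or pH): a plateau at `plateau_level` inside `plateau_range`,
#' declining linearly on each side at `decline_left` / `decline_right`
#' (fraction per condition unit) down to `floor`.
#'
#' @param axis `"temperature"` (deg C) or `"pH"`.
#' @param axis_range Condition range covered by the shape.
#' @param plateau_range Condition range of the plateau; within `axis_range`.
#' @param plateau_level Activity fraction on the plateau, in \[0, 1.05\].
#' @param decline_left,decline_right Decline rates outside the plateau
#'   (fraction per unit).
#' @param floor Lower bound of the profile, in \[0, 1.05\].
#' @return An object of class `stability_shape`.
#' @export
stability_shape <- function(axis = c("temperature", "pH"), axis_range,
                            plateau_range, plateau_level,
                            decline_left = 0, decline_right = 0, floor = 0) {
  axis <- match.arg(axis)
  stopifnot(length(axis_range) == 2L, length(plateau_range) == 2L,
            axis_range[1L] <= plateau_range[1L],
            plateau_range[1L] <= plateau_range[2L],
            plateau_range[2L] <= axis_range[2L])
  lv <- c(plateau_level, floor)
  if (any(lv < 0) || any(lv > 1.05))
    stop("levels must lie in [0, 1.05]")
  if (decline_left < 0 || decline_right < 0)
    stop("decline rates must be >= 0")
  structure(list(axis = axis, axis_range = axis_range,
                 plateau_range = plateau_range,
                 plateau_level = plateau_level,
                 decline_left = decline_left, decline_right = decline_right,
                 floor = floor),
            class = "stability_shape")
}

#' Default temperature-stability shape
#'
#' Emulates a thermostable serpin: at least 90% activity retained after
#' incubation anywhere on 35-75 deg C (plateau level 0.95), rapid decline
#' outside, and 40% retained at 100 deg C.
#' @return A [stability_shape].
#' @export
stability_shape_temperature <- function() {
  stability_shape("temperature", axis_range = c(25, 100),
                  plateau_range = c(35, 75), plateau_level = 0.95,
                  decline_left = 0.02, decline_right = 0.022, floor = 0)
}

#' Default pH-stability shape
#'
#' Near-complete retention of activity across pH 3-10.
#' @return A [stability_shape].
#' @export
stability_shape_ph <- function() {
  stability_shape("pH", axis_range = c(3, 10), plateau_range = c(3, 10),
                  plateau_level = 1.0)
}

stability_level <- function(shape, x) {
  lo <- shape$plateau_range[1L]; hi <- shape$plateau_range[2L]
  y <- ifelse(x < lo, shape$plateau_level - shape$decline_left * (lo - x),
       ifelse(x > hi, shape$plateau_level - shape$decline_right * (x - hi),
              shape$plateau_level))
  pmax(y, shape$floor)
}

#' Generate a stability profile
#'
#' @param shape A [stability_shape].
#' @param grid Condition values; must lie within the shape's axis range.
#'   Default: every 5 deg C (temperature) or every pH unit.
#' @param noise A [noise_model].
#' @return A data frame of class `stability_profile` with columns
#'   `condition_type`, `condition_value`, `residual_activity`.
#' @export
gen_stability_profile <- function(shape, grid = NULL,
                                  noise = noise_model()) {
  stopifnot(inherits(shape, "stability_shape"))
  if (is.null(grid)) {
    grid <- if (shape$axis == "temperature")
      seq(shape$axis_range[1L], shape$axis_range[2L], by = 5)
    else seq(shape$axis_range[1L], shape$axis_range[2L], by = 1)
  }
  if (any(grid < shape$axis_range[1L]) || any(grid > shape$axis_range[2L]))
    stop("grid must lie within the shape's axis range")
  seed_noise(noise)
  act <- apply_noise(stability_level(shape, grid), noise)
  structure(data.frame(condition_type = shape$axis, condition_value = grid,
                       residual_activity = act),
            class = c("stability_profile", "data.frame"),
            metadata = list(shape = shape, noise_sd = noise$sd,
                            seed = noise$seed))
}
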