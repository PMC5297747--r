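#' Rate constants of the branched suicide-substrate mechanism
#'
#' Bundles the mechanistic rates of serpin inhibition. A serpin and its target
#' protease form an initial non-covalent complex (`k_on`, reversible via
#' `k_off`) which then partitions between two fates: the inhibitory branch to
#' an irreversible covalent complex (`k_i`) and the substrate branch releasing
#' cleaved serpin and free, active enzyme (`k_s`). Substrate turnover by the
#' free enzyme is described by `kcat` and `Km` of the chromogenic substrate.
#'
#' The partition ratio `k_s / k_i` sets the stoichiometry of inhibition
#' SI = 1 + k_s/k_i: the mean number of serpin molecules consumed per
#' protease inhibited.
#'
#' @param k_on Second-order association rate of the enzyme-serpin encounter
#'   (M^-1 s^-1).
#' @param k_off Dissociation rate of the initial non-covalent complex (s^-1).
#' @param k_i Branch rate to the irreversible covalent inhibited complex
#'   (s^-1). Must be positive, otherwise SI is undefined.
#' @param k_s Branch rate of the substrate pathway releasing cleaved serpin
#'   and free enzyme (s^-1).
#' @param kcat Turnover number of the chromogenic substrate (s^-1).
#' @param Km Michaelis constant of the chromogenic substrate (M). Required
#'   positive whenever `kcat > 0`.
#'
#' @return An object of class `rate_constants`.
#' @examples
#' rt <- rate_constants(k_on = 1e6, k_i = 0.1, k_s = 0.849,
#'                      kcat = 50, Km = 0.93e-3)
#' effective_observables(rt, S = 1e-3)$SI_true  # 9.49
#' @export
rate_constants <- function(k_on, k_off = 0, k_i, k_s = 0, kcat = 0,
                           Km = NA_real_) {
  vals <- c(k_on = k_on, k_off = k_off, k_i = k_i, k_s = k_s, kcat = kcat)
  if (any(!is.finite(vals)))
    stop("rate constants must be finite numbers, got: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (any(vals < 0))
    stop("rate constants must be non-negative, got negative: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  if (k_i <= 0)
    stop("k_i must be > 0 (k_i = 0 makes the stoichiometry of inhibition ",
         "undefined: no inhibitory branch)")
  if (kcat > 0 && (is.na(Km) || Km <= 0))
    stop("Km must be > 0 when kcat > 0")
  if (!is.na(Km) && Km <= 0)
    stop("Km must be > 0 when supplied")
  structure(list(k_on = k_on, k_off = k_off, k_i = k_i, k_s = k_s,
                 kcat = kcat, Km = Km),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Branched suicide-substrate rate constants:\n")
  cat(sprintf("  k_on  = %g M^-1 s^-1   k_off = %g s^-1\n", x$k_on, x$k_off))
  cat(sprintf("  k_i   = %g s^-1        k_s   = %g s^-1\n", x$k_i, x$k_s))
  cat(sprintf("  kcat  = %g s^-1        Km    = %g M\n", x$kcat, x$Km))
  obs <- effective_observables(x, S = 0)
  cat(sprintf("  => SI = %g, k_ass = %g M^-1 s^-1\n",
              obs$SI_true, obs$kass_true))
  invisible(x)
}

#' Assay conditions for a simulated serpin-protease experiment
#'
#' @param E0 Total enzyme concentration (M).
#' @param I0 Total serpin concentration (M).
#' @param S0 Total chromogenic-substrate concentration (M).
#' @param t_grid Time points (s); must start at 0 and be strictly increasing.
#' @param temperature_label Optional condition tag (deg C); not mechanistic.
#' @param pH_label Optional condition tag; not mechanistic.
#'
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(E0, I0, S0 = 0, t_grid,
                             temperature_label = NA, pH_label = NA) {
  conc <- c(E0 = E0, I0 = I0, S0 = S0)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("E0, I0, S0 must be finite and non-negative")
  if (length(t_grid) < 2L || t_grid[1L] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must start at 0 and be strictly increasing ",
         "(at least two points)")
  structure(list(E0 = E0, I0 = I0, S0 = S0, t_grid = as.numeric(t_grid),
                 temperature_label = temperature_label, pH_label = pH_label),
            class = "assay_conditions")
}

#' Observable kinetic quantities implied by a mechanism
#'
#' Closed forms linking the mechanistic rates to the quantities a titration or
#' progress-curve experiment measures:
#' \deqn{SI = 1 + k_s/k_i}
#' \deqn{k_{ass} = k_{on} k_i / (k_{off} + k_i + k_s)}
#' \deqn{k_{obs}(I) = k_{ass} \, I / (1 + S/K_m)}
#' `k_ass` is the partition-weighted net inactivation rate of standard
#' branched suicide-substrate theory; the `(1 + S/Km)` factor accounts for
#' competition by the chromogenic substrate at concentration `S`.
#'
#' @param rates A [rate_constants] object.
#' @param S Substrate concentration during the progress-curve assay (M).
#' @param Km Michaelis constant used for the competition factor (M); defaults
#'   to the one stored in `rates`.
#'
#' @return A list with `SI_true`, `kass_true`, and `kobs_at(I)`, a function of
#'   inhibitor concentration.
#' @export
effective_observables <- function(rates, S = 0, Km = rates$Km) {
  stopifnot(inherits(rates, "rate_constants"))
  if (!is.finite(S) || S < 0) stop("S must be finite and >= 0")
  if (rates$k_i <= 0) stop("SI undefined: k_i must be > 0")
  if (S > 0 && (is.na(Km) || Km <= 0))
    stop("Km must be > 0 to apply substrate competition with S > 0")
  comp <- if (S > 0) 1 + S / Km else 1
  SI_true <- 1 + rates$k_s / rates$k_i
  kass_true <- rates$k_on * rates$k_i /
    (rates$k_off + rates$k_i + rates$k_s)
  list(SI_true = SI_true,
       kass_true = kass_true,
       competition_factor = comp,
       kobs_at = function(I) kass_true * I / comp)
}
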