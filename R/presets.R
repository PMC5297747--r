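# Reference constants for a thermophilic archaeal serpin: stoichiometries of
# inhibition per protease and incubation temperature, chromogenic-substrate
# Michaelis constants, measured association constants, and protease masses.
# These seed the shipped generator presets so recovery runs are one call.

#' Reference SI values per protease and incubation temperature
#'
#' Stoichiometry of inhibition (mol serpin per mol protease) of the serpin for
#' each target protease across incubation temperatures; entries absent where
#' the assay was not measurable.
#'
#' @return Data frame with columns `enzyme`, `temperature_C`, `SI`.
#' @export
si_reference_table <- function() {
  long <- list(
    CHT      = c("20" = 9.49,  "30" = 5.80,  "40" = 4.76, "50" = 2.21),
    SUC      = c("20" = 10.04, "30" = 8.76,  "40" = 6.95, "50" = 5.34,
                 "60" = 3.97,  "70" = 2.67),
    elastase = c("20" = 10.06, "30" = 9.33,  "40" = 7.9,  "50" = 7.41,
                 "60" = 4.84,  "70" = 2.74),
    PRK      = c("20" = 9.99,  "30" = 7.39,  "40" = 5.99, "50" = 4.69,
                 "60" = 2.75,  "70" = 2.28),
    thrombin = c("20" = 21.13, "30" = 15.16, "40" = 12.22, "50" = 9.31),
    trypsin  = c("20" = 10.19, "30" = 6.14,  "40" = 5.16, "50" = 2.53),
    PnCHT    = c("20" = 32.72, "40" = 23.92, "60" = 19.83, "80" = 11.26,
                 "100" = 6.82))
  do.call(rbind, lapply(names(long), function(e)
    data.frame(enzyme = e,
               temperature_C = as.numeric(names(long[[e]])),
               SI = unname(long[[e]]))))
}

#' Reference Michaelis constants of the chromogenic substrates
#'
#' @return Data frame with columns `enzyme`, `temperature_C`, `Km_mM`.
#' @export
km_reference <- function() {
  data.frame(
    enzyme = c("CHT", "SUC", "elastase", "PRK", "PnCHT", "PnCHT"),
    temperature_C = c(40, 40, 40, 40, 40, 80),
    Km_mM = c(0.05, 0.93, 3.6, 0.26, 2.85, 0.82))
}

#' Reference second-order association constants k_ass
#'
#' @return Data frame with columns `enzyme`, `temperature_C`, `kass`
#'   (M^-1 s^-1).
#' @export
kass_reference <- function() {
  data.frame(
    enzyme = c("CHT", "SUC", "elastase", "PRK", "PnCHT", "PnCHT"),
    temperature_C = c(40, 40, 40, 40, 40, 80),
    kass = c(2.46e4, 1.30e5, 2.27e4, 1.98e5, 3.9e4, 1.07e5))
}

#' Reference protease masses (kD)
#'
#' Five masses are reported for the complex-mass arithmetic; four are named
#' (CHT, SUC, elastase, PRK) and the fifth, 36 kD, is assigned to PnCHT —
#' the only assignment consistent with its ~76 kD covalent complex.
#'
#' @return Named numeric vector of masses in kD.
#' @export
protease_masses <- function() {
  c(CHT = 25, SUC = 27, elastase = 24, PRK = 28, PnCHT = 36)
}

#' List the shipped generator presets
#'
#' Preset names follow `si-<enzyme>-<temperature>` (titrations, e.g.
#' `si-cht-20`), `km-<enzyme>[-<temperature>]` (initial-rate sets, e.g.
#' `km-suc`, `km-pncht-80`), `kass-<enzyme>[-<temperature>]` (progress-curve
#' sets), and `stability-temperature` / `stability-ph`.
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  si <- si_reference_table()
  km <- km_reference()
  ka <- kass_reference()
  tag <- function(e, t, default40 = TRUE)
    ifelse(default40 & t == 40, tolower(e), paste0(tolower(e), "-", t))
  c(sprintf("si-%s-%g", tolower(si$enzyme), si$temperature_C),
    paste0("km-", tag(km$enzyme, km$temperature_C)),
    paste0("kass-", tag(ka$enzyme, ka$temperature_C)),
    "stability-temperature", "stability-ph")
}

# default assay layouts shared by presets
PRESET_S_M <- 1e-3                      # 1 mM chromogenic substrate
PRESET_I_M <- c(1, 2, 3, 4, 5) * 1e-7   # 100-500 nM serpin
PRESET_RATIOS <- 0:35

lookup_row <- function(tab, enzyme, temperature) {
  rows <- tab[tolower(tab$enzyme) == tolower(enzyme), , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  if (is.na(temperature)) {
    if (nrow(rows) > 1L) rows <- rows[rows$temperature_C == 40, , drop = FALSE]
  } else {
    rows <- rows[rows$temperature_C == temperature, , drop = FALSE]
  }
  if (nrow(rows) == 1L) rows else NULL
}

#' Generate a dataset from a shipped preset
#'
#' Builds the synthetic dataset matching a reference condition: titrations
#' with the tabulated SI, initial-rate sets with the tabulated Km,
#' progress-curve sets whose `kunc` is derived from the tabulated `kass`
#' and Km at 1 mM substrate (`kunc = kass / (1 + S/Km)`), or the default
#' stability shapes.
#'
#' @param name Preset name; see [list_presets()].
#' @param noise A [noise_model]; default noise-free.
#' @return The generated dataset (type depends on the preset family).
#' @export
preset_dataset <- function(name, noise = noise_model()) {
  parts <- strsplit(tolower(name), "-")[[1L]]
  family <- parts[1L]
  if (family == "stability") {
    shape <- switch(parts[2L],
                    temperature = stability_shape_temperature(),
                    ph = stability_shape_ph(),
                    stop("unknown stability preset: ", name))
    return(gen_stability_profile(shape, noise = noise))
  }
  enzyme <- parts[2L]
  temperature <- if (length(parts) >= 3L) as.numeric(parts[3L]) else NA
  if (family == "si") {
    row <- lookup_row(si_reference_table(), enzyme, temperature)
    if (is.null(row)) stop("no SI reference entry for preset: ", name)
    ratios <- PRESET_RATIOS[PRESET_RATIOS <= ceiling(2 * row$SI)]
    return(gen_titration(row$SI, ratios = ratios, noise = noise))
  }
  if (family == "km") {
    row <- lookup_row(km_reference(), enzyme, temperature)
    if (is.null(row)) stop("no Km reference entry for preset: ", name)
    Km_M <- row$Km_mM * 1e-3
    S_grid <- Km_M * c(0.2, 0.5, 1, 2, 5, 10, 20)
    return(gen_mm_dataset(Km_M, Vmax = 1, S_grid = S_grid, noise = noise))
  }
  if (family == "kass") {
    row <- lookup_row(kass_reference(), enzyme, temperature)
    if (is.null(row)) stop("no kass reference entry for preset: ", name)
    Km_M <- lookup_row(km_reference(), enzyme,
                       if (is.na(temperature)) 40 else temperature)$Km_mM * 1e-3
    kunc <- row$kass / (1 + PRESET_S_M / Km_M)
    return(gen_progress_set(PRESET_I_M, S = PRESET_S_M, Km = Km_M,
                            kunc = kunc, noise = noise))
  }
  stop("unknown preset: ", name)
}
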