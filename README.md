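# serpkin

Kinetic characterization of serpins — serine protease inhibitors that work
by a *suicide-substrate* mechanism: the protease attacks the serpin's
reactive center loop and the acyl-enzyme intermediate partitions between an
irreversible covalent complex (rate `k_i`) and ordinary turnover that
releases active protease and spent, cleaved serpin (rate `k_s`):

```
E + I  <->  EI  --k_i-->  E_inh        (dead-end covalent complex)
             |---k_s-->  E + I_clv     (serpin consumed as a substrate)
```

Two quantities summarize how good an inhibitor a serpin is:

* **SI**, the stoichiometry of inhibition, SI = 1 + k_s/k_i — mol serpin
  consumed per mol protease inhibited, measured as the x-intercept of a
  residual-activity vs molar-ratio titration line;
* **k_ass** = k_on·k_i/(k_off+k_i+k_s) — the second-order association
  constant, measured from hyperbolic progress curves
  P(t) = v0/k_obs·(1 − e^(−k_obs·t)), the slope k_unc = Δk_obs/Δ[I], and
  the substrate-competition correction k_ass = k_unc·(1 + [S]/K_m).

The package is aimed at enzymologists characterizing (thermophilic)
serpin–protease pairs and at anyone validating progress-curve analysis
code. It provides:

* a mass-action ODE forward model of the branched mechanism with
  chromogenic-substrate competition (`simulate_timecourse()`,
  `simulate_titration()`);
* seeded generators of synthetic assay data — progress-curve sets, SI
  titrations, Michaelis–Menten initial-rate sets, temperature/pH stability
  profiles — each embedding its ground truth (`gen_*()`, `preset_dataset()`);
* the estimator chain (`fit_progress_curve()`, `fit_kunc()`,
  `correct_kass()`, `run_kass_pipeline()`, `estimate_si()`, `fit_km()`,
  `summarize_stability()`);
* serpin sequence annotation: hinge-motif scan (`find_hinge_motif()`),
  P1/P1′ transfer through an alignment (`transfer_p1()`), covalent-complex
  mass prediction (`cleaved_moiety_mass()`, `predict_complex_mass()`);
* CSV IO with metadata headers and a CLI (`cli_dispatch()`,
  `inst/cli/serpkin.R`).

## Worked example

```r
library(serpkin)

# a mechanism whose partition ratio k_s/k_i = 8.49 implies SI = 9.49
rt <- rate_constants(k_on = 1e6, k_off = 0, k_i = 0.1, k_s = 0.849)
rt
#> Branched suicide-substrate rate constants:
#>   k_on  = 1e+06 M^-1 s^-1   k_off = 0 s^-1
#>   k_i   = 0.1 s^-1        k_s   = 0.849 s^-1
#>   kcat  = 0 s^-1        Km    = NA M
#>   => SI = 9.49, k_ass = 105374 M^-1 s^-1

# titrate 50 nM protease against serpin at molar ratios 0..8, then read
# the SI off the x-intercept of the residual-activity line
titr <- simulate_titration(rt, E0 = 50e-9, ratios = 0:8)
estimate_si(titr)
#> SI = 9.49001 +/- 3e-08 mol/mol  (n = 9)

# five noisy progress curves at 100-500 nM serpin, 1 mM substrate
# (Km = 0.93 mM), generated with k_unc = 6.2642e4 M^-1 s^-1, then the
# full pipeline: per-curve k_obs -> k_unc slope -> (1 + S/Km) correction
ps <- gen_progress_set(I_list = c(1, 2, 3, 4, 5) * 1e-7, S = 1e-3,
                       Km = 0.93e-3, kunc = 6.2642e4,
                       noise = noise_model(0.005, seed = 1))
run_kass_pipeline(ps)
#> kass = 130622 +/- 1.39e+03 M^-1 s^-1  (n = 5)

# thermal-stability profile and the range retaining >= 90% activity
prof <- gen_stability_profile(stability_shape_temperature())
summarize_stability(prof, 0.90)
#> Activity >= 90% retained over 35-75 (9 grid points);
#>  retained activity spans 0.400-0.950.
```

The SI estimate inverts the titration exactly (the ideal line is
max(0, 1 − r/SI)); the noisy k_ass lands within ~0.5% of the generating
truth of 1.30×10⁵ M⁻¹·s⁻¹; the stability summary reports the plateau of
the default temperature shape.

From a shell:

```sh
Rscript inst/cli/serpkin.R gen --preset si-cht-20 --seed 7 --out titr.csv
Rscript inst/cli/serpkin.R fit-si --in titr.csv --out si.csv
```

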