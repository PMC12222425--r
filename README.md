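# rptparpi

Mechanistic simulation of combined radiopharmaceutical therapy (RPT) and
PARP-inhibitor (PARPi) treatment of cancer cells in vitro, with
homologous-recombination deficiency (HRD), calibration to
survival-versus-activity data, and translational extrapolation (external
beam comparison, tumor growth-curve inversion, concentration-effect
forecasts for clinical dosing).

It is written for radiopharmaceutical dosimetry and radiobiology
modelers: people who want to ask *what happens to survival if the
exposure window, the drug, the HR status or the activity changes* before
running the next plate or designing the next protocol.

## The model

Three coupled layers are integrated as one stiff ODE system per
cell-cycle starting point:

1. **Compartment kinetics + MIRD cellular dosimetry.** Ligand moves
   between medium, cell surface and cytoplasm of living and dead cells
   (association `k_on`, dissociation `k_off`, internalization `k_int`,
   release `k_rel`; cell death transfers bound ligand to the dead-cell
   compartments). The absorbed dose rate to living-cell nuclei is

   ```
   dD/dt = A(t) [ S_m Σc + S_cs c_acs + S_cy c_acy ] / (Σc · N_alive),
   A(t) = A0 exp(-mu_dec t)
   ```

   with cellular S-values (Gy/decay) for the medium (crossfire),
   cell-surface and cytoplasm source regions. A washout event at the end
   of exposure removes medium activity and dead cells and rebases `A`.

2. **Phase-resolved DNA damage.** SSBs and fast/slow/MMEJ DSB pools with
   induction yields `k_ssb`, `k_dsb` per Gy per genome and first-order
   repair. Complex breaks (probability `p_c`) need HR; failed HR
   (probability `1 - p_HR`, G2/M and replicated DNA) falls back to very
   slow MMEJ. During S phase, lesions on unreplicated DNA are converted
   (SSB → DSB) or duplicated (DSB) by the replication fork — the channel
   through which PARP trapping (slowed SSB repair) radiosensitizes.

3. **Survival.** Death rate
   `mu_dea = 1 − mu_loss · mu_apop · mu_mitot · mu_PARPi` combines a
   quadratic genomic-loss factor in the DSB burden, dose-rate-driven
   apoptosis, mitotic catastrophe capped at the G2/M checkpoint
   (`N_dsb ≤ 20`), and a constant drug term;
   `dN_alive/dt = (mu_gr − mu_dea) N_alive`.

Ensembles of 24 evenly spaced cell-cycle starting points (phase ratio
G1:S:G2:M = 11:8:4:1) are averaged; endpoint relative survival is
reported against an untreated control. Calibration (`fit_kinetics`,
`fit_parpi`) is bounded Levenberg–Marquardt on log survival with
Latin-hypercube multi-start. See the methods vignette
(`vignettes/rptparpi-methods.Rmd`) for assumptions, parameters and
numerical choices.

## Worked example

```r
library(rptparpi)

cfg <- load_config(system.file("extdata", "synthetic_h69_mono.yaml",
                               package = "rptparpi"))
ens <- ensemble_simulate(cfg$protocol, cfg$model)
ens
#> <rpt_ensemble>
#>   endpoint: 72.0 h, mean nucleus dose 7.38 Gy
#>   endpoint relative survival: 0.0006346
```

At 100 kBq of the packaged synthetic Lu-177 scenario, the mean nucleus
dose over 72 h is 7.38 Gy and the surviving cell number is 0.063 % of
untreated wells. Sweeping the activity shows receptor saturation:

```r
for (A in c(1e3, 1e4, 1e5)) {
  p <- cfg$protocol; p$A0 <- A
  e <- ensemble_simulate(p, cfg$model)
  cat(sprintf("A0 = %6.0f Bq   dose = %5.2f Gy   survival = %.4g\n",
              A, e$endpoint_dose, e$endpoint_rel_survival))
}
#> A0 =   1000 Bq   dose =  0.43 Gy   survival = 0.4742
#> A0 =  10000 Bq   dose =  3.22 Gy   survival = 0.009191
#> A0 = 100000 Bq   dose =  7.38 Gy   survival = 0.0006346
```

Dose per added activity falls as the free receptors run out, and the
survival curve flattens accordingly. The packaged configurations use
clearly marked synthetic placeholder parameters at literature-typical
magnitudes; calibrated use starts from your own survival data:

```r
dat <- read.csv("survival.csv")   # activity_Bq, condition, survival, sem
fit <- fit_kinetics(dat, cfg$model, cfg$protocol)
fit$par                           # k_on, k_off, k_int, k_rel
```

A thin command-line front end (`inst/cli/rpt-parpi`) exposes
`simulate`, `fit-kinetics`, `fit-parpi`, `make-synthetic`,
`compare-ebrt`, `dose-curve`, `stability`, `invivo` and `predict`
subcommands over the same functions.

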