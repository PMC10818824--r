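# fluorquench

Analysis of steady-state fluorescence quenching titrations of a protein
fluorophore — typically human serum albumin (HSA), whose single tryptophan
dominates its intrinsic emission — by small-molecule ligands such as per- and
polyfluoroalkyl substances (PFAS). The package is for spectroscopists and
environmental-toxicology groups who titrate a ligand against a protein,
record emission intensities (or full scans, or 3-D excitation–emission
matrices), and want binding constants, stoichiometries and a quenching
mechanism call out the other end, reproducibly.

## The models at the core

With `F0` the intensity at zero ligand and `F` the intensity at ligand
concentration `C` (mol/L):

**Modified Stern–Volmer** — for a fraction `fa` of accessible fluorophores,

```
F0/(F0 − F) = 1/(Ksv′ · fa) · 1/C + 1/fa
```

fitted by OLS on `1/C`; the intercept gives `fa`, intercept/slope gives the
quenching constant `Ksv′` (L/mol), and `Kq = Ksv′/τ0` with `τ0 = 1e-8 s` by
default. `Kq` above the diffusion limit `2.0e10 L mol⁻¹ s⁻¹` classifies the
mechanism as **static** (ground-state complex), otherwise
`dynamic_consistent`.

**Double-logarithmic (Lineweaver–Burk style) isotherm** — for `n`
equivalent sites,

```
lg((F0 − F)/F) = lg KA + n · lg C
```

fitted by OLS on `lg C`; the slope is the apparent site number `n`, and
`KA = 10^intercept` (nominal L/mol) is the binding constant.

Around the fits: EEM reading/writing and peak picking with Rayleigh-ridge
masking, emission-maximum blue-shift tracking, seeded synthetic-data
generators for titrations, scans and EEMs, and a cross-compound comparison
pipeline with optional rank concordance against an externally computed
docking table. Everything takes and returns tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

The package ships the published fitted-line coefficients for ten PFAS–HSA
titrations (`reference_quenching_fits()`, `reference_binding_fits()`). Raw
instrument data for those titrations were never deposited, but
`series_from_sv_line()` / `series_from_lb_line()` rebuild noiseless
titrations that lie exactly on a printed line, so re-fitting them re-derives
the published constants:

```r
library(fluorquench)

ser <- series_from_lb_line(0.8694, 2.5962, ligand_id = "PFOS")
fit_lineweaver_burk(ser)
#> <lb_fit> PFOS
#>   y = 0.8694 x + 2.5962   (R^2 = 1.0000, n = 6, dropped = 0)
#>   KA = 394.6390 L/mol | n = 0.8694 binding sites

sv <- fit_modified_stern_volmer(series_from_sv_line(0.0007969, 0.2456,
                                                    ligand_id = "PFOS"))
sv
#> <sv_fit> PFOS
#>   y = 0.0007969 x + 0.2456   (R^2 = 1.0000, n = 6, dropped = 0)
#>   fa = 4.072 | Ksv' = 308.2 L/mol | Kq = 3.08e+10 L/(mol s) [tau0 = 1e-08 s]
```

`KA = 394.64 L/mol` says PFOS binds HSA with the strongest affinity of the
ten compounds; `n ≈ 0.87` is consistent with 1:1 binding; `Kq = 3.08e10`
exceeds the diffusion limit, so the quenching is static — a bound complex,
not collisions. Doing this for all ten compounds and comparing:

```r
rows <- purrr::map_dfr(seq_len(10), function(i) {
  q <- reference_quenching_fits()[i, ]; b <- reference_binding_fits()[i, ]
  m <- pfas_compounds()[pfas_compounds()$ligand_id == q$ligand_id, ]
  svf <- suppressWarnings(fit_modified_stern_volmer(
    series_from_sv_line(q$slope, q$intercept, ligand_id = q$ligand_id)))
  lbf <- fit_lineweaver_burk(
    series_from_lb_line(b$n_sites, b$lg_ka, ligand_id = b$ligand_id))
  dplyr::bind_cols(glance(svf)[, c("ligand_id", "kq", "mechanism")],
                   glance(lbf)[, c("ka", "n_sites")],
                   m[, c("family", "chain_class")])
})
rep <- merge_docking(
  compare_compounds(rows, expected_orderings = "PFOS > PFHxS > PFOA"),
  reference_docking()
)
rep
#> <comparison_report> 10 compounds
#> # A tibble: 10 × 6
#>    rank_ka ligand_id       ka n_sites            kq mechanism
#>      <int> <chr>        <dbl>   <dbl>         <dbl> <chr>
#>  1       1 PFOS         395.    0.869  30819425273. static
#>  2       2 PFHxS        158.    0.733  84045382024. static
#>  3       3 11Cl-PF3OUdS 128.    0.710 114815515610. static
#>  4       4 9Cl-PF3ONS   117.    0.724 108305292138. static
#>  5       5 PFBS         116.    0.699 112877792378. static
#>  6       6 PFOA         103.    0.681 126117179742. static
#>  7       7 NaDONA        93.1   0.672 131750683861. static
#>  8       8 PFPrS         79.5   0.649 146561396219. static
#>  9       9 HFPO-DA       59.0   0.621 158017664377. static
#> 10      10 PFBA          20.4   0.469 302210781345. static
#> assertions passed: 1/1
#> KA vs docking affinity Spearman concordance: 0.809
```

All ten compounds quench statically; sulfonates outrank carboxylates
(`rep$group_means$family` puts PFSA at mean lg KA 2.19 vs PFCA at 1.66);
and the fluorescence-derived affinity ranking agrees with the docking
energies at Spearman ρ = 0.81.

Synthetic data for testing any stage, seeded and deterministic:

```r
cfg <- titration_sim_config(model = "lineweaver_burk", f0 = 1000,
                            ka = 150, n_sites = 0.7,
                            noise_sigma = 0.01, seed = 42)
glance(fit_lineweaver_burk(simulate_titration_lb(cfg)))

eem <- simulate_eem(hsa_eem_config(seed = 1))
detect_fluorescence_peaks(eem)   # the two protein peaks
locate_rayleigh_ridge(eem)       # the scatter ridge
```

See `vignettes/quenching-analysis.Rmd` for the full model account, the
generator design, and the numerical conventions.

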