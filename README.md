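# immunokin

Quantitative machinery for functionally comparing transplantable syngeneic
tumor models (e.g. the B16F0 and YUMM1.7 melanoma lines) across
immunocompetent (C57BL/6) and severely immunodeficient (NSG) hosts.

For tumor immunologists and biostatisticians, the package answers three
questions that recur in such comparisons:

1. **How fast does each model grow, and how hard does host immunity push
   back?** Longitudinal caliper volumes are fitted to the exponential
   growth model *V(t) = C\_T0 · e^(kt)* on the log scale by multi-chain
   random-walk Metropolis MCMC, with a cohort-shared net rate *k*, one
   initial bolus size *C\_T0* per mouse, and a shared log-scale noise sd.
   In NSG hosts *k = k\_P* (intrinsic proliferation); in C57BL/6 hosts
   *k = k\_P − k\_D*, where *k\_D* absorbs all immune-mediated killing.
   Immune selective pressure is the posterior of the natural-log ratio
   **ln(k\_NSG / k\_C57)** — zero means no detectable pressure.
2. **How sensitive is each line to a drug?** Viability plates are fitted
   to the two-parameter dose-response model
   **viability = 100·(1 − x/(x + IC50))** by least squares over log IC50,
   with a grid-search cross-check and unit equivariance.
3. **Which secreted factors differ between the two lines?** Duplicate-spot
   antibody arrays from the two conditions are compared on raw intensity:
   an abundance-dependent null envelope *h(x) = a·x^b* (twice the local
   null SD) is fitted from on-array positive/negative controls, and each
   analyte's difference becomes a z-score **z = 2·d / h(x)**; |z| ≥ 3 is
   called significant.

Seeded synthetic-data generators emulate each input's statistical
structure (exponential growth with lognormal noise and humane-endpoint
truncation, hyperbolic dose-response with replicate noise, heteroscedastic
duplicate-spot arrays), so the entire pipeline is testable without animal
data. See the methods vignette (`vignettes/immunokin-methods.Rmd`) for
models, priors, and design choices.

## Worked example

```r
library(immunokin)

## paired cohorts: NSG at k_P = 0.65/day, C57 at k_P·exp(-0.195)
cohorts <- simulate_paired_cohorts(
  k_p = 0.65, k_d = 0.65 * (1 - exp(-0.195)),
  growth_sim_config(n_mice = 5, initial_volume_median = 0.3,
                    cell_line = "B16F0", seed = 101))
fit_nsg <- fit_cohort(cohorts$nsg, mcmc_config(n_steps = 10000, thin = 5, seed = 11))
fit_c57 <- fit_cohort(cohorts$c57, mcmc_config(n_steps = 10000, thin = 5, seed = 12))
fit_nsg
#> Cohort growth-model posterior (5 mice, 3000 retained draws, converged)
#>   k = 0.657 day^-1 [0.637, 0.678] (median, 95% CrI)
#>   sigma = 0.152 [0.114, 0.216]

log_ratio(fit_nsg, fit_c57, seed = 21)
#> Immune pressure ln(k_NSG/k_C57): 0.198 [0.155, 0.245] (median, 95% CrI; n = 3000 draws)

immune_death_rate(fit_nsg, fit_c57, seed = 21)$median
#> 0.118   # k_D, per day

## dose-response: PLX-4720-like plate, 4 replicates, 5% noise
plate <- simulate_viability_plate(plate_sim_config(
  true_ic50 = 1.734, concentrations = c(0, 0.375, 0.75, 1.5, 3, 6, 12),
  n_replicates = 4, noise_sd = 5, drug = "PLX-4720",
  cell_line = "YUMM1.7", concentration_unit = "uM", seed = 301))
fit_ic50(plate)
#> IC50 = 1.762 uM (residual sd 4.93%, n = 28)

## secretome: two arrays with two injected differential factors
spots <- simulate_cytokine_arrays(array_sim_config(
  seed = 1, differential_probes = c(analyte_005 = 10, analyte_010 = 0.1)))
res <- analyze_arrays(spots)
res$envelope
#> Null envelope half-width (2 SD): 0.1115 * abundance^1.071 (6 bins)
res$hits
#>         probe mean_abundance difference         z   direction
#> 1 analyte_010       192.3726   312.1557  20.02465 higher_in_A
#> 2 analyte_005      3968.4670 -6427.2997 -16.11795 higher_in_B
```

Reading the output: the NSG posterior recovers the generating rate
(median 0.657 vs the true 0.65/day), the immune-pressure log-ratio
recovers 0.198 vs the generating 0.195, and the fitted IC50 (1.762 μM) is
within the replicate noise of the generating 1.734 μM. On the arrays,
both injected factors are flagged far beyond the |z| ≥ 3 threshold with
the correct direction, and nothing else is.

`run_demo(seed, out_dir)` chains all stages and writes every table
(growth CSVs, posterior summaries, chains, plate CSV, array TSV, scored
secretome table, envelope bins) plus a plain-text summary; outputs are
byte-identical for the same seed. Example input files for each schema are
in `inst/extdata/`, and `read_growth_table()` / `read_plate_table()` /
`read_array_table()` validate them strictly.

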