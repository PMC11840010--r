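# glacierSIP

Single-cell and bulk stable-isotope-probing (SIP) analysis for glacier ice
algae and similar microbial systems.

Dark-pigmented glacier ice algae (*Ancylonema* spp.) bloom on bare glacial
ice, lower its albedo, and accelerate melt. Whether nutrients limit those
blooms is measured by incubating melted surface ice with ¹³C-bicarbonate
and ¹⁵N-ammonium/nitrate tracers and tracking the label into bulk
particulate organic matter (EA-IRMS) and into individual cells (HR-SIMS
ion imaging). `glacierSIP` implements the complete computation from those
measurements to rates and community-level estimates, for anyone running
dual-isotope SIP incubations with single-cell imaging.

At its core are the isotope mass-balance equations. With *E* denoting atom%
excess (atom% above the natural-abundance baseline):

```
assimilation  = (E_POM / E_pool) · [POM] / Δt        (µmol L⁻¹ day⁻¹)
growth rate µ = log₂[ E_pool / (E_pool − E_POM) ] / Δt   (day⁻¹)
doubling time = 1 / µ                                 (days)
contribution  = 100 · rate_cell · N_cell / rate_bulk  (%)
```

applied identically to bulk POM and to single cells (with the cell's
elemental content, derived from cylinder biovolume → dry weight → C/N/P
quota, in place of [POM]). Contribution uncertainty is propagated
first-order: relative SDs of the three factors combine in quadrature.

The package covers:

* **Isotope bookkeeping** — atom%, atom% excess, tracer-pool mixing and
  dilution, pool time-averaging, activity classification (baseline mean +
  3 SD).
* **Bulk rates** — assimilation (volumetric and biomass-normalised),
  growth, doubling times, POC:PON, DON/DOP by difference, LOD/LOQ.
* **Single cells** — ROI quantification from ion-count rasters (TIFF I/O),
  geometry → composition, per-cell fixation/growth, C:N assimilation
  ratios, SEM-EDS C:N:P stoichiometry against Redfield references.
* **Community scaling** — active abundance, contribution with quadrature
  error propagation, POC-corrected abundance variant.
* **Statistics** — Kruskal–Wallis with Holm-adjusted pairwise rank tests
  and compact letter displays.
* **A synthetic-experiment generator** — lognormal growth heterogeneity
  with an inactive subpopulation, depleting tracer pools, Poisson
  ion-count images with label masks, bulk POM with a non-algal background,
  and full ground truth for validation.

## Worked example

Scale a published single-cell rate to the community and propagate its
uncertainty:

```r
library(glacierSIP)

ab  <- active_abundance(16.2e3, 1.2e3, active_fraction = 0.90)
pct <- contribution(4.6, ab$mean, 448)          # pmol C cell⁻¹ d⁻¹, cells L⁻¹, µmol C L⁻¹ d⁻¹
sd  <- propagate_contribution_uncertainty(pct, c(4.6, 16.2e3, 448),
                                          c(3.46, 1.2e3, 101))
round(c(percent = pct, sd = sd))
#> percent      sd
#>      15      12
```

Active glacier ice algae account for ~15 ± 12% of bulk DIC uptake: the
algae fix C vigorously per cell, but most of the label recovered on bulk
filters sits in other material — consistent with rapid transfer of fresh
photosynthate into the wider community.

Or run the full pipeline on a synthetic experiment with known truth:

```r
res <- run_pipeline(run_config(seed = 4, sim = sim_config(seed = 4)))
res$contribution[1, c("treatment", "timepoint", "substrate", "percent", "sd_percent")]
```

The `analysis/` directory holds the same workflow as numbered narrative
scripts, run from the repository root after installing:

```sh
Rscript analysis/01_simulate.R            # synthetic experiment + ground truth
Rscript analysis/02_bulk_rates.R          # bulk EA-IRMS rates
Rscript analysis/03_cell_rates.R          # single-cell rates and activity
Rscript analysis/04_stoichiometry.R       # SEM-EDS C:N:P
Rscript analysis/05_contribution.R        # community contribution vs truth
Rscript analysis/06_treatment_comparison.R
```

Stage 3, for example, reports:

```
23 of 244 cells inactive (9%; threshold 1.158 atom% 13C)
active control cells: C fixation 14.0 (T1) / 11.1 (T2) pmol C cell-1 d-1
active control growth 0.50 +/- 0.32 day-1 at T2
```

— the classifier recovers the planted 10% inactive fraction, and the
recovered growth (0.50 day⁻¹) brackets the planted population mean
(0.47 day⁻¹). All tables land under `results/`.

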