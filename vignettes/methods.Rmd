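---
title: "Isotope mass-balance methods for single-cell and bulk rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope mass-balance methods for single-cell and bulk rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glacierSIP)
```

## The measurement problem

Glacier ice algae (*Ancylonema* spp.) dominate primary production on bare
glacial ice, and their blooms darken and melt the ice surface. To ask
whether nutrient availability limits their growth, one incubates melted
surface ice with a ${}^{13}$C-bicarbonate tracer (all bottles) and
${}^{15}$N-labelled ammonium or nitrate (amended bottles), and measures how
much heavy isotope ends up (a) in bulk particulate organic matter on a
filter (EA-IRMS) and (b) in individual algal cells imaged by high-resolution
secondary ion mass spectrometry (HR-SIMS). This package implements the full
chain from those raw measurements to assimilation rates, growth rates,
doubling times, cellular C:N:P stoichiometry, and the error-propagated
contribution of the algae to community uptake — together with a synthetic
experiment generator so the whole chain can be validated against known
ground truth.

## Isotope bookkeeping

All isotope amounts are carried as **atom%**, $100\,h/(h+l)$ for heavy and
light isotope abundances, on the 0–100 scale everywhere in the package;
fractions (0–1) appear only at the SIMS I/O boundary (`roi_quantify()`
returns fractions because ion-ratio images are conventionally expressed that
way, and `cell_rate_table()` converts on entry). **Atom% excess** is atom%
minus the natural-abundance baseline; it is the tracer signal. Negative
excess values (measurements below baseline) are preserved with a warning
rather than clipped — clipping would bias population means of weakly
labelled populations upward.

The baselines default to values measured on unlabelled cells:
$0.0111 \pm 0.00016$ for ${}^{13}$C and $0.0037 \pm 0.00006$ for ${}^{15}$N
(fractions; $n = 29$ cells), overridable per element because different
instruments measure slightly different baselines.

Tracer additions dilute into the ambient pool
(`tracer_pool_mixing()`): the mixed atom% is the concentration-weighted mean
of tracer purity and ambient atom%. For the N pools this arithmetic defines
the starting pool label (10 µM at 98 atom% into sub-µM ambient pools gives
~97 atom% excess). For DIC the package expects the pool label to be
*measured* (GC-IRMS), not computed by mixing: melting ice equilibrates with
a large and variable DIC reservoir, so mixing arithmetic over- or
under-states the realised label. The synthetic generator follows the same
logic (see below).

Because pool labels decline during an incubation, rates at the late
timepoint use the arithmetic mean of the pool excess at the two bracketing
timepoints (`pool_excess_timeavg()`); rates at the early timepoint use the
early measurement directly.

A cell is classified **active** when its ${}^{13}$C atom% exceeds the
baseline mean plus $k$ baseline standard deviations (`classify_active()`,
default $k = 3$, i.e. a threshold of 1.158 atom% under the default
baseline, with a one-sided Gaussian false-positive rate of ~0.1%). The
threshold is computed from the configured baseline rather than hard-coded.

## Rate equations

With $E_{POM}$ and $E_{pool}$ the atom% excess of particulate matter and of
the dissolved source pool,

$$\text{assimilation} = \frac{E_{POM}}{E_{pool}}\cdot\frac{[POM]}{\Delta t},
\qquad
\mu = \frac{1}{\Delta t}\log_2\!\left[\frac{E_{pool}}{E_{pool}-E_{POM}}\right],
\qquad
t_d = 1/\mu .$$

The growth rate assumes exponential growth and that all newly incorporated
heavy atoms reflect net biomass increase; a rate of 1 day$^{-1}$ means the
population doubles its C (or N) content daily. The same equations apply per
cell, with the cell's elemental content in place of $[POM]$
(`cell_fixation_rate()`, `cell_growth_rate()`). By convention the
*population-mean* C and N content is applied to every cell (the per-cell
label measurement and the geometry measurement come from different images,
so pairing them per cell adds noise without adding information); a
`content = "per_cell"` switch uses each cell's own geometry instead.

Rates are *net* over $\Delta t$: label fixed and then respired or exuded
within the incubation is not recovered on the filter, so C rates are net
photosynthesis. No correction is attempted for label loss during chemical
fixation of cells (none was applied to the data the defaults derive from).

## Cell geometry to elemental content

Cells are treated as cylinders, $V = \tfrac{\pi}{4}w^2 l$. Dry weight uses
a buoyant density of 1160 kg m$^{-3}$ and a dry fraction of 0.28
(1 µm$^3$ at 1000 kg m$^{-3}$ = 1 pg). Elemental content applies median
mass fractions of dry weight — 0.72 C, 0.04 N, 0.04 P — divided by atomic
masses (12.011, 14.007, 30.974 g mol$^{-1}$), giving pmol cell$^{-1}$.
Each constant is a visible, overridable argument. Cells whose geometry
fails to parse receive the population-mean composition and are flagged
(`geometry_imputed`).

One internal tension in these defaults is worth knowing: the median mass
fractions imply atomic C:P $\approx 46$ and N:P $\approx 2.2$, whereas
direct single-cell atomic-ratio measurements of the same populations give
C:P $\approx 509$ and N:P $\approx 26$ — a P mass fraction near 0.004 would
be consistent with the latter. The package does not resolve this: the
stoichiometry module reports what the supplied EDS table contains, and the
synthetic generator reproduces the mass-fraction route. P-rich intracellular
granules (polyphosphate storage) make single-cell P notoriously
heterogeneous, which is likely part of the story.

## ROI quantification from ion images

`roi_quantify()` consumes per-isotopologue count rasters
(${}^{12}$C${}^{14}$N$^-$, ${}^{13}$C${}^{14}$N$^-$,
${}^{12}$C${}^{15}$N$^-$) plus an integer label mask. The default ROI
estimator is the **mean of per-pixel ratios**, matching how SIMS ratio
images are conventionally summarised; a `count_sum` switch forms the ratio
of summed counts instead, which is the lower-variance estimator at low
per-pixel counts. Pixels with a zero denominator are excluded (whether the
original processing did so is not documented; we exclude and say so), and
ROIs whose denominators are all zero are skipped with a warning.

## Scaling to the community

The contribution of the algae to bulk uptake is

$$\text{contribution (\%)} = 100\cdot
\frac{\text{rate}_{cell}\times N_{cell}}{\text{rate}_{bulk}},$$

with $N_{cell}$ the active abundance (total microscopic count × active
fraction, default 0.90, converted to cells L$^{-1}$). Uncertainty is
propagated first-order, treating the three factors as independent:
relative SDs combine in quadrature. This choice is validated by the desk
check it reproduces (4.6 ± 3.46 pmol C cell$^{-1}$ d$^{-1}$,
16.2 ± 1.2 × 10$^3$ cells ml$^{-1}$, 448 ± 101 µmol C L$^{-1}$ d$^{-1}$
→ 15 ± 12%). The active fraction's own binomial uncertainty is not
propagated — no SD is available for it — and covariance between bulk POC
and abundance is ignored; both are documented limitations. A
POC-corrected abundance variant (`poc_corrected_abundance()`) rescales the
T0 count by the fractional POC change to the rate timepoint, absorbing the
uneven biomass distribution between bottles.

## The synthetic experiment generator

`simulate_experiment()` produces every table the analysis stages consume,
plus ground truth. What it emulates:

* **Growth heterogeneity**: per-cell rates are lognormal (field
  distributions are strongly right-skewed). Defaults (median 0.419
  day$^{-1}$, geometric SD 1.62) are chosen so the arithmetic mean and SD
  are 0.47 and 0.24 day$^{-1}$, the unamended-control values the study
  conditions specify. An inactive subpopulation (default 10%) sits on the
  natural-abundance distribution.
* **Labelling**: an active cell's excess inverts the growth equation. Under
  a pool whose excess decays as $E(s) = E_0 e^{-ks}$, weighting the pool
  label by when each unit of biomass was synthesised gives the closed form
  implemented in `tracer_cell_excess()`,
  $E_0\, r\,(e^{(r-k)t}-1)/\big((r-k)e^{rt}\big)$ with $r = \mu\ln 2$,
  which reduces to $E_0(1-2^{-\mu t})$ for a stable pool. A property test
  checks this closed form against an independent numerical time-integral of
  the instantaneous uptake flux to $10^{-9}$ relative — the generator's
  internal label accounting is conservative by construction. Pool
  *depletion itself* is configured (exponential; defaults: DIC 4.4 → 3.6
  atom% excess between 6 h and 30 h; N-pool excess half-lives 12 h for
  NH$_4^+$ and 24 h for NO$_3^-$, reflecting the much faster dilution of
  the rapidly cycled N pools) rather than coupled to the simulated
  community's uptake, so a literal pool-plus-biomass inventory is not a
  conserved quantity of the simulation.
* **Bulk POM**: the algal aggregate (abundance × content, content-weighted
  label) plus a non-algal background (default 2400 µmol C L$^{-1}$, C:N 20)
  with its own labelling rate (0.7 day$^{-1}$ — the bulk community turns
  over faster than the algae). Bottle-to-bottle biomass loading is
  lognormal (CV 0.3, matching the observed POC scatter); atom%
  measurement noise is Gaussian (SD 0.02 atom%).
* **Ion images**: cells are placed as axis-aligned rectangles (cylinder
  projections) in 256 × 256 rasters at 0.5 µm px$^{-1}$; per-pixel counts
  are Poisson with isotopologue means consistent with each cell's true
  fractions (expected total ${}^{12}$C${}^{14}$N counts per cell: 2 × 10$^4$,
  a realistic accumulated count for minutes-long dwell on a CN-rich cell);
  background is near zero, as for a low-noise ion-counting detector.
  Geometric sophistication beyond rectangles is unnecessary for ratio
  estimators, which are insensitive to ROI shape.
* **EDS tables**: per-cell mass fractions are lognormal around the median
  fractions with CVs of 0.08 (C), 0.15 (N), 0.30 (P) — P most variable,
  consistent with granule storage — and atom% computed over C, N, O, P
  with O as the mass complement.

What it does **not** emulate: instrument drift, detector dead time,
quasi-simultaneous-arrival effects, EDS spectral quantification, fungal
parasitism dynamics, and chemical-fixation label loss. Passing tests
therefore demonstrate the correctness of the *computational* chain and its
statistical behaviour under realistic counting noise and population
heterogeneity — not robustness to instrument-level artefacts, which are
assumed corrected upstream.

Noise-free mode (`noise = FALSE`) removes every stochastic layer except the
population draws themselves, making the pipeline exactly invertible when
the pool is stable: a planted growth rate is recovered to machine
precision, which is the basis of several exactness tests.

## Numerical and design choices

* **Two-point pool averaging vs the true exposure.** The analysis uses the
  field convention (T1 excess for T1 rates, T1/T2 mean for T2 rates). The
  generator's growth-weighted exposure is the exact model, so the
  convention carries a small bias — about +2% relative on growth rates
  under the default DIC depletion — which the end-to-end tests quantify and
  absorb within their stated tolerances.
* **Degenerate inputs**: zero heavy+light counts, non-positive pool excess,
  biomass more labelled than its source pool, zero PON, and empty active
  sets are all hard errors or warned-and-flagged outputs, never silent NAs.
* **Ties and ordering**: Holm adjustment resolves p-value ties by original
  comparison order; the compact letter display orders groups by mean rank
  and merges groups with no significant pairwise difference.
* **Group comparison contract**: the omnibus test is the Kruskal–Wallis
  rank test (chi-squared approximation, df = groups − 1) via
  `stats::kruskal.test`; pairwise follow-ups are rank-sum tests with Holm
  correction. The loosely specified post-hoc convention ("LSD-style" rank
  comparisons) is implemented as unrestricted pairwise rank-sum tests,
  Holm-protected — documented here as this package's interpretation.
* **Determinism**: a fixed seed fixes every simulator output byte; the
  pipeline is idempotent given identical inputs and seed.

## Problem sizes

The shipped analysis and test configurations use the study-scale cohort
(244 cells, 48 EDS cells, 1–3 bottles per treatment × timepoint) for the
headline runs; property tests use smaller cohorts (25–80 cells) and
replicate-seed loops (12 seeds) or larger Monte-Carlo draws ($10^5$) where
the property, not the experiment, is under test. The end-to-end
image-based recovery test renders all 244 cells at 2 × 10$^4$ counts per
cell and completes in well under a minute.

## Known limitations

* Storage uptake is indistinguishable from growth: cells that assimilate C
  or N into storage pools without dividing inflate isotope-based growth
  rates. The rates are therefore upper bounds on division rates.
* The contribution estimate inherits the bulk rate's bottle-to-bottle
  variability; with three bottles its propagated SD is honest but wide,
  and ratio estimators carry a small positive bias under noisy
  denominators.
* The activity threshold is calibrated on the ${}^{13}$C channel only;
  N-only activity (e.g. luxury N uptake by C-quiescent cells) would be
  classified inactive.
* Doubling times diverge as growth rates approach zero; summaries of
  doubling times over weakly active populations are dominated by their
  slowest members, which is why growth-rate summaries are preferred.
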