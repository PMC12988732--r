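---
title: "Methods: dietary heavy-metal risk assessment for eggs"
author: "eggrisk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary heavy-metal risk assessment for eggs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggrisk)
library(dplyr)
```

## The problem

Hens accumulate trace metals from feed, soil, water and forage, and a
fraction of that burden transfers into eggs. For populations that eat eggs
daily — and especially for rural consumers of free-range eggs near mining
or industrial districts — the question is whether chronic dietary exposure
to Cr, Mn, Co, Ni, Cu, Zn, As, Se, Cd and Pb at the measured
concentrations carries a non-carcinogenic or carcinogenic health risk.
`eggrisk` implements the standard USEPA-style deterministic assessment,
a seeded Monte Carlo version of it, regulatory compliance screening and
the multi-group statistics used to compare sampling areas and production
systems (free-range vs commercial).

## The risk model

For a metal with mean concentration $C$ (mg/kg) in egg, a population group
with body weight $BW$ (kg) and egg intake rate $FIR$ (g/person/day), the
estimated daily intake is

$$\mathrm{EDI} = \frac{C \times FIR}{BW} \quad [\mathrm{mg/kg/day}],$$

with $FIR$ converted from g/day to kg/day inside `edi()`/`thq()` and
nowhere else, so the factor of $10^{-3}$ can never be applied twice. The
chronic non-carcinogenic hazard of one metal is the target hazard
quotient

$$\mathrm{THQ} = \frac{EF \times ED \times FIR \times C}
                      {RfD \times BW \times AT},$$

where $EF$ is exposure frequency (days/year), $ED$ exposure duration
(years), $AT$ averaging time (days) and $RfD$ the oral reference dose
(mg/kg/day). When $EF \times ED = AT$ the quotient reduces algebraically
to $\mathrm{EDI}/RfD$; the test suite asserts this identity to machine
precision. Cumulative non-carcinogenic risk is the hazard index
$\mathrm{HI} = \sum_i \mathrm{THQ}_i$, and the HI of an empty metal set is
an error, not zero. For the probable oral carcinogens Cr, Cd and Pb,
lifetime cancer risk is $\mathrm{CR} = \mathrm{EDI} \times SF$ with slope
factor $SF$ ((mg/kg/day)$^{-1}$), and
$\mathrm{TCR} = \mathrm{CR_{Cr}} + \mathrm{CR_{Cd}} + \mathrm{CR_{Pb}}$,
requiring exactly those three terms.

Decision thresholds follow the usual bands. HI (or THQ) below 1 means no
expected non-carcinogenic effect; 1 or above flags potential adverse
effects. CR below $10^{-6}$ is negligible, between $10^{-6}$ and $10^{-4}$
acceptable, and at or above $10^{-4}$ potentially unacceptable. Published
risk tables in this field mark cells at or above $10^{-4}$ in bold
("$\geq 1.0 \times 10^{-4}$ may have a potential health risk"), and prose
conventions for the exact boundaries vary; we resolve every boundary in
the flagging direction: HI $= 1$ flags, CR $= 10^{-4}$ flags, CR
$= 10^{-6}$ is acceptable. `render_cr_matrix()` reproduces the table
style, wrapping flagged cells in `**`.

`assess()` summarises each area's concentrations by the arithmetic mean
by default (the quantity the deterministic assessment integrates with
consumption); median and max are available for sensitivity analyses.
Below-LOD records carry the LOD and are substituted by LOD/2 by default
(LOD/$\sqrt2$, LOD and 0 are options) — the substitution convention is a
package choice, stated rather than inherited from any survey.

## Exposure and toxicity parameters

The equations need, per population group (male, female, child): $BW$,
$FIR$, $EF \le 366$, $ED$, $AT$, all strictly positive; and per metal an
$RfD > 0$, plus $SF \ge 0$ for the three carcinogens only (a slope factor
on any other metal is a validation error). These are user-supplied
configuration. The shipped `example_reference.yaml` is a worked example,
not authoritative toxicology: body weights 65.0 / 56.8 / 16.2 kg (Chinese
adult and preschool reference values), $FIR = 50$ g/day (one egg per
person per day, the dietary-guideline rate), $EF = 365$, $ED = 70$ years
for adults and 6 for children, $AT = EF \times ED$, and USEPA IRIS-style
$RfD$/$SF$ values (e.g. Cr 0.003 mg/kg/day and $SF_{Cr} = 0.5$). With the
child profile, one egg per day for a 16 kg child gives roughly four times
the adult dose per kg body weight, which is why child risks dominate
every assessment this package produces.

## Monte Carlo engine

The probabilistic layer replaces point inputs by distributions
(`dist_spec` objects) and pushes `n_iter` joint draws through the same
arithmetic kernels as the deterministic path — literally the same
functions, so a run in which every spec is a point mass reproduces
`assess()` bit for bit (a test asserts exact equality). Defaults, all
overridable and documented here because the choice of families is a
modelling decision the underlying survey literature rarely states:

* concentration, per (area, metal): empirical bootstrap of the observed
  sample values (10 eggs per area in the emulated design); a
  moment-matched lognormal (`fit_lognormal()`, log-scale moments) and a
  point mass are alternatives;
* body weight: normal, CV 0.1, truncated at zero via the inverse CDF;
* intake rate: triangular, mode at the profile value, range ±50%;
* $EF$, $ED$, $AT$, $RfD$, $SF$: fixed constants.

Within one iteration, one concentration draw per metal and one BW/FIR
draw are shared across all metals of a cell, so HI is a sum of
per-iteration THQs and cross-metal dependence through the exposure
parameters is preserved. Percentiles use the type-7 (linear
interpolation) estimator. The decision statistic is the 95th percentile
with 10,000 iterations by default; `exceedance_prob` additionally reports
the fraction of draws at or above each metric's threshold.

Seeding: one master seed spawns one child stream per (area, group) cell,
drawn in a fixed sorted cell order, so results are bit-reproducible and
invariant to the order in which profiles or areas are supplied; the
caller's RNG state is restored afterwards. `convergence_check()` re-runs
one metric at 1e3–5e4 iterations and reports successive relative changes
of the 95th percentile (converged when the final step moves < 1%).

Because no published study we emulate states which inputs its commercial
Monte Carlo software randomised, nor with which families, these defaults
are explicit guesses: simulated percentiles are *a* probabilistic
assessment under stated assumptions, never a reproduction of any
particular published p95 value. Note also that p95(HI) is not in general
$\ge$ p95 of any single THQ (quantiles of sums are not monotone in
components under dependence); the conserved identities are
$\mathrm{HI} = \sum \mathrm{THQ}$ per draw and
$\overline{\mathrm{TCR}} = \sum_m \overline{\mathrm{CR}_m}$ across draws,
both asserted in tests.

## Synthetic data generator

No per-sample concentrations are deposited with the surveys this workflow
targets, so the generator emulates the *design*: nine areas (one clean
background city, three industrial/agricultural cities, three mining
districts, with one city sampled under both production systems), ten eggs
per area, ten metals per egg — 900 records. Per (area, metal) it draws
lognormal values (strictly positive, right-skewed, the natural family for
trace concentrations) with arithmetic mean = base mean × elevation
factors and CV 0.2, a typical within-site replicate spread.

Calibration: base means sit at the midpoints of the per-metal
concentration ranges reported across the nine areas (e.g. Zn 9.99–25.09
mg/kg, Cd 1.5–2.3 µg/kg), and by default draws are clipped to those
ranges by rejection resampling (redraw, never cap, so the density stays
smooth). The midpoints are calibration constants of the generator, not
data. Both elevation factors (`free_range_factor`, `mining_factor`)
default to 1: the emulated surveys report per-metal *ranges*, not
per-area means, and their loose statement that mining free-range eggs run
1.5–3.5× higher applies to three metals only — too little to justify a
per-metal default. Moreover Cd's printed range spans only a factor 1.53,
so any default elevation near 2 would push mining-area target means
outside the clip window; `generate_concentrations()` refuses such
configurations outright instead of silently biasing the draws. Elevated
scenarios are therefore run unclipped, e.g.
`generator_config(free_range_factor = 3, clip = FALSE)` in the power
tests. `truth_table()` exposes the exact generating means (pre-clip) for
parameter-recovery tests; with active clipping the realised mean can
deviate slightly from the target, which is why the CLT recovery test runs
unclipped.

One divergence worth knowing: ranking the ten metals by these midpoint
means gives Zn > Cu > Mn > Se > Cr > Ni > **As > Pb** > Co > Cd, whereas
the survey narrative reports Pb above As. The As and Pb midpoints differ
by only 7%, well inside sampling noise at 10 eggs per area; the rank test
asserts the calibration-implied order on near-constant data and treats
the Pb/As pair as indistinguishable in realistic draws.

What passing tests on synthetic data do *not* show: the generator has no
inter-metal correlation, no spatial structure, no soil-to-egg transfer
model and no measurement-error component, so agreement on synthetic data
validates the arithmetic and the statistical machinery, not any claim
about real contamination patterns.

## Group comparisons and compliance

`compare_groups()` runs one-way ANOVA per metal across areas, production
systems or mining classes, with Tukey HSD pairwise comparisons when the
omnibus test is significant at α = 0.05 (configurable). Normality
(Shapiro–Wilk on residuals) and variance homogeneity (median-centred
Levene) are reported as screens but never auto-switch the test — a
Kruskal–Wallis alternative sits behind `method = "kruskal"`. All-constant
groups yield no finite F and are reported as degenerate, not significant.
Calibration is tested, not assumed: under three identical lognormal
populations of 10, the rejection rate over 1000 seeded replicates must
fall in [0.03, 0.07], and a 3× free-range elevation at n = 10/area must
be detected in ≥ 95% of 200 replicates.

`compliance_screen()` compares each metal's maximum observed
concentration against every configured (metal, authority) maximum level;
a value exactly at the limit passes (limits are maximum *permitted*
levels), and a metal without a configured limit is reported as
unconfigured, never as passing.

## Numerical and degenerate-input choices

* Summations over metals always run in a fixed panel order, so
  deterministic and Monte Carlo paths accumulate identically.
* Truncated normal/triangular sampling uses the inverse CDF restricted to
  $[F(0), 1]$ — exact, no rejection loop.
* A degenerate triangular (low = high) collapses to a point mass; a
  uniform with low = high draws constants.
* Empirical specs with a single value fall back to point masses with a
  warning.
* CSV round-trips are bit-exact: the writer emits shortest round-trip
  decimals and the reader parses them with R's correctly rounded
  `as.numeric`.
* Classification boundaries are closed on the flagging side (see above).

## The published reference table shipped with the package

`survey_cr_p95()` returns 95th-percentile CR values for Cr/Cd/Pb across
nine areas and three population groups, transcribed from a published
nine-area survey of Chinese eggs, as *input* for the aggregation
operations (`aggregate_tcr()`, `classify_cr()`). Aggregating it
reproduces that survey's headline totals: the highest male TCR,
5.905×10⁻⁵ in GY; a child WC total of 9.723×10⁻⁵, inside the acceptable
band; four areas with flagged child Cr risk; child totals above 10⁻⁴
everywhere except GY and WC. The source's own summary sentence for the
female DZ total (1.3×10⁻⁵) contradicts its tabulated row, which sums to
1.262×10⁻⁴; this package treats the tabulated per-metal values as
authoritative and reproduces the row sum.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the full 9×10×10
synthetic design with 10,000 Monte Carlo iterations for pipeline runs,
100,000 iterations for the closed-form lognormal quantile check (2%
tolerance), 1000 replicates for ANOVA type-I calibration and 200
replicates for power — sizes chosen so every stochastic assertion has
comfortable statistical margin while a complete run stays around a
minute.

## Known limitations

* Concentrations are carried on the basis declared at input (dry vs
  fresh mass); the package never converts between bases, and mixing
  bases across inputs is the user's responsibility.
* No dermal or inhalation routes; no age-stratified lifetime averaging
  beyond EF/ED/AT.
* No correlated multivariate concentration model and no variance-based
  sensitivity indices.
* The shipped exposure and toxicity values are examples; conclusions
  about any real population require that population's parameters.
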