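---
title: "Methods: dietary risk indices, rank correlation and probabilistic exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary risk indices, rank correlation and probabilistic exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegrisk)
```

## The problem

Leafy vegetables grown on contaminated urban soils accumulate trace
elements in their edible tissue, and chronic consumption is then a direct
dietary exposure route. `vegrisk` implements the standard screening-level
assessment chain used in food-safety surveys: from a sample-by-metal
concentration table (mg/kg dry weight) it computes deterministic intake and
hazard indices, screens concentrations against regulatory food limits,
quantifies inter-metal association (a source-apportionment clue), and
propagates population variability through a seeded Monte Carlo simulation
of intake. The package ships the complete 19-sample, 19-element survey of
*Brassica pekinensis* leaves from two Kinshasa gardening sites (Cecomaf,
n = 11; Lutendele, n = 8) on which all worked examples run.

## Deterministic indices

For metal $i$ with concentration $C_i$ (mg/kg dw), the estimated daily
intake is

$$\mathrm{EDI}_i = \frac{C_i \times \mathrm{DIR}}{\mathrm{BW}}
  \quad [\mu g\,/\,kg\ bw\,/\,day],$$

with DIR the daily ingestion rate (g/day) and BW the body weight (kg). The
mg/kg-by-g/day combination lands directly on µg/kg bw/day; no unit factor
appears in the formula. The target hazard quotient divides the intake by
the oral reference dose $\mathrm{RfD}_i$ (mg/kg bw/day):

$$\mathrm{THQ}_i = \frac{\mathrm{EDI}_i \times EF \times ED}
  {\mathrm{RfD}_i \times AT} \times 10^{-3},$$

where the $10^{-3}$ is the single µg→mg conversion of the pipeline
(deliberately pinned inside this one formula so unit discipline is
testable), and EF (days/year), ED (years) and AT (days) are the chronic
exposure terms. Under the default lifetime scenario — DIR 60 g/day, BW
58 kg, EF 365, ED 70, AT 25550 — the time terms cancel and
$\mathrm{THQ}_i = \mathrm{EDI}_i \times 10^{-3} / \mathrm{RfD}_i$. The
hazard index is the plain sum $\mathrm{HI} = \sum_i \mathrm{THQ}_i$ over
the seven elements carrying USEPA reference doses (Mn, Fe, Cu, Zn, As, Cd,
Pb); HI > 1 flags likely adverse effects from combined exposure. The
HI metal set is deliberately *not* all 19 surveyed elements: no defensible
oral reference doses are carried for the others, and inventing them would
manufacture risk numbers.

All arithmetic is at full precision; rounding happens only at report
emission. One deliberate exception: published survey tables typically sum
hazard quotients that were rounded to two decimals for display, so
`compute_risk_table(round_thq = 2)` reproduces that convention exactly
when comparison with such a table is the goal. On the packaged dataset the
two conventions differ by at most 0.01–0.02 in the per-site HI extrema.

```{r}
risk <- compute_risk_table(table1_fixture())
unlist(site_summary(risk, "Cecomaf")[c("min", "max")])
unlist(site_summary(risk, "Lutendele")[c("min", "max")])
```

Limit screening reports, per metal with a FAO/WHO maximum permissible
concentration (Cr 1.3, Cu 40, Cd 0.1, Pb 0.3, Hg 0.001 mg/kg), the maximum
concentration over the selected samples and the fold ratio maximum/limit.
The fold ratios are always emitted as computed from the data; for the
packaged dataset the lead ratio is 30.94/0.3 = 103.1, slightly below the
103.3 quoted in the originating survey, an internal inconsistency of that
report which the package documents rather than patches.

```{r}
exceedance_report(table1_fixture())
```

## Below-detection values

The survey prints below-LOD measurements as 0.00, and the packaged table
stores them as exactly that: 0.0, not missing. Downstream this matters
twice. First, zeros participate in rank correlation as genuine ties at the
bottom of the ranking (mid-ranks handle them); excluding them would change
several coefficients and would not reproduce the published matrices.
Second, the lognormal fitter substitutes LOD/2 for zeros (a standard
censoring workaround) *only* when an LOD is on record for that metal, and
otherwise skips the metal with a warning. LOD flagging itself uses strict
`<` — a value exactly at the detection limit counts as detected, because
detected values are printed at or above LOD.

## Tie-corrected Spearman correlation

Concentration data contain ties (repeated rounded values, below-LOD
zeros), so the package computes Spearman's coefficient as the
product-moment correlation of mid-rank vectors — the tie-correct form —
rather than the classical $1 - 6\sum d^2 / (n(n^2-1))$ shortcut, which is
only valid tie-free (the two agree to 1e-12 on tie-free data, and this is
a tested invariant). On the packaged data the mid-rank form reproduces all
six association coefficients quoted by the originating survey (Cecomaf
Cr–As 0.855, Cr–Pb 0.929, Cd–Hg 0.564; Lutendele Cr–As 0.910, Cr–Pb 0.881,
Cd–Hg 0.524) to ±0.001; the shortcut form does not, where ties exist. The
survey labels these coefficients "R²"; they are rank correlations
(Spearman's rho), and the package names them accordingly.

Two-sided p-values use the t transform $t = \rho\sqrt{(n-2)/(1-\rho^2)}$
on $n-2$ degrees of freedom by default — adequate at the n ≥ 8 of the
shipped data — with a permutation audit option: full enumeration of all
$n!$ relabelings for n ≤ 7, seeded Monte Carlo otherwise. The source
survey does not state its p-value method; the t approximation is this
package's choice. Its bold-at-p<0.05 annotation is not fully reproducible
under any standard two-sided test (its Cd–Hg pairs give p ≈ 0.07 and 0.18),
so the package's significance masks are its own, at a configurable alpha.
No multiple-testing correction is applied across the 171 pairs, matching
survey practice; users comparing many matrices should apply `p.adjust`
themselves.

```{r}
cm <- correlation_matrix(table1_fixture(), "Cecomaf")
round(cm$rho[c("Cr", "Cd"), c("As", "Pb", "Hg")], 3)
```

## Probabilistic exposure

The Monte Carlo module answers a different question from the deterministic
indices: not "what is the intake of the average adult" but "what fraction
of a heterogeneous population exceeds a health-based intake limit". Each
iteration draws a consumer stratum by its population proportion, a body
weight and an ingestion rate from that stratum's truncated distributions,
and one concentration per metal; EDI is computed by the same formula as
the deterministic path and compared with the metal's intake limit (µg/kg
bw/day: Mn 700, Fe 1000, Cu 40, Zn 1000, As 2.14, Cd 1, Pb 3.6). The
exceedance probability is the exceeding fraction, with binomial standard
error $\sqrt{p(1-p)/n_{iter}}$ attached.

Defaults, and their status:

* Concentrations: lognormal, fitted per metal by mean/sd of log
  observations pooled over the 19 samples — the smallest-assumption model
  for nonnegative right-skewed data. Fully overridable per metal
  (`dist_spec` families: lognormal, normal, triangular, point, empirical).
* Population: three illustrative strata (adult men 35 %, bw ~ N(65, 10);
  adult women 40 %, bw ~ N(58, 10); children 25 %, bw ~ N(25, 8) kg;
  intake N(60, 15) g/day for adults, N(40, 12) for children; all truncated
  positive, adult bw > 20 kg, child bw > 5 kg). These are **not** survey
  values — the originating study published no distributional assumptions —
  and the published exceedance percentages are therefore not reproduction
  targets. The module's correctness surface is instead analytic: with
  point-mass body weight and intake, a lognormal concentration gives an
  exceedance probability with a closed form
  $1 - \Phi\!\left((\ln L - \mu)/\sigma\right)$, which simulation matches
  within three binomial standard errors at 10,000 iterations (a tested
  property at three parameter settings), plus exact 0/1 behaviour for
  point masses, seed determinism, and monotonicity in the limit.
* Sampling: one RNG stream keyed by a single seed, draws in a fixed
  documented order (strata, body weights, intakes, then metals in config
  order); truncation by rejection. Identical configs are bit-identical.

```{r}
cfg <- mc_config(conc_dist = fit_concentration_dists(table1_fixture(),
                                                     metals = c("Cd", "Pb")),
                 limits = c(Cd = 1, Pb = 3.6), n_iter = 10000, seed = 1)
exceedance_table(run_simulation(cfg))
```

## Synthetic ground truth

`synth_spec()`/`generate_table()` generate concentration tables with known
parameters so every stage is testable without the packaged survey:
lognormal marginals per metal and site, coupled through a latent Gaussian
(a Gaussian copula) whose pairwise correlations are set from target
Spearman values via $r = 2\sin(\pi\rho_s/6)$. That conversion is exact for
the bivariate normal rank correlation, so the induced sample Spearman
approximates the target; correctness is asserted against a large-sample
simulation of the same latent model, not a closed form. The latent matrix
must be positive definite and is validated up front. LOD censoring
reports zeros, mirroring the survey convention and deliberately exercising
the tie handling of the correlation module. Recovery is tested at n = 500:
log-mean within ±0.05, log-sd within ±0.1, each rank-correlation target
within ±0.08.

What the generator does *not* emulate: replicate measurement error (the
survey reports triplicate CVs < 3 % but prints single values), spatial
structure within a site, soil-to-plant transfer, or temporal trends. A
pass on synthetic data therefore validates the computational chain, not
the field-sampling design.

## Numerical and interface choices

* Problem sizes in the shipped tests: the full 19-sample dataset for all
  deterministic checks; 10,000 iterations for Monte Carlo properties;
  n = 500–1000 for synthetic recovery; one 10^6-draw oracle for the copula
  target. The whole suite runs in a few seconds.
* The ingestion rate (60 g/day) is applied to dry-weight concentrations as
  in the originating survey; whether the consumption figure refers to
  fresh weight is unresolved there, and a fresh-weight correction would
  lower all indices by the dry-matter fraction. Users can pass any
  `exposure_scenario`.
* The scenario contract applies the THQ formula as written for any
  positive EF, ED, AT; `ef * ed == at` is not enforced, and deviating from
  it scales THQ by `ef*ed/at` (a tested identity).
* Degenerate inputs: constant vectors raise a named error in correlation
  (undefined coefficient) and degenerate to point masses in distribution
  fitting; empty selections, missing RfDs, non-positive-definite copula
  targets and malformed cells each raise distinct named conditions.
* `run_full_pipeline()` stages all outputs in a temporary directory and
  moves them only on success, so a failed run leaves no partial files. An
  `inst/scripts/vegrisk` Rscript exposes the stages as shell subcommands
  (`all`, `risk`, `correlate`, `simulate`, `synth`, `qc`).

## Known limitations

Carcinogenic risk indices are out of scope (no slope factors are carried).
The registry holds exactly the reference values needed here and is not a
general regulatory database; the FAO/WHO citation years for the food
limits vary across source documents and the registry does not adjudicate
them. Exceedance screening uses the site maximum (a worst-case screen),
not a mean with confidence interval. The t-approximate p-values are
anti-conservative at very small n; use the permutation method below n ≈ 8.
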