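---
title: "Methods: multi-taxon diversity scaling with scalediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-taxon diversity scaling with scalediv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalediv)
```

This vignette is the package's account of its statistical machinery: the
estimators, the model-selection procedure, the partition and congruence
definitions, the synthetic data generator, and the numerical and design
choices that were genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The setting

The design is a set of P equal-sized, spatially separated plots (the
default emulation: 27 plots of 30 × 30 m, i.e. 0.09 ha each, scattered
over a heterogeneous landscape with a mean pairwise spacing of a few
kilometres, inside a reference area of 8,000 ha). For each taxon a
plot × species matrix records abundances (or incidences). The questions
the pipeline answers are: how does expected richness grow with pooled
area; what overall richness γ does that growth imply for the reference
area; how is γ apportioned between local (α) richness and turnover (β)
across nested scales; and how congruent are these patterns across taxa.

Non-contiguous pooling means "area" is cumulative sampled area, k plots
× mean plot area — not a contiguous block. Nothing in the pipeline is
spatially explicit beyond the plot coordinates used for the core-subset
sensitivity analysis.

## Accumulation curves

Two estimators of expected pooled richness at k plots:

* **Permutation** (`accumulate_permutation`): average over random
  orderings of the plots; one ordering contributes to all k. Default 999
  permutations; the permutation spread (sd over orderings) is reported
  per k.
* **Exact** (`accumulate_exact`): the hypergeometric expectation
  E[S(k)] = Σ_j (1 − C(P−p_j, k)/C(P, k)), evaluated with `lchoose` for
  stability. This is the noise-free limit of the permutation estimator
  and serves as its oracle in the tests (and is cross-checked against
  vegan's analytic sample-based rarefaction).

Both anchor exactly at the observed totals: E[S(1)] is the mean per-plot
richness and E[S(P)] the observed union. Model fitting uses the curve's
points equally weighted; the permutation sds are reported but not used as
weights (weighted fitting would privilege the tightly-determined ends of
the curve, and the common practice in this literature is unweighted
least squares).

## Species–area models and selection

Eight forms are fitted (S = richness, A = area in ha): power c·A^z;
exponential c + z·ln A; negative exponential d(1 − e^(−zA)); Monod
dA/(c + A); rational (c + zA)/(1 + dA); logistic d/(1 + e^(−zA+c));
Lomolino d/(1 + f^(log10(z/A))); cumulative Weibull d(1 − e^(−cA^z)).
Six are asymptotic (asymptote d, or z/d for the rational form); the
power and exponential forms are not. Parameter bounds: c, z, d > 0,
f > 1; the exponential form uses the natural log, Lomolino log base 10.

**Fitting** is multi-start Levenberg–Marquardt (minpack.lm) from a
deterministic grid scaled by the data ranges (richness starts at
{1, 1.5, 3} × max S for asymptotes; rate/shape parameters on coarse
logarithmic grids; the exponential form additionally starts from its OLS
solution). The best converged start by RSS wins; fitting therefore needs
no seed. A form for which every start fails is reported as
non-converged, not an error.

**AICc** is n·ln(RSS/n) + 2K + 2K(K+1)/(n−K−1) with K = number of model
parameters + 1, counting the error variance — the usual convention in
species–area multimodel inference. RSS = 0 (an exact interpolation)
yields −Inf with a warning: the perfect fit wins by construction.

**Validation** excludes fits whose residuals look non-normal
(Lilliefors test) or heteroscedastic (Pearson correlation between
|residuals| and fitted values), both at α = 0.05. Two degenerate cases
skip the tests and pass: fewer than 5 residuals, and residual sd below
10⁻⁸ of the fitted scale (a perfect fit has no residual distribution to
test). The simulated size of the joint check on well-behaved residuals
is the nominal (1−α)² ≈ 0.90, and a strong variance-fan is caught with
power above 0.8 — both measured in the test suite.

**Selection** picks the valid fit with the lowest AICc (ties by RSS,
then model-name order) and flags the winner unambiguous when every other
valid fit trails by more than ΔAICc = 2.

*Fallback rule.* A strongly saturating taxon (the bacteria-like regime)
produces a curve the best forms fit almost perfectly — residual sd on
the order of 0.1 % of the signal. At that scale both residual tests
reject on numerical structure rather than model misspecification, and
every form can end up excluded. With `fallback = TRUE` (the pipeline's
setting) selection then proceeds by AICc among all converged fits and
the result is flagged; with the default `fallback = FALSE` the situation
is an error ("no admissible model"). This keeps the validation step
meaningful where it can be, without making saturated taxa unanalysable.

## Extrapolation and confidence bands

The selected model evaluated at a target area gives Ŝ(A); γ̂ is Ŝ at
the reference area, and `fraction_of_reference` = Ŝ(A)/γ̂ is the
fraction of overall richness attained by area A.

Uncertainty comes from a nonparametric bootstrap over plots: resample P
plots with replacement, rebuild the exact accumulation curve, refit the
selected form (warm-started at the point estimate, full grid on
failure), re-evaluate. A resample contains on average 63 % unique plots,
so replicate richness is systematically biased low; plain percentile
intervals of the replicates barely ever cover a known truth. The bands
are therefore **bias-corrected percentile intervals**: the replicate
mean's offset from the point estimate is subtracted from both replicate
quantiles. The point estimate always lies inside the band, and on
synthetic taxa with a known pool the band's coverage of the truth is
checked directly in the acceptance tests. Which construction the
original analyses of this kind used is generally unstated; this choice
is the package's own and is labelled in the output.

## Additive turnover partition

With scales s₁ < s₂ < … < s_m (defaults 0.1, 0.5, 1, 10, 8000 ha):

* α_plot = observed mean per-plot richness (the curve at k = 1);
* β_plot = Ŝ(plot area) − α_plot — the gap between the fitted curve at
  one plot's true area and observed α. The partition literature leaves
  this term's operational definition open; here it mainly absorbs model
  lack-of-fit at the origin and is near zero by construction;
* β_{s} = Ŝ(s) − Ŝ(previous scale) for the remaining scales;
* γ̂ = Ŝ(reserve), so γ̂ = α + Σβ identically.

The plot scale is *reported* at its nominal 0.1 ha but *computed* at the
true mean plot area (0.09 ha); fitting always uses true areas. A
negative component (possible when the model undershoots observed α) is
clipped to zero and the deficit carried into the next larger scale, so
non-negativity and exact additivity both hold; if the largest scale
would go negative the residue is absorbed into α (never observed in
practice — the partition refuses non-monotone fitted curves outright).
Bootstrap intervals re-derive the full partition per replicate — α from
the replicate's own k = 1 value — so the additive identity holds in
every replicate, which the tests assert to 10⁻⁹ relative tolerance.

## Cross-taxon congruence

Two complementary views:

* **Linear reference** (`linear_reference`, `congruence_deviation`): OLS
  of a focal taxon's model-predicted richness on a reference taxon's
  (the woody-plant role), calibrated on 20 log-spaced areas between the
  plot scale and 1 ha, then extrapolated across the full area grid. The
  deviation Ŝ_t(A) − linear prediction quantifies how misleading a
  small-scale linear surrogate becomes at large scales. Calibrating on
  model predictions rather than raw per-plot richness pairs is
  deliberate: the comparison targets the fitted relationships, and raw
  pairs exist only below 2.43 ha anyway. Proportional curves give zero
  deviation everywhere — the null the tests pin at 10⁻⁸.
* **Relative profiles** (`relative_profiles`): r_t(A) = Ŝ_t(A)/γ̂_t
  clipped to [0, 1], the cross-taxon mean r̄(A), and
  D_t(A) = 100·(r_t − r̄)/r̄. D is a percent-of-mean deviation by
  default (a percentage-point variant is exposed); positive D marks taxa
  that reach their richness at smaller scales than the average. The
  equal-weight deviations r_t − r̄ cancel at every area by construction.

The area grid is 200 log-spaced points from the plot scale to the
reference area.

## Sample coverage and rarefaction

Coverage of a pooled abundance sample uses the Chao–Jost estimator
Ĉ = 1 − (f1/n)·[(n−1)f1/((n−1)f1 + 2f2)] (f1 singletons, f2 doubletons,
n individuals; a single-individual sample has coverage 0, a sample
without singletons coverage 1). `coverage_by_combination` pools counts
over every k-plot combination — exhaustively while C(P, k) stays within
`max_combinations` (default 100,000), otherwise over a seeded draw of
that many *distinct* combinations — and reports the mean with 2.5/97.5
quantiles. Abundances are pooled across the combination's plots before
f1/f2 are counted (the alternative, averaging per-plot coverages, is not
what "coverage of the pooled sample" means). Per-plot completeness is
S_obs divided by bias-corrected Chao1, S_obs + f1(f1−1)/(2(f2+1)).
`rarefy_counts` is an exact multivariate hypergeometric subsample to a
fixed depth, the OTU-table normalisation step.

## The synthetic generator

`generate_landscape` scatters plots uniformly in a square (default side
6.5 km, giving the 0.5214 × side ≈ 3.4 km mean spacing of the emulated
design) and attaches standardised environmental gradients (linear trend
plus three seeded Gaussian bumps each). `generate_taxon` gives each of
`pool_size` species a niche optimum uniform over the gradient ranges;
occupancy probability at a plot is a Gaussian kernel of gradient
distance with width `niche_breadth`, rescaled to a target mean occupancy
(capped at 1); presence is Bernoulli, conditional abundance lognormal or
geometric, thinned binomially by a detection probability. Occupancy is
niche-based rather than distance-based because environmental
heterogeneity, not dispersal limitation, is the turnover mechanism being
emulated; everything is a pure function of seed and config.

Presets pin the contrast the study design revolves around:
bacteria-like (pool 250, breadth 6, occupancy 0.75 — near-saturated by a
few plots), woody-plant-like (pool 170, breadth 1.5, occupancy 0.3 —
per-plot richness ≈ 50, within the 25–68 range of a woody-plant
inventory, saturating within the sampled extent), lepidopteran-like
(pool 400, breadth 0.35, occupancy 0.06, detection 0.6 — still climbing
at the full design). These values were fixed once, when the generator
was built, to reproduce that qualitative contrast; they are study
conditions, not tuning knobs.

What the generator does *not* emulate: within-plot spatial structure,
temporal turnover between sampling years, phylogenetic or trait
structure, read-level sequencing noise, and dispersal limitation (a
distance-based occupancy term is deliberately absent). Passing tests
therefore demonstrate correct behaviour under niche-driven turnover with
independent Bernoulli occupancy — not robustness to every process
shaping real censuses.

## Ground truth and what the tests check

The true γ of a generated taxon is its `pool_size`. Recovery is only a
fair target when the expected occupancy union approaches the pool, so
the recovery checks use a saturating configuration (pool 120, breadth
2.5, occupancy 0.3, 27 plots), under which the acceptance tests require
γ̂ within ±15 % of truth in ≥ 80 % of 100 seeded runs and truth inside
the 95 % band in ≥ 90 %. The preset contrast is required to order the
1-ha fractions (bacteria > woody > lepidopteran) and sign the 1-ha
deviations D in ≥ 18 of 20 seeds. Problem sizes throughout the tests —
10-plot × 40-species matrices for the permutation-vs-exact comparison,
100 recovery runs at 150 bootstrap replicates, 10 partition taxa at 220
replicates — were chosen as the smallest designs that leave the
Monte-Carlo error clearly below the tolerances being asserted.

## Known limitations

* Extrapolation quality is entirely the selected form's: a
  non-asymptotic winner (power/exponential) sends γ̂ far above anything
  observable, and the fraction-of-reference then mostly reflects the
  exponent. The selection table flags such winners via `asymptotic`
  status in `sar_model_specs()`.
* The core-subset construction (greedy farthest-point removal, exact
  search for small designs) approximates "the spatially central plots";
  it is a deterministic stand-in for a geographic choice the emulated
  design made by hand, and is labelled as such in its output.
* The residual-validation fallback trades strictness for coverage on
  saturated curves; selections made through it carry `fallback = TRUE`
  and should be read as "best available description", not "validated
  model".
* Bootstrap-over-plots treats plots as exchangeable; spatial
  autocorrelation between nearby plots is ignored, which narrows the
  bands somewhat on strongly structured landscapes.
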