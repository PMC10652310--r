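---
title: "Methods: the two-phase ageing model and Smurf/age deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-phase ageing model and Smurf/age deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling assumptions, numerical choices and
known limitations behind `smurfdeconv`. The package implements a two-phase
view of ageing in *Drosophila*: individuals spend most of life in a healthy
phase, then switch — detectably, via intestinal-permeability ("Smurf")
staining — into a terminal phase with high, roughly constant mortality.
Because the proportion of Smurfs rises with age, any bulk measurement taken
on unlabeled, age-binned animals mixes two physiological states, and effects
of the terminal phase masquerade as effects of chronological age. The
package provides both the demographic machinery of the two-phase model and
the statistical machinery to undo that confounding in transcriptomic data.

## 1. The two-phase demographic model

An individual transitions from the non-Smurf to the Smurf state with hazard
$\lambda(t)$ and, once a Smurf, dies with constant hazard $h$. The default
transition hazard is linear in age, $\lambda(t) = c\,t$, so transition ages
follow $T = \sqrt{2E/c}$ with $E \sim \mathrm{Exp}(1)$ (inverse-CDF
sampling in `simulate_cohort()`). A constant-hazard variant
($\lambda_0 > 0$) is also supported. The default Smurf mortality is
calibrated so that the median remaining lifespan after transition is 2.04
days: $h = \log 2 / 2.04$.

Three routes to the same demography are implemented and cross-checked:

1. **Closed form.** Under the quasi-static approximation the Smurf
   proportion among live animals is well described by a clipped line
   $p(t) = \min(\max(a t + b, 0), 1)$, and population survival is
   $S(t) = \exp(-h \int_0^t p(u)\,du)$, integrable in closed form
   (`closed_form_survival()`). The quasi-static slope is $a = c/h$.
2. **Compartment ODE.** $n_{NS}' = -\lambda n_{NS}$,
   $n_S' = \lambda n_{NS} - h n_S$, solved with `deSolve::lsoda` at
   `rtol = 1e-10` (`prevalence_curve()`).
3. **Stochastic cohort.** Individual-level simulation
   (`simulate_cohort()`), the generator behind all synthetic longevity
   tables.

Routes 2 and 3 agree to Monte-Carlo accuracy. Route 1 differs from them by
a factor of order $e^{a t_{lag}}$ with $t_{lag} \approx 1/h$ — the
quasi-static line ignores the finite time spent dying — so the closed form
is validated against direct numerical integration of its own hazard (to
$10^{-3}$), and the stochastic cohort against the compartment ODE (within
binomial confidence bands). The three-way chain, rather than a single
three-way tolerance, is deliberate: the quasi-static approximation error is
a property of the model, not a bug in the integrator.

## 2. The synthetic expression generator

`generate_gene_truth()` and `simulate_counts()` produce negative-binomial
counts for a biphasic cohort. The default design is the study condition the
package is calibrated for: 16 Smurf and 16 non-Smurf samples at ages 20, 30
and 40 days (5/6/5 per state), 15,364 genes.

For gene $g$ in sample $j$ the mean is

$$\mu_{gj} = s_j\,\mu_g\,2^{\beta_S S_j + \beta_A (a_j - 20)/10 +
\beta_I S_j (a_j - 20)/10},$$

with lognormal baseline $\mu_g$ (`meanlog = 7`, `sdlog = 1`, matching the
scale of typical whole-fly bulk libraries), lognormal size factors
($\sigma = 0.1$), and NB dispersion

$$\alpha_g(a) = \alpha_{0g}\,(1 + 3\,(a - 20)/20),$$

i.e. dispersion at 40 d is four times dispersion at 20 d. The baseline
$\alpha_{0g}$ is lognormal around 0.0025. This age-dependent overdispersion
is what makes the modal relative standard deviation (RSD) of expression
rise roughly two-fold from 20 to 40 days in both Smurf states — the
transcriptional-noise signature the deconvolution module quantifies.

Gene classes are drawn with fractions 10.5% Smurf-up, 9.1% Smurf-down,
about 2% age-linear and 15.1% old-Smurf interaction; Smurf effect sizes
$|\beta_S|$ follow a Gamma with mean 0.8 plus a 5% heavy tail, so a
minority of genes carry large, easily detected effects while most sit near
the detection boundary. Six hallmark tags (`ATH1`–`ATH6`) mark subsets of
these classes; `make_gene_sets()` splits each hallmark into two gene sets,
adds per-class sets, and adds decoy sets drawn from null genes so that
enrichment calibration can be checked on the same bundle.

## 3. Differential expression

Two deliberately independent estimators are exposed: `nb_wald_test()`
(negative-binomial GLM Wald test on unshrunken effect estimates) and
`nb_quasi_test()` (quasi-likelihood F-test). Both use median-of-ratios size
factors with a positive-counts fallback for matrices where no gene is
observed everywhere. Multiplicity is handled by Benjamini–Hochberg over the
tested subset only (`baseMean >= 1`); untested genes carry `NA` p- and
q-values rather than being silently dropped, so downstream joins stay
aligned with the input gene list. Agreement between the two estimators
(call overlap and log-fold-change correlation) is part of the test suite;
on the default study-size bundle the two agree on over 99% of calls.

## 4. Enrichment

`gsea()` is a from-scratch preranked weighted-KS enrichment: the running
enrichment score is computed in closed form from hit positions, the null is
a gene-label (membership) permutation preserving set size, p-values are
sign-stratified with the $+1$ correction $p = (1 + k)/(1 + n)$, and NES is
the score divided by the mean absolute same-sign permutation score. The
enrichment score itself is validated two ways: against an exhaustive
running-sum oracle on all small universes, and against an independent
implementation on real rankings, where the scores agree to machine
precision. Decoy gene sets on all-null generator bundles give p-values
consistent with the uniform distribution, which is the operationally
relevant calibration check.

## 5. Deconvolution

The deconvolution module asks, for each signal, *which axis drives it*:
Smurf state, chronological age within non-Smurfs, or age within Smurfs.

- `pca_factor_association()`: in a biphasic cohort the first principal
  component separates Smurfs from non-Smurfs and the second tracks age.
- `interaction_scan()`: vectorized per-gene OLS of log-normalized
  expression on Smurf state, age and their interaction (QR-based, one
  decomposition for all genes).
- `age_regression()`: genes tracking age *within non-Smurfs*
  ($p < 0.05$ and $R^2 > 0.5$), the stringent definition of a
  chronological-age gene.
- `rsd_analysis()`: per-group RSD distributions, their modal peaks
  (kernel density, `bw = "nrd0"`, 512-point grid anchored at zero) and
  old/young peak ratios per state.
- `correlation_map()` + `fasano_franceschini()`: each gene gets a 2-D
  coordinate (point-biserial correlation with Smurf state, Pearson
  correlation with age); each gene set is compared against its complement
  with a two-dimensional Kolmogorov–Smirnov test.
- `hallmark_attribution()`: precedence *chronological* (responsive in the
  non-Smurf age contrast) over *old-Smurf* over *Smurf-specific*, with a
  separate noise facet attributed chronological only when the RSD peak
  ratio exceeds 1.5 in **both** Smurf states.
- `mixture_projection()`: the algebra of the confounding itself — at
  prevalence $p$, bulk expression is $(1-p)\mu_{NS} + p\mu_S$, so a purely
  Smurf-associated gene acquires a spurious age slope in unlabeled samples.

### The two-dimensional KS statistic

The Fasano–Franceschini statistic is implemented in C++ with a Fenwick-tree
sweep ($O(n \log n)$ per evaluation). One convention deserves note: at
every origin the four quadrant probabilities are evaluated under **both**
the closed ($\le, \le$) and the strict ($<, <$) boundary conventions, and
the larger discrepancy is kept. This makes the statistic exact in the two
reference situations used to validate it — it reduces to the classical
one-sample-axis `ks.test` statistic when one coordinate is constant, and it
reaches $D = 1$ for samples confined to disjoint open quadrants — and it
matches an $O(n^2)$ brute-force oracle on ties-heavy integer grids.
Permutation p-values are computed inside the C++ loop with R's own RNG, so
`set.seed()` governs them.

## 6. Longevity statistics

`mean_lifespan()` computes death-table mean/median lifespans and percent
change versus a control (one decimal, matching standard reporting).
`fit_prevalence()` regresses Smurf proportion on day, per condition and
jointly with a day-by-condition interaction (control releveled first), with
optional precision weighting by the number of animals scored.

One scoring rule matters for unbiasedness: prevalence observations are
only taken while at least 20 animals remain alive
(`min_alive_prevalence = 20` in `simulate_longevity_tables()`). Late,
nearly empty cohorts produce wildly variable proportions whose average is
biased relative to the underlying curve; truncating at 20 alive keeps the
fitted slope within a few percent of the slope of the true prevalence curve
over the realistic slope range.

## 7. Limitations

- The quasi-static closed form is an approximation; for steep transition
  hazards its survival curve departs from the compartment solution at late
  ages. Use `prevalence_curve()` when exactness matters.
- With ~150 animals per condition scored weekly over 60 days, the power of
  the prevalence-slope interaction test for a two-fold slope difference is
  limited by the information in the weekly binomial counts; detecting such
  differences reliably requires larger cohorts or longer scoring windows.
- The negative-binomial generator models per-state means and age-scaled
  dispersion but not library-composition artefacts or batch structure.
- Gene-label permutation nulls (as in all preranked GSEA) ignore
  inter-gene correlation; decoy-set calibration on matched null bundles is
  the recommended sanity check on real data.

## 8. Reproducibility

All stochastic functions take explicit seeds; multi-stage procedures derive
per-stage seeds from a single master seed with `derive_seed()`, and
`with_seed()` guarantees the caller's RNG state is untouched. Pipeline
artifacts carry a configuration hash and the master seed in their headers,
and identical configurations yield byte-identical outputs.
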