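---
title: "Quantifying information flow in heterogeneous single-cell signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying information flow in heterogeneous single-cell signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question

Cells within one clonal population express signalling proteins at widely
varying copy numbers.  When a population is stimulated with a cytokine, two
questions arise:

1. **Robustness.** How strongly does each cell's response depend on its
   protein content?  If a cell with three times more STAT3 phosphorylates
   three times more STAT3, the output is a readout of protein abundance as
   much as of the stimulus.
2. **Information transfer.** How many distinct stimulus levels can the
   population response distinguish, given all the noise — intrinsic
   biochemical noise, measurement noise, and the cell-to-cell expression
   heterogeneity itself?

`cytoinfo` answers both with information theory, on two-colour
flow-cytometry data: per cell, an *expression* readout (e.g. total STAT3)
and a *response* readout (e.g. STAT3 pY705), across a ladder of cytokine
doses, time points, replicates and cell lines.

## Mutual information between expression and response

Robustness is quantified as the mutual information, in bits, between the two
continuous per-cell readouts within one (replicate, dose) stratum:

$$ MI(S;R) = \iint p(S,R)\,\log_2 \frac{p(S,R)}{p(S)\,p(R)}\; dR\, dS $$

Zero bits means the response carries no information about expression —
perfect robustness.  `estimate_mi_kde()` estimates the densities with a
Gaussian product-kernel KDE and integrates the integrand numerically:

* **Transform.**  Fluorescence is approximately lognormal; both margins are
  log10-transformed by default before estimation (`mi_dose_sweep()`'s
  `transform` argument; `arcsinh` and `none` are available).  Non-positive
  values cannot be log-transformed; they are dropped and counted.
* **Bandwidths.**  Scott's rule per coordinate, $h = \hat\sigma\,n^{-1/6}$,
  the standard normal-reference rule for a two-dimensional KDE.  A Silverman
  rule-of-thumb ($0.9\,\min(\hat\sigma, IQR/1.34)\,n^{-1/5}$) and fixed
  bandwidths are available.
* **Marginals.**  The marginals are the analytic marginals of the joint KDE
  (same kernels, same bandwidths), not independently refit, so joint and
  marginals are mutually consistent and the integrand is exactly zero for
  product-form data in the infinite-sample limit.
* **Integration.**  Adaptive two-dimensional quadrature (target 1e-4 bits)
  by default, with a fixed-grid Riemann integrator (256 points per axis)
  that matches it to well under 0.01 bits and is used for throughput in the
  dose sweeps.  The integrand is set to zero wherever the joint density
  falls below 1e-12, which avoids log-of-zero without affecting the value
  at the reported precision.
* **Smoothing-bias correction.**  A plug-in KDE integral is biased downward
  at strong dependence: convolving the data with the kernel shrinks the
  dependence (for a bivariate Gaussian, $\rho \mapsto \rho/(1+h^2)$, about
  −0.26 bits at $\rho = 0.9$, $n = 5000$ under Scott bandwidths).  The
  default estimator therefore evaluates the integral at $h$ and $h/\sqrt2$
  and extrapolates linearly in $h^2$ to $h \to 0$
  (`bias_correction = "extrapolate"`).  The residual error on bivariate
  Gaussians is below 0.05 bits for $\rho \le 0.9$ at $n = 5000$.  The cost
  is a small positive bias at independence (about +0.02 bits at $n = 5000$,
  +0.04 at $n = 2000$), which matters only near zero and is why near-zero
  estimates are interpreted as "at the noise floor" rather than as exact
  zeros.
* **Exclusion rule.**  Mutual information cannot be negative; a negative
  estimate indicates a numerically ill-conditioned stratum.  Such estimates
  are flagged `valid = FALSE`, reported with their raw value, and excluded
  from the per-dose aggregates (`summarize_mi_sweep()`), never clamped.
* **Stratum size.**  Strata below `min_cells` (default 100) are skipped
  with a warning rather than extrapolated.

Two independent cross-checks guard the estimator: the closed form
$-\tfrac12 \log_2(1-\rho^2)$ for bivariate Gaussians
(`mi_gaussian_closed_form()`), and an equal-frequency histogram plug-in
estimator (`estimate_mi_plugin()`), which is exactly invariant under
monotone rescaling and has a known positive bias bounded by the
Miller–Madow term.

```{r}
library(cytoinfo)
cells <- simulate_cells(sim_config(n_cells = 2000, seed = 1))
sweep <- mi_dose_sweep(cells)
summary(sweep)
plot(sweep)
```

## Channel capacity of the dose-response channel

The doses applied in an experiment form a finite input alphabet $S$; the
single-cell response distribution at each dose is the conditional
$p(R\,|\,S=s)$.  The channel capacity

$$ CC(S;R) = \max_{p(S)} MI(S;R) $$

is the maximal information any dose distribution could push through the
pathway; $2^{CC}$ is roughly the number of reliably distinguishable dose
levels.  Two estimation routes are provided:

* **Discretized Blahut–Arimoto** (`capacity_basic()`'s default): responses
  are binned into 20 equal-frequency bins (equal-frequency binning is
  invariant under monotone transforms), each dose's histogram is smoothed
  with a 0.5 pseudocount, and `blahut_arimoto()` solves the resulting
  discrete channel exactly — the iteration maintains a lower and an upper
  capacity bound and stops when the gap is below 1e-8 bits.  This route is
  exact given the discretization and serves as the oracle for the second.
* **Statistical-learning estimator** (`estimate_cc_classifier()`): a
  ridge-regularized multinomial logistic regression predicts the dose from
  basis-expanded (default quadratic), log10-transformed response features,
  trained under the empirical dose frequencies; per-cell posteriors are
  converted to likelihood ratios, reweighted to any candidate input
  distribution, and the same Blahut–Arimoto fixed point maximizes the
  Monte-Carlo MI over the input simplex.  The ridge penalty is chosen from
  a small fixed grid (1e-2, 1e-3, 1e-4) by held-out log-loss on a fixed
  80/20 split.  This route extends to multivariate responses, which the
  binned route cannot do well (a 12x12 product grid's pseudocounts dominate
  small strata).

**Capacity var.**  `capacity_var()` gives the decoder the
stimulus-independent expression covariate alongside the response
(`response_features = c("response", "expression")`).  Expression
heterogeneity blurs the response distributions *across* cells; a decoder
that knows each cell's expression can undo much of that blur.  The gap
between `capacity_var` and `capacity_basic` therefore measures how much
information heterogeneity destroys.

**Truncation sweep.**  `truncation_capacity_sweep()` makes the same point
experimentally: `truncate_heterogeneity()` removes extreme expressers
symmetrically (residual 0.90 = the central 90% of the expression
distribution) and both capacities are recomputed per replicate at each
residual level.  Basic capacity rises as heterogeneity is removed;
covariate-aware capacity stays approximately flat, because the covariate
already accounted for the heterogeneity.  Within the sweep the classifier's
ridge penalty is selected once per replicate on the full-heterogeneity data
and held fixed, so decoder complexity does not vary with truncation level.

Numerical notes for the capacity routes:

* Capacity is reported non-negative and never exceeds $\log_2(\#\text{inputs})$.
* Inputs with identical response distributions receive a deterministic
  weight split (the fixed point starts uniform and ties persist
  symmetrically).
* A dose level whose expected posterior mass falls below one cell flags the
  estimate `converged = FALSE` (degenerate fit) rather than erroring.
* The unstimulated dose 0 is part of the input alphabet by default
  (`channel_dataset(include_zero_dose = TRUE)`).
* Per-replicate capacities are the headline; pooled-replicate capacity is
  available by passing pooled cells.

```{r}
ds <- channel_dataset(cells[cells$replicate == "1", ])
capacity_basic(ds)
capacity_var(ds)
summary(truncation_capacity_sweep(cells))
```

## Gating and normalization

`gate_extreme_expressers()` selects the lowest and highest expression tails
(default 10% each) by rank with stable tie-breaking, for the classic
visual comparison: at a weak dose the two sub-populations' response
distributions overlap almost completely, at a saturating dose they
separate.  `overlap_coefficient()` quantifies this as
$\int \min(f_{low}, f_{high})$ via a shared-bandwidth KDE.

`normalize_experiment()` implements the common flow-cytometry convention of
scaling each experiment so its maximal per-dose mean fluorescence is 100%,
independently per replicate, time point and channel; raw values are kept
alongside and the operation is idempotent.

`truncate_heterogeneity()` has two semantics because "residual variability"
is used ambiguously in the literature: symmetric quantile trimming (the
default; residual 0.90 trims 5% from each tail and retains a predictable
cell count) and a mean-window variant (keep cells within
mean × (1 ± residual/2)), provided for sensitivity analysis.  Quantiles use
linear interpolation between order statistics; boundary ties are kept.

## The synthetic generator

`simulate_cells()` generates flow-cytometry-like datasets with the
statistical structure the analysis assumes, so that every estimator is
testable end-to-end without external data.  Per cell $i$ at dose $d$:

$$ E_i \sim \mathrm{LogNormal}(\mu, \sigma), \qquad
   h(d) = \frac{d^{n}}{d^{n}+K^{n}}, \qquad
   \kappa(d) = \frac{1}{1+\phi\,h(d)} \;\text{(only at } t=90\text{)} $$

$$ P_i = \beta\,\frac{E_i}{1+E_i/E_{sat}}\,h(d)\,\kappa, \qquad
   R_i = (P_i + \varepsilon_b)\,10^{\varepsilon_m}, \qquad
   E^{obs}_i = E_i\,10^{\varepsilon_m'} $$

with $\varepsilon_b \sim N(0, \sigma_b)$ truncated at $-P_i$
(non-negativity, by truncation rather than rejection for determinism) and
$\varepsilon_m, \varepsilon_m' \sim N(0, \sigma_{meas})$ in log10 units.

Defaults and what they emulate:

| parameter | default | meaning |
|---|---|---|
| `n_cells` | 10000 | cells per condition, the usual acquisition count |
| `doses` | 0–200 ng/ml, 12 levels | dose ladder saturating near 25 ng/ml |
| `n_replicates` | 3 | independent experiments |
| `expression_mu`, `expression_sigma` | ln 100, 0.5 | lognormal expression heterogeneity (CV ≈ 0.53) |
| `beta` | 1 | response gain at saturation |
| `cap_esat` | 150 | phosphorylation-capacity scale (see below) |
| `hill_K`, `hill_n` | 10 ng/ml, 1.5 | half-saturating dose and cooperativity |
| `sigma_b` | 20 | additive background noise floor (response units) |
| `meas_sigma` | 0.05 | multiplicative measurement noise (log10 units) |
| `feedback_phi` | 2 | late-time feedback attenuation strength |
| `gain_factor` | 1.8 | response-gain multiplier of the S727A-type scenario |

The **multiplicative-expression / additive-floor structure** is the minimal
model in which the expression–response coupling is dose-dependent: at low
dose the floor dominates and MI is near zero; at saturating dose the
response tracks expression and MI plateaus.  A purely multiplicative model
would make MI dose-invariant.

The **capacity saturation** $E/(1+E/E_{sat})$ encodes that a finite pool of
activated receptor/JAK complexes phosphorylates STAT3: when expression far
exceeds that capacity, extra protein is phosphorylated less efficiently and
the response decouples from expression.  This is what makes the
overexpression scenario *more* robust (lower MI) at high doses — without
it, scaling expression up cannot reduce MI, because MI is invariant under
monotone rescaling of a margin.  The default $E_{sat} = 150$ places
baseline cells (median expression 100) in the mildly saturated regime and
3-fold overexpressing cells deep in it.  It also flattens per-cell channel
quality across the expression range (low expressers are floor-limited, high
expressers capacity-limited), which is what keeps the covariate-aware
capacity approximately constant under truncation.  Setting
`cap_esat = Inf` recovers the purely multiplicative coupling.

Scenarios are pure parameter transforms, never branches in the sampling
code: `STAT3high` shifts `expression_mu` by ln 3 (3-fold overexpression),
`SOCS3ko` sets `feedback_phi = 0`, `S727Ahigh` combines the overexpression
shift with `beta * gain_factor`.  Random streams are split per
(replicate, dose) through a deterministic integer hash, so adding a dose
level leaves all other strata byte-identical.

What the generator does **not** emulate: cell-cycle or volume covariates,
doublets and debris (fixtures are pre-gated by construction), spectral
spillover, receptor-level stochasticity, or any mechanistic ODE kinetics.
Passing tests on synthetic data therefore demonstrate estimator
correctness under the stated statistical structure, not biological fidelity
of any particular parameter value.

## Problem sizes

The bundled analyses and the test-suite run at deliberately desk-scale
sizes: 2000 cells per condition (12 doses × 3 replicates) for the MI sweep
and the truncation sweep, 5000 paired draws for the Gaussian MI oracle, and
10000 cells per level for the classifier-vs-Blahut–Arimoto agreement
checks.  At these sizes the complete analysis runs in a few minutes on one
core; estimator accuracy at the full 10000-cells-per-condition acquisition
scale only improves.

## Analysing real data

`load_cells()` reads tidy CSV (canonical columns `expression, response,
dose, time, replicate, line`) and FCS 3.0/3.1 list-mode files.  FCS files
carry no stimulus metadata, so dose/time/replicate/line come from a JSON
sidecar (`<file>.fcs.json`) or the `metadata` argument — one acquisition
per condition is assumed.  Spectral compensation is not applied.
`run_robustness_analysis()` and `run_capacity_analysis()` orchestrate the
per-stratum analyses from an `analysis_config` (YAML/JSON loadable) and
write tidy CSV plus a manifest embedding the resolved configuration, seed
and package version; identical configs reproduce byte-identical outputs.
`run_deposited_analysis()` points the capacity profile at a local copy of a
deposited dataset and reports computed capacities next to published
reference values (0.7 bits at full heterogeneity, 1.0 bits at 15% residual
variability for early-response MEF data); it never downloads anything and
skips cleanly when the data are absent.

## Known limitations

* The KDE MI estimator's extrapolation trades the large smoothing bias for
  a small positive bias near independence; MI differences below ~0.05 bits
  should not be over-interpreted at these sample sizes.
* The classifier capacity estimator evaluates posteriors in-sample, as is
  conventional for this estimator family; at a few hundred cells per dose
  this inflates capacity by a few hundredths of a bit.
* Equal-frequency binning collapses bins over point masses (e.g. exact
  zeros from unstimulated cells), so the effective output alphabet can be
  smaller than requested.
* The covariate-aware capacity is only approximately flat under truncation
  even in the generator's ground truth: cells whose expression sits at the
  noise floor are genuinely less informative to any decoder.
* No k-nearest-neighbour MI estimator and no continuous-input capacity are
  provided; the input alphabet is the finite applied dose set.
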