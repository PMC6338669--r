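# cytoinfo

Information-theoretic analysis of single-cell signalling dose-response data.

Clonal cell populations are heterogeneous: protein copy numbers vary several-
fold between cells. For anyone studying cytokine signalling with multiplexed
flow cytometry (e.g. total STAT3 vs STAT3 pY705 across a dose ladder of
IL-6-type stimulation), two quantitative questions follow:

* **Robustness** — how much does a cell's phospho-response depend on its
  protein expression? Measured as the mutual information (bits) between the
  two per-cell readouts at each dose:

  $$MI(S;R) = \iint p(S,R)\,\log_2\frac{p(S,R)}{p(S)p(R)}\,dR\,dS$$

* **Information transfer** — how many stimulus levels can the response
  resolve? Measured as the channel capacity of the dose→response channel,
  $CC = \max_{p(S)} MI(S;R)$, where $2^{CC}$ is roughly the number of
  distinguishable dose levels.

The package provides: KDE-based MI estimation with numerical integration and
a smoothing-bias correction, plus histogram and closed-form oracles; an exact
Blahut–Arimoto solver on discretized channels and a statistical-learning
capacity estimator (regularized multinomial classifier + Monte-Carlo input
optimization) that also computes the covariate-aware "capacity var"
(decoder conditions on expression); expression-tail gating,
heterogeneity truncation and per-experiment normalization; FCS 3.0/3.1 and
tidy-CSV input; and a synthetic flow-cytometry generator with scenario knobs
(overexpression, feedback knockout, elevated gain) so the full analysis is
testable end-to-end without external data.

## Worked example

```r
library(cytoinfo)

# a synthetic experiment: 12 doses x 3 replicates x 2000 cells
cells <- simulate_cells(sim_config(n_cells = 2000, n_replicates = 3, seed = 1))

# robustness: MI(expression; response) per replicate and dose
sweep <- mi_dose_sweep(cells)
print(sweep)
#> <mi_sweep> 33 stratum estimate(s), 0 invalid (MI < 0), 0 skipped
#> per-dose summary over valid replicate estimates:
#>     dose mi_median  mi_q25  mi_q75 n_replicates n_excluded
#> 1    0.5   0.05262 0.05031 0.05662            3          0
#> 5   10.0   0.12985 0.12099 0.13039            3          0
#> 7   25.0   0.23328 0.23206 0.25450            3          0
#> 10 100.0   0.34095 0.33699 0.35765            3          0
#> 11 200.0   0.34380 0.33456 0.35750            3          0
```

At sub-saturating doses the response sits at the noise floor and carries
almost no information about expression (robust signalling, ~0.05 bits); as
the dose saturates the pathway, the response increasingly tracks protein
content and MI plateaus around 0.34 bits.

```r
# capacity of the dose -> response channel, one replicate
ds <- channel_dataset(cells[cells$replicate == "1", ])
capacity_basic(ds)
#> Channel capacity = 0.6575 bits (1.58 distinguishable states) [blahut_arimoto]
capacity_var(ds)
#> Channel capacity = 0.6721 bits (1.59 distinguishable states) [classifier]
```

Despite 12 applied doses, the channel resolves fewer than two reliably
distinguishable stimulus levels (~0.66 bits). The covariate-aware capacity
(decoder knows each cell's expression) is slightly higher; the gap widens
when heterogeneity is larger. The truncation sweep
(`truncation_capacity_sweep(cells)`) shows the mirror image: removing
extreme expressers raises the basic capacity while the covariate-aware
capacity stays flat.

To analyse real data, read it with `load_cells()` (CSV or FCS + JSON
sidecar) and run the same functions, or orchestrate whole studies with
`run_robustness_analysis()` / `run_capacity_analysis()` from an
`analysis_config()`.

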