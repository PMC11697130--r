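# spotts

Nonparametric Bayesian cell typing for single-cell resolution spatial
transcriptomics (MERFISH, STARmap, Slide-seq and similar platforms).

`spotts` clusters cells using both their gene-expression principal
components and their spatial coordinates, and — unlike most spatial
clustering tools — learns the number of cell types from the data instead
of requiring it up front. It is aimed at analysts doing exploratory cell
typing on single-cell ST sections, and at methods people who want a
carefully tested reference implementation of the underlying sampler.

## Model

Cell labels $C_i$ follow a Potts model on a directed k-nearest-neighbour
graph of the cell positions, with countably many states:

$$
\mathbb{P}(\mathbf{C} \mid \beta, \{\pi_\ell\}) \propto
\prod_{i=1}^n \pi_{C_i}\,
\exp\Big\{\beta \sum_i \sum_{j \in \mathrm{Nei}_k(i)}
\mathbb{I}(C_i = C_j)\Big\},
$$

where $\beta > 0$ measures spatial coupling between neighbouring cells
and the external-field weights $\{\pi_\ell\}$ carry a stick-breaking
prior ($\xi_\ell \sim \mathrm{Beta}(1,\alpha)$,
$\pi_\ell = \xi_\ell \prod_{m<\ell}(1-\xi_m)$), so the number of occupied
clusters is unbounded a priori. Given its label, a cell's top-$H$ PC
vector is Gaussian: $Y_{hi} \mid C_i=\ell \sim
\mathrm{N}(\eta_{h\ell}, \sigma_h^2)$.

Inference is a partially collapsed Gibbs sampler: slice augmentation
truncates the infinite label space to finite per-cell candidate sets; a
sequential sweep updates labels; emission means and variances have
conjugate updates; and $(\beta, \{\xi_\ell\})$ are updated jointly by an
exchange (double Metropolis–Hastings) step that cancels the intractable
Potts normalising constant by simulating an auxiliary label field under
the proposed parameters. Small-instance enumeration oracles, built into
the package, verify every kernel against the exact distribution. See the
methods vignette (`vignettes/spatial-potts-cell-typing.Rmd`) for the
full model, defaults and design decisions.

## Worked example

Simulate a section with four spatially coherent cell types and recover
them without telling the model the answer is four:

```r
library(spotts)

sim <- simulate_st_data(sim_config(seed = 1))   # 500 cells, K_true = 4
fit <- fit_potts_celltypes(sim$pcs, coords = sim$coords, k = 6,
                           config = mcmc_config(n_iter = 2000,
                                                burn_in = 1000,
                                                seed = 1001, init_k = 4))
fit
#> Nonparametric spatial Potts cell-typing fit
#>   cells: 500   k = 6
#>   iterations: 2000 (burn-in 1000 , stored 1000 )
#>   estimated cell types: 4
#>   posterior beta: 1.016 (mean)   exchange acceptance: 0.236

adjusted_rand_index(fit$point_labels, sim$labels)
#> [1] 1
```

The fit reports 4 estimated cell types (the occupied-cluster count of
the posterior point clustering), a posterior mean spatial interaction
$\beta \approx 1.02$ — close to the generating value 1 — and a 24%
acceptance rate for the exchange proposals. The adjusted Rand index of 1
means the point clustering reproduces the ground-truth partition
exactly. `tidy(fit)`, `glance(fit)`, `autoplot(fit)`,
`plot_cell_labels(sim$coords, fit$point_labels)` and
`chain_diagnostics(fit)` give traces, summaries, maps and stability
checks.

For real data, start from `read_expression()` / `read_coordinates()` and
`preprocess_pcs()` (library-size normalisation, `log1p`, top-50 PCs). A
thin command-line wrapper with `simulate` / `preprocess` / `fit` /
`evaluate` / `self-check` subcommands is installed at
`inst/cli/stpotts.R`.

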