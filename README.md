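# ionrank

Rank proteins of a protein–protein interaction (PPI) network by predicted
essentiality. Essential proteins — those whose deletion is lethal — are
both evolutionarily conserved and clustered inside protein complexes.
`ionrank` exploits both signals: it seeds every protein with an
orthology-derived conservation score and propagates scores along edges
weighted by how strongly they participate in local community structure.
The package is aimed at computational biologists who have a PPI edge list
and precomputed ortholog memberships and want a ranked candidate list of
essential proteins, together with the standard baselines and evaluation
machinery to judge it.

## The model

For a network $G = (V, E)$ with $N$ proteins, each protein gets an
orthologous score $d(i) = o(i) / \max_j o(j)$, where $o(i)$ is the number
of reference organisms containing an ortholog of $i$. Each edge gets an
edge clustering coefficient

$$\mathrm{ECC}_{ij} = \frac{Z_{ij}}{\min(k_i - 1, k_j - 1)},$$

with $Z_{ij}$ the triangles on the edge and $k_i, k_j$ the endpoint
degrees. Row-normalising the ECC matrix gives the propagation operator
$H$ (each row sums to 1 or 0), and the ranking score is the fixed point of

$$pr = (1 - \alpha)\,d + \alpha\,H\,pr, \qquad 0 \le \alpha < 1,$$

solved by Jacobi iteration from $pr^0 = d$ until the L1 change drops
below $\varepsilon$ (defaults: $\alpha = 0.5$, $\varepsilon = 10^{-6}$).
Seven baseline centralities (degree, betweenness, closeness, subgraph,
eigenvector, information, and summed-ECC centrality) and four evaluation
instruments (top-K% accuracy, precision–recall curves with AUC, jackknife
curves with random-assortment controls, connectivity/overlap breakdowns)
round out the toolkit, plus a seeded synthetic benchmark generator with
planted complexes and conservation-shifted ortholog counts.

## Worked example

```r
library(ionrank)

bench <- generate_benchmark(synthetic_config(seed = 42))
bench
#> <ion_benchmark> 1000 proteins, 4590 interactions, 221 essential, 20 planted complexes (seed 42)

res <- run_ion(bench$network, bench$orthology, ion_config(alpha = 0.5))
glance(res)
#> # A tibble: 1 × 6
#>   n_proteins alpha  epsilon iterations final_residual converged
#>        <int> <dbl>    <dbl>      <int>          <dbl> <lgl>
#> 1       1000   0.5 0.000001         16    0.000000900 TRUE

head(tidy(res), 5)
#> # A tibble: 5 × 4
#>    rank protein score ortholog_score
#>   <int> <chr>   <dbl>          <dbl>
#> 1     1 P0537   0.870          1
#> 2     2 P0753   0.838          0.952
#> 3     3 P0498   0.819          0.976
#> 4     4 P0953   0.803          0.976
#> 5     5 P0896   0.794          0.929

top_k_accuracy(res$scores, bench$essentials)
#> # A tibble: 6 × 4
#>   k_percent n_candidates n_essential accuracy
#>       <dbl>        <int>       <int>    <dbl>
#> 1         1           10          10    1
#> 2         5           50          49    0.98
#> 3        10          100          99    0.99
#> 4        15          150         139    0.927
#> 5        20          200         168    0.84
#> 6        25          250         176    0.704
```

The converged solver took 16 Jacobi sweeps; the top candidates combine a
high conservation score with membership in dense complexes. Compared with
plain degree centrality on the same instance:

```r
precision_recall(res$scores, bench$essentials)$auc
#> [1] 0.8497817
precision_recall(degree_centrality(bench$network), bench$essentials)$auc
#> [1] 0.4663991

jk <- jackknife_curve(res$scores, bench$essentials, n_random = 10, seed = 42)
jk$area          #> 0.925 — min–max normalised (random ≈ 0.5, perfect = 1)
autoplot(jk)     # cumulative-hit curve over the 10 grey random controls
```

Real data enters through three plain-text readers:
`read_ppi_edgelist()` (two-column TSV, self-interactions and repeats
dropped), `read_orthology_pairs()` (protein/organism pairs), and
`read_essential_list()`; `write_ranking()` emits the tie-broken ranked
table. A thin command-line wrapper with `rank`, `baselines`, `evaluate`,
`simulate`, `sweep-alpha` and `sweep-organisms` subcommands lives at
`inst/cli/ion.R` and writes a `manifest.json` beside every output.

See `vignettes/ion-methods.Rmd` for the full account of the model,
parameter defaults, numerical conventions, what the synthetic generator
does and does not emulate, and known limitations.

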