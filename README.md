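# otunet

Selecting an ecologically optimal OTU clustering threshold for amplicon
data by AIC on a bipartite OTU×plot network — with the downstream
network-ecology statistics (generalists, specialists, endemics,
singletons, co-occurrence clustering) computed on the selected network.

## The problem

Surveys of protein-coding marker genes (such as *nirS*, a marker for
denitrifying bacteria) have no natural analogue of the 16S rRNA "97%"
OTU convention: each gene diverges at its own rate, so the similarity
level at which sequence variants become ecologically interchangeable
must be inferred from the data. `otunet` does this by treating every
candidate clustering as a statistical model of where sequences occur
and how abundant they are, and letting AIC pick the clustering that
compresses the community most without losing ecological signal.

## The model

Cluster the `S` dereplicated sequence types at similarity `s` into `k`
OTUs over `r` plots. With `S_i` members in OTU `i` and `L_iq` of them
present in plot `q`, the occurrence probability is `p(iq) = L_iq/S_i`
and the binary network log-likelihood and AIC are

```
LL(iq)  = L_iq log p(iq) + (S_i − L_iq) log(1 − p(iq)),   0 log 0 = 0
AIC     = 2kr + 2S − 2 Σ_iq LL(iq)
```

Abundances `a_jiq` enter through a within-OTU exchangeability model —
Poisson with mean `λ = a_.iq/S_i` (default) or Binomial
`(size = a_.iq, p = 1/S_i)` — adding `2kr` parameters:

```
AIC_w   = 4kr + 2S − 2 Σ_iq [ LL(iq) + LL_A(iq) ]
```

The similarity grid (default 74–99%) is scanned by cutting one
average-linkage tree built on exact global-alignment identities, and
the threshold minimising `AIC_w` is selected (ties go to the lower,
more parsimonious threshold). See the vignette
(`vignettes/threshold-selection.Rmd`) for the full model, conventions
and design choices.

## Worked example

On a synthetic community with known structure (8 plots in duplicated
nitrogen-dose treatments, 5 core OTUs plus dose-scaled plot endemics,
~300 reads/plot of 432 bp sequences):

```r
library(otunet)

cfg <- sim_config(seed = 42)
sim <- simulate_community(cfg)
res <- otu_pipeline(sim$records, doses = cfg$doses)

glance(res$curve)
#> # A tibble: 1 × 5
#>   optimal_threshold     k aic_min selection    model
#>               <int> <int>   <dbl> <chr>        <chr>
#> 1                74    15   2076. aic_weighted poisson
```

The selected clustering has 15 OTUs: the 5 planted core OTUs (all
generalists, present in 6–8 plots) and 10 planted endemics:

```r
dplyr::count(res$profiles, class)
#> # A tibble: 2 × 2
#>   class          n
#>   <fct>      <int>
#> 1 generalist     5
#> 2 specialist    10

res$gradient
#> # A tibble: 8 × 4
#>   plot   dose proportion_generalist_sequences proportion_specialist_sequences
#>   <chr> <dbl>                           <dbl>                           <dbl>
#> 1 P1     0                              1                             0
#> 2 P2     0                              1                             0
#> 3 P3     0.85                           0.997                         0.00314
#> 4 P4     0.85                           0.983                         0.0166
#> 5 P5     2.52                           1                             0
#> 6 P6     2.52                           0.988                         0.0116
#> 7 P7     7.56                           0.940                         0.0598
#> 8 P8     7.56                           0.905                         0.0952
```

The specialist (plot-endemic) share of sequences rises with the
nitrogen dose, while generalist OTUs still dominate every plot — the
occupancy structure the generator plants. `recovery_check()` runs the
whole pipeline against the ground truth:

```r
recovery_check(cfg)
#> # A tibble: 1 × 9
#>   optimal_threshold k_selected k_planted   ari gap_ok gap_low_pct gap_high_pct ...
#> 1                74         15        15     1 TRUE          53.6         97.2
```

Adjusted Rand index 1: the AIC-selected partition is exactly the
planted one, at a threshold strictly inside the realized identity gap
(here 53.6–97.2%). `autoplot(res$curve)` draws the AIC curve,
`plot_cooccurrence(res$cooccurrence)` the plot co-occurrence heatmap.

A shell entry point wrapping the same functions is installed at
`system.file("scripts", "otunet", package = "otunet")`, with
subcommands `derep`, `scan-aic`, `ecology`, `simulate` and `run-all`.

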