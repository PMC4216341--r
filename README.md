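# ethnoconsensus

Quantitative analysis of ethnomedicinal field surveys in R: informant
consensus and fidelity statistics over use reports, descriptive
frequency tabulations, and two-mode ailment–plant network analysis,
plus a seeded survey simulator so every stage is testable without raw
field data.

## Who this is for

Ethnobotanists and ethnopharmacologists who interview informants about
medicinal plant use and need the standard quantitative summaries of
such surveys, reproducibly and from tidy tables. The atomic record is
the **use report**: one informant citing one plant species for one
ailment, with plant part, preparation mode and administration route as
attributes. Duplicated `(informant, species, ailment)` triples are
merged by attribute-set union so no index denominator is inflated.

## The statistics

For an ailment category with `nur` use reports citing `nt` distinct
species, the **informant consensus factor** is

    ICF = (nur − nt) / (nur − 1)

ICF approaches 1 when informants converge on few species and 0 when
every citation names a different species. For a species cited `N`
times, `Np` of them for one specific ailment, the **fidelity level** is

    FL = 100 · Np / N

so a species' FL values across its ailments always sum to 100. The
network stage arranges the same data as an ailment-category × species
incidence matrix, exports it in UCINET DL, GraphML and edge-list
formats, projects it onto categories by shared species, and groups
categories by greedy modularity maximisation with a seeded
force-directed layout for display.

The survey simulator draws per-category species preferences from a
symmetric Dirichlet(α/S) and Poisson citation attempts per informant,
with a ledger of ground truth; α tunes consensus from one-species
convergence (ICF → 1) to uniform pool use.

## A worked example

Reproduce a published consensus table from its printed `(nt, nur)`
counts:

```r
library(ethnoconsensus)
counts <- readr::read_csv(system.file("extdata", "gayasan_icf_counts.csv",
                                      package = "ethnoconsensus"))
icf_from_counts(counts)
#> # A tibble: 16 × 6
#>   category                        nt   nur icf_printed   icf icf_2dp
#>   <chr>                        <dbl> <dbl>       <dbl> <dbl>   <dbl>
#> 1 Muscular-skeletal disorders     49  2142        0.98 0.978    0.98
#> 2 Pains                           87  2942        0.97 0.971    0.97
#> 3 Respiratory system disorders    46  1513        0.97 0.970    0.97
#> 4 Liver complaints                15   447        0.97 0.969    0.97
#> 5 Cuts and wounds                 20   473        0.96 0.960    0.96
#> # ℹ 11 more rows
```

The `icf_2dp` column (full-precision ICF rounded half-up to two
decimals) reproduces every printed value. On a synthetic survey:

```r
cfg <- survey_config(n_informants = 40,
                     categories = default_categories()[1:4],
                     n_species = 60, pool_size = 25,
                     lambda = 2, alpha = 3, seed = 2026)
sim <- generate_survey(cfg)
category_consensus_table(sim$reports)
#> # A tibble: 4 × 6
#>   category                        nt   nur   icf icf_2dp degenerate
#>   <chr>                        <int> <int> <dbl>   <dbl> <lgl>
#> 1 Muscular-skeletal disorders      5    62 0.934    0.93 FALSE
#> 2 Pains                            7    49 0.875    0.88 FALSE
#> 3 Respiratory system disorders    10    63 0.855    0.85 FALSE
#> 4 Liver complaints                11    55 0.815    0.81 FALSE

flora_coverage(200, 542)
#> [1] 36.9
```

At `alpha = 3` the four categories land at moderately high consensus
(5–11 species absorbing ~50–63 citations each); lowering `alpha`
drives `nt` toward 1 and ICF toward 1. `run_pipeline()` chains
validation, indices, network analysis and reporting into one output
directory with a manifest, deterministically for a fixed seed.

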