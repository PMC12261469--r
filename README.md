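# lapaint

Site-based **local ancestry inference** (LAI) for admixed haplotypes, built
on a compact population-graph representation of the reference panel.

Local ancestry inference assigns an ancestral population label to every
site of an admixed individual's haplotype — the per-segment counterpart of
global ancestry estimates, and an input to admixture mapping,
ancestry-aware GWAS, and ancestry-specific polygenic scores. `lapaint` is
aimed at population-genetics analysts who have a phased (or unphased)
labeled reference panel and phased query haplotypes in VCF, plus a genetic
map, and want per-site ancestry calls and tract segments.

## The model

A reference panel of m haplotypes over n sites with p population labels is
collapsed, site by site, into the set of unique (allele, population)
pairs — the *compact population graph* G′. Collapsing keeps at most 2p
nodes per bi-allelic site regardless of panel depth, and the only
between-population information that survives is the set of **discrete
ancestry informative markers (dAIMs)**: sites where some allele is present
in one population's panel but absent from another's.

A query haplotype Q = (q₁, …, qₙ) is painted by the minimum-penalty
threading path P = (u₁, …, uₙ) through G′:

```
f(P) = Σⱼ d(a(qⱼ), a(uⱼ))  +  w · Σⱼ r(l(uⱼ), l(uⱼ₊₁))
```

where d(·,·) is a 0/1 allele mismatch, and r(·,·) is 0 within a population
and R′ⱼ,ⱼ₊₁ between populations. R′ is the min–max-normalized reciprocal of
the local recombination rate (cM/Mb from the genetic map),
R′ = 2/(Rnorm + 1) ∈ [1, 2]: switching ancestry is cheapest across
recombination hotspots and dearest across cold regions. The scale factor
`w` (default 1.5) balances the two penalty kinds. Because within-population
switches are free, the dynamic program runs over population states in
O(np) time; an exhaustive enumeration oracle verifies its optimality in
the test suite.

## Worked example

Everything below is synthetic and generated in code — no downloads.

```r
library(lapaint)

scenario <- sim_scenario(p = 3, n_sites = 2000, n_ref_per_pop = 60,
                         n_queries = 40, generations = 15, seed = 42)
sim <- simulate_scenario(scenario)

graph <- build_compact_graph(sim$panel)
graph
#> <compact_population_graph> 2000 sites, 3 populations, K=2; node-set sizes 3..6 (mean 5.68)
#>   dAIMs: 462 of 2000 sites

penalties <- compute_switch_penalties(graph, sim$map)
penalties
#> <switch_penalties> 1999 intervals; raw rate 0.1..37.56 cM/Mb; penalties 1.0000..2.0000

paintings <- infer_queryset(graph, penalties, sim$queries)
glance(paintings[[1]])
#> # A tibble: 1 × 7
#>   query_id n_sites n_switches total_cost mismatch_cost_sum switch_cost_sum     w
#>   <chr>      <int>      <int>      <dbl>             <dbl>           <dbl> <dbl>
#> 1 Q0001_1     2000          0          4                 4               0   1.5

evaluate_painting(paintings, sim$truth, sim$queries, mac_threshold = 10)
#> <lai_evaluation> accuracy 0.9560, mean r2 0.8699 over 954 markers (1046 filtered)
```

Reading the output: the panel collapses to ≤ 6 nodes per site with 462
dAIMs carrying the ancestry signal; the first query haplotype is painted
as a single tract whose total penalty decomposes into 4 mismatches and no
switches; and against the simulated truth, 95.6% of retained
(haplotype, marker) labels are correct, with a population-averaged
ancestry-dosage r² of 0.87 after the minor-allele marker filter.
`tidy()` turns paintings, penalties, graphs and evaluations into tibbles;
`autoplot()`/`plot_paintings()` draw tract bars and penalty tracks.

A command-line wrapper (`inst/scripts/lapaint`) exposes the same pipeline
as `lapaint build | infer | simulate | evaluate` for VCF-in/TSV-out use:

```sh
lapaint infer --ref panel.vcf --pop-map pops.tsv --query q.vcf \
       --genetic-map chr.map --w 1.5 --out run
```

which writes `run.painting.tsv` (per-site labels) and `run.segments.tsv`
(half-open ancestry tracts). `build` serializes the compact panel as a
small population-template VCF that can replace `--ref` in later runs.

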