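---
title: "Local ancestry inference with compact population graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local ancestry inference with compact population graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapaint)
```

## The problem and the model

An admixed individual's chromosome is a mosaic of segments inherited from
different ancestral populations. Local ancestry inference (LAI) labels
each site of a query haplotype with the population it was copied from,
given a reference panel of haplotypes with known population labels. The
classical framing is the Li–Stephens haplotype-copying model: the query is
an imperfect mosaic of reference haplotypes, mismatches play the role of
mutation, and template switches the role of recombination.

`lapaint` implements a deliberately simplified, site-based variant of this
model with two structural choices:

1. **Collapsing.** At every site the panel is reduced to the set of
   distinct (allele, population) pairs observed there — the *compact
   population graph*. Node sets have at most $Kp$ members ($2p$ for
   bi-allelic data) however deep the panel is. After collapsing, the only
   between-population signal left is the *discrete ancestry informative
   markers* (dAIMs): sites where an allele is present in one population's
   panel and absent from another's.
2. **Free within-population switching.** The template-change penalty is
   zero within a population. This is what makes collapsing lossless for
   the optimum: the best node of each population at a site is always
   reachable, so the state space shrinks from haplotypes to populations.

A query $Q=(q_1,\dots,q_n)$ is painted by the minimum-penalty threading
path $P=(u_1,\dots,u_n)$ through the graph,

$$f(P) \;=\; \sum_{j=1}^{n} d\!\left(a(q_j), a(u_j)\right)
\;+\; w \sum_{j=1}^{n-1} r\!\left(l(u_j), l(u_{j+1})\right),$$

with $d$ a 0/1 allele mismatch and $r$ equal to 0 within a population and
to the recombination-scaled penalty $R'_{j,j+1}$ between populations. The
path's population labels are the ancestry calls.

## Switch penalties from the genetic map

For each adjacent site pair the raw recombination rate is the genetic
distance over the physical distance (cM/Mb), with cM at site positions
obtained by piecewise-linear interpolation of the map. Rates are min–max
normalized over the analyzed region's $n-1$ intervals and passed through
the reciprocal transform

$$R' = \frac{2}{R_{\mathrm{norm}} + 1} \in [1, 2],$$

so the hottest interval costs 1 and the coldest 2 — switching ancestry is
cheapest where recombination is most likely. Keeping $R'$ within one order
of magnitude of the 0/1 mismatch cost prevents either penalty from
dominating; the scale factor $w$ does the fine balancing.

Numerical conventions, chosen where the formulation is silent:

* **Interpolation/extrapolation.** Linear between map anchors; beyond the
  map, constant extrapolation of the flanking interval's rate, never
  negative. Negative interpolated cM differences are clipped to 0, and a
  zero physical gap defines rate 0 (fully linked).
* **Degenerate normalization.** If every interval has the same raw rate,
  min–max normalization is undefined; we set $R_{\mathrm{norm}} = 0$, so
  all penalties equal 2, and warn. Rationale: with no rate signal, only
  mismatch evidence should drive switches, and 2 is the transform's limit
  as $R_{\mathrm{norm}} \to 0$. Normalization is always computed over the
  analyzed region (one chromosome per run), not per map file.

## The dynamic program and its conventions

With population states the recurrence is

$$C_{1}(l) = m_{1}(l), \qquad
C_{j}(l) = m_{j}(l) + \min\!\left( C_{j-1}(l),\;
\min_{l' \neq l} C_{j-1}(l') + w R'_{j-1,j} \right),$$

where $m_j(l)$ is 0 if the query allele at $j$ is present in population
$l$'s node set and 1 otherwise — $O(np)$ time and memory. The test suite
verifies exact optimality against two independent oracles: exhaustive
enumeration over all $p^n$ label paths on small instances, and a
node-level dynamic program over the uncollapsed (allele, population)
states.

* **Tie-breaking.** Among equal-cost predecessors the path stays in its
  population (fewer switches); remaining ties take the lowest population
  index, and the final site does the same. Applied from the last site
  backwards this defines a total order, which the enumeration oracle
  reproduces, so outputs are deterministic and the oracle comparison can be
  exact. The lowest-index rule is intentionally not equivariant under
  relabeling populations when optima are exactly tied.
* **Missing data.** A missing query allele scores 0 against every
  population — an uninformative site should not induce switches. A
  population with no observed allele at a site (all genotypes missing)
  scores `missing_population_cost` (default 1): absence of evidence is a
  mismatch, never better than an explicit match.
* **Marker masks.** `infer_queryset(marker_mask = ...)` treats excluded
  sites as uninformative (cost 0 for every population) while keeping their
  intervals in the path, rather than splicing them out; distances and
  switch penalties are unchanged.
* **Ablation.** `penalty_params(within_population_switch_cost = c)`
  restores a uniform within-population template-change term $c\,w R'$ on
  every non-switching step. Setting $c > 0$ can only raise path costs and
  blunts the relative advantage of staying, which degrades discrimination
  — the reason the model fixes it at 0 by default.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `w` | 1.5 | scale between mismatch and switch penalties; larger values produce fewer, longer tracts, and the limit is a single best population |
| `within_population_switch_cost` | 0 | ablation switch, see above |
| `missing_population_cost` | 1 | site cost for a population with no node |
| `maf_threshold`, `mac_threshold` | 0.005, 50 | marker filter before evaluation: a site is excluded when its minor allele frequency **or** count is at or below the cutoff |
| `prune_rare_alleles()` threshold | 0 (off) | population-level masking of alleles below a frequency, applied before collapsing |

The default `w = 1.5` keeps one switch (cost $wR' \in [1.5, 3]$) on the
order of a handful of mismatches, appropriate for panels where tracts span
hundreds of sites; it is also the setting used throughout the package's
own evaluations.

## Rare-allele pruning

`prune_rare_alleles()` masks, per site and population, alleles carried by
a fraction of that population's haplotypes below the threshold, so they
contribute no node; if everything would vanish the majority allele is
kept. Masking can only shrink node sets (monotonically in the threshold),
and it can turn a non-discriminative site into a dAIM — useful when a
panel has few dAIMs. Note that the dAIM *count* is not monotone in the
threshold: masking can also delete exactly the allele that made a site
discriminative, so pruning is a trade-off to be validated per dataset,
not a free lunch.

## What the simulator emulates — and what it does not

`sim_scenario()`/`simulate_scenario()` generate labeled panels and admixed
queries with ground truth, emulating the statistical structure of a
forward admixture simulation at desk scale:

* **Divergence** via the Balding–Nichols model: ancestral frequency
  $q \sim U(0.05, 0.95)$ per site, population frequencies
  $\mathrm{Beta}\!\left(q\frac{1-F}{F},\,(1-q)\frac{1-F}{F}\right)$, so the
  across-population variance is $F q(1-q)$.
* **Admixture** $g$ generations back: crossover count
  $\sim \mathrm{Poisson}(gL)$ with $L$ the map length in Morgans,
  breakpoints uniform on the genetic scale, segment ancestries drawn from
  the admixture proportions, alleles copied from a fresh founder haplotype
  per segment. Founders are disjoint from the reference panel, so queries
  are never verbatim panel rows.
* **Noise**: each allele flips independently with probability
  `error_rate` (default $2\times 10^{-4}$, i.e. 0.02% genotyping error),
  applied to reference and query haplotypes alike.

Defaults were fixed once, on realism grounds: 3 populations at
$F_{ST}=0.2$ (inter-continental scale), 100 reference haplotypes per
population, 5000 sites on a 10 Mb chromosome — one site per 2 kb,
i.e. genotyping-array density (sequencing panels are denser still; much
sparser grids starve the tracts of markers) — a non-uniform "hotspot"
genetic map averaging 1.46 cM/Mb with 95% of the genetic length in 5% of
intervals, 15 generations since admixture, equal proportions, and 200
query haplotypes (100 diploid individuals, enough for the minor-allele
count filter to retain common markers). The package's own evaluation at
these sizes (fixed seed, `w = 1.5`) reaches accuracy ≈ 0.987 and dosage
r² ≈ 0.96, computed end-to-end in the acceptance tests.

Deliberately **not** emulated: background linkage disequilibrium within
populations (sites are independent given frequencies; the only LD is the
mosaic structure itself), a realistic site-frequency spectrum (no
rare-variant tail), population-specific genetic maps, phasing error, and
coalescent/forward demographic realism. Passing tests on this generator
demonstrate correctness of the machinery and recoverability of tract
signal — not performance on real cohorts.

One consequence worth spelling out: with an all-common frequency spectrum,
enlarging the reference panel saturates each population's observed allele
sets, so the number of dAIMs — the collapsed model's only discriminative
signal — *shrinks* as panels grow, and painting accuracy drifts down
rather than up with panel size on this generator. On real sequencing
panels the rare-variant tail keeps supplying dAIMs as panels grow and the
trend runs the other way. This is a limitation of the synthetic frequency
model, not of the inference machinery, and it is documented by a failing
expectation in the acceptance tests rather than hidden.

## Evaluation metrics

`evaluate_painting()` applies the marker filter (computed on the query
haplotypes by default; pass a panel to `marker_filter_mask()` to filter on
reference frequencies instead — "at the threshold" is excluded) and then
reports:

* **Accuracy rate** — the fraction of correctly labeled
  (haplotype, marker) cells over retained markers.
* **Ancestry-dosage r²** — for each population, the squared Pearson
  correlation between true and inferred per-individual dosages (0/1/2
  haplotype labels per diploid individual and marker), averaged over
  populations. The default pools individuals × markers into one
  correlation per population; a `per_marker` variant averages marker-wise
  correlations instead. A population with zero variance in either dosage
  vector contributes 1 if the vectors agree exactly and 0 otherwise.

## File formats and the compact panel

Reference and query haplotypes travel as VCF (unphased genotypes are
accepted for the reference, since collapsing is phase-insensitive;
queries must be phased). Genetic maps may be PLINK `.map`-style
(`chrom id cM bp`) or HapMap-style (`chrom bp rate cM`), auto-detected.
Paintings are written as a per-site TSV plus a segment TSV of maximal
constant-label runs with half-open `[start, end)` bp intervals anchored at
site positions.

The compact panel's VCF serialization is this package's own dialect,
since only the graph semantics are fixed by the model: one pseudo-sample
column per population whose GT lists the alleles present in that
population at the site (`0`, `1`, `0/1`, or `.` for none), with the
population names recorded in a `##compact_populations` header line. The
round trip is exact on node sets, and inference from a reloaded compact
panel is byte-identical to inference from the raw panel. The compact file
grows with sites and populations only, not with panel depth, which is the
point of storing it.

## Problem sizes used in the tests

The suite checks exact DP-versus-enumeration agreement on 200 random
instances (≤ 10 sites, ≤ 3 populations), collapsing/phase invariance on
100 randomized panels, compact-panel round trips on randomized panels plus
an end-to-end smoke scenario, the full three-way recovery scenario above,
a 15-run panel-size sweep, and simulator calibration with 1000 breakpoint
replicates — sizes chosen so the whole suite stays a desk-scale run while
every claim is still computed rather than asserted.

## Known limitations

* Single best path only: no posterior, no uncertainty, no sampling of
  near-optimal paintings.
* Haploid decoding: each query haplotype is painted independently; no
  diploid joint model.
* One genetic map for all populations; ancestry-specific recombination is
  not modeled.
* The synthetic generator's frequency model has no rare-variant tail (see
  above) and no background LD, so absolute metric values on it do not
  transfer to real panels.
* Collapsing discards allele-frequency differences that do not reach
  presence/absence; panels of very close populations may carry few dAIMs,
  where `prune_rare_alleles()` can help but is not guaranteed to.
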