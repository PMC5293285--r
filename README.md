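# radnorm

MaxRank normalization and quantitative comparison of rank abundance
distributions (RADs).

## Why

Many biological systems are *generalized communities*: assemblages of
genetically or otherwise distinguishable classes with a count of
individuals per class — OTUs in a microbiome sample, sequence variants per
V<sub>H</sub> segment in a B-cell receptor repertoire, species in an
ecological survey. Dropping the class identities and sorting the counts
gives the sample's **rank abundance distribution**, a compact,
system-agnostic summary of its abundance structure.

RADs from different samples almost never have the same richness (number of
ranks), so they live in vector spaces of different dimension and cannot be
compared directly. **MaxRank normalization** maps every RAD to a common
dimension *R*: individuals are repeatedly subsampled uniformly without
replacement until just before the (R+1)-th distinct rank would appear, each
subsample is sorted and normalized to relative abundances, and the
repetitions are averaged rank-wise. The result — a **normalized RAD
(NRAD)** — is a valid relative RAD of dimension exactly *R*, with
bootstrap 90% confidence intervals per rank. Unlike simply cutting the RAD
off at rank *R*, MaxRank subsampling lets the (possibly long) tail
influence the normalized head, which preserves between-sample distance
structure much better as *R* shrinks.

On top of the core normalization the package provides Manhattan distances
between NRADs, Shannon entropy and evenness, broken-stick and geometric
reference models, classical multidimensional scaling, complete-linkage
clustering with Newick export, group averaging with bootstrap CIs,
random-forest classification evaluated by the chance-corrected kappa
statistic, an exponential-saturation model of entropy versus age, a
synthetic community generator, tabular and BIOM input, and a command-line
interface (`inst/cli/radnorm.R`).

## Worked example

Three communities of very different richness are generated, normalized to
a common MaxRank, and compared:

```r
library(radnorm)
specs <- list(
  community_spec("lognormal", richness = 3000, depth = 5e4, sdlog = 1.2,
                 seed = 11, label = "gut_A"),
  community_spec("lognormal", richness = 8000, depth = 1e5, sdlog = 1.8,
                 seed = 12, label = "gut_B"),
  community_spec("geometric", richness = 500, depth = 2e4, p = 5e-3,
                 seed = 13, label = "repertoire_C"))
rads <- lapply(specs, generate_community)
rads[[1]]
#> RAD 'gut_A': richness 2839, 50,000 individuals
#>   head counts: 684 321 319 292 282 280 ...

sapply(rads, function(r) r$richness)
#> [1] 2839 6014  500

R <- choose_max_R(rads)   # largest R every sample supports
R
#> [1] 500

nrads <- maxrank_normalize_set(rads, R = R, n_reps = 100, seed = 1)
nrads[[1]]
#> NRAD 'gut_A': R = 500, 100 repetitions
#>   head abundances: 0.01517 0.01031 0.00867 0.007827 0.007337 ...

dm <- distance_matrix(nrads)
dm
#> manhattan distance matrix over 3 samples
#>                gut_A   gut_B repertoire_C
#> gut_A        0.00000 0.04351       0.3583
#> gut_B        0.04351 0.00000       0.3808
#> repertoire_C 0.35830 0.38080       0.0000

entropy_table(nrads)
#>          label   R        H         J
#> 1        gut_A 500 6.085989 0.9793038
#> 2        gut_B 500 6.065964 0.9760815
#> 3 repertoire_C 500 5.971557 0.9608904

cmds(dm, k = 2)
#> cMDS embedding: 3 samples, 2 dimensions, 100.0% explained
```

The two log-normal gut communities end up close to each other and far from
the geometric repertoire, even though their raw richness differed by a
factor of twelve.

Real data enter through `read_abundance_table()` (TSV/CSV or BIOM) and
`as_rads()`; see the package vignette for the methods and design decisions
in detail.

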