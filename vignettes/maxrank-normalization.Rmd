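---
title: "MaxRank normalization of rank abundance distributions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MaxRank normalization of rank abundance distributions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(radnorm)
```

# The problem

A *generalized community* is any assemblage of genetically or otherwise
distinguishable entity classes with counts of individuals per class: OTUs in
a microbiome sample, sequence variants per V~H~ segment in a B-cell receptor
repertoire, species in an ecological survey. Discarding the class identities
and keeping only the sorted count vector yields the sample's **rank
abundance distribution (RAD)**: rank 1 carries the largest count, rank
$R_s$ (the *richness*) the smallest.

RADs summarize the abundance structure of a community in a way that is
comparable *across* systems, but two RADs of different richness live in
different dimensions, so vector distances between them are undefined. Naive
fixes distort the data: truncating at a common rank ("cutoff") throws away
the tail and re-weights the head; padding with zeros makes distances depend
on the arbitrary padding length.

# MaxRank normalization

The package's core operation maps a RAD with $N_s$ individuals and richness
$R_s$ to a **normalized RAD (NRAD)** of prescribed dimension
$R \le R_s$:

1. Draw individuals uniformly at random, without replacement, from the
   pool of $N_s$ individuals. A draw that would introduce the $(R+1)$-th
   *distinct* rank is rejected and sampling stops (the rejected individual
   is not counted).
2. Sort the sub-sampled counts in decreasing order and divide by the
   sub-sample total $N_s'$, giving a relative-abundance vector of length
   exactly $R$.
3. Repeat `n_reps` times and average rank-wise.

The average of sorted, normalized vectors is itself sorted and normalized,
so the NRAD is again a valid relative RAD, now of common dimension $R$
across samples. A 90% confidence interval of the rank-wise mean is obtained
by bootstrap: resample the `n_reps` repetition vectors with replacement,
average, and take the 5% and 95% percentiles over `n_boot` bootstrap
averages.

```{r}
r <- rad(c(40, 25, 12, 6, 3, 2, 1, 1), label = "demo")
maxrank_normalize(r, R = 4, n_reps = 50, seed = 1)
```

## Implementation of the stop rule

A draw-by-draw loop is quadratic in the pool size. The package instead
permutes the pool once (`sample.int`), finds the first occurrences of
distinct ranks (`which(!duplicated(perm))`), and truncates the permutation
just before the $(R+1)$-th first occurrence. The truncated prefix has
exactly the distribution of the draw-by-draw process, because a uniform
random permutation read left to right *is* sampling without replacement.
This makes pools of $5 \times 10^5$ individuals practical at
$R = 1000$ with 20–100 repetitions.

Two exactness properties follow from the stop rule and are enforced in the
tests:

* **Identity at $R = R_s$**: no draw can ever introduce rank $R_s + 1$, so
  every repetition returns the full pool. The implementation short-circuits
  this case and returns the exact relative abundances, avoiding even
  last-ulp floating-point noise from averaging identical vectors.
* **Re-sorting**: sub-sampling can invert near-equal ranks, so each
  repetition is re-sorted before averaging; rank-wise averaging is only
  meaningful between sorted vectors.

## Parameter defaults

* `n_reps = 100`: repetitions trade Monte-Carlo error (which shrinks as
  $1/\sqrt{n_\mathrm{reps}}$) against time, with 10–100 a practical range;
  the default sits at the accurate end. Several long-running examples and
  tests in this package use 20–50 repetitions, which is sufficient when the
  quantities of interest are distances an order of magnitude above the
  Monte-Carlo noise.
* `n_boot = 200` bootstrap resamples for the CI: percentile CIs stabilize
  quickly; 200 resamples put the Monte-Carlo error of the 5%/95% quantiles
  well below the CI width itself.
* `choose_max_R()` returns the minimum richness of a sample set — the
  largest $R$ at which *every* sample can be normalized, which preserves
  the most information without excluding samples.

## Cutoff normalization (baseline)

`cutoff_normalize()` keeps the first $R$ counts and renormalizes over the
kept mass. It is deterministic and cheap, and serves as the comparison
baseline: it systematically inflates head abundances (the discarded tail
mass is redistributed onto the head) and ignores the tail entirely. The
renormalization step is a deliberate choice: without it the vector would
not sum to 1 and would not be an NRAD at all.

# Distances, ordination, clustering

NRADs of common $R$ are compared by the Manhattan distance
$d_R(i,j) = \sum_{r=1}^{R} |a_{ir} - a_{jr}|$, which weights every rank by
its absolute abundance difference and is bounded by 2. A
Kolmogorov–Smirnov statistic on the rank-indexed cumulative abundance
curves (`ks_distance()`, computed on zero-padded raw RADs) is provided as a
baseline that works without normalization but is dominated by the head of
the distribution.

Distance matrices feed into classical multidimensional scaling
(`cmds()`, via `stats::cmdscale`) and complete-linkage hierarchical
clustering (`hierarchical_cluster()`, exportable as Newick). Manhattan
distances are not Euclidean, so the cMDS eigendecomposition can produce
negative eigenvalues; the reported explained fraction uses only the
positive spectrum, and the negative part is reported alongside as the
non-Euclidean residual.

# Diversity and reference models

`shannon_entropy()` returns $H = -\sum_r a_r \log a_r$ in nats and
`evenness()` the Pielou ratio $J = H / \log R$. Empirically, $H_R$ grows
approximately proportionally to $\log R$, so $J$ is nearly invariant under
changes of $R$ — the property that makes entropies measured at different
MaxRanks comparable. This approximation is good for moderately uneven
communities; the package's tests verify drift $\le 0.05$ per decade of $R$
for log-normal abundances up to `sdlog` 1.6, geometric communities with
$p \le 10^{-3}$, and broken-stick communities. For extremely uneven
communities (log-normal `sdlog` $\ge 2$) the drift exceeds 0.05 — almost
all mass sits in the first few ranks, so $H$ saturates while $\log R$ keeps
growing. That is a genuine limitation of the scaling argument, not of the
implementation.

Two parameter-free or one-parameter references are built in:

* **Broken stick** (`broken_stick_nrad()`): the expected sorted fragment
  lengths of a unit stick broken at $R - 1$ uniform points,
  $a_r = \frac{1}{R}\sum_{k=r}^{R} 1/k$. `simulate_broken_stick()` is the
  direct Monte-Carlo stick-breaking oracle used in the tests.
* **Geometric ML fit** (`fit_geometric()`): maximum likelihood
  $\hat p = 1/\bar x$ on support $\{1, 2, \dots\}$ (counts of observed
  classes are at least 1), with a KS consistency test against the fitted
  distribution. The plug-in KS p-value is conservative, and with heavily
  tied small-value samples the KS statistic is inflated; the fit is
  intended for repertoire-like data (tens of observations, large counts).

# The entropy-versus-age model

Developmental series of communities (e.g. infant gut microbiomes) show
entropy rising from a base value toward saturation. The package fits

$$H_R(t) = H_\mathrm{max} - (H_\mathrm{max} - H_0)\, e^{-\lambda t}$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`), with starting
values $(H_0, \lambda, H_\mathrm{max}) = (3.5, 0.19, 6.0)$ — a
representative saturating-growth configuration on the nat scale of
$R \approx 10^3$ communities. 90% CIs are $t$-based half-widths from the
Jacobian at the optimum. Because entropies scale with $\log R$, refitting
the same data normalized at $R/2$ shifts $H_0$ and $H_\mathrm{max}$ down
by the factor $\log(R/2)/\log R$ while leaving the growth rate $\lambda$
essentially unchanged — verified in the acceptance tests.

# Classification and the kappa statistic

`classify_nrads()` trains a random forest (500 trees) on the per-rank NRAD
abundances with stratified threefold cross-validation, reporting accuracy
and the chance-corrected kappa
$\kappa = (ACC - ACC_\mathrm{expect})/(1 - ACC_\mathrm{expect})$ with
$ACC_\mathrm{expect} = \sum_c (n_{\mathrm{pred},c}/N)(n_{\mathrm{true},c}/N)$,
equal to Cohen's kappa on the confusion table (cross-checked against
`e1071::classAgreement` in the tests).

Per-rank importance is permutation importance computed per tree on
out-of-bag samples (the `randomForest` mean decrease in accuracy,
unscaled), averaged over folds. Whole-model held-out permutation — permute
one rank in the test set of a trained forest — was evaluated and rejected:
neighbouring NRAD ranks are strongly correlated, so a full forest is almost
unaffected by permuting any single rank, and the importance profile
degenerates to noise. Per-tree OOB permutation resolves correlated
predictors because individual trees commit to individual ranks.

# The synthetic community generator

`community_spec()`/`generate_community()` produce observed RADs in two
stages: a *true* relative-abundance law (geometric, log-normal,
broken-stick, or uniform) over a prescribed richness, then a multinomial
draw of `depth` individuals. Species unobserved at the given depth are
dropped, so observed richness falls below true richness for uneven laws or
shallow depths — exactly as in real sequencing, where depth limits
richness. What the generator does *not* model: taxonomic identity (RAD
methods are identity-free by construction), phylogenetic correlation
between abundances, overdispersion beyond multinomial noise, or chimeras
and other sequencing artifacts. It is a generator of realistic abundance
*structure*, not of realistic reads.

`generate_labeled_nrad_set()` plants a class signal — a triangular
log-abundance bump confined to a middle-rank band — on a common
geometric-decay template, with multiplicative log-normal per-rank noise,
then re-sorts and renormalizes so that every sample is a valid NRAD. It
exists to test that the classifier can both detect (κ) and localize
(importance peak) signal that sits neither in the head nor in the tail.

`generate_entropy_age_dataset()` draws ages log-uniformly (developmental
change is fastest at young ages, so log-spacing allocates samples where the
curve bends) and adds Gaussian noise to the exact model curve.

# Study conditions of the long-running verifications

The test suite fixes the following problem sizes; they are this package's
own choices, balancing statistical resolution against runtime.

* **Down-sampling robustness.** 50 log-normal communities of true
  richness $10^5$ at depth $10^6$, with `sdlog` spanning 1.0–3.4, each
  down-sampled tenfold in observed richness; both versions are normalized
  at $R = 1000$ (50 repetitions) and the paired
  original-vs-down-sampled distance must fall below the 5th percentile of
  between-community distances. The design of the community set deserves
  explanation. At $R = 1000$ the NRAD shapes of this package's generator
  families occupy an effectively *one-dimensional* continuum: varying
  richness at fixed depth, the geometric parameter $p$, or the broken-stick
  model all land on the same evenness axis that `sdlog` parameterizes
  (e.g. doubling richness is nearly indistinguishable from adding ≈ 0.3 to
  `sdlog`). The most heterogeneous 50-community set this generator can
  produce is therefore a ladder along that axis, spaced uniformly in
  *measured* NRAD distance (the axis is traversed much faster at the
  uneven end, so uniform `sdlog` spacing would crowd the even end). Large
  richness and depth keep the down-sampled communities far richer than
  $R$, which suppresses the single-realization bias of the down-sampling
  draw — the dominant term in the paired distance. Real cross-sectional
  datasets (different subjects, sites, conditions) are heterogeneous in
  many more dimensions than a two-parameter synthetic family, which makes
  this synthetic version of the experiment *harder*, not easier, than the
  real one.
* **Cutoff comparison.** 26 log-normal communities whose richness spans
  1 500–30 000 at fixed depth $2 \times 10^5$, so that between-sample
  differences live substantially in the RAD tails — the regime where
  normalization schemes genuinely differ. Distance preservation under
  $R$-reduction ($r^2$ between distance vectors at $R = 1000$ and at
  $R \in \{250, 100\}$) is higher for MaxRank than for cutoff.
* **Model recovery.** Noiseless Eq.-fit recovery to $10^{-4}$; CI coverage
  estimated from 200 noisy replicates ($\sigma = 0.5$, $n = 500$), with
  acceptance band [0.84, 0.98] ≈ 90% ± 3 binomial SDs.
* **Enumeration oracle.** For pools of ≤ 8 individuals the MaxRank mean is
  computed exactly by exhausting all multiset permutations of the pool and
  compared to $10^4$ Monte-Carlo repetitions within 3 standard errors.

# Known limitations

* MaxRank normalization is a randomized estimator; two runs differ unless
  seeded. All sampling functions accept `seed` arguments and the package
  restores the caller's RNG state afterwards.
* NRAD confidence intervals quantify sub-sampling variability of the mean,
  not biological variability between replicate samples (use
  `average_nrads()` bootstrap CIs for that).
* Entropy scaling ($J$ invariance in $R$) degrades for extremely uneven
  communities; see above.
* The KS consistency test in `fit_geometric()` is unreliable for heavily
  tied samples.
* Manhattan distances are non-Euclidean; cMDS coordinates are
  approximations whose quality is reported via the explained fraction and
  the eigenvalue spectrum.
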