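---
title: "Null-model inference of community assembly in rare and common biospheres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model inference of community assembly in rare and common biospheres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarescape)
```

## The inference problem

Soil bacterial communities — and microbial communities generally — contain a
small set of abundant taxa and a long tail of rare ones. Whether a given
fraction of the community is shaped by deterministic niche processes
(selection) or by stochastic ones (dispersal and drift) is not observable
directly; it has to be inferred from the *pattern* of between-sample
turnover, compared against what turnover would look like if taxon identities
were random with respect to phylogeny and abundance. `rarescape` implements
that two-step null-model inference for rarefied amplicon (ASV) feature
tables with a matching rooted phylogeny, together with the rarity
machinery needed to apply it separately to the rare and common biospheres,
a Sloan neutral-model cross-check, and a synthetic-data generator with
known ground truth used to validate the whole pipeline end to end.

## The two-step decision rule

**Step 1 — phylogenetic turnover.** For communities $k$ and $m$, the
abundance-weighted between-community mean nearest taxon distance is

$$\beta\mathrm{MNTD} = \tfrac12\Big[\sum_{i_k=1}^{n_k} f_{i_k}\,
\min_{j_m}\Delta_{i_k j_m} + \sum_{i_m=1}^{n_m} f_{i_m}\,
\min_{j_k}\Delta_{i_m j_k}\Big],$$

where $f_{ik}$ is the relative abundance of taxon $i$ in community $k$,
$n_k$ its richness, and $\Delta$ the cophenetic (patristic) distance to the
closest taxon of the other community. A null distribution is built by
shuffling taxa among the tips of the phylogeny (999 permutations by
convention; one permutation per replicate, shared by all pairs, which is
statistically equivalent per pair and fully vectorizable). The z-score

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{obs} -
\overline{\beta\mathrm{MNTD}_{null}}}{sd(\beta\mathrm{MNTD}_{null})}$$

classifies a pair as *variable selection* when $\beta\mathrm{NTI} > +2$
(more phylogenetic turnover than the null expects: different conditions
select different lineages) and *homogeneous selection* when
$\beta\mathrm{NTI} < -2$. The sd uses the $n-1$ denominator; pairs whose
null sd is zero (degenerate trees or identical taxon sets) get `NaN` and
are reported as unclassifiable rather than silently dropped.

**Step 2 — taxonomic turnover.** Pairs with $|\beta\mathrm{NTI}| \le 2$ are
passed to the abundance-based Raup–Crick statistic. For each pair, 999 null
community pairs are assembled preserving each sample's observed richness
and read total: taxon identities are drawn without replacement with
probability proportional to metacommunity occurrence frequency, then the
remaining reads are placed with replacement proportional to metacommunity
relative abundance. With $n_<$ null Bray–Curtis values below the observed
one and $n_=$ ties (counted at half weight),

$$RC_{bray} = 2\Big(\frac{n_< + 0.5\,n_=}{n_{null}} - 0.5\Big) \in [-1, 1].$$

$RC_{bray} > +0.95$ is read as dispersal limitation (plus drift),
$RC_{bray} < -0.95$ as homogenizing dispersal, and anything in between as
undominated processes. Boundary values ($\beta\mathrm{NTI} = \pm 2$,
$RC = \pm 0.95$) are deliberately assigned to the weaker claim, since the
published rules use strict inequalities in both directions and the boundary
has measure zero.

Percentages of pairs in each class, per community component (rare, common,
whole) and per grouping (all pairs; same-stage pairs for temporal turnover;
same-time different-stage pairs for spatial turnover), form the assembly
report. The five percentages always close to 100 within each row;
unclassifiable pairs are excluded from denominators and counted separately.

### Null-model scope

Two choices deserve emphasis because they change results materially.

* *Which taxa does the shuffle span?* By default the tip shuffle is
  restricted to the taxa present in the analyzed table (`prune = TRUE`),
  which preserves the observed richness and abundance structure exactly and
  is the right choice for real data, where the table *is* the best
  available estimate of the regional pool. When the regional pool is known
  to be larger — as for the synthetic generator, whose tree is the pool by
  construction — `full_tree_null = TRUE` shuffles across every tip of the
  supplied tree. With a narrow observed pool (e.g., a dataset where a
  single strong filter was active everywhere), the pruned null can only
  randomize within the already-filtered set and will understate selection.
* *Are component abundances renormalized?* When analyzing the rare or
  common submatrix, each community's $f$ vector is renormalized to sum to 1
  within the component, so $\beta$MNTD stays a weighted mean.

## Rarity cutoffs and rarity types

Rarity is defined per sample on the rarefied table (fixed depth, so
relative abundance is count/depth). An ASV is **rare** in a sample when its
relative abundance is positive and *no greater than* the cutoff, and
**common** when strictly above it; the boundary is inclusive on the rare
side, and this off-by-one choice propagates into every downstream count, so
it is asserted explicitly in the tests.

Besides fixed cutoffs (0.2%, 0.1%, 0.05% are the conventional ladder), a
sample-specific cutoff mirrors the h-index: sort the sample's counts in
decreasing order and find the first rank $r$ whose abundance is $\le r$;
the crossing abundance over the sample total is the cutoff fraction. Ties
are resolved by taking the crossing abundance itself (the largest
qualifying abundance). Optionally the cutoff is recalibrated by sampling
completeness, multiplying by $S_{obs}/S_{chao1} \le 1$ so that
under-sampled communities get a stricter cutoff; the opposite direction
(`divide`) is exposed because the recalibration arithmetic is a modeling
choice, but multiplication is the default since completeness is a shrinkage
factor. Chao1 uses the classic form $S_{obs} + F_1^2/(2F_2)$ and switches
to the bias-corrected $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ only when no
doubletons exist, so the estimator is always finite and never below
$S_{obs}$.

Across all samples, each detected ASV then receives exactly one label:

* `permanently_common` — detected and common in every sample;
* `conditionally_rare_common` — common somewhere, rare somewhere else;
* `permanently_rare` — never common, rare in two or more samples;
* `transiently_rare` — never common, rare in exactly one sample.

ASVs that are common in some samples, absent in the rest, and never rare
fall outside the four rules; they are labelled `conditionally_rare_common`
(reading absence as sub-detection rarity) and flagged in the output so the
choice is auditable.

## Sloan's neutral model

As an independent cross-check that does not use the phylogeny, the Sloan
neutral community model predicts a taxon's occurrence frequency across
samples from its mean relative abundance $p$ under neutral
birth–death–immigration dynamics: local relative abundance follows
$\mathrm{Beta}(Nmp,\; Nm(1-p))$, so the probability of detection at limit
$d$ reads is $1 - I_{d/N}(Nmp, Nm(1-p))$ with $I$ the regularized
incomplete beta function. The migration parameter $m$ is fitted by
nonlinear least squares with $N$ fixed to the rarefaction depth; each taxon
is classed `above`/`within`/`below` a Wilson binomial band (with $n$ = the
number of samples) around the prediction, and the classes are
cross-tabulated against rarity types. The model describes whole-community
species distributions and is not fitted to rare/common subsets.

Two approximation limits matter. The detection model treats a taxon as
observed when its local relative abundance exceeds $d/N$; real read
sampling adds binomial noise around that threshold, which is negligible
when $Nmp \gtrsim 1$ but inflates detection of very rare taxa below that
scale (the Monte-Carlo agreement of ±0.02 documented in the tests holds for
$Nmp \ge 1$). For the same reason the parameter-recovery generator
(`simulate_sloan_dataset`) converts local abundances to reads by
deterministic rounding rather than binomial resampling: the recovery check
is a check of the *fit* against the *model*, and binomial blurring at the
detection limit would bias the recovered $Nm$ upward by roughly a quarter.

## The synthetic generator

`simulate_dataset()` produces a feature table, metadata, tree, and truth
labels under five assembly regimes. Its defaults emulate the study design
this pipeline targets: 5 successional stages × 4 sampling times × 3
replicates = 60 samples at a rarefaction depth of 31,500 reads, with a
lognormal carrying-capacity distribution supplying the long-tailed
species-abundance curve. The tests and the acceptance script run the same
generator scaled down (200 taxa, 2 × 2 × 3 = 12 samples, 2,000 reads, 199
null replicates, three independent seeds per scenario) so the whole
validation executes in minutes on one core; these sizes are the package's
documented validation conditions.

In the selection scenarios, the expected relative abundance of taxon $i$
in sample $s$ is

$$E[f_{is}] \propto K_i \cdot
\exp\!\Big(-\frac{(z_i - E_s)^2}{2\sigma_w^2}\Big) \cdot B_{is} \cdot
\varepsilon_{is},$$

with $K_i$ lognormal carrying capacities, $z_i$ a Brownian niche trait,
$E_s$ the stage's environmental optimum (a trait quantile), $\sigma_w$ the
niche width (default $0.2\,sd(z)$), $B_{is}$ a Bernoulli(0.5) colonization
indicator and $\varepsilon_{is}$ lognormal noise; counts are one
multinomial draw at the target depth. Scenario wiring: homogeneous
selection places every stage at the same optimum in the trait tail
(quantile 0.9); variable selection spreads stage optima from quantile 0.9
to 0.1, a separation of many $\sigma_w$; neutral drift uses flat fitness
with each sample an independent serial multinomial-resampling chain from
one common pool; dispersal limitation splits taxa at random (with respect
to the phylogeny) into disjoint regional pools, one per stage; mixed shares
an optimum over half the stages and spreads the rest.

Three design choices in the generator were forced by what the inference
can actually detect at desk scale, and are worth recording:

* **Conserved niches.** The niche trait is Brownian motion on a copy of the
  tree whose node heights are raised to a small power
  (`trait_conservatism = 0.05`), concentrating trait divergence on deep
  splits so that lineages carry near-constant niche values. Plain Brownian
  motion on a 200-tip pure-birth tree produces trait bands scattered across
  distant clades — communities then violate the niche-conservatism premise
  the inference assumes, and no amount of filtering produces a detectable
  phylogenetic signal. Strong clade-level conservatism is also the regime
  real 16S data occupy, where broad ecological strategies track coarse
  taxonomy.
* **A colonization lottery.** $\beta$NTI only "sees" taxa that differ
  between the two communities (shared taxa contribute zero nearest-taxon
  distance to both the observed and the null statistic). Without a
  presence lottery, two samples under the same filter differ only in a
  handful of detection-boundary taxa, and a null standard deviation driven
  by so few terms is too wide for $|z| > 2$ at 200 taxa and 2,000 reads.
  The Bernoulli colonization indicator makes equally-fit taxa turn over
  among samples — ecologically, a lottery among equivalent colonists — and
  gives the z-score enough independent terms to resolve selection.
* **Coherence screening.** Even with conserved traits, an occasional
  tree/trait draw leaves the niche band phylogenetically incoherent. The
  selection scenarios therefore redraw the pair (up to 40 times) until the
  `band_size = 30` taxa nearest each optimum are clustered on the tree
  (`band_coherence` ≤ 0.35, measured as mean within-band nearest-neighbour
  distance relative to random sets). This is input-side validation of the
  scenario's premise, not output tuning: a draw that fails it does not
  represent selection under niche conservatism.

The generator's table keeps all pool taxa as rows, including never-observed
ones, because in simulation the regional pool is known and the tip-shuffle
null should span it (`full_tree_null = TRUE` in the validation runs).

What the generator does *not* emulate — and what passing its checks
therefore does not establish about real data: sequencing error and chimeric
reads (upstream denoising is out of scope), compositional biases of
amplification, spatial or temporal autocorrelation beyond the drift chains,
interaction-driven assembly, and the sheer scale of real tables. The last
point matters most: $|\beta\mathrm{NTI}|$ grows roughly with the square
root of the number of taxa contributing turnover, so desk-scale magnitudes
(±2–4) are much smaller than those of 20,000-ASV datasets, and the
rare-only submatrix of a 200-taxon simulation (its anchors removed) carries
too few terms to classify reliably — at realistic scale the rare biosphere
is itself thousands of taxa deep and does not have this problem.

## Numerical and degenerate-input choices

* Rarefaction is without replacement (hypergeometric), one draw by default;
  samples under the target depth are dropped with a warning rather than
  kept unrarefied, and `n_draws > 1` returns independent draws rather than
  an averaged table (averaging would break the integer-count invariant).
* Feature-table readers skip BIOM-TSV comment lines, accept a `#OTU ID`
  header, and transpose sample-in-rows tables on a recognized header token,
  with a message.
* PCoA double-centres $-\tfrac12 D^2$ and eigendecomposes; negative
  eigenvalues (non-Euclidean input, as Bray–Curtis typically is) are
  reported and axis percentages are taken over the positive spectrum only.
  A zero matrix yields zero coordinates rather than an error.
* PERMANOVA is the one-factor form with the add-one permutation p-value
  $p = (1 + \#\{F^* \ge F\})/(n_{perm}+1)$; the paper-scale sequential
  (interaction) decomposition is out of scope.
* All stochastic steps (rarefaction, both null models, the generator) are
  bit-reproducible under a supplied seed, and `run_full_analysis` derives
  stage-specific seeds from one master seed so a full run is reproducible
  end to end.

## Validation summary

The test suite ships the validation: exactness of $\beta$MNTD against a
naive double-loop oracle (and against `picante::comdistnt`), calibration of
$\beta$NTI (mean ≈ 0, sd ≈ 1 under tree-random composition) and of
RC$_{bray}$ under its own null generator, exact rank-statistic behaviour of
RC, recovery of all four assembly regimes by the full pipeline, exact
behaviour of the rarity fixtures and cutoff algorithms, Sloan parameter
recovery within ±20%, and near-nominal PERMANOVA type-I error.
`scripts/acceptance.R` recomputes the same quantities from scratch for any
seed.
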