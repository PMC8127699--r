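---
title: "Designing ex situ collections and translocations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing ex situ collections and translocations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`exsitu` turns the rescue of a condemned plant population into a chain of
explicit, seeded computations on a diploid SNP dosage matrix. This
vignette documents the models behind each stage, the tunable parameters
and their defaults, the numerical choices that matter, and what the
synthetic data used by the test suite does and does not establish about
real data.

## Data model and filtering

Genotypes are held as a samples × loci matrix of alternate-allele
dosages in {0, 1, 2, NA} (`geno_matrix()`). Loci are opaque identifiers:
reduced-representation markers are treated as unanchored and unlinked,
so no coordinates or strand information is carried. Because every
downstream statistic uses the folded minor-allele frequency, the choice
of which allele counts as "alternate" cannot change any result.

Filtering follows strict threshold conventions, applied in a fixed
order by `filter_loci()`:

* reproducibility (technical-replicate concordance supplied with DArT
  data): keep loci **strictly greater than** 0.96;
* missingness: drop loci missing in **more than** 20% of samples
  (i.e. keep ≤ 0.20);
* for optimization work, keep only loci with complete data
  (`require_complete = TRUE`), so the objective needs no missing-data
  correction;
* samples missing **more than** 50% of calls are removed
  (`remove_high_missing_samples()`).

Whether locus missingness should be computed over all loaded samples or
within a species subset is genuinely open; the package computes it over
all samples in the matrix at hand, and users wanting subset-wise
filtering can subset first — `subset_geno()` recomputes call rates.

## Kinship and clone pruning

`estimate_kinship()` implements the method-of-moments IBD-sharing
estimator on identity-by-state counts. For each pair, over
pairwise-complete loci, the expected per-locus probabilities of IBS
class given IBD state (with allele frequency $p$, $q = 1 - p$) are

$$P(\mathrm{IBS}=0 \mid \mathrm{IBD}=0) = 2p^2q^2, \quad
  P(\mathrm{IBS}=1 \mid \mathrm{IBD}=0) = 4p^3q + 4pq^3, \quad
  P(\mathrm{IBS}=1 \mid \mathrm{IBD}=1) = 2pq,$$

from which $k_0$ and $k_1$ are solved and $k_2 = 1 - k_0 - k_1$;
kinship is $\tfrac12(k_2 + \tfrac12 k_1)$. Allele frequencies default to
the full loaded matrix (an explicit vector can be supplied, e.g. to use
per-population frequencies). The raw moment estimates can stray outside
the probability simplex by sampling noise; by default they are clamped
to it before the kinship is formed (`bound = FALSE` disables this),
which is why a duplicated error-free sample returns exactly 0.5. Pairs
sharing fewer than 50 non-missing loci (a conservative floor; the
estimator is very noisy below that) are flagged unreliable.

Clone groups are the connected components of the graph with an edge
wherever kinship ≥ threshold (`similar_groups()`), i.e. single linkage —
the conservative choice for removal, since any chain of
near-identical pairs is treated as one genet. The threshold is
species-specific because genotyping error depresses clone kinship below
0.5 by an amount that depends on error rate; `kinship_histogram()`
exists so the user can place the threshold in the gap between the clone
mode and the close-relative background (0.4 and 0.45 are typical for
error rates around 0.5%). Each group keeps the member with the fewest
missing calls, ties broken lexicographically by id so runs are
reproducible.

## Diversity objectives and allele capture

The optimization objective is Nei's gene diversity: the mean over loci
of $2p(1-p)$ with $p$ computed on the candidate subset. No
$2n/(2n-1)$ small-sample correction is applied *inside the objective*:
all subsets compared have the same size, so the correction is a constant
factor and cannot change any ranking. Reported absolute values follow
the same convention. `fis_and_richness()`, which is evaluative rather
than an objective, does use the unbiased expected heterozygosity in its
multilocus $F_{IS} = 1 - \bar H_o / \bar H_e$ (a ratio of averages, the
standard multilocus form), and offers optional rarefaction for allelic
richness (off by default).

Allele capture is deliberately cruder than diversity: a reference locus
is captured when **both** alleles occur at least once in the subset.
The reference set (`common_loci()`) is the loci whose minor allele
frequency in a stated reference population strictly exceeds a
threshold — 2% by default, 3% when singletons must be excluded (with 18
diploid samples a singleton sits at 1/36 ≈ 2.8%, within reach of a
single genotyping error).

## Simulated annealing

Both optimizers (subset selection, maximizing diversity; spatial
arrangement, minimizing f) share one acceptance rule: improving moves
always accepted, worsening moves with probability $\exp(\Delta/T)$
under a geometric schedule (`sa_cooling()`). Defaults: initial
temperature set adaptively to the standard deviation of the objective
change over 100 random proposals from the starting state (scale-free,
so the same schedule works for objectives in heterozygosity units and
in 1/metre units), cooling factor 0.95, 100 proposals per temperature,
200 temperatures, early stop after 2000 consecutive rejections. The
best-ever state is returned, so a longer run can never report a worse
design. With the temperature forced to zero the algorithm reduces to a
greedy hill-climb, which the tests use as a structural check.

Subset proposals swap one selected non-locked individual for one
unselected candidate; locked members (plants already propagated, or
survivors of an established planting) are never swapped out. Arrangement
proposals swap the positions of two plants. All stochastic entry points
take explicit integer seeds, and a fixed seed plus schedule reproduces
the design exactly.

The test suite holds the optimizers to exhaustive enumeration on every
instance small enough to enumerate (all subset instances with
$\binom{n}{k} \le 10{,}000$; all bijections for up to 8 plants). On
desk-scale synthetic data the default schedule reaches those optima with
a wide margin; for matrices with many thousands of loci the schedule is
the knob to turn first.

### Multiobjective supplementation

The trade-off between maximizing diversity and keeping the collection
local is mapped with an ε-constraint sweep rather than a weighted sum:
for each admissible count *c* of nonlocal members, diversity is
maximized subject to exactly *c* nonlocal and $N_P - c$ local members.
This produces one design per attainable local proportion — a discrete
trade-off front with no weight tuning, directly plottable as diversity
versus proportion local. The constrained search uses the same annealer
with proposals restricted to within-pool swaps.

## Translocation simulation

`simulate_translocation()` is a neutral discrete Wright–Fisher model:
constant population size $N_T$, non-overlapping generations; each
offspring draws two parents uniformly with replacement (forced selfing
with probability `selfing_rate`, default 0; independent draws can still
coincide by chance, as in the standard model), each parent transmits one
allele per locus by fair Mendelian segregation, and loci are unlinked —
reasonable for genomically sparse reduced-representation markers. There
is no mutation, selection, migration or fecundity variance beyond the
multinomial. Founders are exact copies of their genets
(`found_population()`), so the set of retained loci is structurally
bounded by the founder-polymorphic set in every replicate: the capture
proportion of the propagation population is a hard ceiling on retention.

Retention is measured at the final generation exactly (not averaged),
over all $N_T$ individuals, against the common-locus reference set.
Defaults: 10 generations, 100 replicates per design. Two calibrations
anchor the implementation: expected heterozygosity must decay by
$(1 - 1/(2N_T))$ per generation, and the one-generation retention of a
single locus founded as {0, 2} with $N_T = 2$ must match its 16-outcome
enumeration (7/8). Both are asserted in the test suite at Monte-Carlo
tolerances.

Because the mating model is deliberately coarse (selfing rates and
reproductive-success variance of the target species are typically
unknown), absolute retention values should be read as an *index* for
comparing candidate designs, not as predictions.

## Spatial arrangement

A planting of $n$ plants on fixed positions is scored by

$$f = \frac{1}{n_\mathrm{pairs}} \sum_{i<j} \frac{G_{ij}}{S_{ij}},$$

with $S_{ij}$ the Euclidean distance in metres and $G_{ij}$ the genetic
similarity. The package takes $G_{ij} = \max(\mathrm{kinship}_{ij},\ 0)$:
kinship is the natural similarity measure already computed upstream, and
flooring at zero stops negative (noise-driven) estimates from *rewarding*
proximity of dissimilar plants. The floor is configurable; any
alternative similarity can be injected by passing a different matrix.
$f$ depends only on pairwise distances (rigid-motion invariant) and
halves when all distances double.

`clumped_layout()` is a parameterized stand-in for a real planting plan:
clumps of five positions (a layout that promotes seed set in eucalypts)
on a ring with 3 m between neighbours, clump centres on a 30 m grid —
orders of magnitude consistent with reporting thresholds of 25 m
("close") and 50 m ("far") — plus a regular-grid mode. Coincident
positions are a hard error since $1/S$ diverges. Evaluation intentionally
does not stop at f: `close_similar_pairs()` counts pairs with kinship ≥
0.12 within 25 m, and `null_arrangements()` builds the distribution of
that count over (by default) 1000 uniformly random assignments, because a
single random start can be unrepresentative.

## The synthetic-data generator

`generate_synthetic()` plants ground truth for every pipeline stage:
ancestral allele frequencies are beta-distributed (symmetric shape 0.5,
truncated to [0.02, 0.98], giving a realistic excess of low-MAF loci);
per-site frequencies follow a Balding–Nichols model with a single
$F_{ST}$ knob; unrelated individuals are Hardy–Weinberg draws; families
arise by Mendelian segregation from site-drawn parents; clonal ramets
are copies of their genet; genotyping error is a symmetric single-step
dosage perturbation (0↔1↔2), which is exactly what pushes clone kinship
below 0.5 and motivates sub-0.5 thresholds; missingness is uniform;
reproducibility scores place a configurable fraction of loci below the
0.96 filter.

Two presets fix the study conditions used throughout the tests and the
acceptance script:

* **pimelea_like** — a condemned site of 100 genets (15 full-sib
  families of four plus 33 unrelated) sampled as 112 stems: seven clonal
  genets appear as 19 ramets, so clone pruning must find exactly 7
  groups and remove 12 samples. 2000 loci, $F_{ST}$ 0.08 to two
  20-sample outlying sites, error 0.005, missingness 0.015. After
  quality and complete-data filtering this yields on the order of 300
  common loci — a deliberate desk-scale size that keeps the full
  size-sweep (N_P = 16–64 by 4, 100 random baselines each) and the
  retention grid (N_P ∈ {16, 32, 64} × N_T ∈ {64, ..., 320}, 100
  replicates, 10 generations) inside a few minutes on one CPU.
* **eucalyptus_like** — 18 adults and 59 open-pollinated seedlings from
  12 seed parents at the condemned site, four extra seedlings flagged as
  putative hybrids (flags are taken as input; hybrid detection is out of
  scope), and nonlocal seedling pools of 1, 3 and 4 from three outlying
  sites. Five percent of the loci common among adults have their minor
  allele erased from every local seedling, so the seedling capture
  ceiling — common adult alleles simply absent from the collectable
  material — is present by construction and measurable.

What passing tests on these data do **not** show: robustness to
non-uniform missingness (e.g. allele-dropout correlated with
heterozygosity), linked loci, null alleles, or structured genotyping
error — all real phenomena in reduced-representation data that the
generator does not emulate. They also do not validate absolute retention
forecasts for any real species, for the mating-model reasons above.

One behaviour of the method itself is worth flagging: the optimizer
maximizes expected heterozygosity while the evaluation metric is allele
capture. These usually agree, but they are not the same functional, and
on small reference sets a random draw can occasionally capture as many
common loci as the diversity-optimal subset of equal size — the benefit
of optimization concentrates in small collections and fades as $N_P$
grows.

## Numerical and degenerate-input conventions

* Frequencies at loci with no non-missing call are `NA` and flagged, not
  0; an all-monomorphic subset has $F_{IS}$ undefined (with a warning)
  rather than 0/0.
* Filters that remove every locus warn and return an empty matrix, so
  pipelines can report rather than crash.
* `n_select` equal to the candidate count, a fully locked selection, and
  an empty clone-group list are all exact no-search identities.
* Translocation sizes must be divisible by the genet count under the
  equal-ramet scheme; indivisible grid cells are skipped with a warning.
* All writers emit plain tab-separated text with ids in headers; every
  pipeline stage logs its full parameter set and seed so a run can be
  reproduced from its log alone.

## Command-line use

`run_pipeline()` exposes the stages as subcommands (`simulate-data`,
`filter`, `kinship`, `design`, `supplement`, `arrange`, `amplify`) over
a plain `key = value` config; `inst/cli/exsitu-cli.R` is a thin Rscript
wrapper for shell use. The R functions remain the primary interface.
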