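# exsitu

Tools for preserving the genetic diversity of *condemned* plant
populations — wild populations whose destruction is imminent and
unavoidable — by designing ex situ collections and translocation
populations from SNP genotype data.

When a population must be cleared, a manager faces a chain of decisions:
which plants to sample and propagate, how many, how to amplify the
propagated material into a planted population, and how to arrange that
planting. Each decision loses or preserves alleles. `exsitu` makes the
chain quantitative for diploid, biallelic SNP data (e.g. DArTseq or
RADseq dosage tables):

1. **Filtering** — locus quality filters (technical reproducibility
   > 0.96, per-locus missingness ≤ 20%, complete-data subsets) and
   removal of samples with > 50% missing calls.
2. **Clone pruning** — pairwise kinship by the PLINK method of moments
   (for a pair, IBD-state probabilities *k₀, k₁, k₂* are solved from
   identity-by-state counts and allele frequencies, and kinship
   = ½(*k₂* + ½*k₁*)); groups of highly similar samples (kinship above a
   species-specific threshold, e.g. 0.4) are reduced to the member with
   the fewest missing calls. Genetically identical ramets sit at kinship
   0.5, slightly lower with genotyping error.
3. **Propagation-population design** — simulated-annealing selection of
   N_P genets maximizing gene diversity (Nei's expected heterozygosity,
   H̄ₑ = mean over loci of 2p(1−p)), with optional locked-in members,
   size sweeps against random-selection baselines, and nestedness
   reporting across sizes.
4. **Allele capture** — the proportion of *common* loci (minor allele
   frequency > 2–3% in a stated reference population) at which both
   alleles occur in a candidate collection.
5. **Translocation simulation** — populations of N_T plants founded as
   equal numbers of ramets per genet are simulated forward under a
   neutral Wright–Fisher model (random parent pairs, Mendelian
   segregation, unlinked loci, optional selfing) for 10 generations; the
   proportion of common loci still polymorphic measures retention.
6. **Supplementation trade-offs** — ε-constraint multiobjective
   optimization of diversity versus the proportion of local individuals
   when a collection may be supplemented from other sites.
7. **Spatial arrangement** — assignment of plants to a clumped planting
   layout minimizing f = (1/n_pairs) Σ G_ij / S_ij (G genetic
   similarity, S distance in metres), so similar plants do not pollinate
   each other, evaluated against 1000 random-arrangement nulls.

A seeded synthetic-data generator (`condemned_scenario()`,
`generate_synthetic()`) emulates the relevant field situations — site
differentiation, families, clonal ramets observed with genotyping error,
missingness — with planted ground truth, so the whole workflow is
testable end to end without access to restricted data.

## Worked example

A shrub-like condemned population (100 genets sampled with clonal
redundancy, plus two outlying sites), from raw table to a translocation
design:

```r
library(exsitu)

sim <- condemned_scenario("pimelea_like", seed = 42)
g <- sim$genotypes
g
#> <geno> 152 samples x 2000 loci (1.5% missing calls)
#>   sites: airportlike, outsiteA, outsiteB

gf <- filter_loci(g)                       # reproducibility > 0.96, missing <= 20%
filter_report(gf)
#>                      rule removed retained
#> 1  reproducibility > 0.96     216     1784
#> 2 missing fraction <= 0.2       0     1784
gf <- remove_high_missing_samples(gf)      # > 50% missing calls

k <- estimate_kinship(gf)
groups <- similar_groups(k, threshold = 0.4, n_missing = gf)
length(groups)                             # 7 clone groups ...
#> [1] 7
gp <- prune_similar(gf, groups)            # ... pruned to one ramet each
length(attr(gp, "removed_samples"))
#> [1] 12

# complete-data common loci of the condemned population
local <- gp$sample_meta$sample_id[gp$sample_meta$is_local]
gl <- filter_loci(subset_geno(gp, samples = local),
                  reproducibility_min = NULL, missing_max = NULL,
                  require_complete = TRUE)
ref <- common_loci(gl, maf_min = 0.02)     # MAF > 2%
gd <- subset_geno(gl, loci = ref)          # 100 genets x 321 common loci

# a propagation population of 32 genets, maximizing gene diversity
des <- optimize_subset(gd, n_select = 32, seed = 1)
des
#> <subset_design> sa, N_P = 32, He = 0.3276
capture_proportion(gd, des$selected, ref)
#> capture: 319/321 reference loci polymorphic (99.4%) in 32 samples

# amplify to 256 plants (8 ramets per genet) and simulate 10 generations
td <- translocation_design(des$selected, n_total = 256)
founders <- found_population(gd, td)
simulate_translocation(founders, reference_common = ref,
                       generations = 10, n_replicates = 100, seed = 2)
#> <retention> N_T = 256, 10 generations: mean 0.983 [0.975, 0.991] of 321 loci polymorphic (100 reps)
```

So a carefully chosen third of the condemned genets captures 99.4% of
its common alleles, and a planting of 256 cuttings is expected to keep
about 98% of them polymorphic a decade of generations later. The
companion functions `size_sweep()` (capture versus N_P, optimized vs
random), `design_grid()` (retention over an N_P × N_T factorial),
`multiobjective_front()` (diversity vs local provenance) and
`anneal_arrangement()` / `null_arrangements()` (spatial design) cover
the remaining panels of the workflow; `run_pipeline()` chains them with
a plain-text config, and `inst/cli/exsitu-cli.R` wraps that for shell
use.

See `vignettes/design-workflow.Rmd` for the models, parameter choices
and limitations.

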