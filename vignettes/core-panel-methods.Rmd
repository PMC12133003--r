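---
title: "Core SNP panel selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core SNP panel selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corepanel)
```

# The problem

Cultivar seedlings with near-identical morphology must be distinguished
genetically. Given genotyping-by-sequencing calls for a few dozen samples
drawn from a handful of cultivars, the goal is a *core panel*: a small
subset of SNPs that is high-quality, discriminates the cultivars, is
individually informative and mutually non-redundant, so that cheap assays
(KASP, arrays) can later be designed against it. `corepanel` implements
the screening cascade, its validation statistic, and the
population-structure analyses used to sanity-check a panel, with a genotype
simulator to exercise everything end to end.

# Data model

Genotypes are diploid codes 0/1/2 (copies of the alternate allele) with a
distinguished missing value; per-call sequencing depth rides along.
Missing is never conflated with homozygous reference, and every statistic
shrinks its denominator rather than imputing: a pair's similarity divides
by *common* non-missing loci, a cultivar's gene identity rate divides by
its non-missing calls, and pairwise-complete samples define LD r².
Coordinates follow VCF convention (1-based positions); density windows are
half-open `[k·step, k·step + window)`.

# The selection cascade

Stage order and thresholds (see `filter_params()`):

| stage | rule | boundary |
|---|---|---|
| depth/biallelic | call depth must exceed 4; locus must be a single-base biallelic SNP | strict `> 4`; any non-ACGT or extra allele fails |
| consensus | modal genotype per cultivar if gene identity rate ≥ 70% | inclusive, so 7/10 agreeing calls qualify |
| polymorphism + HWE | non-missing consensus calls not all identical; exact HWE p ≥ 1e-5 | strict `< 1e-5` removes |
| missingness + MAF | consensus missingness ≤ 30% and consensus MAF ≥ 0.01 | strict `> 0.30` / `< 0.01` remove |
| PIC | Botstein PIC ≥ 0.1 from consensus frequencies | strict `< 0.1` removes |
| LD pruning | sliding 50-SNP window, 10-SNP step, r² ≤ 0.99 | strict `> 0.99` removes one of the pair |

Each boundary is read literally from the workflow the package implements;
all are configurable. Two level choices deserve justification:

* **HWE runs on pooled sample genotypes.** With only four cultivar
  consensus calls the exact test's smallest attainable p-value is far
  above 1e-5, so a consensus-level test would be a no-op; the filter is
  only meaningful on the pooled individuals. The level is exposed as
  `filter_params(hwe_level = )` for users who want the (vacuous)
  consensus variant.
* **Missingness, MAF and PIC run on the consensus matrix.** They are
  applied after consensus construction, and with four cultivars the
  attainable consensus MAF values are multiples of 1/8 — which is why a
  minimal polymorphic locus has MAF 0.125, PIC ≈ 0.195 and expected
  heterozygosity ≈ 0.219, the boundary values the analytic tests pin.

A locus with some missing consensus calls whose non-missing calls agree is
treated as non-polymorphic (the missing cultivars contribute no evidence
of variation). LD pruning operates on sample-level genotypes of the loci
alive at that stage — 40 dosage vectors resolve correlation far better
than 4 consensus calls — removing the lower-MAF member of an offending
pair (ties remove the later locus), matching common pruning-tool behavior.
The r² is the squared Pearson correlation of 0/1/2 dosages over
pairwise-complete samples; haplotype-EM r² is out of scope.

The `FilterReport` guarantees `n_out = n_in − n_removed` per stage and
chaining across stages; per-locus removal reasons are retained.

# The exact Hardy–Weinberg test

Conditional on observed allele counts, the heterozygote count under HWE
follows the Levene/Haldane distribution; the two-sided p-value sums the
probabilities of all configurations no more probable than the observed one.
Probabilities are computed by the standard parity recurrence in log space
and normalized, which is stable to n in the thousands; a 1e-9 relative
fudge guards the `≤` comparison against floating-point ties.

Because the statistic is discrete, the p-value is *super-uniform* under
the null — P(p ≤ t) ≤ t with large jumps at small n — so naive
uniformity checks of p itself must fail even for a perfect implementation
and a perfect simulator. Calibration therefore uses the randomized
probability integral transform
u = P(prob(T) < prob(obs)) + U·P(prob(T) = prob(obs)), which is exactly
Uniform(0,1) under HWE sampling and detects simulator deviations just as
well (`hwe_exact_pit()`); the raw p-value's super-uniformity bound is
asserted alongside.

# Similarity validation

For samples i, j: `similarity = consistent / common`, where heterozygotes
match only heterozygotes (consistent *typing*, not allele sharing).
Panel validation regresses core-panel similarity on total-SNP similarity
over all n(n−1)/2 unordered pairs — self-pairs are excluded, since their
similarity is 1 in both panels and would inflate the correlation — and
reports the OLS fit with Pearson r and its two-sided t-test p-value.
The identity `p_distance = 1 − similarity` holds on identical locus sets
and missing-handling, and is computed by an independent code path (indicator
matrix products) as a cross-check.

# Population structure

* **PCA** uses the genomic relationship matrix of standardized dosages
  `z = (x − 2p)/√(2p(1−p))`, missing entries contributing zero after
  centering (mean imputation). Coordinates are eigenvectors scaled by
  √eigenvalue; variance fractions are taken over the positive eigenvalue
  mass.
* **Neighbor-joining** on p-distance delegates the Saitou–Nei
  agglomeration to `ape::nj`; small negative branch-length estimates are
  clamped to zero with the deficit moved to the sibling edge, preserving
  path lengths through the parent. Bootstrap resamples loci (columns,
  not samples) and supports attach to bipartitions of the reference tree;
  replicates that leave a sample pair with no common locus fall back to
  maximal distance 1 for that pair.
* **Admixture** maximizes the binomial likelihood
  `Σ g log(QF) + (2−g) log(Q(1−F))` by multiplicative EM updates
  (monotone in the likelihood; Q rows remain exactly on the simplex, F is
  clamped to [1e-6, 1−1e-6]). Dedicated block-relaxation solvers are
  faster per iteration, but at desk scale (40 samples × a few thousand
  loci) EM with 8 random restarts, tolerance 1e-6 relative log-likelihood
  and a 2000-iteration cap converges in a few hundred iterations and
  avoids a compiled dependency; this is a deliberate fidelity/simplicity
  trade-off with the same optimum.
* **Choosing K** masks a fold of non-missing genotype *entries*, refits,
  and scores RMSE of `g − 2·(QF)` on the held-out entries; the CV error
  per K averages folds and the argmin (ties to smaller K) is selected.
  An RMSE criterion rather than held-out deviance keeps the error on the
  genotype scale; the fold partition, restarts and initialization all
  derive from one seed.

# The simulator

`sim_config()` encodes the study design the analyses assume: 4 cultivar
populations × 10 diploid individuals, biallelic SNPs spread uniformly over
31 chromosomes (10 Mb each by default), ancestral minor-allele frequency
Uniform(0.05, 0.5) randomly assigned to the reference or alternate allele,
Balding–Nichols per-population frequencies (Beta with mean p, variance
Fst·p(1−p); Fst defaults to 0.2), genotypes Binomial(2, p_pop) — exact
HWE within population — Poisson depth with mean 11.6, and a call missing
when an MCAR draw falls below 0.05 or its depth is ≤ 4. The default of
40,000 loci is a desk-scale stand-in for a GBS call set of hundreds of
thousands of sites, sized so that a few thousand loci survive the cascade;
at these settings the whole pipeline runs in seconds and the admixture
cross-validation in minutes on one CPU.

What the simulator does *not* emulate: linkage disequilibrium (loci are
exchangeable; an optional block-copy mode duplicates genotype columns with
flip noise purely so LD pruning has work to do), non-Poisson depth
overdispersion, allele-specific dropout or genotyping error, and any
demography beyond a single star-shaped divergence. Tests passing on these
fixtures therefore demonstrate correctness of the algorithms under the
stated sampling model, not robustness to artifacts of real GBS data.
Within-cultivar heterogeneity arises naturally from binomial sampling;
an `admixture_noise` knob adds off-cultivar ancestry for experiments, but
defaults to 0 so that within-population HWE holds exactly.

# Numerical and degenerate-input choices

* Report rounding is half-up at 3 decimals (`round_half_up()`), matching
  conventional table formatting rather than banker's rounding.
* A zero-genotype HWE test returns p = 1 (no evidence); an all-missing
  locus has undefined statistics (NA), never 0.
* Ties in the consensus mode cannot pass an identity threshold above 0.5
  and thus never decide a consensus.
* `cor()` returning NA (monomorphic column) never triggers LD removal.
* An empty surviving panel is valid: the report is complete and a warning
  is emitted.
* Every stochastic stage derives its own stream from one global seed via
  a stage-name hash, so stages are independently reproducible and
  reordering analyses does not perturb earlier results.

# Known limitations

Consensus-level MAF/PIC with four cultivars is extremely coarse (nine
attainable frequencies), so the PIC stage rarely removes anything beyond
what the polymorphism screen already caught — its value appears with more
cultivars. The admixture model assumes unlinked loci; applying it after
LD pruning is consistent with that assumption, but the CV error is still
computed under independence. The NJ bootstrap assumes loci are
exchangeable, which the simulator satisfies but real reduced-representation
data only approximates.
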