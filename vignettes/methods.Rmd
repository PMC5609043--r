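---
title: "Models and methods behind pigpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pigpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models each
stage implements, the assumptions behind them, the parameter defaults and
why they were chosen, what the synthetic-data generators do and do not
emulate, and the numerical choices that were genuinely open. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## Data model

Genotypes are dosages of a *counted allele*: an integer matrix with samples
in rows, variants in columns, entries in {0, 1, 2, NA}. Missing calls are
`NA` throughout; no numeric sentinel such as -9 ever enters arithmetic.
The counted allele is the ALT allele in VCF and the first allele column (A1)
in BIM files; PED files carry no designation, so the counted allele of a
biallelic column is fixed by convention to the lexicographically greater
allele label (which subsumes PLINK's 1/2 recoding). A monomorphic PED column
is read as dosage 0 of its single observed allele — the file simply does not
determine the other allele, a limitation inherent to the format.

Intervals (gene annotations) are stored 0-based half-open internally;
variant positions are 1-based, matching their VCF/MAP display convention.
Conversions happen only at I/O boundaries, so no off-by-one can accumulate:
a BED record `100 200` and a GFF3 record `101 200` normalize to the same
internal interval. Only autosomal, diploid, biallelic data are in scope;
imputation and statistical phasing are out of scope (phased input is
consumed, never inferred).

## Quality control

`filter_samples()` reproduces the cohort-assembly cascade common to
SNP-array diversity panels: breeds with fewer than 5 members are dropped;
within breeds that entered with more than 20 members, one random member of
every pair with IBS similarity above 0.95 is removed (seeded), and survivors
are ranked by call rate with the top 20 kept. Relatedness pruning applies
only to over-cap breeds, matching the protocol this mirrors. `filter_variants()`
removes variants below the MAF threshold (default 0.01) or 90% call rate,
then samples below 90% call rate, in that order; MAF is recomputed on the
entering sample set so repeated application is idempotent.

`ld_prune()` slides 50-variant windows advanced by 10 and greedily drops one
member of every retained pair with genotype r² > 0.2. Which member to drop
is not specified by the protocol this mirrors; the package drops the variant
with the lower MAF (tie: later position), a deterministic rule close to
common practice. Bitwise concordance with any particular external pruning
tool is explicitly not a goal — the relevant guarantee, asserted by tests,
is that no retained pair within a window exceeds the r² ceiling.

## Structure

IBS similarity between individuals i and j is the mean over co-called
variants of $(2 - |d_i - d_j|)/2$; distance is its complement. Pairs with no
co-called variants are `NA` with a warning, never silently zero. The
computation is exact (indicator cross-products), so it is invariant to
variant order and allele-coding flips.

Ordination uses classical Torgerson scaling — the double-centered
eigendecomposition computed by `stats::cmdscale()` — on the 1 − IBS matrix.
The tool chain this emulates documents only "MDS"; classical scaling was
chosen because it is deterministic and reproduces Euclidean-embeddable
distances exactly, which the tests assert to 1e-9. Coordinates are defined
only up to rotation/reflection, so all tests compare distance matrices,
never raw coordinates. Negative eigenvalues (non-Euclidean input, which
1 − IBS can be) trigger a warning and are clipped from the axes.

Trees come from Saitou–Nei neighbor joining (`ape::nj`) on an optionally
subsampled matrix (at most 6 individuals per population, seeded), with
negative branch lengths set to zero and the deficit moved to the adjacent
branch — the convention popularized by PHYLIP. NJ is consistent on additive
matrices; the tests exercise this on random 6–10-leaf trees.

Geographic distances are haversine great-circle distances on a sphere of
mean Earth radius 6371.0088 km, between population centroids (mean member
coordinates). The genetic–geographic correlation is a plain Pearson
correlation over population pairs with the t-based p-value, treating pairs
as independent — the field's conventional (if statistically generous)
analysis; a label-permutation p-value is available for callers who want a
null-respecting alternative, and a Mantel test is deliberately out of scope.
Population-level genetic distance defaults to the mean of between-population
individual distances; a frequency-centroid alternative is exposed because
the aggregation step is genuinely underdetermined.

## Admixture model

Each individual's genome is a mixture of K ancestral populations with
proportions $q_i$ (on the simplex); the dosage at variant j is
$d_{ij} \sim \mathrm{Binomial}(2, \pi_{ij})$, $\pi_{ij} = \sum_k q_{ik} p_{kj}$.
`fit_admixture()` maximizes the likelihood by plain EM with the standard
expected-ancestry-count updates. EM was chosen over quasi-Newton block
relaxation deliberately: it is simpler, provably monotone in the
log-likelihood (asserted at every iteration in tests), and adequate at the
cohort sizes this package targets. The cost is slower convergence near the
optimum, mitigated by multiple restarts (default 3, Dirichlet-random initial
Q, jittered observed-frequency initial P) with best-likelihood selection.
Convergence is declared when the log-likelihood improves by less than `tol`
(default 1e-4, a documented choice — not an inference about any external
program's settings); `max_iter` defaults to 2000. Missing genotypes
contribute to neither update (complete-case per entry). $\pi$ is clamped to
[1e-9, 1 − 1e-9] so boundary configurations cannot produce infinite
log-likelihoods. Component order is arbitrary (label switching);
`match_ancestry_columns()` handles it in tests by permutation matching, and
the estimator itself makes no ordering promise. K is swept by the caller;
no cross-validation criterion is imposed.

## Runs of homozygosity

`detect_roh()` is the two-stage SNP-count sliding-window scan in the style
of PLINK's `--homozyg`: a 50-SNP window is "homozygous" when it has at most
1 heterozygous and 5 missing calls; each SNP is scored by the fraction of
overlapping windows called homozygous; runs of SNPs scoring at least 0.05
(the scanning tool's documented default, since the protocol does not state
it) become segments, reported when they have ≥ 50 SNPs and span ≥ 500 kb.
Protocols in this literature often quote both a kb window and a SNP-count
window; the SNP-count window is primary here because the het/missing
allowances are per-SNP-window parameters in the tool family this mirrors,
and a 5-Mb span guard disqualifies windows stretched over sparse regions.
Exact numeric concordance with any particular PLINK build is a non-goal.

F_ROH divides summed segment length by a genome denominator. The default is
the SNP-map span (sum over chromosomes of last minus first SNP position),
which keeps the statistic self-contained; a fixed assembly length can be
supplied for cross-study comparability. Which of the two any given published
F_ROH used is generally unstated, so both are supported and neither is
asserted as "the" convention.

## Haplotype diversity

For each population with at least 10 individuals, exactly 10 individuals
(20 haplotypes) are drawn — never all of them, even in larger populations —
so values are comparable across populations of different sizes. Chromosomes
are tiled with non-overlapping windows of 5, 10 and 15 SNPs (trailing
remainder dropped) and the statistic is the mean number of distinct
haplotype strings per window. Non-overlapping windows were chosen because
they make window counts unambiguous; the source protocols say only
"windows". Input must be phased and complete; the package never phases.

## LD and effective population size

Pairwise LD is the squared Pearson correlation of dosage vectors over
co-called samples, after excluding variants with MAF ≤ 0.05 or exact-HWE
p ≤ 1e-6 (the Wigginton-style exact test, anchored at the modal heterozygote
count for numerical stability at large n, validated against full enumeration
for all tables up to n = 30). "Adjacent" mode reproduces the classical
within-population computation; "window" mode takes all pairs within a
physical distance and is what the Ne trajectory uses, because adjacent-only
pairs populate long-range bins poorly.

Genetic distance c (Morgans) comes from the variant table's map positions
where present, otherwise physical distance × a constant rate (default
1 cM/Mb, logged as a fallback). Ne comes from inverting the Sved relation at
bin means: $N_e = (1/\bar{r^2} - 1)/(4\bar{c})$, with the bin labelled
generation $T = 1/(2\bar{c})$. No sample-size correction is applied by
default (matching the analysis this reproduces); an optional adjustment
subtracts $1/(2n)$ from $\bar{r^2}$ first. Bins whose mean r² falls outside
(0, 1) — possible after adjustment or in tiny bins — are skipped with a
warning. A whole-range nonlinear least-squares fit of a single Ne is also
reported for convenience.

## Fst scan

Per-SNP differentiation is the Weir–Cockerham (1984) variance-components
estimator for the two-population biallelic case,
$\theta = a/(a+b+c)$, with the standard finite-sample and heterozygosity
corrections. Negative estimates are kept: they are informative about
sampling noise, and can never enter a top-quantile outlier set. Two
summaries coexist deliberately: per-SNP θ is the ranking statistic for the
outlier scan, while the genome-wide figure is the multi-locus ratio of
summed components ($\sum a / \sum (a+b+c)$) — the estimator Weir and
Cockerham define for multiple loci, and the one that is consistent for the
generating drift parameter. Averaging per-SNP ratios is known to deflate the
genome-wide value and is reported separately.

Outliers are the `round(q·M)` top-θ variants (q defaults to 0.01); ties at
the cutoff and NA values resolve by genome order, making the selection
deterministic and invariant under monotone transforms of θ. Candidate genes
are those whose interval lies within an inclusive 100-kb flank of an outlier
SNP. Whether two scans share more outliers than chance is judged against a
resampling null: random outlier-sized sets drawn without replacement from
the common variant universe, with empirical p `(1 + #{null ≥ obs})/(1 + R)`;
the null mean is the hypergeometric expectation $|A||B|/M$, which the tests
verify.

## Synthetic-data generators

Each generator produces data with exactly known truth for one validation
axis, and is bit-reproducible from its arguments plus a seed (generators
save and restore the caller's RNG state).

- **Balding–Nichols** (`sim_balding_nichols`): ancestral frequencies
  Uniform(0.05, 0.95); population frequencies Beta-drifted with parameter F;
  individuals pure, Dirichlet-admixed, or given an explicit Q. Chosen over
  coalescent simulation for structure/Fst truth because F maps directly onto
  expected Fst. An optional ascertainment emulation was considered and
  rejected as out of scope for the properties tested.
- **Stepping stone** (`sim_stepping_stone`): demes on a line, symmetric
  nearest-neighbor migration at rate m then binomial drift, genotypes drawn
  from final deme frequencies; coordinates assigned along a parallel. This
  forces isolation by distance, the truth for the genetic–geographic
  correlation; m > 0.5 and single-deme configurations are rejected.
- **Wright–Fisher** (`sim_wright_fisher`): discrete generations, standing
  variation, per-gamete crossover counts Poisson in the map length. Forward
  simulation (not coalescent) was chosen because the Sved relation concerns
  recent pedigree LD, and the realized Ne equals the census size by
  construction. Replicates of small populations can lose all variation to
  drift; downstream analyses treat such replicates as uninformative (NA)
  rather than inventing a value.
- **Pedigrees** (`sim_pedigree_inbreeding`): gene dropping of labelled
  founder haplotypes with recombination through outbred, full-sib
  (expected F = 0.25), n-generation selfing (F = 1 − 2⁻ⁿ), and
  F1-of-inbred-lines designs (heterozygous everywhere, hence zero ROH).
  Realized autozygosity is returned per offspring alongside the pedigree
  expectation. The default genome — 5 chromosomes × 120 Mb, one SNP per
  40 kb, 1 cM/Mb — mimics a 60K-array density on a pig-sized autosomal map.

What the generators do *not* emulate: SNP ascertainment bias, genotyping
error, non-uniform recombination maps, selection, and overlapping
generations. Passing tests therefore validate the estimators under their
own model assumptions, not robustness to array design artifacts.

## Problem sizes and determinism

The validation suite runs at desk scale, chosen so the full suite completes
in about a minute: Fst consistency uses 2 × 200 samples × 5,000 SNPs;
admixture recovery 100 samples × 1,000 SNPs; the Wright–Fisher Ne study 50
replicates of N = 50 over 200 generations on a 10-Mb/0.1-Morgan chromosome
(400 initial SNPs); the pedigree ROH study 200 gene-dropped full-sib
offspring; the ROH-vs-diversity contrast five populations with N from 12 to
200. Every stochastic step takes an explicit seed, and the acceptance script
derives all of its seeds from a single `--seed` argument.

## Known limitations

- PED round trips cannot restore the counted allele of columns observed
  monomorphic (format limitation, documented above).
- The EM fit can stop short of the global optimum for small `tol` budgets;
  restarts mitigate but do not eliminate this.
- LD pruning guarantees the r² ceiling only within its scanning windows, as
  windowed pruning always does.
- The Pearson p-value of the geography correlation inherits the
  non-independence of distance pairs; use the permutation option when the
  p-value itself matters.
- Sved inversion assumes drift–recombination equilibrium; trajectories from
  recently bottlenecked or admixed populations reflect that assumption.
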