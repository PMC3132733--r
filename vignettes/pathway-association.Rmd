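---
title: "Pathway-based association analysis for case-control GWAS"
author: "pathwayGWAS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based association analysis for case-control GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwayGWAS)
```

## The problem and the model

Single-SNP genome-wide association scans are underpowered for complex
phenotypes in which many variants of small effect act through a common
biological pathway. Pathway-based association analysis borrows the logic
of gene set enrichment analysis: rank all genes by their strength of
association with the phenotype, then ask whether the members of a
candidate pathway concentrate near the top of that ranking more than
chance allows. The motivating application is a matched case-control study
of osteoporotic hip fracture genotyped on a genome-wide SNP array, testing
an apoptosis-signalling pathway of 38 genes — but the machinery is
generic: any case-control cohort, any SNP-to-gene annotation, any gene
set.

The pipeline has four stages.

**1. SNP quality control.** A SNP is discarded when its call rate is
below 90%, its Hardy-Weinberg exact-test p-value is below $10^{-7}$, or
its minor allele frequency (MAF) in the total sample is below 0.01.
Boundary values pass: the discard rules are strict inequalities. The HWE
test is the exact conditional test — the probability of every possible
heterozygote count given the subject count and minor-allele count is
enumerated, and the p-value sums the probabilities of all outcomes no
more probable than the observed one. We chose the exact test over the
chi-square approximation because a $10^{-7}$ threshold targets the
extreme tail, exactly where the chi-square approximation is least
reliable at low genotype counts. MAF and HWE are computed on non-missing
genotypes in cases and controls combined.

**2. Per-SNP association.** Each SNP is tested with a Wald test in an
additive-coded logistic regression,
$$\mathrm{logit}\,P(\text{case}) = \beta_0 + \beta_1 d + \beta_2\,
\text{age} + \beta_3\, \text{sex},$$
where $d \in \{0,1,2\}$ counts minor alleles. The per-allele odds ratio
is $e^{\beta_1}$ with 95% CI $e^{\beta_1 \pm 1.959964\,\mathrm{se}}$.
Subjects with a missing genotype are dropped for that SNP only. Fits
with constant dosage are flagged as monomorphic; non-convergence or an
implausibly large $|\beta_1|$ (above 12 on the log-odds scale) or
standard error is flagged as suspected complete separation, and flagged
SNPs carry no p-value rather than an unstable one — a very wide CI
around an extreme OR is a symptom of sparse cells, not evidence.

Inflation from residual structure is checked by genomic control: each
p-value is converted to a 1-df chi-square statistic and
$\lambda = \mathrm{median}(\chi^2)/0.4549364$. When $\lambda > 1$ every
statistic is divided by $\lambda$ before conversion back to a p-value;
when $\lambda \le 1$ p-values are left untouched, the standard practice.

**3. Gene statistics and ranking.** A gene is represented by its most
significant surviving SNP: $p_{\min}$ over the gene's SNPs, transformed
to the ranking statistic $r = -\log_{10} p_{\min}$. Genes with no array
coverage or whose SNPs were all removed by QC simply drop out of the
analysis (and members of the tested set that drop out reduce its
effective size $N_S$). Genes are sorted by decreasing $r$ into the list
$L = (r_1 \ge r_2 \ge \dots \ge r_N)$.

**4. The weighted running-sum enrichment score.** Walking down $L$, the
running sum increases by $|r_j|^p / N_R$ at members of the set $S$
(where $N_R = \sum_{g_j \in S} |r_j|^p$) and decreases by $1/(N - N_S)$
at non-members. With weight $p = 1$ (the default) genes with extreme
statistics dominate the increments; $p = 0$ recovers the classic
unweighted Kolmogorov-Smirnov statistic. The enrichment score ES is the
maximum positive deviation of the walk, so $0 \le \mathrm{ES} \le 1$,
and the *leading edge* is the set members ranked at or before the
position where the maximum is attained. Significance comes from
permuting the case/control labels uniformly across subjects — genotypes
and covariates stay attached to their subjects, preserving their joint
structure — and recomputing *the whole pipeline* (scan, gene statistics,
ranking, score) for each of $K$ permutations (default $K = 1000$). The
nominal p-value is the fraction of permuted scores at least as large as
the observed one, and the normalized enrichment score is
$$\mathrm{NES} = \mathrm{ES}_{\text{obs}} \big/
\overline{\mathrm{ES}}_{\text{perm}},$$
the observed score over the mean of the (positive) permuted scores.

## Design choices where the method is underdetermined

Several points of the procedure admit more than one reasonable reading;
the package fixes them as follows and exposes switches where an
alternative is defensible.

- *Ranking statistic.* "Association evidence" is not a single number;
  we rank by $-\log_{10} p_{\min}$, which is positive, monotone in
  evidence, and weights extreme genes heavily — matching the intent of
  the weighted increment. A 1-df chi-square quantile alternative is
  available (`statistic = "chisq"`).
- *Sign convention.* ES is the maximum *positive* deviation, so a set
  depleted from the top of the list is never reported as enriched. A set
  whose members all sit at the very bottom of the list scores 0, the
  infimum of the statistic; the theoretical range `0 < ES <= 1` is
  attained whenever at least one member precedes a non-member.
- *Ties.* A tie in $p_{\min}$ within a gene resolves to the
  lexicographically smaller SNP id; ties in $r$ across genes rank in
  ascending gene id (C-locale radix order). Both are arbitrary but
  deterministic, so repeated runs are byte-identical.
- *Permutation p tie rule.* Permuted scores equal to the observed score
  count toward the p-value (the `>=` rule), so p is never artificially
  zero; a p of exactly 0 is still possible and is formatted as below
  resolution, e.g. `<0.001` at $K = 1000$.
- *Degenerate weights.* If every member statistic is exactly zero,
  $N_R = 0$ and the weighted increment is undefined; the score falls
  back to equal member weights ($1/N_S$), the $p = 0$ limit.
- *Covariates.* Age (years, uncentred) and sex (0 = female, 1 = male)
  are the default covariates when present; constant covariate columns
  are dropped before fitting since they carry no information and would
  make the normal equations singular. Affine recoding of covariates
  leaves the dosage Wald statistic invariant.
- *Multiple pathways.* The multi-set driver shares one permutation
  stream across sets (each permutation's re-ranked list is scored
  against every set) for consistency and speed; it applies no
  cross-pathway correction by default, with an optional
  Benjamini-Hochberg column (`adjustBH = TRUE`).
- *Fast approximate mode.* `mode = "gene"` redraws random sets against
  the observed ranking instead of permuting phenotypes. It ignores
  inter-SNP correlation and gene-size effects on the scan and is *not*
  the reference method; it exists for quick exploration only.

## What the synthetic cohorts emulate — and what they do not

Because the genotype data of the motivating study were never deposited,
the package ships a generator that reproduces the *structure* of such a
cohort with known truth:

- biallelic SNPs drawn independently per subject as Binomial(2, MAF) —
  i.e. exact Hardy-Weinberg proportions;
- independent per-entry genotype missingness at a configurable rate;
- Gaussian age (default 69.4 years, SD 6.8) and Bernoulli sex (default
  42% male), matching an elderly fracture cohort;
- disease status from a logistic model with per-minor-allele log-odds
  effects planted in the first SNP of each designated causal gene, all
  causal genes belonging to one designated pathway; age/sex effects
  default to zero but are configurable so confounding scenarios can be
  constructed;
- either a population design (status sampled per subject) or a fixed
  case/control design via rejection sampling (e.g. 350/350) to mirror a
  matched study.

Missing genotypes contribute their expected dosage $2 \times$ MAF to the
*risk model* only; the association stage drops those subjects per SNP.
The two conventions are independent and both documented.

The generator deliberately omits linkage disequilibrium, haplotype
structure and population admixture. The pipeline's statistics never
model LD — the permutation null inherits whatever correlation the data
carry — so independent SNPs are sufficient to validate correctness,
calibration and power of the implementation. Passing tests therefore
demonstrate that the machinery is right, *not* that real-data p-values
are immune to LD-induced clumping of gene statistics or to population
stratification beyond what genomic control captures.

## Numerical choices and problem sizes

The logistic fits use iteratively reweighted least squares in compiled
code (convergence when the largest coefficient change falls below
$10^{-8}$, 30 iterations maximum, fitted probabilities clamped away from
0/1), because the permutation null refits every SNP for every
permutation; agreement with `stats::glm` is at the level of glm's own
stopping rule (~$10^{-6}$). The HWE exact test enumerates in log-space
with a $1+10^{-10}$ relative guard on the "no more probable" comparison
so that floating-point jitter cannot drop exactly-tied outcomes.

The validation suite runs at desk scale, chosen to finish in minutes
while keeping the statistical checks sharp: type-I error uses four null
cohorts of 400 subjects, 2000 SNPs in 200 genes and 25 sets each at
$K = 200$ (100 null p-values); power uses fifty replicates of a 500/500
cohort with 7 causal genes (per-allele OR 1.6, MAF 0.3) inside a 38-gene
set among 150 genes at $K = 200$. The same conditions, at $K = 1000$,
drive `scripts/acceptance.R`.

## A worked example

```{r example, eval = FALSE}
st <- simulateStudy(nGenes = 150, snpsPerGene = 1, setSizes = c(38, 38),
                    nCausal = 7, effectSize = log(1.6), causalMaf = 0.3,
                    fixedCounts = c(500, 500), seed = 1)
qc <- applyQc(st$genotypes)
qc$report

res <- runPathwayAnalysis(qc$genotypes, st$truth@geneSets,
                          st$truth@snpGeneMap, k = 1000, seed = 14)
res[, c("set", "nS", "es", "nes", "nominalP")]

S4Vectors::metadata(res)$results[[1]]   # leading edge, profile, perm ES
```

The first set carries the planted signal and should attain a small
nominal p with its leading edge dominated by the causal genes
(`st$causalGenes`); the second, disjoint set is a size-matched negative
control.

## Known limitations

- No LD-aware gene statistics: a gene's min-p is taken at face value, so
  on real data gene size and SNP density influence the ranking (the
  permutation null accounts for this in distribution but the ranking
  itself is density-biased, a known property of min-p collapsing).
- Phenotype permutation assumes exchangeable subjects under the null; a
  structured cohort (relatedness, strata) would need restricted
  permutations, which are not implemented.
- Only the genomic-control component of stratification checking is
  provided; ancestry inference (PCA/model-based clustering) is out of
  scope.
- The PED/MAP reader holds genotypes densely in memory; it is meant for
  cohorts up to a few hundred thousand SNPs, not biobank scale.
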