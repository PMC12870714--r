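---
title: "Methods: gene-centric rare-variant screening with varscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centric rare-variant screening with varscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varscreen)
```

## The problem

Rare coding variation in a single candidate gene can contribute to disease
risk through several distinct signatures: ultra-rare, highly penetrant
alleles seen only in affected individuals; modest per-allele effects
detectable by case-control association; a cumulative gene-level burden; and
co-segregation with disease inside pedigrees. Large multi-cohort studies of
neurodegenerative disease (Alzheimer's disease, related dementias,
dementia with Lewy bodies, Parkinson's disease) screen all four signatures
per ancestry stratum, plus a fifth line of evidence from population GWAS
summary statistics: single-causal-variant fine-mapping of the gene's
region. `varscreen` packages that whole workflow — readers and writers for
the interchange formats, the statistics, and a synthetic-cohort generator
that makes every stage testable without access-controlled data.

The unit of analysis is one gene region (the bundled demonstration mirrors
a roughly 180 kb locus on chromosome 11); multi-gene screens iterate.
Analyses are run within strata defined by genetically determined ancestry
(eleven labels: EUR, AFR, AMR, AAC, AJ, CAS, EAS, SAS, MDE, FIN, CAH) and
disease group, mirroring how joint-called biobank data are released.

## The filter cascades

The case-control prioritization cascade retains a variant when all of the
following hold in the stratum:

* **present only in cases** — control alternate-allele count 0;
* **minor allele count at least 2 in cases** — conservative against
  genotyping or imputation artifacts (singletons are unverifiable);
* **CADD phred score strictly above 20** — about the top 1% most
  deleterious substitutions genome-wide;
* **protein-altering or splicing consequence** — here the closed set
  \{missense, stopgain, frameshift\} plus splicing.

The criteria are conjunctive, so filter order cannot change the result;
the pipeline asserts the cascade is monotone (adding a criterion never
enlarges the surviving set). The allele-count threshold is applied within
the ancestry stratum, the same place the case-only rule is applied; since
controls contribute zero alternate alleles by construction, the count is
effectively counted in cases.

The family track uses a different damaging-variant definition:
loss-of-function consequences (stopgain, frameshift, splicing) are kept
regardless of CADD, missense requires CADD > 20, and the ancestry-specific
reference allele frequency (a gnomAD-style panel, consumed as a table)
must be below 1%. A missing reference frequency is treated as 0 — an
allele absent from the panel is, by definition, not known to be common;
the alternative (dropping such variants) would silently discard exactly
the novel alleles the track exists to find.

Frequencies are rendered in scientific notation with three significant
digits (`2.58E-04`), matching the convention of published carrier tables;
zygosity is reported as `het (k), hom (k)`. Missing genotypes are excluded
from every denominator and never imputed, with one documented exception in
the burden kernel (below).

## Single-variant association

Per variant, an additive-dosage logistic regression of case status on
dosage, sex, age, and ten principal components (maximum likelihood,
complete-case rows). The report carries the Wald per-allele odds ratio,
95% confidence interval and p-value, plus the effect-allele frequencies in
affected (`f_a`) and unaffected (`f_u`) individuals, which are asserted to
match the allele-statistics module exactly. Monomorphic variants are
skipped with a reason. Covariate columns that are aliased (constant or
collinear) are dropped before fitting, so a fit with zero-information
covariates equals the covariate-free fit exactly.

Separation is a fact of life for ultra-rare variants: with zero carrier
controls the ML odds ratio diverges. The package deliberately reports the
plain ML/Wald fit — published tables print exactly such extreme intervals
— and flags the row (`converged = FALSE`, triggered by non-convergence,
|log OR| > 10, or a near-singular information matrix), substituting the
Haldane-Anscombe crude allelic odds ratio as the point estimate. Firth
penalization was considered and rejected as a default because it would
silently change the estimand relative to the reported convention; it can
be layered on by the user.

Multiple testing uses the per-stratum Bonferroni threshold `0.05 / m`,
where `m` is the number of variants the package itself tested in that
stratum — never a count imported from elsewhere.

Carrier enrichment between cases and controls uses the one-sided Fisher
exact test (hypergeometric tail, greater-in-cases) with the conditional
MLE odds ratio, via `stats::fisher.test`; the test suite checks it against
a from-scratch enumeration of all tables with the observed margins.

## SKAT-O, from scratch

Gene-level burden testing uses the score statistics

$$Q_\mathrm{SKAT} = \sum_j (w_j g_j^\top r)^2, \qquad
  Q_\mathrm{burden} = \Big(\sum_j w_j g_j^\top r\Big)^2,$$

with $r = y - \hat\mu$ the residuals of the logistic null model (sex, age,
PC1–10) and $w_j$ the Beta(1, 25) density at the pooled-sample alternate
allele frequency — finite as the frequency tends to 0 and decreasing on
(0, 0.5]. SKAT-O scans the convex combinations
$Q_\rho = (1-\rho)Q_\mathrm{SKAT} + \rho Q_\mathrm{burden}$ over the grid
$\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ (the standard
grid: the squares of evenly spaced correlations, plus 0.5 and the pure
burden end).

Under the null, the score vector $S$ is asymptotically
$N(0, \Sigma)$ with $\Sigma$ the covariate-projected kernel
$G_w^\top V G_w - (G_w^\top V X)(X^\top V X)^{-1}(X^\top V G_w)$,
$V = \mathrm{diag}(\hat\mu(1-\hat\mu))$. Each $Q_\rho$ is then a mixture
of 1-df chi-squares whose weights are the eigenvalues of
$R_\rho^{1/2}\Sigma R_\rho^{1/2}$; tail probabilities come from numerical
inversion of the characteristic function (Imhof's integral) with a
moment-matching (Liu-Tang-Zhang) fallback that is flagged when used.
Numerical choices that matter:

* the Imhof integral is truncated where the oscillating integrand's
  envelope divided by the oscillation frequency drops below 1e-9, which
  keeps the adaptive quadrature on a finite, well-behaved range;
* mixture components below 1e-4 of the largest eigenvalue are absorbed as
  their deterministic mean — their variance is negligible but they
  otherwise stretch the integrand's support by orders of magnitude;
* a single-component mixture is evaluated exactly via `pchisq`.

The combined p-value $P(\min_\rho p_\rho \le T)$ is computed **exactly**
under the Gaussian score model rather than by the usual one-dimensional
approximation: conditional on the burden-direction component
$x = (\mathbf 1^\top S)^2/(\mathbf 1^\top\Sigma\mathbf 1) \sim \chi^2_1$,
the SKAT statistic $S^\top S$ is a *noncentral* chi-square mixture (plus a
deterministic offset), so the rejection region's probability is the
noncentral Imhof tail integrated over $x$. The grid quantiles of the
observed minimum p are computed by exact root-finding on the central
Imhof tail. In validation against a 50,000-draw Monte Carlo of the
Gaussian null, the combined p agreed to within Monte-Carlo error
(max 3.1 SE over 12 instances) across the full range of p — the common
shortcut of moment-matched quantiles plus a variance-shrunk central
remainder showed absolute errors up to 0.02 in the same experiment.

Two caveats are deliberate. Missing dosages are mean-imputed within
variant *for the kernel only*, because the kernel needs rectangular input;
this is the one divergence from the strict complete-case rule. And no
small-sample moment adjustment is applied: the p-value is asymptotic, as
in the biobank-scale tools this workflow mirrors. At very small n (tens of
samples) the exact permutation null of a binary trait is visibly discrete
and can differ from any chi-square-based approximation by a few
hundredths in the body of the distribution; the package's own validity
evidence is therefore the Gaussian-null agreement above plus an empirical
type-I error check at n = 1,000 (rejection rate at $\alpha = 0.05$ within
[0.035, 0.065] over 1,000 null replicates).

## Pedigrees and segregation

Families are reconstructed from kinship coefficient pairs: individuals
already in core pedigrees are excluded, edges require kinship strictly
above 0.0884 (the conventional second-degree cutoff, the strict complement
of the relatedness-removal rule used for unrelated cohorts), and each
connected component with at least two members becomes a family whose
members are all recorded as founders — kinship magnitude alone cannot
orient a relationship, and guessing directions would fabricate structure.
Core and inferred sets are merged with source labels preserved;
overlapping membership is an error, and family-id collisions are
namespaced. "Informative" families have at least one PD case and at least
two members.

A candidate variant (from the family-track filter, restricted to the gene
under analysis) is *prioritized* when, in at least one family, every
genotyped PD member carries at least one alternate allele and no genotyped
family control carries it. A PD member missing the genotype neither
supports nor vetoes segregation — it is simply not genotyped. Heterozygous
and homozygous-alternate genotypes both count as carrying. Pathogenic
variants in known PD genes (a user-supplied screen list emulating a
ClinVar query over genes such as *GBA1*, *LRRK2*, *SNCA*, *VPS35*,
*PRKN*, *PINK1*, *PARK7*, *RAB39B*, *RAB32*) are attached to each family's
summary as co-occurring alleles, because a co-carried established variant
weakens the causal interpretation of a segregation signal.

Prioritized variants are then tested for carrier enrichment in an
unrelated case-control cohort with the one-sided Fisher test; with
ultra-rare alleles these tests are expected to be non-significant even
for true risk alleles — the package reports them as evidence, not as a
gate.

## Fine-mapping by approximate Bayes factors

From summary statistics alone, assuming at most one causal variant in the
region, each variant's evidence is the Wakefield approximate Bayes factor

$$\log \mathrm{ABF} = \tfrac12\log\frac{V}{V+W^2} +
  \tfrac12 z^2 \frac{W^2}{V+W^2},$$

with $V = \mathrm{se}^2$, $z = \beta/\mathrm{se}$, and effect-scale prior
$W = 0.2$ on the log-odds scale (the conventional case-control choice;
configurable). Each variant carries prior probability $p_1 = 10^{-4}$ of
being the causal one; the null model (no association in the region) takes
the rest. Posterior masses are normalized in log space so
$\mathrm{pp}_\mathrm{null} + \sum_k \mathrm{pp}_k = 1$ to within 1e-9.

The decision rule exposes both hypotheses against the 0.6
posterior-probability threshold: `causal-candidate` when the best
variant's posterior exceeds 0.6, `null-favored` when the null's does,
`inconclusive` otherwise. A single-trait posterior threshold is ambiguous
between those two readings, so the package reports the three-way decision
and both numbers rather than collapsing them. Multi-signal (conditional or
stepwise) fine-mapping is out of scope; the single-causal assumption is
what the single-PP reporting convention implies.

## The synthetic-cohort generator

`sim_config()` fixes the study conditions; every generator is
deterministic given the seed. Defaults describe a well-powered
single-ancestry stratum: 5,812 cases and 4,411 controls (the size of the
European AD stratum used for the worked examples), one planted case-only
missense variant with CADD 27.3 and 3 heterozygous carriers (the classic
rare carrier pattern, case MAF 2.58E-04), and 200 background variants.
Background genotypes are Hardy-Weinberg draws at their allele frequency,
independent of phenotype and of each other — no linkage disequilibrium.
Half the background is common (MAF 0.05–0.4, any consequence class,
damaging CADD allowed, so the case-only rule is what removes it); half is
rare and benign (CADD < 15), so the planted-truth property of the cascade
is deterministic rather than probabilistic.

Planted association variants are drawn retrospectively: genotypes are
sampled from their exact conditional distributions given case or control
status under a logistic disease model with the configured per-allele odds
ratio, so the case-control conditional odds ratio equals the plant by
construction, with no Monte-Carlo drift from prevalence choices.
Covariates are sampled independently of genotype (null effects):
sex ~ Bernoulli(0.5), age ~ Normal(65, 10) truncated at 18 years,
PC1–10 ~ Normal(0, 1) — plain documented defaults, chosen because the
emulated studies publish none.

Family simulation plants one private rare damaging variant per family
(heterozygous in all PD members and absent from family controls when
segregating; missing from one PD member otherwise), pairwise kinship 0.25,
optional co-planted known-PD-gene pathogenic variants, and an unrelated
case-control cohort (default 1,793 cases / 346 controls with 4 and 0
carriers of each segregating variant — the scale of an East Asian WGS
stratum) for the enrichment stage. The summary-statistic generator gives
non-causal SNPs `beta ~ Normal(0, se)` with
`se = 1/sqrt(2 n maf (1-maf))` and the causal SNP the configured effect
plus the same noise.

What the generator does **not** emulate — and hence what green tests do
not show about real data: linkage disequilibrium (an optional
autoregressive switch exists for stress tests but is off by default),
imputation error and its R² structure, population stratification
correlated with phenotype, genotyping batch effects, pedigree founder
allele-frequency drift, and relatedness *within* the "unrelated" cohort.
Passing tests certify the statistics and the plumbing, not robustness to
those artifacts.

## Problem sizes used by the test and acceptance suites

Tests exercise the worked examples at their printed sizes (e.g. 5,812
cases for the carrier-pattern arithmetic; 1,793/346 for enrichment
counts), Monte-Carlo suites at sizes chosen to keep the whole run in
minutes on one core: 200 replicates of the 5,000/5,000 odds-ratio
recovery, 1,000 replicates of the n = 1,000, 20-variant null for SKAT-O
type-I error, 20,000-permutation oracles at 60 samples for the SKAT-O
combination, 200-node random graphs for pedigree reconstruction, and
200-SNP regions for fine-mapping.

## Known limitations

* Asymptotic SKAT-O only; no relatedness-aware (mixed-model) burden test.
* Single-causal-variant fine-mapping without LD; no colocalization.
* The VCF reader targets uncompressed VCF v4.2 with GT fields — the
  interchange subset the pipeline itself writes — not the full spec.
* One ancestry stratum per run; multi-ancestry analyses loop over strata,
  and a family spanning two ancestry files would be split.
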