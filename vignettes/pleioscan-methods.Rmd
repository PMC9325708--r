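---
title: "Methods: calling causal brain proteins and mRNAs from GWAS and molecular QTL data"
author: "pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling causal brain proteins and mRNAs from GWAS and molecular QTL data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genome-wide association studies point to regions, not genes. For brain
disorders the gap between an associated locus and an actionable gene is
especially wide, because most association signal sits in non-coding
sequence and presumably acts by changing the abundance of some gene
product. `pleioscan` implements a pipeline that integrates GWAS summary
statistics for many brain traits with a reference molecular cohort
(genotypes plus measured protein or mRNA abundance) to nominate genes
whose *cis*- or *trans*-regulated abundance is **consistent with a causal
role** for a trait — "consistent with causality or pleiotropy", never
proven causation, since a single shared variant can act on both abundance
and trait through separate paths.

The pipeline then asks a second-order question: how much of the causal
architecture is *shared* across trait groups (psychiatric disorders,
neurodegenerative diseases, brain-structure measures), both directly
(the same gene called for traits in two groups) and at the network level
(an excess of physical protein–protein interactions between the two
groups' causal-gene sets).

Because the real inputs (dozens of GWAS, hundreds of brain proteomes, a
BioGRID release) cannot ship with a package, `pleioscan` includes a
first-class synthetic-data generator with planted truth. Every stage of
the pipeline has parameter-recovery tests against that truth, and the
`analysis/` scripts run the whole chain end to end on the generated
study.

## Pipeline stages and their models

### Genetic correlations (LD score regression)

For each trait pair we regress the per-SNP product of association
z-scores on `sqrt(N1 N2) * l_j / M`, where `l_j` is SNP *j*'s LD score
(the windowed sum of squared correlations with its neighbours, after the
unbiased small-sample adjustment `r2 - (1 - r2)/(n - 2)`) and `M` the
number of regression SNPs. The slope estimates the genetic covariance;
dividing by the square root of the product of the two univariate slopes
(the SNP heritabilities, from the same regression applied to chi-square
statistics) gives the genetic correlation `rg`. The free intercept
absorbs confounding and sample overlap, which is why the estimator
tolerates overlapping cohorts. SNPs with chi-square above 80 are removed
first, since single huge effects would otherwise dominate the
regression.

Numerical choices: heteroskedasticity weights `1/(1 + N h2 l/M)^2`
recomputed once from an unweighted first pass (no iteration); standard
errors from a 200-block contiguous jackknife, with the rg jackknife
re-deriving all three regressions per deleted block so the error of the
ratio is honest; estimates with either heritability slope at or below
zero are returned as flagged records rather than numbers; |rg| > 1.25 is
flagged but reported. Benjamini–Hochberg FDR is applied across all trait
pairs, with significance tiers at 0.05/0.01/0.001.

### Heritability screen and predictive weights

A gene enters the association stage only if its abundance has a
detectable cis genetic component. We estimate cis SNP heritability by
Haseman–Elston regression — phenotype cross-products `y_i y_j` regressed
on the entries of the cis genetic relationship matrix — which is closed
form and deterministic; the one-sided p comes from a 100-block jackknife
over samples. Genes pass at p < 0.01; genes in the HLA region (default
chr6:25–34 Mb, configurable) are excluded regardless, because the
region's extreme LD makes all downstream inference unreliable.

For each passing gene we train predictive cis weights on
covariate-residualized data with four models — marginal top-SNP, ridge,
lasso and elastic net (alpha 0.5) — and keep the weights of the model
with the best 5-fold cross-validated R2, with one shared fold assignment
per gene derived from the study seed. Ridge stands in for BSLMM: it is
the point-mass-free limit of that model and needs no MCMC. A gene where
no model attains positive CV R2 is dropped with a recorded reason;
because out-of-fold R2 is noisy, a truly null gene escapes the drop rule
in a minority of draws, which is why the screen precedes it.

### Gene-trait association (PWAS/TWAS)

The gene-level association statistic is `z = w'Z / sqrt(w'Rw)`: the
weighted combination of the GWAS z-scores over the weight SNPs, variance-
normalized by the reference-panel LD of those SNPs (ridge-regularized by
1e-6 for stability). Weight SNPs missing from the sumstats are dropped,
not imputed — deterministic and conservative — with counts logged. The
same operation serves proteome and transcriptome weights; the modality
is a label. Genes are tested per trait, BH-adjusted within trait, and
significant at FDR p < 0.05.

### Mediation and linkage (SMR + HEIDI)

For significant genes we test whether abundance plausibly *mediates* the
SNP–trait association: with the top cis pQTL as instrument,
`T_SMR = z_gwas^2 z_pqtl^2 / (z_gwas^2 + z_pqtl^2)` is compared with
chi-square(1). A significant T_SMR is still compatible with linkage —
two distinct causal variants in LD. HEIDI tests that explanation: under
pleiotropy/causality the ratio estimate `b_xy = beta_gwas / beta_pqtl`
is the same at every SNP in LD with the causal variant, so the
deviations `d_i = b_xy(SNP_i) - b_xy(top)` should be jointly zero.
We standardize the deviations with a first-order delta-method covariance
built from the LD matrix, sum their squares, and evaluate the tail of
the resulting positively weighted chi-square mixture (weights = the
eigenvalues of the deviation correlation matrix) by Imhof's integral,
falling back to 1e5 Monte Carlo draws under a fixed sub-seed if the
integration fails; the method used is recorded. Instruments follow the
SMR tool's published defaults — pQTL p < 1.57e-3, r2 to the top SNP in
[0.05, 0.9], at most 20 SNPs, at least 3 to run — all configurable.
Genes with fewer than 3 eligible instruments skip HEIDI (and can then
qualify only through colocalization).

The delta-method covariance is first order, so HEIDI's type-I error is
exactly nominal only in the strong-instrument limit; our null
calibration (500 pleiotropy-null regions with top-instrument z around
13) observes rates near 0.05, rising toward ~0.075 when the top
instrument weakens to z around 11. The SMR tool itself restricts HEIDI
to strong top pQTLs for the same reason.

### Colocalization (COLOC)

As a complementary route we compute the standard single-causal-variant
posterior enumeration from per-SNP Wakefield log approximate Bayes
factors, `log ABF = 0.5 log(1 - r) + z^2 r / 2` with
`r = W/(W + se^2)`, in log space throughout (no overflow up to |z| of
100 and beyond). Priors default to the COLOC tool's `p1 = p2 = 1e-4`,
`p12 = 1e-5`; the prior effect variance is `W = 0.15^2` on the
standardized scale, with GWAS effects reconstructed from z and N as
`se = 1/sqrt(N)`, `beta = z se`. PP4 > 0.5 is the evidence threshold.

### Decision rules

A *cis* gene is called for a trait when it is XWAS-significant (FDR
p < 0.05) **and** either mediation survives the linkage filter (SMR
p < 0.05 and HEIDI p > 0.05; route `SMR_HEIDI`) or the signals
colocalize (PP4 > 0.5; route `COLOC`); `BOTH` records both. The two
published criterion lists share their first condition (the XWAS gate),
which is implemented once.

The *trans* arm clumps each trait's genome-wide-significant SNPs
(greedy by p; r2 < 0.5 within 250 kb), tests every clumped SNP against
every gene, and declares trans pQTLs at p < 5e-8 when SNP and gene are
more than 500 kb apart. Trans SMR is restricted to pairs at least 5 Mb
apart (or on different chromosomes), with HEIDI instruments drawn from
the ±500 kb window centred on the trans SNP. A trans call requires the
pQTL association, a trans-SMR result passing a Bonferroni threshold of
0.05 over the number of significant trans pQTLs, and HEIDI p > 0.05.
The multiplicity rule is switchable to FDR, because the source
description is internally inconsistent on this point; Bonferroni is the
default as the stricter stated rule.

### Sharing and the PPI bootstrap

Per trait and trait group, the sharing percentage is
`100 x |{genes causal for t and for >= 1 other trait in the group}| /
|{genes causal for t}|`, within-group sharing excluding the trait
itself; traits with no calls print dashes. The relationship between
genetic correlation and sharing is summarized by a Spearman rank
correlation over cross-group trait pairs; the pairing denominator (which
trait's causal-set size scales the percentage) is ambiguous in the
source and defaults to the second group's trait, switchable.

Network-level sharing is tested with a constrained bootstrap: count the
physical PPIs (evidence types physical association, association,
colocalization, direct interaction) with one endpoint in each causal
set; then repeatedly draw node sets of the same sizes *and the same
overlap* uniformly from the network's node universe and recount. The
empirical p is exactly `(1 + sum I(s_i >= s0)) / (N + 1)` with ties in
the tail, so the smallest attainable p is `1/(N+1)`; the fold is s0
over the null mean. Set members absent from the network are dropped
before sizing (with counts logged), matching how the published
404-of-407 / 43-of-44 adjustment works. Edges between two shared
members count once by default (switchable) — the source is silent on
this corner. Annotation enrichment is the fold `(k/n)/(K/N_bg)` with
one-sided hypergeometric and Fisher p; the background size is a
required argument because different backgrounds are appropriate in
different contexts (e.g. an 18,215-protein ontology background vs a
20,338-sequence proteome), and no single background reproduces every
printed fold at once.

## The synthetic-data generator

The generator defines the study conditions; all tests and the
acceptance script run against it.

* **Genome**: 200 independent LD blocks of 100 SNPs (2 kb spacing,
  blocks 2 Mb apart so no cis or LD-score window spans blocks) over 10
  chromosomes; MAF uniform on [0.05, 0.5]; one gene per block centred
  on the block's middle SNP. Genotypes are 0/1/2 by Gaussian-copula
  thresholding of two latent AR(1) haplotypes with rho = 0.8, so LD
  targets are latent-scale; the population dosage-scale LD that the
  genotypes (and hence LD scores, pQTL scans and HEIDI) realize is
  computed analytically via Mehler's tetrachoric expansion and is the
  scale on which GWAS z-scores are simulated, keeping the two arms of
  the simulation mutually consistent.
* **GWAS**: summary-level per block, `z ~ MVN(sqrt(N) R a, R)` with
  N = 50,000 — orders of magnitude faster than individual-level
  simulation and exactly what the pipeline consumes. Polygenic effects
  (h2 = 0.4 over all 20k SNPs) are drawn once for all five traits
  jointly with cross-trait correlation equal to the target rg matrix
  (0.5 within groups, 0.2 psychiatric-neurodegenerative, 0.1
  elsewhere). All traits are continuous-Z; case/control liability is
  out of scope since every downstream statistic consumes z-scores only.
* **Molecular cohort**: 500 individuals at individual level (pQTL
  regression needs genotypes); abundance = cis genetic value (target
  cis h2 0.3 through the block-centre causal SNP) + trans genetic value
  + covariate effects (5% of variance) + Gaussian noise; columns
  z-scaled.
* **Planted signals**: 20 pleiotropic gene-trait links at
  |b_xy| = 0.06 (mediated GWAS z around 7), four of them hitting one
  psychiatric and one neurodegenerative trait to plant cross-group
  sharing; 10 linkage decoys — a trait-causal SNP placed so its latent
  r2 with the gene's abundance-causal SNP is 0.7, with direct GWAS z
  around 12 and no mediation; 6 trans links of 0.8 SD from
  quarter-block SNPs on a different chromosome (strong hotspot-like
  trans pQTLs; the quarter position gives the trans SNP a two-sided LD
  neighbourhood for HEIDI instruments, distinct from the resident
  gene's block-centre cis SNP), with the trans-regulated genes also
  mediating a trait at b_xy = 0.1 so criteria i–iii have true
  positives.
* **PPI network**: background edge probability 0.005 over a
  3,000-symbol universe; pairs between the two designated sets appear
  at 2.5x the background rate; evidence labels drawn 80% physical. The
  two sets carry the planted psychiatric- and neurodegenerative-trait
  causal genes respectively, padded with filler symbols to sizes 400
  and 40 with 13 shared members, so the network excess sits between the
  gene sets the calling stage actually recovers.
* **Annotations**: GMT sets whose overlap with a target list is planted
  in expectation.
* **Determinism**: one global seed; each stage hashes its name into a
  sub-seed, so stages rerun independently and bytes are identical under
  the same seed.

What the generator does **not** emulate: realistic MAF spectra and
imputation quality, population structure, X chromosome and indels,
case/control ascertainment, cross-block LD, batch structure in the
abundance matrix beyond simple covariates. Passing the recovery tests
therefore shows that the estimators are implemented correctly and
calibrated under the stated model, not that they are robust to every
artefact of real data.

A note on polygenic confounding: because the polygenic background gives
*every* SNP a small true effect, genes with no planted mediation still
accumulate LD-borne association signal, and some are called causal.
This mirrors the well-known behaviour of TWAS-style tests under
polygenicity and is why sensitivity is scored against planted links
while specificity is scored against the linkage decoys (whose exclusion
HEIDI handles) rather than against "all unplanted genes".

## Problem sizes used by the tests and acceptance script

The standard study is 20,000 SNPs, 5 traits, 200 genes, panel n = 2,000,
cohort n = 500. The LDSC recovery check averages 10 replicate GWAS
pairs on one genome; HEIDI calibration uses 500 pleiotropy-null regions
of 30 SNPs; the bootstrap calibration uses 50 null networks at 500
iterations each, and the full-scale bootstrap 10,000 iterations. These
sizes were chosen so the whole chain reruns comfortably on a laptop
core while leaving every estimate's Monte Carlo error well inside the
asserted tolerances.

## Known limitations

* The HEIDI covariance is first-order delta-method; with weak top
  instruments the test runs slightly hot (see calibration above).
* LD score regression at 20k SNPs has non-trivial sampling noise; the
  rg recovery criterion is therefore stated for the mean over replicate
  GWAS draws, not a single pair.
* The Haseman–Elston heritability p is one-sided normal from a sample
  jackknife; for very small cohorts (< 100) its calibration degrades.
* COLOC's single-causal-variant assumption is inherited; regions with
  two causal variants for the same trait push mass to PP3/PP4
  unpredictably, which is one reason the decision rules accept either
  the SMR/HEIDI or the COLOC route.
* The bootstrap null preserves set sizes and overlap but not degree
  structure; hub-heavy real networks may need a degree-matched null,
  which is out of scope here.
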