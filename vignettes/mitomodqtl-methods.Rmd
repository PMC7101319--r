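---
title: "Quantifying mitochondrial m1A/m1G modification from RNA-seq mismatches and mapping its nuclear genetic drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitomodqtl methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomodqtl)
```

## The measurement model

N1-methyladenosine (m1A) and N1-methylguanosine (m1G) disrupt Watson–Crick
pairing, so when a modified mitochondrial transcript is reverse-transcribed
during RNA-seq library preparation the enzyme misincorporates a random base
at the modified position. The fraction of quality-passing non-reference
base calls in a pileup at such a position is therefore a semi-quantitative
proxy for the modification level of the transcript pool. `mitomodqtl`
quantifies this proxy at 15 functionally important positions of the human
mitochondrial genome (rCRS coordinates): 13 mt-tRNA position-9 ("P9")
sites, position 2617 in *MT-RNR2* and position 13710 in *MT-ND5*, plus an
averaged phenotype over the 11 P9 sites that vary consistently in whole
blood — 16 phenotypes in all (`mod_sites()`, `phenotype_names()`).

The quantification rules, in order:

* base calls with Phred quality below 13 are discarded; deletions,
  reference skips and `N` calls enter neither numerator nor denominator;
* a sample–site cell needs filtered coverage of at least 20×, otherwise it
  is missing;
* a site is retained within a dataset–tissue only if the mean mismatch
  proportion across samples exceeds 1% — below that, modification is
  indistinguishable from sequencing error;
* values more than 3 standard deviations from the column mean are masked
  (single pass, with mean and SD computed from the pre-mask values; masked
  values are retained for audit). Masking after a single pass is
  deterministic and idempotent; we deliberately do not iterate.

Two open choices were resolved as follows: the 1% site rule is applied
*before* 3-SD masking (the site-evidence decision should not depend on
which extremes get masked), and the averaged-P9 phenotype requires only
one contributing site by default (`min_sites` is configurable for stricter
availability).

The pileup parser handles the full samtools text grammar (`^` + mapping
quality, `$`, `+n`/`-n` indel runs, strand-coded reference and mismatch
symbols) in compiled code, and the simulator records the exact
quality-passing counts of every draw so the parser can be checked for
byte-exact recovery — a property test, not a tolerance test.

## The association model

For each phenotype and dataset–tissue, the mQTL scan is ordinary least
squares of the methylation proportion on additive allele dosage plus
covariates: 5 genetic principal components (dosages standardised by
$\sqrt{2p(1-p)}$), and hidden expression factors computed as expression
PCs over genes expressed in all samples with mean TPM > 2 — 10 factors for
tissues with at least 100 samples, 5 otherwise. The Wald t-test on the
dosage coefficient gives a two-sided P on $n-p$ degrees of freedom.
Phenotypes are analysed on the raw proportion scale, so effect sizes are
per-allele changes in modification proportion (a `rint` flag offers a
rank-inverse-normal alternative). Genome-wide significance 5e-8 is
corrected by the 16 phenotypes and the 46 dataset–tissue analyses,
giving `significance_threshold()` = 6.79e-11.

Tissues measured in several datasets are pooled by inverse-variance
fixed-effects meta-analysis ($w_i = 1/SE_i^2$); the pooled SE
$(\sum w)^{-1/2}$ is strictly below every per-study SE. Peaks are selected
by greedy clumping: repeatedly take the smallest P below threshold and
remove everything within 500 kb on the same chromosome, ties broken by
position then id (the clumping rule is our own deterministic choice; only
the window scale is given by the analysis design). Replication in another
tissue requires P < 0.05 divided by the number of discovery pairs *and*
the same direction of effect. Where one phenotype has two independent
same-sign loci, the additive check compares carriers heterozygous at the
higher-MAF locus and reference-homozygous at the other against double
heterozygotes with a Welch t-test, Bonferroni-corrected over the pairs
tested.

## Mediation, consequences, LD and disease overlap

For each peak SNP, genes within 1 Mb whose rank-inverse-normal expression
associates with dosage (Bonferroni over the cis genes tested per SNP)
become mediator candidates. Mediation fits $M = aX$ and $Y = c'X + bM$
(same covariates as the scan) and reports ACME $= ab$, with uncertainty
from a nonparametric case-resampling bootstrap of both fits jointly: 1000
replicates, 95% percentile interval, and a two-sided bootstrap P equal to
twice the smaller tail fraction around zero, floored at $1/n_{boot}$. In
linear-Gaussian models the product-of-coefficients equals the
total-minus-direct decomposition exactly, which the tests assert to 1e-8.
We chose the case bootstrap (rather than a quasi-Bayesian posterior
simulation) because it matches a plain bootstrap description, and report
the proportion mediated only on point estimates — the ratio is unstable in
bootstrap tails.

Because P9 methylation stabilises the tRNA cloverleaf used for transcript
cleavage, the package also regresses the expression of the gene
immediately 5′ of each of nine P9-bearing tRNAs on the methylation level
(`adjacency_pairs()`), Bonferroni over the nine pairs; at least 30
complete cases are required per pair.

LD between two loci uses direct haplotype counting when phased haplotypes
are available and an EM over the double-heterozygote phase ambiguity
otherwise (convergence when the largest frequency change drops below
1e-8, at most 1000 iterations, three starting points with the best
log-likelihood kept; the log-likelihood is asserted non-decreasing each
iteration). D′ is reported as $|D|/D_{max}$. Catalogue overlap reports,
for each peak, genome-wide-significant (P < 5e-8) European-study entries
within 500 kb having at least 10,000 cases or a quantitative measure, and
D′ ≥ 0.9 with the peak; catalogue variants absent from the genotype panel
are kept with an explicit "LD not computable" flag rather than dropped.

## What the synthetic cohort emulates

The generator (`sim_config()`, `simulate_*`) produces every input with
known ground truth:

* **Modification levels.** Per individual $i$, site $s$, tissue $t$:
  $m_{ist} = \mathrm{clamp}_{[0,1]}(\mu_s + \lambda_s F_i + u_{is} +
  \sum\beta G_i + bE_i + \varepsilon_{ist})$. $F_i$ is a standard-normal
  factor shared across P9 sites and tissues; loadings and noise scale
  with the site mean (constant CV 0.15), with $\lambda_s = \sqrt{3}\,
  \sigma_s$ so the model-implied pairwise P9 correlation is exactly
  $\lambda^2/(\lambda^2+\sigma^2) = 0.75$, the centre of the observed
  distribution. The non-shared variance is split 60/40 between a
  tissue-shared individual component and tissue noise, giving positive
  cross-tissue correlations at the same site. Site means default to
  whole-blood-like values (P9 sites 2–12%, 2617 at 55%, 13710 at 10%).
* **Planted genetics.** Additive per-allele effects at the scale reported
  for whole-blood methylation QTLs (e.g. 0.0459 on the averaged P9
  measure, 0.0233 at 2617), one locus per LD block. Blocks come from a
  finite haplotype pool (24 haplotypes): individuals draw pool pairs with
  replacement, block mates copy the planted allele with a 5% flip, and a
  perfect proxy duplicates the planted column exactly (D′ = 1) for the
  catalogue-overlap machinery. No coalescent simulation is attempted —
  the pool construction is sufficient to exercise D′/EM and overlap
  logic, not to mimic human LD decay.
* **Pileups.** Depth is negative binomial (mean 500, size 0.91, putting
  5.0% of draws under the 20× filter); each read mismatches with
  probability $m\,e_{mod} + (1-m)\,e_{seq}$. The default
  misincorporation efficiency is $e_{mod}=1$, making the mismatch
  proportion an unbiased estimate of the level, so recovery tests are
  direct; lowering it simulates the proxy's semi-quantitative bias. The
  enzyme's true per-site efficiency is not publicly calibrated, so
  $e_{mod}$ stays a free parameter. Sequencing errors (default 0.002)
  draw 30% of their qualities below Phred 13 so the quality filter does
  real work. A single per-read Bernoulli is used; RT stops/truncations
  are not modelled because the proxy argument concerns mismatches only.
* **Expression, QC and catalogue.** Mediator genes follow
  $E = a\,G + \mathcal{N}(0, 0.5)$; upstream mitochondrial genes follow
  the configured adjacency slopes (defaults at the scale of the
  whole-blood estimates, e.g. 2.36 for 3238 → *MT-RNR2*); noise genes
  load on one latent batch factor that the hidden-factor step should
  absorb. QC metrics plant exact numbers of rule violations; the GWAS
  catalogue plants entries on the perfect-proxy columns plus three decoy
  rows per locus (outside the window, under-powered cohort,
  non-European) that the filters must reject.

What passing these tests does **not** show about real data: the generator
has unrelated individuals (no twin structure, hence no mixed models), no
NUMT contamination, no population stratification beyond what the PC tests
construct explicitly, no imputation uncertainty, and linear-Gaussian
effects throughout. Recovery under this model validates the estimators
and the plumbing, not the biological effect sizes.

## Numerical choices and problem sizes

The HWE test uses the exact conditional distribution computed by the
stable recurrence over heterozygote counts (no mid-P); tests compare it
exhaustively against a log-factorial enumeration oracle for all genotype
configurations with up to 50 individuals. OLS goes through QR; the test
suite cross-checks it against an explicit normal-equations oracle at
1e-8. Principal components use a deterministic sign convention (the
largest-magnitude loading is positive) so runs are reproducible.

Verification sizes were chosen to make Monte-Carlo bands decisive while
keeping the default test run quick: 200 samples at depth 500 for proxy
fidelity, 200 replicates of n = 2000 for QTL recovery with 1000 null SNPs
for type-I error, 300 replicates of n = 500 with 1000 bootstrap draws for
mediation CI coverage, and 1e5 fuzzed pileup lines (coverage mean 80) for
parser byte-exactness. Where a criterion checks a Monte-Carlo proportion
against a nominal rate (e.g. 2-SE recovery at 95%), the test's acceptance
region is the nominal rate minus three binomial standard deviations of
the estimate — set by sampling theory before running, not tuned.

The pipeline defaults (`run_config()`) simulate 2 datasets × 2 tissues ×
250 individuals (500 in total), run all eight stages, and write
plain-text TSVs with commented provenance headers plus a JSON manifest of
seeds, row counts and file hashes; reruns with the same seed are
byte-identical.

## Known limitations

Mismatch proportions remain a proxy: with $e_{mod} < 1$ the quantified
level underestimates the true level by a factor the package can simulate
but not correct. The expression-PC stand-in for richer latent-factor
models recovers planted batch structure but is not equivalent to them on
real data. Mediation assumes sequential ignorability and a single
mediator; no sensitivity analysis is provided. The EM for LD operates on
two loci at a time and does not phase longer haplotypes.
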