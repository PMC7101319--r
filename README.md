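# mitomodqtl

Quantify m1A/m1G RNA modification levels on the human mitochondrial
transcriptome from RNA-seq pileup mismatch proportions, and map them to
nuclear genetic variants.

## The problem

N1-methyladenosine and N1-methylguanosine at a handful of functionally
important mitochondrial positions — position 9 of 13 mt-tRNAs ("P9"
sites), position 2617 in *MT-RNR2* and position 13710 in *MT-ND5* —
disrupt Watson–Crick pairing and make the reverse transcriptase
misincorporate random bases during library preparation. The proportion of
quality-passing non-reference base calls at such a position,

    m̂ = (non-reference calls with Phred ≥ 13) / (filtered depth ≥ 20×),

is therefore a semi-quantitative proxy for the modification level of the
transcript pool. `mitomodqtl` implements the full population-scale
analysis around this proxy for statistical geneticists and mitochondrial
RNA biologists:

* **Quantification** — a compiled samtools-pileup text parser (escape
  grammar, strand symbols, indel runs, base-quality filtering), per-site
  mismatch phenotypes with a 1% site-evidence rule and single-pass 3-SD
  outlier masking, the 11-site averaged P9 phenotype, and within- and
  cross-tissue correlation tables (91 P9 comparisons).
* **Genetics** — genotype QC (exact Hardy–Weinberg test, MAF 5%,
  missingness 5%), sample QC on RNA-seq metrics, genetic PCs and hidden
  expression factors; per-SNP OLS mQTL scans
  `y = β·dosage + covariates`, a multiple-testing threshold
  5×10⁻⁸ / (16 phenotypes × 46 analyses) = 6.79×10⁻¹¹, greedy 500 kb
  peak clumping, inverse-variance fixed-effects meta-analysis
  (β̂ = Σwβ/Σw, SE = (Σw)^(−1/2), w = 1/SE²), cross-tissue replication
  and additive two-locus t-tests.
* **Interpretation** — bootstrap causal mediation through cis-gene
  expression (ACME = a·b, 1000 case resamples, percentile CI),
  regressions of upstream mitochondrial gene expression on P9
  methylation, two-locus LD (D′, r²) by phased counting or EM, and
  GWAS-catalogue overlap through D′ ≥ 0.9 proxies within 500 kb.
* **Synthetic cohorts** — a first-class generator with known ground truth
  (shared latent factor giving ~0.75 cross-site correlation, planted
  effect sizes, mediation chains, haplotype-pool LD blocks, RT
  misincorporation + sequencing error in emitted pileup text) used for
  parameter-recovery testing throughout.

## Worked example

Simulate one whole-blood-like dataset of 500 individuals, quantify
methylation from the emitted pileups, and scan the averaged P9 phenotype:

```r
library(mitomodqtl)
cfg <- sim_config(n_individuals = 500, n_datasets = 2, n_tissues = 1, seed = 42)
g   <- simulate_genotypes(cfg, dataset = 1)
tr  <- simulate_methylation(g, cfg, dataset = 1)
tr  <- simulate_pileups(tr, cfg, dir = tempfile("pileups"), tissue = 1)

recs <- do.call(rbind, lapply(names(tr$pileup_files), function(s)
  parse_pileup_file(tr$pileup_files[[s]], sample = s, min_phred = 13)))
mm <- build_methylation_matrix(recs, min_cov = 20, site_mean_threshold = 0.01)
mm <- mask_outliers(average_p9(mm), k = 3)
print(mm)
#> methylation_matrix: 500 samples x 16 phenotypes ( dataset1 / tissue1 )
#>   values present: 7598 | low coverage: 366 | masked: 36 | excluded columns: 0

scan  <- qtl_scan(mm$values[g$samples, "P9_avg"], g, phenotype_name = "P9_avg")
peaks <- select_peaks(scan, threshold = significance_threshold())
print(peaks[, c("snp", "chr", "pos", "beta", "se", "p")], digits = 3)
#>         snp chr      pos  beta      se        p
#> 6 snp_MRPP3  14 35735967 0.047 0.00175 5.89e-99
```

The 366 low-coverage cells are the ~5% of sample–site draws that the
negative-binomial depth model places below the 20× filter; the 36 masked
cells are the 3-SD outliers. The scan recovers the planted per-allele
effect of 0.0459 on the averaged P9 proportion (β̂ = 0.047 ± 0.0018) far
below the 6.79×10⁻¹¹ threshold, and clumping collapses the surrounding LD
block onto the causal variant.

The whole chain — simulate → quantify → qc → qtl → meta → mediate →
consequences → overlap — runs as one call:

```r
run_pipeline(run_config(out_dir = "run1", seed = 1))
```

which writes commented TSVs per stage plus `manifest.json` (seed, row
counts, file MD5 hashes; reruns with the same seed are byte-identical).
A thin CLI wrapper lives at `inst/scripts/mitomodqtl.R`.

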