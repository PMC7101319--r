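test_that("simulated allele frequencies match the target MAF", {
  cfg <- no_effect_config(n_individuals = 10000, n_datasets = 1,
                          n_tissues = 1, n_null_snps = 1,
                          maf_range = c(0.3, 0.3), seed = 5)
  g <- simulate_genotypes(cfg)
  p_hat <- mean(g$dosage[, 1]) / 2
  tol <- 3 * sqrt(0.3 * 0.7 / (2 * 10000))
  expect_lt(abs(p_hat - 0.3), tol)
})

test_that("perfect-proxy columns are identical haplotypes with D' = 1", {
  cfg <- sim_config(n_individuals = 200, n_tissues = 1, n_null_snps = 0,
                    seed = 2)
  g <- simulate_genotypes(cfg)
  expect_identical(g$haplotypes[, "snp_MRPP3"],
                   g$haplotypes[, "snp_MRPP3_proxy"])
  ld <- ld_stats(g$haplotypes[, "snp_MRPP3"],
                 g$haplotypes[, "snp_MRPP3_proxy"], mode = "phased")
  expect_equal(ld$dprime, 1)
  expect_equal(ld$r2, 1)
})

test_that("a fixed seed reproduces the emitted VCF byte for byte", {
  cfg <- sim_config(n_individuals = 40, n_tissues = 1, n_null_snps = 10,
                    seed = 77)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genotypes_vcf(simulate_genotypes(cfg), f1)
  write_genotypes_vcf(simulate_genotypes(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("VCF writer and reader round-trip dosages and haplotypes", {
  cfg <- sim_config(n_individuals = 30, n_tissues = 1, n_null_snps = 8,
                    seed = 12)
  g <- simulate_genotypes(cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, f)
  g2 <- read_genotypes_vcf(f)
  ord <- match(g$snps$id, g2$snps$id)
  expect_identical(unname(g2$dosage[, ord]), unname(g$dosage))
  expect_identical(unname(g2$haplotypes[, ord]), unname(g$haplotypes))
})

test_that("shared latent factor induces the intended cross-site correlation", {
  cfg <- no_effect_config(n_individuals = 2000, n_datasets = 1,
                          n_tissues = 1, n_null_snps = 0, seed = 11)
  g <- simulate_genotypes(cfg)
  tr <- simulate_methylation(g, cfg)
  cm <- cor(tr$levels[, p9_columns(), 1])
  expect_gt(mean(cm[upper.tri(cm)]), 0.70)
  expect_lt(mean(cm[upper.tri(cm)]), 0.80)

  # zero loadings: independence, |r| below 3/sqrt(n)
  cfg0 <- no_effect_config(n_individuals = 2000, n_datasets = 1,
                           n_tissues = 1, n_null_snps = 0, seed = 13,
                           shared_factor_loadings = setNames(
                             rep(0, 15), paste0("p", mod_sites()$position)))
  tr0 <- simulate_methylation(simulate_genotypes(cfg0), cfg0)
  cm0 <- cor(tr0$levels[, p9_columns(), 1])
  expect_lt(max(abs(cm0[upper.tri(cm0)])), 3 / sqrt(2000))
})

test_that("planted additive effects are recovered by OLS within 2 SE", {
  cfg <- sim_config(n_individuals = 2000, n_datasets = 1, n_tissues = 1,
                    n_null_snps = 0, seed = 3)
  g <- simulate_genotypes(cfg)
  tr <- simulate_methylation(g, cfg)
  fit <- summary(lm(tr$levels[, "p5520", 1] ~ g$dosage[, "snp_MRPP3"]))
  expect_lt(abs(fit$coefficients[2, 1] - 0.0459), 2 * fit$coefficients[2, 2])
})

test_that("mis-scaled site means trigger the clamping warning", {
  means <- setNames(rep(0.005, 15), paste0("p", mod_sites()$position))
  cfg <- no_effect_config(n_individuals = 100, n_datasets = 1,
                          n_tissues = 1, n_null_snps = 0, seed = 4,
                          site_means = means, noise_cv = 3)
  expect_warning(simulate_methylation(simulate_genotypes(cfg), cfg),
                 "clamped")
})

test_that("pileup mismatch proportions follow m*e_mod + (1-m)*e_seq", {
  base_means <- setNames(rep(0.5, 15), paste0("p", mod_sites()$position))
  mk <- function(e_mod, e_seq, m, seed, depth = 10000) {
    cfg <- no_effect_config(n_individuals = 4, n_datasets = 1, n_tissues = 1,
                            n_null_snps = 0, seed = seed,
                            site_means = setNames(rep(m, 15), names(base_means)),
                            shared_factor_loadings = setNames(rep(0, 15), names(base_means)),
                            noise_cv = 0, e_mod = e_mod, e_seq = e_seq,
                            coverage_mean = depth, coverage_size = 1e6)
    tr <- simulate_methylation(simulate_genotypes(cfg), cfg)
    simulate_pileups(tr, cfg, dir = NULL, tissue = 1)
  }
  ref_count <- function(pt) mapply(function(r, a, c, g, t)
    switch(r, A = a, C = c, G = g, T = t), pt$ref, pt$A, pt$C, pt$G, pt$T)

  # no modification, no error: exactly zero mismatches
  tr <- mk(1, 0, 0, 21)
  pt <- tr$pileup_truth
  expect_true(all(pt$A + pt$C + pt$G + pt$T - ref_count(pt) == 0))

  # m = 0.5, e_mod = 1, e_seq = 0: binomial around 0.5 at depth 10,000
  tr <- mk(1, 0, 0.5, 22)
  pt <- tr$pileup_truth
  refn <- ref_count(pt)
  depth <- pt$A + pt$C + pt$G + pt$T
  rate <- (depth - refn) / depth
  # per-line draws stay within a generous binomial band, and the pooled
  # estimate within 3 SD of its own (much tighter) sampling error
  expect_true(all(abs(rate - 0.5) < 4.5 * sqrt(0.25 / depth)))
  expect_lt(abs(sum(depth * rate) / sum(depth) - 0.5),
            3 * sqrt(0.25 / sum(depth)))

  # m = 0.5, e_mod = 0.8, e_seq = 0.01: expectation 0.405 on raw calls
  tr <- mk(0.8, 0.01, 0.5, 23)
  pt <- tr$pileup_truth
  rec <- do.call(rbind, lapply(split(pt$line, pt$sample), function(ln) {
    tf <- tempfile(); writeLines(ln, tf); on.exit(unlink(tf))
    parse_pileup_file(tf, min_phred = 0)
  }))
  raw_rate <- with(rec, (filtered_depth - mapply(
    function(r, a, c, g, t) switch(r, A = a, C = c, G = g, T = t),
    ref, A, C, G, T)) / filtered_depth)
  expect_lt(abs(mean(raw_rate) - 0.405), 3 * sqrt(0.405 * 0.595 / sum(rec$filtered_depth)) + 0.002)
})

test_that("expression generator recovers eQTL slope and records mediation truth", {
  cfg <- sim_config(n_individuals = 2000, n_datasets = 1, n_tissues = 1,
                    n_null_snps = 0, seed = 6,
                    mediation_specs = data.frame(
                      snp = "snp_M", chr = "1", pos = 1000000L, maf = 0.3,
                      gene = "GENE_M", gene_pos = 1100000L,
                      phenotype = "p2617", a = 0.5, b = 0.5, direct = 0,
                      stringsAsFactors = FALSE))
  g <- simulate_genotypes(cfg)
  tr <- simulate_methylation(g, cfg)
  tr <- simulate_expression(tr, cfg, tissue = 1)
  e <- tr$expression[[1]]$tpm["GENE_M", ]
  fit <- summary(lm(e ~ g$dosage[, "snp_M"]))
  expect_lt(abs(fit$coefficients[2, 1] - 0.5), 2 * fit$coefficients[2, 2])
  # product of paths recorded in the truth
  expect_equal(tr$mediation_specs$a * tr$mediation_specs$b, 0.25)

  # a zero adjacency slope yields a null downstream link
  cfg0 <- sim_config(n_individuals = 1000, n_datasets = 1, n_tissues = 1,
                     n_null_snps = 0, seed = 7,
                     adjacency_gammas = c(p3238 = 0))
  tr0 <- simulate_methylation(simulate_genotypes(cfg0), cfg0)
  tr0 <- simulate_expression(tr0, cfg0, tissue = 1)
  fit0 <- summary(lm(tr0$expression[[1]]$tpm["MT-RNR2", ] ~
                       tr0$levels[, "p3238", 1]))
  expect_lt(abs(fit0$coefficients[2, 3]), 3)  # |t| small for a null link
})

test_that("QC metric generator plants the exact number of failures", {
  cfg <- sim_config(n_individuals = 100, n_tissues = 1, n_null_snps = 0,
                    seed = 8,
                    qc_fail_counts = c(low_reads = 5, low_mito = 2,
                                       high_rrna = 1, high_mismatch = 1,
                                       high_intergenic = 1))
  tr <- simulate_methylation(simulate_genotypes(cfg), cfg)
  tr <- simulate_qc_metrics(tr, cfg)
  expect_equal(sum(tr$qc_metrics$remaining_reads < 5e6), 5L)
  expect_equal(sum(tr$qc_metrics$mito_reads < 1e4), 2L)
  expect_equal(sum(tr$qc_metrics$planted_fail != ""), 10L)
})

test_that("GWAS catalogue entries sit on the planted haplotype columns", {
  cfg <- sim_config(n_individuals = 200, n_tissues = 1, n_null_snps = 0,
                    seed = 9)
  g <- simulate_genotypes(cfg)
  tr <- simulate_methylation(g, cfg)
  tr <- simulate_gwas_catalogue(tr, g, cfg)
  cat_tab <- tr$gwas_catalogue
  proxy <- cat_tab$rsid[grepl("_proxy$", cat_tab$rsid)][1]
  planted <- sub("_proxy$", "", proxy)
  ld <- ld_stats(g$haplotypes[, planted], g$haplotypes[, proxy],
                 mode = "phased")
  expect_equal(ld$dprime, 1)

  # empty trait list: header-only catalogue
  cfg0 <- sim_config(n_individuals = 50, n_tissues = 1, n_null_snps = 0,
                     seed = 9, catalogue_traits = character(0))
  tr0 <- simulate_methylation(simulate_genotypes(cfg0), cfg0)
  tr0 <- simulate_gwas_catalogue(tr0, simulate_genotypes(cfg0), cfg0)
  expect_equal(nrow(tr0$gwas_catalogue), 0L)
})

test_that("truth JSON serialisation round-trips losslessly", {
  cfg <- sim_config(n_individuals = 25, n_tissues = 2, n_null_snps = 0,
                    seed = 10)
  tr <- simulate_methylation(simulate_genotypes(cfg), cfg)
  tr <- simulate_qc_metrics(tr, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth_json(tr, f)
  tr2 <- read_truth_json(f)
  expect_equal(tr2$levels, tr$levels)
  expect_equal(tr2$factor, tr$factor)
  expect_equal(tr2$mediator_expr, tr$mediator_expr)
  expect_equal(tr2$causal_effects$beta, tr$causal_effects$beta)
  expect_equal(tr2$qc_metrics$remaining_reads, tr$qc_metrics$remaining_reads)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_individuals = 0), "configuration error")
  expect_error(sim_config(coverage_mean = -1), "configuration error")
  expect_error(sim_config(maf_range = c(0, 0.6)), "configuration error")
  cfg <- sim_config(n_individuals = 20, seed = 1)
  g <- simulate_genotypes(cfg)
  g$snps <- g$snps[g$snps$id != "snp_MRPP3", ]
  g$dosage <- g$dosage[, g$snps$id]
  expect_error(simulate_methylation(g, cfg), "absent from genotypes")
})
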