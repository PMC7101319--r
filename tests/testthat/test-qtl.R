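test_that("hidden-factor count follows the 100-sample rule and recovers structure", {
  set.seed(8)
  mk_tpm <- function(n, batch_effect = 2) {
    batch <- rnorm(n)
    tpm <- t(sapply(1:60, function(j) {
      base <- runif(1, 5, 50)
      pmax(0, base + batch_effect * runif(1, 0.5, 1) * batch +
             rnorm(n, 0, 1))
    }))
    rownames(tpm) <- sprintf("g%02d", 1:60)
    colnames(tpm) <- sprintf("s%03d", 1:n)
    list(tpm = tpm, batch = batch)
  }
  big <- mk_tpm(150)
  hf <- hidden_factors(big$tpm)
  expect_equal(ncol(hf), 10L)
  expect_gt(abs(cor(hf[, 1], big$batch)), 0.9)
  small <- mk_tpm(80)
  expect_equal(ncol(hidden_factors(small$tpm)), 5L)
  # factors are mutually orthogonal
  G <- crossprod(hf)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  # lowly expressed genes are excluded from the decomposition
  tpm_lo <- rbind(big$tpm, low = rep(1, 150))
  expect_silent(hidden_factors(tpm_lo))
  expect_error(hidden_factors(big$tpm, k = 150), "smaller than")
})

test_that("QTL scan equals the normal-equations oracle", {
  set.seed(9)
  n <- 30
  dosage <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
                   dimnames = list(sprintf("s%02d", 1:n), c("a", "b", "c")))
  covar <- matrix(rnorm(n * 2), n, 2,
                  dimnames = list(rownames(dosage), c("c1", "c2")))
  y <- 0.05 * dosage[, 1] + 0.3 * covar[, 1] + rnorm(n, 0, 0.1)
  names(y) <- rownames(dosage)
  scan <- qtl_scan(y, dosage, covariates = covar)
  for (j in 1:3) {
    o <- ols_oracle(y, cbind(dosage[, j], covar))
    expect_equal(scan$beta[j], o$beta, tolerance = 1e-8)
    expect_equal(scan$se[j], o$se, tolerance = 1e-8)
    expect_equal(scan$p[j], o$p, tolerance = 1e-8)
  }
  expect_equal(scan$t, scan$beta / scan$se)
  expect_true(all(scan$n == n))
})

test_that("an exact linear phenotype gives the exact slope", {
  n <- 50
  dosage <- matrix(rbinom(n, 2, 0.4), n, 1,
                   dimnames = list(sprintf("s%02d", 1:n), "snp"))
  y <- 0.02 * dosage[, 1]
  scan <- qtl_scan(y, dosage)
  expect_equal(scan$beta, 0.02, tolerance = 1e-12)
  expect_equal(scan$se, 0, tolerance = 1e-10)
})

test_that("rank-deficient designs are skipped and logged", {
  n <- 20
  dosage <- matrix(1L, n, 1, dimnames = list(sprintf("s%02d", 1:n), "mono"))
  scan <- qtl_scan(rnorm(n), dosage)
  expect_equal(nrow(scan), 0L)
  expect_equal(attr(scan, "skipped"), "mono")
})

test_that("multiple-testing threshold reproduces the corrected level", {
  expect_equal(signif(significance_threshold(16, 46), 3), 6.79e-11)
  expect_equal(significance_threshold(1, 1), 5e-8)
  expect_equal(significance_threshold(2, 2), 1.25e-8)
  expect_error(significance_threshold(0, 46), "positive")
})

test_that("greedy clumping merges within-window signals and keeps distant ones", {
  res <- data.frame(snp = c("a", "b", "c"), chr = c("1", "1", "2"),
                    pos = c(1e6, 1.1e6, 1e6), phenotype = "p",
                    beta = 0.05, se = 0.01, p = c(1e-20, 1e-15, 1e-12),
                    stringsAsFactors = FALSE)
  pk <- select_peaks(res, threshold = 1e-10)
  expect_setequal(pk$snp, c("a", "c"))         # b within 500 kb of a
  res$chr <- c("1", "2", "3")
  expect_equal(nrow(select_peaks(res, 1e-10)), 3L)
  # ties on P broken by position then id
  res2 <- data.frame(snp = c("z", "y"), chr = "1", pos = c(5e6, 2e6),
                     phenotype = "p", beta = 1, se = 1, p = c(1e-12, 1e-12))
  expect_equal(select_peaks(res2, 1e-10)$snp, c("y", "z"))
})

test_that("two planted loci 2 Mb apart emerge as two peaks", {
  cfg <- sim_config(
    n_individuals = 2000, n_datasets = 1, n_tissues = 1, n_null_snps = 50,
    seed = 17,
    causal_effects = data.frame(
      snp = c("snp_locus1", "snp_locus2"), chr = "14",
      pos = c(35000000L, 37000000L), maf = c(0.3, 0.3),
      phenotype = "p9999", beta = c(0.05, 0.05), stringsAsFactors = FALSE),
    mediation_specs = data.frame(snp = character(), chr = character(),
                                 pos = integer(), maf = numeric(),
                                 gene = character(), gene_pos = integer(),
                                 phenotype = character(), a = numeric(),
                                 b = numeric(), direct = numeric()))
  g <- simulate_genotypes(cfg)
  tr <- simulate_methylation(g, cfg)
  scan <- qtl_scan(tr$levels[, "p9999", 1], g)
  pk <- select_peaks(scan, threshold = significance_threshold())
  expect_true(all(c("snp_locus1", "snp_locus2") %in% pk$snp))
})

test_that("fixed-effects meta-analysis matches the closed form", {
  s <- function(beta, se, snp = "s", ph = "p")
    data.frame(snp = snp, chr = "1", pos = 1L, phenotype = ph, beta = beta,
               se = se, t = beta / se, p = 0.5, n = 100L, n_covar = 0L,
               stringsAsFactors = FALSE)
  # single study: identity with P recomputed from z
  m1 <- fixed_effects_meta(list(s(0.04, 0.01)))
  expect_equal(m1$beta, 0.04)
  expect_equal(m1$se, 0.01)
  expect_equal(m1$p, 2 * pnorm(-4))
  # two equal studies: same beta, SE / sqrt(2)
  m2 <- fixed_effects_meta(list(s(0.05, 0.01), s(0.05, 0.01)))
  expect_equal(m2$beta, 0.05)
  expect_equal(m2$se, 0.01 / sqrt(2))
  # three studies with distinct SEs: inverse-variance oracle to 1e-12
  betas <- c(0.02, 0.05, 0.03); ses <- c(0.01, 0.02, 0.005)
  m3 <- fixed_effects_meta(list(s(betas[1], ses[1]), s(betas[2], ses[2]),
                                s(betas[3], ses[3])))
  w <- 1 / ses^2
  expect_equal(m3$beta, sum(w * betas) / sum(w), tolerance = 1e-12)
  expect_equal(m3$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_true(m3$se < min(ses))
  expect_equal(m3$n_studies, 3L)
  # non-positive SE studies are excluded and logged
  m4 <- fixed_effects_meta(list(s(0.05, 0.01), s(0.9, 0)))
  expect_equal(m4$n_studies, 1L)
  expect_equal(nrow(attr(m4, "excluded")), 1L)
})

test_that("replication requires the corrected P and matching sign", {
  peaks <- data.frame(snp = "s1", phenotype = "p585", beta = 0.05,
                      stringsAsFactors = FALSE)
  scan_same <- data.frame(snp = "s1", phenotype = "p585", beta = 0.04,
                          p = 1e-5, stringsAsFactors = FALSE)
  scan_opp <- data.frame(snp = "s1", phenotype = "p585", beta = -0.04,
                         p = 1e-8, stringsAsFactors = FALSE)
  scan_absent <- data.frame(snp = "s9", phenotype = "p585", beta = 0.04,
                            p = 1e-8, stringsAsFactors = FALSE)
  out <- replication_test(peaks, list(t2 = scan_same, t3 = scan_opp,
                                      t4 = scan_absent), n_pairs = 25)
  expect_equal(out$alpha, rep(0.05 / 25, 3))   # 25 pairs -> 0.002 each
  expect_equal(out$status[out$tissue == "t2"], "replicated")
  expect_equal(out$status[out$tissue == "t3"], "not_replicated")
  expect_equal(out$status[out$tissue == "t4"], "untestable")
})

test_that("additive two-locus test detects the sum of planted effects", {
  set.seed(30)
  n <- 5000
  dA <- rbinom(n, 2, 0.4); dB <- rbinom(n, 2, 0.3)
  y <- 0.05 * dA + 0.05 * dB + rnorm(n, 0, 0.05)
  out <- additive_two_locus_test(y, dA, dB, n_tests = 5)
  expect_equal(out$status, "tested")
  expect_lt(abs(out$diff - 0.05), 0.01)
  expect_lt(out$p_bonferroni, 0.05)
  expect_equal(out$p_bonferroni, min(1, out$p * 5))
  # null second locus: no detectable difference at matched n
  y0 <- 0.05 * dA + rnorm(n, 0, 0.05)
  out0 <- additive_two_locus_test(y0, dA, dB, n_tests = 5)
  expect_gt(out0$p, 0.01)
  # too-small groups are untestable
  out_small <- additive_two_locus_test(y[1:4], c(1, 1, 0, 2), c(0, 1, 1, 2))
  expect_equal(out_small$status, "untestable")
})

test_that("null scans keep nominal type-I error", {
  set.seed(31)
  n <- 500
  dosage <- matrix(rbinom(n * 400, 2, 0.3), n, 400,
                   dimnames = list(sprintf("s%03d", 1:n),
                                   sprintf("snp%03d", 1:400)))
  y <- rnorm(n); names(y) <- rownames(dosage)
  scan <- qtl_scan(y, dosage)
  frac <- mean(scan$p < 0.05)
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})
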