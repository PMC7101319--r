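mk_record <- function(position = 2617, ref = "A", A = 0, C = 0, G = 0, T = 0,
                      sample = "s1") {
  depth <- A + C + G + T
  data.frame(sample = sample, chrom = "MT", position = position, ref = ref,
             A = A, C = C, G = G, T = T, filtered_depth = depth,
             raw_depth = depth, stringsAsFactors = FALSE)
}

test_that("mismatch rate honours the 20x coverage boundary", {
  expect_equal(site_mismatch_rate(mk_record(A = 20)), 0)
  expect_true(is.na(site_mismatch_rate(mk_record(A = 19))))
  expect_equal(site_mismatch_rate(mk_record(A = 15, G = 5)), 0.25)
  expect_error(site_mismatch_rate(mk_record(ref = "X", A = 20)),
               "unknown reference base")
})

test_that("quantified rates track true levels at high depth", {
  # depth 1000, true level 0.5, perfect misincorporation, no error
  means <- setNames(rep(0.5, 15), paste0("p", mod_sites()$position))
  cfg <- no_effect_config(n_individuals = 10, n_datasets = 1, n_tissues = 1,
                          n_null_snps = 0, seed = 41, site_means = means,
                          shared_factor_loadings = setNames(rep(0, 15), names(means)),
                          noise_cv = 0, e_mod = 1, e_seq = 0,
                          coverage_mean = 1000, coverage_size = 1e6)
  tr <- simulate_methylation(simulate_genotypes(cfg), cfg)
  dir <- withr::local_tempdir()
  tr <- simulate_pileups(tr, cfg, dir = dir, tissue = 1)
  recs <- do.call(rbind, lapply(names(tr$pileup_files), function(s)
    parse_pileup_file(tr$pileup_files[[s]], sample = s)))
  rate <- site_mismatch_rate(recs)
  expect_true(all(abs(rate - 0.5) < 4.5 * sqrt(0.25 / recs$filtered_depth)))
  expect_lt(abs(mean(rate) - 0.5), 3 * sqrt(0.25 / sum(recs$filtered_depth)))
})

test_that("sites are excluded by the 1% dataset-mean evidence rule", {
  recs <- rbind(
    mk_record(position = 2617, A = 991, G = 9,  sample = "s1"),
    mk_record(position = 2617, A = 991, G = 9,  sample = "s2"),
    mk_record(position = 13710, A = 989, G = 11, sample = "s1"),
    mk_record(position = 13710, A = 989, G = 11, sample = "s2"),
    mk_record(position = 585, A = 900, G = 100, sample = "s1"),
    mk_record(position = 585, A = 900, G = 100, sample = "s2"))
  mm <- build_methylation_matrix(recs)
  expect_true("p2617" %in% names(mm$excluded_sites))    # mean 0.009
  expect_false("p13710" %in% names(mm$excluded_sites))  # mean 0.011
  expect_true(all(is.na(mm$values[, "p2617"])))
  expect_true(all(mm$state[, "p2617"] == "site_excluded"))
  # a site with no data at all is excluded with a recorded reason
  expect_match(unname(mm$excluded_sites["p1610"]), "no samples")
  expect_equal(mm$values["s1", "p585"], 0.1)
})

test_that("averaged P9 phenotype is the mean of available sites", {
  sites <- mod_sites()
  avg_cols <- paste0("p", sites$position[sites$in_p9_average])
  vals <- matrix(NA_real_, 3, 15,
                 dimnames = list(c("s1", "s2", "s3"),
                                 paste0("p", sites$position)))
  vals["s1", avg_cols] <- 0.10
  vals["s2", avg_cols[1:6]] <- c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3)
  mm <- structure(list(values = vals, premask = vals,
                       state = ifelse(is.na(vals), "missing_low_coverage", "value"),
                       excluded_sites = character(0), sites = sites,
                       dataset = "d", tissue = "t"),
                  class = "methylation_matrix")
  mm <- average_p9(mm)
  expect_equal(unname(mm$values["s1", "P9_avg"]), 0.10)
  expect_equal(unname(mm$values["s2", "P9_avg"]), 0.2)
  expect_true(is.na(mm$values["s3", "P9_avg"]))
  # a stricter availability rule turns the partial average off
  mm2 <- structure(list(values = vals, premask = vals,
                        state = ifelse(is.na(vals), "missing_low_coverage", "value"),
                        excluded_sites = character(0), sites = sites,
                        dataset = "d", tissue = "t"),
                   class = "methylation_matrix")
  mm2 <- average_p9(mm2, min_sites = 11)
  expect_true(is.na(mm2$values["s2", "P9_avg"]))
})

test_that("3-SD masking is single-pass, audited and idempotent", {
  set.seed(7)
  vals <- matrix(rnorm(100, 0.1, 0.01), 100, 1,
                 dimnames = list(sprintf("s%03d", 1:100), "p585"))
  vals[100, 1] <- 0.9
  mu <- mean(vals); sdv <- sd(vals)
  stopifnot(abs(0.9 - mu) > 3 * sdv,
            all(abs(vals[1:99, 1] - mu) <= 3 * sdv))
  mm <- structure(list(values = vals, premask = vals,
                       state = matrix("value", 100, 1,
                                      dimnames = dimnames(vals)),
                       excluded_sites = character(0), sites = mod_sites(),
                       dataset = "d", tissue = "t"),
                  class = "methylation_matrix")
  out <- mask_outliers(mm, k = 3)
  expect_equal(sum(out$state == "masked_outlier"), 1L)
  expect_true(is.na(out$values[100, 1]))
  expect_equal(out$premask[100, 1], 0.9)   # pre-mask value kept for audit
  out2 <- mask_outliers(out, k = 3)        # idempotent: stats from premask
  expect_identical(out2$values, out$values)
  expect_identical(out2$state, out$state)

  # constant column: SD 0, nothing masked
  cvals <- matrix(0.2, 10, 1, dimnames = list(sprintf("s%d", 1:10), "p585"))
  cm <- structure(list(values = cvals, premask = cvals,
                       state = matrix("value", 10, 1, dimnames = dimnames(cvals)),
                       excluded_sites = character(0), sites = mod_sites(),
                       dataset = "d", tissue = "t"),
                  class = "methylation_matrix")
  expect_identical(mask_outliers(cm, 3)$values, cvals)
})

test_that("within-individual correlation table has the 91 P9 comparisons", {
  cfg <- no_effect_config(n_individuals = 2000, n_datasets = 1,
                          n_tissues = 1, n_null_snps = 0, seed = 11)
  tr <- simulate_methylation(simulate_genotypes(cfg), cfg)
  vals <- cbind(tr$levels[, , 1],
                P9_avg = rowMeans(tr$levels[, p9_columns()[-c(3, 13)], 1]))
  mm <- structure(list(values = vals, premask = vals,
                       state = matrix("value", nrow(vals), ncol(vals),
                                      dimnames = dimnames(vals)),
                       excluded_sites = character(0), sites = mod_sites(),
                       dataset = "d", tissue = "t"),
                  class = "methylation_matrix")
  tab <- pairwise_site_correlations(mm)
  expect_equal(nrow(tab), 91L)
  expect_equal(nrow(tab), choose(14, 2))
  expect_true(mean(tab$r[grepl("^p", tab$site_a) & grepl("^p", tab$site_b)],
                   na.rm = TRUE) > 0.5)
  # duplicated columns correlate exactly at r = 1
  vals2 <- vals; vals2[, "P9_avg"] <- vals2[, "p585"]
  mm$values <- vals2
  tab2 <- pairwise_site_correlations(mm)
  expect_equal(tab2$r[tab2$site_a == "p585" & tab2$site_b == "P9_avg"], 1)
  # too few complete pairs: skipped with a reason
  vals3 <- vals; vals3[3:2000, "p585"] <- NA
  mm$values <- vals3
  tab3 <- pairwise_site_correlations(mm)
  expect_match(tab3$note[tab3$site_a == "p585"][1], "skipped")
})

test_that("cross-tissue correlations respect the mean and pairing rules", {
  cfg <- no_effect_config(n_individuals = 300, n_datasets = 1,
                          n_tissues = 2, n_null_snps = 0, seed = 15)
  tr <- simulate_methylation(simulate_genotypes(cfg), cfg)
  as_mm <- function(t) {
    vals <- tr$levels[, , t]
    structure(list(values = vals, premask = vals,
                   state = matrix("value", nrow(vals), ncol(vals),
                                  dimnames = dimnames(vals)),
                   excluded_sites = character(0), sites = mod_sites(),
                   dataset = "d", tissue = paste0("t", t)),
              class = "methylation_matrix")
  }
  tab <- cross_tissue_correlations(list(t1 = as_mm(1), t2 = as_mm(2)))
  expect_true(nrow(tab) > 0)
  # tissue replicates share the individual component: positive correlation
  expect_true(all(tab$r > 0))
  # sites below the per-tissue mean rule are not compared
  tab_hi <- cross_tissue_correlations(list(t1 = as_mm(1), t2 = as_mm(2)),
                                      min_mean = 0.05)
  expect_false("p3238" %in% tab_hi$phenotype)   # mean 0.02 < 0.05
  # and the shared-sample requirement can rule out every comparison
  tab100 <- cross_tissue_correlations(list(t1 = as_mm(1), t2 = as_mm(2)),
                                      min_pairs = 400)
  expect_equal(nrow(tab100), 0L)
})
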