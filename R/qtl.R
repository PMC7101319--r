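#' Hidden expression factors (expression PCs)
#'
#' Latent covariates absorbing hidden structure in RNA-seq expression,
#' computed as the top principal components of log-transformed,
#' gene-standardised expression over genes expressed in all samples with
#' mean TPM above 2. The number of factors follows the sample-size rule
#' used throughout the analysis: 10 for tissues with at least 100
#' samples, 5 otherwise (overridable via \code{k}).
#'
#' @param tpm Genes x samples TPM matrix.
#' @param k Number of factors; default by the n >= 100 rule.
#' @param min_mean_tpm Gene inclusion threshold (default 2).
#' @return Samples x k matrix (columns \code{HF1..k}).
#' @export
hidden_factors <- function(tpm, k = NULL, min_mean_tpm = 2) {
  n <- ncol(tpm)
  if (is.null(k)) k <- if (n >= 100L) 10L else 5L
  if (k >= n) stop("k (", k, ") must be smaller than the number of samples (", n, ")")
  keep <- apply(tpm > 0, 1L, all) & rowMeans(tpm) > min_mean_tpm
  X <- log2(tpm[keep, , drop = FALSE] + 1)
  X <- X[apply(X, 1L, stats::sd) > 0, , drop = FALSE]
  Z <- t(scale(t(X)))                       # standardise genes
  sv <- svd(t(Z), nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(colnames(tpm), paste0("HF", seq_len(k)))
  scores
}

#' Linear methylation-QTL scan
#'
#' Per-SNP ordinary least squares of a methylation phenotype on additive
#' allele dosage plus covariates (genetic PCs, hidden expression factors,
#' sex/batch where supplied), with a Wald t-test on the dosage
#' coefficient and two-sided P from the t distribution on n - p degrees
#' of freedom. Samples with missing phenotype, dosage or covariates are
#' dropped per test; rank-deficient designs are skipped and logged.
#'
#' @param phenotype Named numeric vector (samples), values in \[0,1\] or
#'   rank-inverse-normal transformed when \code{rint = TRUE}.
#' @param genotypes A \code{genotype_set}, or a samples x SNPs dosage
#'   matrix.
#' @param covariates Optional samples x q matrix (aligned rownames).
#' @param phenotype_name Label carried into the result.
#' @param rint Apply a rank-based inverse-normal transform to the
#'   phenotype first (default FALSE: raw proportion scale).
#' @return Data.frame with one row per tested SNP: \code{snp}, \code{chr},
#'   \code{pos}, \code{phenotype}, \code{beta}, \code{se}, \code{t},
#'   \code{p}, \code{n}, \code{n_covar}; skipped SNPs appear in attribute
#'   \code{skipped}.
#' @export
qtl_scan <- function(phenotype, genotypes, covariates = NULL,
                     phenotype_name = "phenotype", rint = FALSE) {
  if (inherits(genotypes, "genotype_set")) {
    dosage <- genotypes$dosage
    snps <- genotypes$snps
  } else {
    dosage <- as.matrix(genotypes)
    snps <- data.frame(id = colnames(dosage), chr = NA_character_,
                       pos = NA_integer_, stringsAsFactors = FALSE)
  }
  samples <- rownames(dosage)
  if (!is.null(names(phenotype))) phenotype <- phenotype[samples]
  if (rint) phenotype <- rank_inverse_normal(phenotype)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates))) covariates <- covariates[samples, , drop = FALSE]
  }
  res <- vector("list", ncol(dosage))
  skipped <- character(0)
  for (j in seq_len(ncol(dosage))) {
    fit <- ols_term(phenotype, dosage[, j], covariates)
    if (is.null(fit)) { skipped <- c(skipped, snps$id[j]); next }
    res[[j]] <- data.frame(snp = snps$id[j], chr = snps$chr[j],
                           pos = snps$pos[j], phenotype = phenotype_name,
                           beta = fit$beta, se = fit$se, t = fit$t,
                           p = fit$p, n = fit$n, n_covar = fit$n_covar,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(snp = character(), chr = character(), pos = integer(),
                      phenotype = character(), beta = numeric(), se = numeric(),
                      t = numeric(), p = numeric(), n = integer(),
                      n_covar = integer(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Multiple-testing threshold for the QTL scans
#'
#' Genome-wide significance divided by the number of methylation
#' phenotypes examined and the number of dataset-tissue analyses: with
#' the defaults (16 phenotypes, 46 analyses) the threshold is
#' 6.79e-11 to three significant figures.
#'
#' @param n_phenotypes Number of methylation phenotypes (default 16: 13
#'   P9 sites, the averaged P9 measure, 2617 and 13710).
#' @param n_analyses Number of dataset-tissue analyses (default 46).
#' @param genomewide Genome-wide significance level (default 5e-8).
#' @return The corrected threshold.
#' @export
significance_threshold <- function(n_phenotypes = 16, n_analyses = 46,
                                   genomewide = 5e-8) {
  if (n_phenotypes <= 0 || n_analyses <= 0)
    stop("counts must be positive integers")
  genomewide / (n_phenotypes * n_analyses)
}

#' Greedy peak selection (distance clumping)
#'
#' Repeatedly takes the lowest-P SNP below the threshold and removes all
#' SNPs within \code{window_bp} on the same chromosome until none remain.
#' Ties on P are broken by position, then SNP id.
#'
#' @param results Association data.frame as from [qtl_scan()] or
#'   [fixed_effects_meta()] (needs \code{snp}, \code{chr}, \code{pos},
#'   \code{p}).
#' @param threshold Significance threshold.
#' @param window_bp Exclusion half-window in bp (default 500000).
#' @return The peak rows, ordered by P.
#' @export
select_peaks <- function(results, threshold, window_bp = 500000) {
  sig <- results[!is.na(results$p) & results$p < threshold, , drop = FALSE]
  sig <- sig[order(sig$p, sig$pos, sig$snp), , drop = FALSE]
  peaks <- sig[0, , drop = FALSE]
  while (nrow(sig)) {
    top <- sig[1L, , drop = FALSE]
    peaks <- rbind(peaks, top)
    near <- sig$chr == top$chr & abs(sig$pos - top$pos) <= window_bp
    sig <- sig[!near, , drop = FALSE]
  }
  peaks
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-study effect estimates for each SNP-phenotype pair with
#' weights \eqn{w_i = 1/SE_i^2}: pooled beta \eqn{\sum w\beta / \sum w},
#' pooled SE \eqn{(\sum w)^{-1/2}}, z = beta/SE and a two-sided normal P.
#' Studies with non-positive SE are excluded and logged.
#'
#' @param studies List of association data.frames (as from [qtl_scan()]).
#' @return Data.frame \code{snp}, \code{phenotype}, \code{beta},
#'   \code{se}, \code{z}, \code{p}, \code{n_studies}, \code{n} (summed
#'   sample size); excluded study rows in attribute \code{excluded}.
#' @export
fixed_effects_meta <- function(studies) {
  all_rows <- do.call(rbind, lapply(seq_along(studies), function(i) {
    d <- studies[[i]]; d$study <- i; d
  }))
  bad <- is.na(all_rows$se) | all_rows$se <= 0
  excluded <- all_rows[bad, , drop = FALSE]
  all_rows <- all_rows[!bad, , drop = FALSE]
  key <- paste(all_rows$snp, all_rows$phenotype, sep = "\r")
  out <- lapply(split(all_rows, key), function(d) {
    w <- 1 / d$se^2
    beta <- sum(w * d$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    z <- beta / se
    data.frame(snp = d$snp[1L], chr = d$chr[1L], pos = d$pos[1L],
               phenotype = d$phenotype[1L], beta = beta, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), n_studies = nrow(d),
               n = sum(d$n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Cross-tissue replication of discovery peaks
#'
#' A discovery site-variant pair replicates in another tissue when the
#' same SNP-phenotype association reaches P below 0.05 divided by the
#' number of discovery pairs AND has the same direction of effect. Pairs
#' absent from a tissue's scan are untestable.
#'
#' @param peaks Discovery peak data.frame (\code{snp}, \code{phenotype},
#'   \code{beta}).
#' @param tissue_scans Named list of association data.frames, one per
#'   tissue.
#' @param n_pairs Number of discovery pairs corrected for (default
#'   \code{nrow(peaks)}).
#' @return Data.frame with one row per peak x tissue: \code{snp},
#'   \code{phenotype}, \code{tissue}, \code{beta_disc}, \code{beta_rep},
#'   \code{p_rep}, \code{alpha}, \code{status}
#'   (replicated/not_replicated/untestable).
#' @export
replication_test <- function(peaks, tissue_scans, n_pairs = nrow(peaks)) {
  alpha <- 0.05 / n_pairs
  rows <- list()
  for (tis in names(tissue_scans)) {
    scan <- tissue_scans[[tis]]
    for (i in seq_len(nrow(peaks))) {
      hit <- scan[scan$snp == peaks$snp[i] &
                    scan$phenotype == peaks$phenotype[i], , drop = FALSE]
      if (!nrow(hit)) {
        status <- "untestable"; b <- NA_real_; p <- NA_real_
      } else {
        b <- hit$beta[1L]; p <- hit$p[1L]
        status <- if (p < alpha && sign(b) == sign(peaks$beta[i]))
          "replicated" else "not_replicated"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        snp = peaks$snp[i], phenotype = peaks$phenotype[i], tissue = tis,
        beta_disc = peaks$beta[i], beta_rep = b, p_rep = p, alpha = alpha,
        status = status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Additive two-locus comparison
#'
#' For a methylation phenotype associated with two independent nuclear
#' loci with the same direction of effect: compares individuals
#' heterozygous at the higher-MAF locus and homozygous reference at the
#' other (group 1) against individuals heterozygous at both (group 2)
#' with a Welch two-sided t-test, Bonferroni-corrected over the number of
#' site-pairs tested.
#'
#' @param phenotype Numeric vector (samples).
#' @param dosage_a Dosage at the higher-MAF locus.
#' @param dosage_b Dosage at the second locus.
#' @param n_tests Number of site-pairs tested (default 1).
#' @return List with group sizes and means, \code{diff} (group2 -
#'   group1), \code{t}, \code{p}, \code{p_bonferroni}; or status
#'   "untestable" when either group has fewer than 2 samples.
#' @export
additive_two_locus_test <- function(phenotype, dosage_a, dosage_b,
                                    n_tests = 1) {
  g1 <- dosage_a == 1L & dosage_b == 0L & !is.na(phenotype)
  g2 <- dosage_a == 1L & dosage_b == 1L & !is.na(phenotype)
  g1[is.na(g1)] <- FALSE; g2[is.na(g2)] <- FALSE
  if (sum(g1) < 2L || sum(g2) < 2L) {
    return(list(status = "untestable", n1 = sum(g1), n2 = sum(g2)))
  }
  tt <- stats::t.test(phenotype[g2], phenotype[g1])
  list(status = "tested", n1 = sum(g1), n2 = sum(g2),
       mean1 = mean(phenotype[g1]), mean2 = mean(phenotype[g2]),
       diff = mean(phenotype[g2]) - mean(phenotype[g1]),
       t = unname(tt$statistic), p = tt$p.value,
       p_bonferroni = min(1, tt$p.value * n_tests))
}
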