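#' Regression of upstream-gene expression on P9 methylation
#'
#' For each tRNA P9 site with an mRNA/rRNA gene immediately 5' on the
#' polycistronic transcript (the nine [adjacency_pairs()]), regresses the
#' rank-inverse-normal transformed expression of the upstream gene on the
#' methylation level at the site, with the supplied covariates, and
#' Bonferroni-corrects over the pairs tested. Pairs with fewer than 30
#' complete cases are untestable.
#'
#' @param meth A \code{methylation_matrix} or samples x phenotypes
#'   numeric matrix.
#' @param tpm Genes x samples TPM matrix containing the upstream genes.
#' @param covariates Optional samples x q matrix (batch, genetic PCs,
#'   hidden factors).
#' @param pairs Adjacency table (default [adjacency_pairs()]).
#' @param min_n Minimum complete cases (default 30).
#' @return Data.frame \code{position}, \code{upstream_gene}, \code{beta},
#'   \code{se}, \code{p}, \code{p_bonferroni}, \code{n}, \code{status}.
#' @export
upstream_expression_regression <- function(meth, tpm, covariates = NULL,
                                           pairs = adjacency_pairs(),
                                           min_n = 30) {
  vals <- if (inherits(meth, "methylation_matrix")) meth$values else as.matrix(meth)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    col <- paste0("p", pairs$position[i])
    gene <- pairs$upstream_gene[i]
    if (!col %in% colnames(vals) || !gene %in% rownames(tpm)) {
      rows[[i]] <- data.frame(position = pairs$position[i],
                              upstream_gene = gene, beta = NA_real_,
                              se = NA_real_, p = NA_real_, n = 0L,
                              status = "untestable", stringsAsFactors = FALSE)
      next
    }
    samples <- intersect(rownames(vals), colnames(tpm))
    y <- rank_inverse_normal(as.numeric(tpm[gene, samples]))
    x <- vals[samples, col]
    cv <- if (is.null(covariates)) NULL else as.matrix(covariates)[samples, , drop = FALSE]
    ok <- sum(stats::complete.cases(cbind(y, x, cv)))
    if (ok < min_n) {
      rows[[i]] <- data.frame(position = pairs$position[i],
                              upstream_gene = gene, beta = NA_real_,
                              se = NA_real_, p = NA_real_, n = ok,
                              status = "untestable", stringsAsFactors = FALSE)
      next
    }
    fit <- ols_term(y, x, cv)
    rows[[i]] <- data.frame(position = pairs$position[i],
                            upstream_gene = gene, beta = fit$beta,
                            se = fit$se, p = fit$p, n = fit$n,
                            status = "tested", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n_tested <- sum(out$status == "tested")
  out$p_bonferroni <- pmin(1, out$p * max(n_tested, 1L))
  out
}

#' Pairwise linkage disequilibrium statistics
#'
#' Computes D, D' and r-squared between two biallelic loci. With phased
#' haplotypes the four haplotype frequencies are counted directly; with
#' unphased genotypes they are estimated by EM over the double-het phase
#' ambiguity (convergence when the largest frequency change falls below
#' \code{tol}, at most \code{max_iter} iterations, multiple starts with
#' the best log-likelihood retained). D' is reported as
#' \eqn{|D|/D_{max}} with the standard bound for the sign of D.
#'
#' @param a,b For \code{mode = "phased"}: 0/1 allele vectors over
#'   chromosome copies (aligned). For \code{mode = "genotype"}: 0/1/2
#'   dosage vectors over individuals.
#' @param mode \code{"phased"} or \code{"genotype"} (EM).
#' @param tol EM convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return An object of class \code{ld_stat}: list with \code{D},
#'   \code{dprime}, \code{r2}, \code{hap_freq} (pAB, pAb, paB, pab for
#'   alt/ref alleles), \code{freq_a}, \code{freq_b}, \code{mode},
#'   \code{defined}.
#' @export
ld_stats <- function(a, b, mode = c("phased", "genotype"), tol = 1e-8,
                     max_iter = 1000) {
  mode <- match.arg(mode)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  undef <- function(reason) structure(
    list(D = NA_real_, dprime = NA_real_, r2 = NA_real_,
         hap_freq = rep(NA_real_, 4L), freq_a = mean(a) / ifelse(mode == "phased", 1, 2),
         freq_b = mean(b) / ifelse(mode == "phased", 1, 2),
         mode = mode, defined = FALSE, reason = reason), class = "ld_stat")
  if (mode == "phased") {
    pA <- mean(a); pB <- mean(b)
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(undef("monomorphic"))
    h <- c(pAB = mean(a == 1 & b == 1), pAb = mean(a == 1 & b == 0),
           paB = mean(a == 0 & b == 1), pab = mean(a == 0 & b == 0))
  } else {
    stopifnot(all(a %in% 0:2), all(b %in% 0:2))
    pA <- mean(a) / 2; pB <- mean(b) / 2
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(undef("monomorphic"))
    h <- em_haplotype_freqs(a, b, tol = tol, max_iter = max_iter)
  }
  pA <- h[1L] + h[2L]; pB <- h[1L] + h[3L]
  D <- h[1L] - pA * pB
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (d_max == 0) NA_real_ else abs(D) / d_max
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(D = unname(D), dprime = unname(dprime), r2 = unname(r2),
                 hap_freq = h, freq_a = unname(pA), freq_b = unname(pB),
                 mode = mode, defined = TRUE, reason = NULL),
            class = "ld_stat")
}

#' @export
print.ld_stat <- function(x, ...) {
  if (!x$defined) {
    cat("ld_stat: undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("ld_stat (%s): D = %.4g, D' = %.4g, r2 = %.4g\n",
                x$mode, x$D, x$dprime, x$r2))
  }
  invisible(x)
}

# EM for two-locus haplotype frequencies from unphased genotypes.
# Multiple starting points; keeps the solution with the best
# log-likelihood; asserts the log-likelihood never decreases.
em_haplotype_freqs <- function(a, b, tol = 1e-8, max_iter = 1000) {
  n <- length(a)
  cnt <- table(factor(a, 0:2), factor(b, 0:2))
  pA <- mean(a) / 2; pB <- mean(b) / 2
  loglik <- function(h) {
    # cell probabilities from haplotype frequencies (h = pAB,pAb,paB,pab)
    pr <- matrix(0, 3L, 3L)
    pr[3, 3] <- h[1]^2;            pr[3, 2] <- 2 * h[1] * h[2]
    pr[3, 1] <- h[2]^2
    pr[2, 3] <- 2 * h[1] * h[3];   pr[2, 1] <- 2 * h[2] * h[4]
    pr[2, 2] <- 2 * h[1] * h[4] + 2 * h[2] * h[3]
    pr[1, 3] <- h[3]^2;            pr[1, 2] <- 2 * h[3] * h[4]
    pr[1, 1] <- h[4]^2
    sum(cnt * log(pmax(pr, 1e-300)))
  }
  run_em <- function(h) {
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      denom <- h[1] * h[4] + h[2] * h[3]
      phi <- if (denom > 0) h[1] * h[4] / denom else 0.5  # P(double het is AB/ab)
      ndh <- cnt[2, 2]
      eAB <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3] + phi * ndh
      eAb <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1] + (1 - phi) * ndh
      eaB <- 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2] + (1 - phi) * ndh
      eab <- 2 * cnt[1, 1] + cnt[2, 1] + cnt[1, 2] + phi * ndh
      h_new <- c(eAB, eAb, eaB, eab) / (2 * n)
      ll <- loglik(h_new)
      if (ll < ll_prev - 1e-9)
        stop("EM log-likelihood decreased: ", ll_prev, " -> ", ll)
      delta <- max(abs(h_new - h))
      h <- h_new; ll_prev <- ll
      if (delta < tol) break
    }
    list(h = h, ll = ll_prev)
  }
  starts <- list(
    c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB)),
    c(min(pA, pB), pA - min(pA, pB), pB - min(pA, pB),
      1 - pA - pB + min(pA, pB)) + 1e-6,
    c(max(0, pA + pB - 1), pA - max(0, pA + pB - 1),
      pB - max(0, pA + pB - 1), 1 - pA - pB + max(0, pA + pB - 1)) + 1e-6)
  fits <- lapply(starts, function(s) run_em(s / sum(s)))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1L), "ll"))]]
  h <- best$h / sum(best$h)
  names(h) <- c("pAB", "pAb", "paB", "pab")
  h
}

#' Overlap of peak SNPs with a GWAS catalogue through LD proxies
#'
#' For each peak SNP, reports catalogue variants within \code{window} bp
#' that reach genome-wide significance (\code{gw_p}), come from European
#' studies with at least \code{min_cases} cases or a quantitative
#' measure, and are in LD with the peak at D' of at least
#' \code{dprime_min}. Catalogue SNPs absent from the genotype panel are
#' retained with an "LD not computable" flag. LD uses phased haplotypes
#' when the panel carries them, EM otherwise; the mode is recorded.
#'
#' @param peaks Data.frame of peak SNPs (\code{snp}, \code{chr},
#'   \code{pos}).
#' @param catalogue Catalogue data.frame (\code{rsid}, \code{chr},
#'   \code{pos}, \code{trait}, \code{p}, \code{n_cases}, \code{ancestry},
#'   \code{quantitative}).
#' @param genotypes \code{genotype_set} used for LD.
#' @param dprime_min D' threshold (default 0.9).
#' @param window Interval half-width in bp (default 500000).
#' @param gw_p Genome-wide significance for catalogue SNPs (default
#'   5e-8).
#' @param min_cases Minimum case count for non-quantitative studies
#'   (default 10000).
#' @return Data.frame of reported overlaps with D', r2, MAF and an LD
#'   flag; a subset of the filtered catalogue rows.
#' @export
gwas_overlap <- function(peaks, catalogue, genotypes, dprime_min = 0.9,
                         window = 500000, gw_p = 5e-8, min_cases = 10000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    cand <- catalogue[catalogue$chr == pk$chr &
                        abs(catalogue$pos - pk$pos) <= window &
                        catalogue$p < gw_p &
                        catalogue$ancestry == "European" &
                        (catalogue$quantitative | catalogue$n_cases >= min_cases),
                      , drop = FALSE]
    if (!nrow(cand)) next
    for (k in seq_len(nrow(cand))) {
      row <- cand[k, ]
      j_pk <- match(pk$snp, genotypes$snps$id)
      j_ct <- match(row$rsid, genotypes$snps$id)
      if (is.na(j_ct) || is.na(j_pk)) {
        out[[length(out) + 1L]] <- data.frame(
          peak_snp = pk$snp, rsid = row$rsid, trait = row$trait,
          pos = row$pos, dprime = NA_real_, r2 = NA_real_,
          maf = NA_real_, ld_mode = NA_character_,
          flag = "LD not computable", stringsAsFactors = FALSE)
        next
      }
      if (!is.null(genotypes$haplotypes)) {
        ld <- ld_stats(genotypes$haplotypes[, j_pk],
                       genotypes$haplotypes[, j_ct], mode = "phased")
      } else {
        ld <- ld_stats(genotypes$dosage[, j_pk], genotypes$dosage[, j_ct],
                       mode = "genotype")
      }
      if (!ld$defined || is.na(ld$dprime) || ld$dprime < dprime_min) next
      maf <- min(ld$freq_b, 1 - ld$freq_b)
      out[[length(out) + 1L]] <- data.frame(
        peak_snp = pk$snp, rsid = row$rsid, trait = row$trait,
        pos = row$pos, dprime = ld$dprime, r2 = ld$r2, maf = maf,
        ld_mode = ld$mode, flag = "", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(peak_snp = character(), rsid = character(),
                      trait = character(), pos = integer(),
                      dprime = numeric(), r2 = numeric(), maf = numeric(),
                      ld_mode = character(), flag = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
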