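#' Cis-gene eQTL candidates for a peak SNP
#'
#' Tests every gene whose position lies within \code{window} of the peak
#' SNP for association between its quantile-normalised expression
#' (rank-based inverse normal per gene) and the SNP dosage, with the same
#' covariates as the QTL scan. Genes with P below 0.05 divided by the
#' number of cis genes tested for that SNP are retained as mediator
#' candidates.
#'
#' @param dosage Named numeric dosage vector (samples).
#' @param snp_chr,snp_pos Peak SNP location.
#' @param tpm Genes x samples TPM matrix.
#' @param gene_info Data.frame \code{gene}, \code{chr}, \code{pos}.
#' @param covariates Optional samples x q matrix.
#' @param window Cis window in bp (default 1e6).
#' @return Data.frame \code{gene}, \code{beta}, \code{se}, \code{p},
#'   \code{n_cis_tested}, \code{alpha}, \code{kept}; zero rows when no
#'   genes fall in the window.
#' @export
cis_gene_candidates <- function(dosage, snp_chr, snp_pos, tpm, gene_info,
                                covariates = NULL, window = 1e6) {
  cis <- gene_info[gene_info$chr == snp_chr &
                     abs(gene_info$pos - snp_pos) <= window, , drop = FALSE]
  cis <- cis[cis$gene %in% rownames(tpm), , drop = FALSE]
  if (!nrow(cis)) {
    return(data.frame(gene = character(), beta = numeric(), se = numeric(),
                      p = numeric(), n_cis_tested = integer(),
                      alpha = numeric(), kept = logical(),
                      stringsAsFactors = FALSE))
  }
  samples <- names(dosage)
  if (is.null(samples)) samples <- colnames(tpm)
  res <- lapply(cis$gene, function(gn) {
    y <- rank_inverse_normal(as.numeric(tpm[gn, samples]))
    fit <- ols_term(y, dosage, covariates)
    if (is.null(fit)) return(NULL)
    data.frame(gene = gn, beta = fit$beta, se = fit$se, p = fit$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  out$n_cis_tested <- nrow(cis)
  out$alpha <- 0.05 / nrow(cis)
  out$kept <- out$p < out$alpha
  out
}

#' Bootstrap average causal mediation effect (ACME)
#'
#' Linear-model mediation of a SNP's effect on methylation through a
#' mediator gene's expression: fits \eqn{M = a X + covariates} and
#' \eqn{Y = c' X + b M + covariates} on complete cases, reports
#' ACME = a*b, the average direct effect (ADE) c', the total effect from
#' \eqn{Y = c X + covariates}, and the proportion mediated
#' ACME/(ACME + ADE) on the point estimates. Uncertainty comes from a
#' nonparametric case-resampling bootstrap of both fits jointly: 95\%
#' percentile interval, and a two-sided bootstrap P equal to twice the
#' smaller tail fraction of the bootstrap ACME distribution around zero,
#' floored at 1/n_boot. Rank-deficient resamples are redrawn and counted.
#'
#' @param dosage SNP dosage vector (the exposure).
#' @param mediator Mediator gene expression vector.
#' @param outcome Methylation phenotype vector.
#' @param covariates Optional matrix, identical to the QTL scan's.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Mandatory integer seed for the bootstrap stream.
#' @return An object of class \code{mediation_result}.
#' @export
bootstrap_acme <- function(dosage, mediator, outcome, covariates = NULL,
                           n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory for the bootstrap")
  dat <- cbind(x = dosage, m = mediator, y = outcome)
  if (!is.null(covariates)) dat <- cbind(dat, as.matrix(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  q <- ncol(dat) - 3L
  C <- if (q > 0L) dat[, -(1:3), drop = FALSE] else NULL
  x <- dat[, "x"]; m <- dat[, "m"]; y <- dat[, "y"]

  fit_paths <- function(x, m, y, C) {
    Xm <- cbind(1, x, C)
    Xy <- cbind(1, x, m, C)
    qm <- qr(Xm); qy <- qr(Xy)
    if (qm$rank < ncol(Xm) || qy$rank < ncol(Xy)) return(NULL)
    a <- qr.coef(qm, m)[2L]
    cy <- qr.coef(qy, y)
    c(a = unname(a), b = unname(cy[3L]), cprime = unname(cy[2L]))
  }
  pt <- fit_paths(x, m, y, C)
  if (is.null(pt)) stop("rank-deficient design on the full data")
  total_fit <- ols_term(y, x, C)
  acme <- pt[["a"]] * pt[["b"]]
  ade <- pt[["cprime"]]

  set.seed(seed)
  boot_acme <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- fit_paths(x[idx], m[idx], y[idx],
                      if (is.null(C)) NULL else C[idx, , drop = FALSE])
      if (!is.null(pb)) break
      n_redrawn <- n_redrawn + 1L
    }
    boot_acme[b] <- pb[["a"]] * pb[["b"]]
  }
  ci <- unname(stats::quantile(boot_acme, c(0.025, 0.975), type = 7))
  p_boot <- max(2 * min(mean(boot_acme <= 0), mean(boot_acme >= 0)), 1 / n_boot)
  p_boot <- min(1, p_boot)
  structure(list(a = pt[["a"]], b = pt[["b"]], acme = acme, ade = ade,
                 total = total_fit$beta,
                 prop_mediated = acme / (acme + ade),
                 ci = ci, p_boot = p_boot, boot_acme = boot_acme,
                 n = n, n_boot = n_boot, seed = seed,
                 n_redrawn = n_redrawn),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: ACME = %.4g [%.4g, %.4g], ADE = %.4g, total = %.4g\n",
              x$acme, x$ci[1], x$ci[2], x$ade, x$total))
  cat(sprintf("  proportion mediated %.3f | bootstrap P = %.4g (n = %d, n_boot = %d, seed = %d)\n",
              x$prop_mediated, x$p_boot, x$n, x$n_boot, x$seed))
  invisible(x)
}
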