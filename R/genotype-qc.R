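#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the P-value
#' is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Probabilities are computed by the stable recurrence over heterozygote
#' counts (stepping out from the modal count), not by direct factorials.
#' Monomorphic input returns P = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return The exact P-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n <= 0) stop("total genotype count must be positive")
  n_a <- 2L * n_hom_alt + n_het          # minor-ish allele count below
  n_A <- 2L * n_hom_ref + n_het
  rare <- min(n_a, n_A)
  if (rare == 0L) return(1.0)
  # possible het counts share the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # start at the modal het count and apply the recurrence both ways:
  # P(h-2)/P(h) = h(h-1) / (4 (nAA+1)(naa+1)), with nAA, naa at h
  mode_h <- round(rare * (2 * n - rare) / (2 * n))
  if (mode_h %% 2L != rare %% 2L) mode_h <- mode_h + 1L
  mode_h <- min(max(mode_h, hets[1L]), rare)
  mid_idx <- match(mode_h, hets)
  probs[mid_idx] <- 1
  h <- mode_h
  if (mid_idx > 1L) {
    for (i in seq(mid_idx - 1L, 1L)) {
      h2 <- hets[i + 1L]                  # moving h2 -> h2 - 2
      naa <- (rare - h2) / 2
      nAA <- n - h2 - naa
      probs[i] <- probs[i + 1L] * h2 * (h2 - 1) / (4 * (naa + 1) * (nAA + 1))
    }
  }
  if (mid_idx < length(hets)) {
    for (i in seq(mid_idx + 1L, length(hets))) {
      h2 <- hets[i - 1L]                  # moving h2 -> h2 + 2
      naa <- (rare - h2) / 2
      nAA <- n - h2 - naa
      probs[i] <- probs[i - 1L] * 4 * naa * nAA / ((h2 + 2) * (h2 + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Filter SNPs on MAF, missingness, HWE and allele count
#'
#' Removes SNPs with minor allele frequency below \code{maf_min},
#' genotype missingness above \code{missing_max}, exact-test HWE P below
#' \code{hwe_p_min}, or a multi-allelic ALT record. Removal counts per
#' rule are attached as attribute \code{qc_log} (a SNP can fail several
#' rules).
#'
#' @param g A \code{genotype_set}.
#' @param maf_min Minimum MAF (default 0.05).
#' @param missing_max Maximum missing fraction (default 0.05).
#' @param hwe_p_min Minimum HWE exact P (default 0.001).
#' @return The filtered \code{genotype_set}; empty output raises a
#'   warning, not an error.
#' @export
filter_snps <- function(g, maf_min = 0.05, missing_max = 0.05,
                        hwe_p_min = 0.001) {
  d <- g$dosage
  miss <- colMeans(is.na(d))
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(1.0)
    hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1L))
  multi <- grepl(",", g$snps$alt, fixed = TRUE)
  fail_maf <- maf < maf_min
  fail_miss <- miss > missing_max
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_maf | fail_miss | fail_hwe | multi)
  if (!any(keep)) warning("all SNPs removed by QC filters")
  out <- g
  out$snps <- g$snps[keep, , drop = FALSE]
  out$dosage <- g$dosage[, keep, drop = FALSE]
  if (!is.null(g$haplotypes)) out$haplotypes <- g$haplotypes[, keep, drop = FALSE]
  attr(out, "qc_log") <- data.frame(
    rule = c("maf", "missingness", "hwe", "multiallelic"),
    n_removed = c(sum(fail_maf), sum(fail_miss), sum(fail_hwe), sum(multi)))
  out
}

#' Sample-level quality control from RNA-seq metrics
#'
#' Removes samples with fewer than 5,000,000 remaining reads, fewer than
#' 10,000 mitochondrial reads, rRNA content above 30\%, RNA-seq mismatch
#' percentage above 1\%, or intergenic read percentage above 30\%, and
#' flags expression-PC outliers automatically as coordinates more than
#' \code{pc_mad_k} median absolute deviations from the median on any of
#' PCs 1-3 (an automatic stand-in for visual outlier exclusion). Samples
#' with a missing metric are flagged unevaluable.
#'
#' @param metrics Data.frame as from [simulate_qc_metrics()].
#' @param thresholds Named list overriding any of \code{min_reads} (5e6),
#'   \code{min_mito_reads} (1e4), \code{max_rrna} (0.3),
#'   \code{max_mismatch} (0.01), \code{max_intergenic} (0.3).
#' @param pc_mad_k MAD multiplier for expression-PC outliers (default 5).
#' @return List with \code{kept}, \code{removed} (data.frame sample +
#'   reasons) and \code{unevaluable}.
#' @export
filter_samples <- function(metrics, thresholds = list(), pc_mad_k = 5) {
  th <- utils::modifyList(list(min_reads = 5e6, min_mito_reads = 1e4,
                               max_rrna = 0.3, max_mismatch = 0.01,
                               max_intergenic = 0.3), thresholds)
  need <- c("remaining_reads", "mito_reads", "rrna_fraction",
            "mismatch_fraction", "intergenic_fraction")
  miss_col <- setdiff(need, names(metrics))
  if (length(miss_col)) stop("missing metric column(s): ", paste(miss_col, collapse = ", "))
  uneval <- apply(is.na(metrics[, need]), 1L, any)
  reasons <- vector("list", nrow(metrics))
  add <- function(idx, r) for (i in which(idx & !uneval)) reasons[[i]] <<- c(reasons[[i]], r)
  add(metrics$remaining_reads < th$min_reads, "low_reads")
  add(metrics$mito_reads < th$min_mito_reads, "low_mito")
  add(metrics$rrna_fraction > th$max_rrna, "high_rrna")
  add(metrics$mismatch_fraction > th$max_mismatch, "high_mismatch")
  add(metrics$intergenic_fraction > th$max_intergenic, "high_intergenic")
  for (pc in c("expr_pc1", "expr_pc2", "expr_pc3")) {
    if (!pc %in% names(metrics)) next
    v <- metrics[[pc]]
    md <- stats::median(v, na.rm = TRUE)
    mad_v <- stats::mad(v, na.rm = TRUE)
    if (is.finite(mad_v) && mad_v > 0)
      add(!is.na(v) & abs(v - md) > pc_mad_k * mad_v, paste0(pc, "_outlier"))
  }
  failed <- vapply(reasons, function(r) length(r) > 0L, logical(1L))
  list(kept = metrics$sample[!failed & !uneval],
       removed = data.frame(
         sample = metrics$sample[failed],
         reasons = vapply(reasons[failed], paste, character(1L), collapse = ";"),
         stringsAsFactors = FALSE),
       unevaluable = metrics$sample[uneval])
}

#' Genetic principal components from dosages
#'
#' PCs of the sample covariance of dosages standardised per SNP by the
#' allele-frequency mean and \eqn{\sqrt{2p(1-p)}}. Zero-variance SNPs are
#' dropped; missing dosages are mean-imputed (zero after centring). Signs
#' follow a deterministic convention: the largest-magnitude SNP loading
#' of each component is positive.
#'
#' @param g A \code{genotype_set} (QC-passed).
#' @param k Number of components (default 5).
#' @return Samples x k matrix of coordinates (columns \code{gPC1..k});
#'   loadings as attribute \code{loadings}.
#' @export
genetic_pcs <- function(g, k = 5) {
  n <- length(g$samples)
  if (n < k + 1L) stop("need at least k+1 samples for ", k, " PCs")
  d <- g$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1 & apply(d, 2L, function(x) stats::var(x, na.rm = TRUE) > 0)
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(d, 2L, 2 * p, `-`)
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), `/`)
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(g$samples, paste0("gPC", seq_len(k)))
  attr(scores, "loadings") <- loadings
  scores
}
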