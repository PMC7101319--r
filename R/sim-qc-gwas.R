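#' Simulate per-sample RNA-seq QC metrics with planted failures
#'
#' Generates the metric table consumed by [filter_samples()]: remaining
#' reads, mitochondrial reads, rRNA fraction, genome-wide RNA-seq mismatch
#' fraction and intergenic fraction, plus the first three expression-PC
#' coordinates. A configured number of samples is deliberately planted
#' below/above each threshold (disjoint sets, assigned in shuffled sample
#' order) so QC rules can be checked against exact counts.
#'
#' @param truth A \code{truth_set}.
#' @param config The same [sim_config()].
#' @return The \code{truth_set} with \code{$qc_metrics} attached: columns
#'   \code{sample}, \code{remaining_reads}, \code{mito_reads},
#'   \code{rrna_fraction}, \code{mismatch_fraction},
#'   \code{intergenic_fraction}, \code{expr_pc1..3} and
#'   \code{planted_fail} (rule name or empty).
#' @export
simulate_qc_metrics <- function(truth, config) {
  samples <- dimnames(truth$levels)[[1]]
  n <- length(samples)
  set.seed(config$seed + 11000L + 1000L * as.integer(truth$dataset))
  qc <- data.frame(
    sample = samples,
    remaining_reads = round(stats::runif(n, 2e7, 4e7)),
    mito_reads = round(stats::runif(n, 5e4, 5e5)),
    rrna_fraction = stats::runif(n, 0.05, 0.20),
    mismatch_fraction = stats::runif(n, 0.002, 0.008),
    intergenic_fraction = stats::runif(n, 0.05, 0.20),
    expr_pc1 = stats::rnorm(n, 0, 1),
    expr_pc2 = stats::rnorm(n, 0, 1),
    expr_pc3 = stats::rnorm(n, 0, 1),
    planted_fail = "", stringsAsFactors = FALSE)
  counts <- config$qc_fail_counts
  total_fail <- sum(counts)
  if (total_fail > n) stop("configuration error: more planted QC failures than samples")
  ord <- sample.int(n)
  at <- 0L
  take <- function(k) { idx <- ord[at + seq_len(k)]; at <<- at + k; idx }
  i <- take(counts[["low_reads"]])
  qc$remaining_reads[i] <- round(stats::runif(length(i), 1e6, 4.99e6))
  qc$planted_fail[i] <- "low_reads"
  i <- take(counts[["low_mito"]])
  qc$mito_reads[i] <- round(stats::runif(length(i), 100, 9999))
  qc$planted_fail[i] <- "low_mito"
  i <- take(counts[["high_rrna"]])
  qc$rrna_fraction[i] <- stats::runif(length(i), 0.31, 0.6)
  qc$planted_fail[i] <- "high_rrna"
  i <- take(counts[["high_mismatch"]])
  qc$mismatch_fraction[i] <- stats::runif(length(i), 0.011, 0.05)
  qc$planted_fail[i] <- "high_mismatch"
  i <- take(counts[["high_intergenic"]])
  qc$intergenic_fraction[i] <- stats::runif(length(i), 0.31, 0.6)
  qc$planted_fail[i] <- "high_intergenic"
  truth$qc_metrics <- qc
  truth
}

#' Simulate a GWAS-catalogue table linked to the planted loci
#'
#' Plants one catalogue entry per planted SNP on its perfect-proxy
#' haplotype column (so D' with the planted SNP is 1), cycling through the
#' configured trait list, plus three decoy rows per planted SNP that the
#' overlap filters must exclude: one 600 kb away (outside the 500 kb
#' window), one from a 9,000-case non-quantitative study, and one from a
#' non-European study. An empty trait list yields a header-only catalogue.
#'
#' @param truth A \code{truth_set}.
#' @param genotypes The matching \code{genotype_set} (for proxy
#'   positions).
#' @param config The same [sim_config()].
#' @return The \code{truth_set} with \code{$gwas_catalogue} attached
#'   (columns \code{rsid}, \code{chr}, \code{pos}, \code{trait}, \code{p},
#'   \code{n_cases}, \code{ancestry}, \code{quantitative}).
#' @export
simulate_gwas_catalogue <- function(truth, genotypes, config) {
  empty <- data.frame(rsid = character(), chr = character(), pos = integer(),
                      trait = character(), p = numeric(), n_cases = integer(),
                      ancestry = character(), quantitative = logical(),
                      stringsAsFactors = FALSE)
  traits <- config$catalogue_traits
  if (!length(traits)) { truth$gwas_catalogue <- empty; return(truth) }
  planted <- planted_snps(config)
  rows <- list()
  for (k in seq_len(nrow(planted))) {
    p <- planted[k, ]
    proxy <- paste0(p$snp, "_proxy")
    j <- match(proxy, genotypes$snps$id)
    trait <- traits[((k - 1L) %% length(traits)) + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = proxy, chr = p$chr, pos = genotypes$snps$pos[j], trait = trait,
      p = 1e-12, n_cases = 50000L, ancestry = "European",
      quantitative = FALSE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = paste0(p$snp, "_far_cat"), chr = p$chr, pos = p$pos + 600000L,
      trait = trait, p = 1e-12, n_cases = 50000L, ancestry = "European",
      quantitative = FALSE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = paste0(p$snp, "_small_cat"), chr = p$chr,
      pos = genotypes$snps$pos[j] + 1000L, trait = trait, p = 1e-12,
      n_cases = 9000L, ancestry = "European", quantitative = FALSE,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = paste0(p$snp, "_noneur_cat"), chr = p$chr,
      pos = genotypes$snps$pos[j] + 2000L, trait = trait, p = 1e-12,
      n_cases = 50000L, ancestry = "East Asian", quantitative = FALSE,
      stringsAsFactors = FALSE)
  }
  truth$gwas_catalogue <- do.call(rbind, rows)
  truth
}

#' Write phased haplotypes as a TSV (rows: chromosome copies)
#' @param g A \code{genotype_set} with haplotypes.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_haplotypes_tsv <- function(g, path) {
  stopifnot(!is.null(g$haplotypes))
  df <- data.frame(hap = rownames(g$haplotypes), g$haplotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, path, header = "phased haplotypes, 0/1 per chromosome copy")
  invisible(path)
}
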