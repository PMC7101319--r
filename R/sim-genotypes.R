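#' Simulate a genotype panel with planted and null SNPs
#'
#' Draws phased biallelic genotypes for one dataset. Planted SNPs (from the
#' causal and mediation specifications) are each embedded in an LD block:
#' a finite pool of haplotypes carries the planted allele at the stated
#' MAF, block-mate SNPs copy that allele with a small per-haplotype flip
#' probability, and one \emph{perfect proxy} SNP duplicates the planted
#' haplotype column exactly (D' = 1), which the GWAS-catalogue generator
#' uses. Individuals sample one pool haplotype pair per block with
#' replacement, so within-block D' is high; null SNPs are drawn
#' independently under Hardy-Weinberg equilibrium at MAFs uniform on
#' \code{maf_range}.
#'
#' @param config A [sim_config()].
#' @param dataset Dataset index (1-based); individuals are independent
#'   across datasets.
#' @return An object of class \code{genotype_set}: list with
#'   \code{samples}, \code{snps} (id, chr, pos, ref, alt, maf_target,
#'   role, block), \code{dosage} (samples x SNPs, 0/1/2) and
#'   \code{haplotypes} (2n x SNPs, 0/1, rows \code{<sample>_h1/_h2}).
#' @export
simulate_genotypes <- function(config, dataset = 1L) {
  validate_sim_config(config)
  n <- config$n_individuals
  set.seed(config$seed + 1000L * as.integer(dataset))
  samples <- sprintf("D%d_S%04d", dataset, seq_len(n))
  spec <- config$ld_block_spec
  planted <- planted_snps(config)

  snp_ids <- character(0); chr <- character(0); pos <- integer(0)
  maf <- numeric(0); role <- character(0); block <- character(0)
  hap_cols <- list()

  # pool-based LD blocks around each planted SNP
  for (k in seq_len(nrow(planted))) {
    p <- planted[k, ]
    pool <- stats::rbinom(spec$pool_size, 1L, p$maf)
    while (length(unique(pool)) < 2L) pool <- stats::rbinom(spec$pool_size, 1L, p$maf)
    mates <- matrix(0L, spec$pool_size, spec$snps_per_block)
    for (j in seq_len(spec$snps_per_block)) {
      flip <- stats::rbinom(spec$pool_size, 1L, spec$mate_flip)
      mates[, j] <- as.integer(xor(pool, flip))
    }
    idx <- matrix(sample.int(spec$pool_size, 2L * n, replace = TRUE), ncol = 2L)
    hap_pair <- function(alleles) {
      h <- matrix(0L, 2L * n, 1L)
      h[seq(1L, 2L * n, by = 2L), 1L] <- alleles[idx[, 1L]]
      h[seq(2L, 2L * n, by = 2L), 1L] <- alleles[idx[, 2L]]
      h
    }
    block_id <- paste0("block_", p$snp)
    # planted SNP, perfect proxy, block mates
    hap_cols[[length(hap_cols) + 1L]] <- hap_pair(pool)
    snp_ids <- c(snp_ids, p$snp); chr <- c(chr, p$chr)
    pos <- c(pos, p$pos); maf <- c(maf, p$maf)
    role <- c(role, "planted"); block <- c(block, block_id)

    hap_cols[[length(hap_cols) + 1L]] <- hap_pair(pool)
    snp_ids <- c(snp_ids, paste0(p$snp, "_proxy")); chr <- c(chr, p$chr)
    pos <- c(pos, p$pos + 25000L); maf <- c(maf, p$maf)
    role <- c(role, "proxy"); block <- c(block, block_id)

    mate_off <- round(seq(-spec$span_bp / 2, spec$span_bp / 2,
                          length.out = spec$snps_per_block))
    for (j in seq_len(spec$snps_per_block)) {
      hap_cols[[length(hap_cols) + 1L]] <- hap_pair(mates[, j])
      snp_ids <- c(snp_ids, sprintf("%s_mate%d", p$snp, j))
      chr <- c(chr, p$chr); pos <- c(pos, as.integer(p$pos + mate_off[j] + 1000L))
      maf <- c(maf, mean(mates[, j])); role <- c(role, "block_mate")
      block <- c(block, block_id)
    }
  }

  # unlinked null SNPs under HWE
  if (config$n_null_snps > 0L) {
    null_maf <- stats::runif(config$n_null_snps, config$maf_range[1], config$maf_range[2])
    null_chr <- as.character(sample.int(22L, config$n_null_snps, replace = TRUE))
    null_pos <- sample.int(2e8L, config$n_null_snps, replace = TRUE)
    for (j in seq_len(config$n_null_snps)) {
      hap_cols[[length(hap_cols) + 1L]] <-
        matrix(stats::rbinom(2L * n, 1L, null_maf[j]), ncol = 1L)
    }
    snp_ids <- c(snp_ids, sprintf("snp_null%04d", seq_len(config$n_null_snps)))
    chr <- c(chr, null_chr); pos <- c(pos, null_pos)
    maf <- c(maf, null_maf)
    role <- c(role, rep("null", config$n_null_snps))
    block <- c(block, rep(NA_character_, config$n_null_snps))
  }

  if (!length(hap_cols)) {
    haplotypes <- matrix(0L, 2L * n, 0L)
  } else {
    haplotypes <- do.call(cbind, hap_cols)
  }
  colnames(haplotypes) <- snp_ids
  rownames(haplotypes) <- paste0(rep(samples, each = 2L), c("_h1", "_h2"))
  dosage <- haplotypes[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    haplotypes[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(dosage) <- samples

  snps <- data.frame(id = snp_ids, chr = chr, pos = as.integer(pos),
                     ref = rep("A", length(snp_ids)),
                     alt = rep("G", length(snp_ids)),
                     maf_target = maf, role = role,
                     block = block, stringsAsFactors = FALSE)
  structure(list(samples = samples, snps = snps, dosage = dosage,
                 haplotypes = haplotypes, dataset = dataset),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", length(x$samples), "samples x", nrow(x$snps), "SNPs")
  if (!is.null(x$haplotypes)) cat(" (phased)")
  cat("\n  roles:", paste(names(table(x$snps$role)), table(x$snps$role),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a minimal VCF v4.2 with GT genotypes
#'
#' Emits phased GT calls (\code{0|1} style) when haplotypes are present,
#' unphased otherwise.
#'
#' @param g A \code{genotype_set}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mitomodqtl",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  n <- length(g$samples)
  phased <- !is.null(g$haplotypes)
  ord <- order(factor(g$snps$chr, levels = unique(g$snps$chr)), g$snps$pos)
  for (j in ord) {
    if (phased) {
      h1 <- g$haplotypes[seq(1L, 2L * n, by = 2L), j]
      h2 <- g$haplotypes[seq(2L, 2L * n, by = 2L), j]
      gt <- paste0(h1, "|", h2)
      gt[is.na(h1) | is.na(h2)] <- ".|."
    } else {
      d <- g$dosage[, j]
      gt <- c("0/0", "0/1", "1/1")[d + 1L]
      gt[is.na(d)] <- "./."
    }
    writeLines(paste(c(g$snps$chr[j], g$snps$pos[j], g$snps$id[j],
                       g$snps$ref[j], g$snps$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a minimal GT-only VCF
#'
#' Parses a VCF v4.2 through \pkg{vcfR} and returns a \code{genotype_set}
#' with dosages (alt-allele counts) and, where all calls are phased, the
#' haplotype matrix.
#'
#' @param path VCF path.
#' @return A \code{genotype_set}.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  snps <- data.frame(id = vcfR::getID(v), chr = vcfR::getCHROM(v),
                     pos = vcfR::getPOS(v), ref = vcfR::getREF(v),
                     alt = vcfR::getALT(v), stringsAsFactors = FALSE)
  alleles <- function(k) {
    a <- substr(gt, k, k)
    out <- suppressWarnings(matrix(as.integer(a), nrow(gt), ncol(gt)))
    out
  }
  a1 <- alleles(1L); a2 <- alleles(3L)
  dosage <- t(a1 + a2)
  colnames(dosage) <- snps$id
  rownames(dosage) <- samples
  phased <- all(grepl("|", gt[!is.na(gt)], fixed = TRUE))
  haplotypes <- NULL
  if (phased) {
    n <- length(samples)
    haplotypes <- matrix(0L, 2L * n, nrow(snps))
    haplotypes[seq(1L, 2L * n, by = 2L), ] <- t(a1)
    haplotypes[seq(2L, 2L * n, by = 2L), ] <- t(a2)
    colnames(haplotypes) <- snps$id
    rownames(haplotypes) <- paste0(rep(samples, each = 2L), c("_h1", "_h2"))
  }
  snps$role <- NA_character_; snps$maf_target <- NA_real_; snps$block <- NA_character_
  structure(list(samples = samples, snps = snps, dosage = dosage,
                 haplotypes = haplotypes, dataset = NA_integer_),
            class = "genotype_set")
}
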