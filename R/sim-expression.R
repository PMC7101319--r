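#' Simulate a gene-expression matrix tied to the planted truth
#'
#' Emits a TPM-scale genes-by-samples matrix for one tissue containing:
#' the mediator genes (expression \code{a * dosage + noise}, already drawn
#' inside [simulate_methylation()] so the mediated methylation component
#' is consistent), the mitochondrial genes immediately upstream of tRNA P9
#' sites (expression \code{gamma * methylation + noise} per the configured
#' adjacency slopes), null genes placed inside the cis window of each
#' planted SNP (eQTL candidates with no effect), a far gene 1.2 Mb from
#' each planted SNP (outside the 1 Mb window), and independent noise genes
#' loaded on one latent batch factor (the structure the hidden-factor
#' step is meant to absorb). Values are shifted to a positive TPM scale
#' and clamped at zero.
#'
#' @param truth A \code{truth_set}.
#' @param config The same [sim_config()].
#' @param tissue Tissue index (default 1).
#' @return The \code{truth_set} with \code{$expression[[tissue]]}: a list
#'   with \code{tpm} (genes x samples), \code{genes} (id, chr, pos) and
#'   \code{batch} (the latent factor per sample).
#' @export
simulate_expression <- function(truth, config, tissue = 1L) {
  samples <- dimnames(truth$levels)[[1]]
  n <- length(samples)
  set.seed(config$seed + 8000L + 1000L * as.integer(truth$dataset) +
             37L * as.integer(tissue))
  expr <- list(); genes <- list()
  add_gene <- function(id, chr, pos, values) {
    expr[[length(expr) + 1L]] <<- values
    genes[[length(genes) + 1L]] <<- data.frame(gene = id, chr = chr,
                                               pos = as.integer(pos),
                                               stringsAsFactors = FALSE)
  }

  med <- truth$mediation_specs
  for (k in seq_len(nrow(med))) {
    add_gene(med$gene[k], med$chr[k], med$gene_pos[k],
             pmax(0, 20 + truth$mediator_expr[, k]))
  }

  adj <- adjacency_pairs()
  mt_pos <- c(`MT-RNR1` = 1200L, `MT-RNR2` = 2500L, `MT-ND1` = 3900L,
              `MT-ND2` = 5000L, `MT-CO2` = 8000L, `MT-CO3` = 9600L,
              `MT-ND3` = 10200L, `MT-ND4` = 11500L, `MT-CYB` = 15400L)
  for (k in seq_len(nrow(adj))) {
    site_col <- paste0("p", adj$position[k])
    gamma <- config$adjacency_gammas[site_col]
    if (is.na(gamma)) gamma <- 0
    meth <- truth$levels[, site_col, tissue]
    add_gene(adj$upstream_gene[k], "MT", mt_pos[adj$upstream_gene[k]],
             pmax(0, 30 + gamma * meth +
                    stats::rnorm(n, 0, config$mt_expr_noise_sd)))
  }

  planted <- planted_snps(config)
  for (k in seq_len(nrow(planted))) {
    p <- planted[k, ]
    if (config$n_cis_null_genes > 0L) {
      off <- round(seq(-4e5, 4e5, length.out = config$n_cis_null_genes))
      for (j in seq_len(config$n_cis_null_genes)) {
        base <- stats::runif(1, 10, 60)
        add_gene(sprintf("%s_cisnull%d", p$snp, j), p$chr, p$pos + off[j],
                 pmax(0, base + stats::rnorm(n, 0, base * 0.1)))
      }
    }
    base <- stats::runif(1, 10, 60)
    add_gene(paste0(p$snp, "_far"), p$chr, p$pos + 1200000L,
             pmax(0, base + stats::rnorm(n, 0, base * 0.1)))
  }

  batch <- stats::rnorm(n)
  if (config$n_noise_genes > 0L) {
    for (j in seq_len(config$n_noise_genes)) {
      base <- stats::runif(1, 3, 100)
      load <- config$expr_batch_loading * stats::runif(1, 0.4, 1) * base * 0.1
      add_gene(sprintf("gene_noise%03d", j),
               as.character(sample.int(22L, 1L)),
               sample.int(2e8L, 1L),
               pmax(0, base + load * batch + stats::rnorm(n, 0, base * 0.05)))
    }
  }

  tpm <- do.call(rbind, expr)
  genes <- do.call(rbind, genes)
  rownames(tpm) <- genes$gene
  colnames(tpm) <- samples
  if (is.null(truth$expression)) truth$expression <- list()
  truth$expression[[tissue]] <- list(tpm = tpm, genes = genes, batch = batch)
  truth
}

#' Write an expression matrix as a genes-by-samples TSV
#' @param expr List as stored in \code{truth$expression[[t]]} (or a plain
#'   matrix).
#' @param path Output path; gene metadata goes to \code{<path>.genes.tsv}
#'   when available.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  tpm <- if (is.list(expr)) expr$tpm else expr
  df <- data.frame(gene = rownames(tpm), tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, path, header = "genes x samples, TPM scale")
  if (is.list(expr) && !is.null(expr$genes)) {
    write_tsv_commented(expr$genes, paste0(path, ".genes.tsv"),
                        header = "gene positions (1-based)")
  }
  invisible(path)
}

#' Read a genes-by-samples expression TSV
#' @param path TSV written by [write_expression_tsv()].
#' @return Numeric matrix, genes in rows.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_commented(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
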