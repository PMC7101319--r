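#' Configuration for the synthetic cohort generator
#'
#' Defines the ground-truth generative model used for parameter-recovery
#' testing of the whole pipeline: per-site modification means, a shared
#' latent factor inducing the observed ~0.75 cross-site correlation of P9
#' methylation levels, planted additive SNP effects on the proportion
#' scale, SNP -> cis-gene expression -> methylation mediation chains,
#' reverse-transcriptase misincorporation and sequencing error for the
#' pileup layer, and the multi-dataset / multi-tissue cohort structure
#' needed for meta-analysis and replication.
#'
#' The latent model per individual \eqn{i}, site \eqn{s}, tissue \eqn{t} is
#' \deqn{m_{ist} = clamp_{[0,1]}(\mu_s + \lambda_s F_i + u_{is} +
#'   \sum \beta G_i + b E_i + \epsilon_{ist})}
#' with \eqn{F_i} a standard-normal factor shared across P9 sites and
#' tissues, \eqn{u_{is}} an individual-by-site component shared across
#' tissues, and \eqn{\epsilon} independent noise. Default loadings are
#' proportional to the site mean (constant coefficient of variation), with
#' the shared-factor share of variance set so the model-implied pairwise
#' P9 correlation is 0.75.
#'
#' @param n_individuals Individuals per dataset (default 200).
#' @param n_datasets Number of independent datasets (default 2).
#' @param n_tissues Tissues per dataset, repeated measures on the same
#'   individuals (default 2).
#' @param site_means Named numeric: mean modification level per phenotype
#'   column (\code{p585} ... \code{p13710}), all in \[0,1\].
#' @param shared_factor_loadings Named numeric \eqn{\lambda_s} per site
#'   column; default \code{sqrt(3) * cv * site_means} over P9 sites (zero
#'   at 2617/13710), giving cross-site r = 0.75.
#' @param noise_cv Coefficient of variation of the non-shared noise
#'   (default 0.15); split 60/40 between the tissue-shared individual
#'   component and tissue-specific noise.
#' @param causal_effects Data.frame \code{snp}, \code{chr}, \code{pos},
#'   \code{maf}, \code{phenotype}, \code{beta}: planted per-allele additive
#'   effects on the proportion scale (betas at the scale reported for
#'   whole-blood methylation QTLs, e.g. 0.0459 on the averaged P9 measure).
#' @param mediation_specs Data.frame \code{snp}, \code{chr}, \code{pos},
#'   \code{maf}, \code{gene}, \code{gene_pos}, \code{phenotype}, \code{a},
#'   \code{b}, \code{direct}: SNP -> mediator expression -> methylation
#'   chains; the methylation effect of these SNPs enters only through
#'   \code{a*b + direct}.
#' @param e_mod Reverse-transcriptase misincorporation efficiency at a
#'   modified base (default 1: mismatch proportion identifies the level).
#' @param e_seq Per-base sequencing error rate (default 0.002).
#' @param seq_error_low_qual_frac Fraction of sequencing-error bases drawn
#'   below Phred 13 so the quality filter is exercised (default 0.3).
#' @param coverage_mean,coverage_size Negative-binomial read depth per
#'   sample-site; defaults mean 500, size 0.91, putting ~5\% of draws
#'   below the 20x coverage filter.
#' @param maf_range Range of minor allele frequencies for null SNPs
#'   (default c(0.05, 0.5)).
#' @param n_null_snps Unlinked null SNPs per dataset (default 300).
#' @param ld_block_spec List: \code{pool_size} haplotypes per block,
#'   \code{snps_per_block} high-LD neighbours per planted SNP,
#'   \code{span_bp} block length, \code{mate_flip} per-haplotype allele
#'   flip probability for block mates.
#' @param adjacency_gammas Named numeric per tRNA P9 position: slope of
#'   upstream mitochondrial gene expression on methylation level.
#' @param mt_expr_noise_sd Noise sd of mitochondrial gene expression
#'   (default 0.05).
#' @param mediator_noise_sd Noise sd of mediator gene expression
#'   (default 0.5).
#' @param n_noise_genes Unlinked expression genes (default 40).
#' @param expr_batch_loading Loading of a latent batch factor on noise
#'   genes (default 0.5), recovered by the hidden-factor step.
#' @param n_cis_null_genes Null genes placed within the cis window of each
#'   planted SNP (default 3).
#' @param qc_fail_counts Named integer: samples deliberately planted to
#'   fail each sample-QC rule (\code{low_reads}, \code{low_mito},
#'   \code{high_rrna}, \code{high_mismatch}, \code{high_intergenic}).
#' @param catalogue_traits Character vector of trait names for planted
#'   GWAS-catalogue entries; \code{character(0)} gives an empty catalogue.
#' @param seed Integer master seed; all emitted files are byte-identical
#'   for a fixed seed.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_individuals = 200,
                       n_datasets = 2,
                       n_tissues = 2,
                       site_means = NULL,
                       shared_factor_loadings = NULL,
                       noise_cv = 0.15,
                       causal_effects = NULL,
                       mediation_specs = NULL,
                       e_mod = 1.0,
                       e_seq = 0.002,
                       seq_error_low_qual_frac = 0.3,
                       coverage_mean = 500,
                       coverage_size = 0.91,
                       maf_range = c(0.05, 0.5),
                       n_null_snps = 300,
                       ld_block_spec = list(pool_size = 24, snps_per_block = 3,
                                            span_bp = 100000, mate_flip = 0.05),
                       adjacency_gammas = NULL,
                       mt_expr_noise_sd = 0.05,
                       mediator_noise_sd = 0.5,
                       n_noise_genes = 40,
                       expr_batch_loading = 0.5,
                       n_cis_null_genes = 3,
                       qc_fail_counts = NULL,
                       catalogue_traits = c("diastolic blood pressure",
                                            "breast cancer", "psoriasis"),
                       seed = 1L) {
  sites <- mod_sites()
  site_cols <- paste0("p", sites$position)
  if (is.null(site_means)) {
    site_means <- c(p585 = 0.08, p1610 = 0.12, p3238 = 0.02, p4271 = 0.03,
                    p5520 = 0.10, p7526 = 0.09, p8303 = 0.12, p9999 = 0.11,
                    p10413 = 0.10, p12146 = 0.10, p12274 = 0.09,
                    p14734 = 0.06, p15896 = 0.05, p2617 = 0.55, p13710 = 0.10)
  }
  stopifnot(all(site_cols %in% names(site_means)))
  if (is.null(shared_factor_loadings)) {
    # lambda^2 / (lambda^2 + sigma^2) = 0.75 when lambda = sqrt(3) * sigma
    shared_factor_loadings <- sqrt(3) * noise_cv * site_means
    shared_factor_loadings[c("p2617", "p13710")] <- 0
  }
  if (is.null(causal_effects)) {
    causal_effects <- rbind(
      data.frame(snp = "snp_SLC25A26", chr = "3", pos = 66419956L, maf = 0.20,
                 phenotype = c("p585", "p1610", "p7526"),
                 beta = c(0.0204, 0.0453, 0.0241)),
      data.frame(snp = "snp_MRPP3", chr = "14", pos = 35735967L, maf = 0.35,
                 phenotype = paste0("p", sites$position[sites$in_p9_average]),
                 beta = 0.0459),
      data.frame(snp = "snp_585b", chr = "4", pos = 135793550L, maf = 0.30,
                 phenotype = "p585", beta = 0.0138),
      data.frame(snp = "snp_LONP1", chr = "19", pos = 5711930L, maf = 0.25,
                 phenotype = c("p9999", "p12146"),
                 beta = c(-0.0431, -0.0335)),
      data.frame(snp = "snp_ND5", chr = "10", pos = 30643872L, maf = 0.30,
                 phenotype = "p13710", beta = 0.0284))
  }
  if (is.null(mediation_specs)) {
    mediation_specs <- data.frame(
      snp = c("snp_PNPT1", "snp_TRMT61B"),
      chr = c("2", "2"), pos = c(55900459L, 29088450L),
      maf = c(0.30, 0.30),
      gene = c("PNPT1", "TRMT61B"),
      gene_pos = c(55800000L, 29200000L),
      phenotype = c("p2617", "p2617"),
      a = c(-0.5, 0.6), b = c(0.0166, 0.0322),
      direct = c(0, 0.004), stringsAsFactors = FALSE)
  }
  if (is.null(adjacency_gammas)) {
    adjacency_gammas <- c(p1610 = 0.2201, p3238 = 2.3615, p4271 = 0.156,
                          p5520 = 0.0755, p8303 = 0.0462, p9999 = -0.0477,
                          p10413 = 0.0953, p12146 = 0.0166, p15896 = 0.0202)
  }
  if (is.null(qc_fail_counts)) {
    n <- n_individuals
    qc_fail_counts <- c(low_reads = max(1L, round(0.02 * n)),
                        low_mito = max(1L, round(0.01 * n)),
                        high_rrna = max(1L, round(0.01 * n)),
                        high_mismatch = max(1L, round(0.01 * n)),
                        high_intergenic = max(1L, round(0.01 * n)))
  }
  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    n_datasets = as.integer(n_datasets),
    n_tissues = as.integer(n_tissues),
    site_means = site_means[site_cols],
    shared_factor_loadings = shared_factor_loadings[site_cols],
    noise_cv = noise_cv,
    causal_effects = causal_effects,
    mediation_specs = mediation_specs,
    e_mod = e_mod, e_seq = e_seq,
    seq_error_low_qual_frac = seq_error_low_qual_frac,
    coverage_mean = coverage_mean, coverage_size = coverage_size,
    maf_range = maf_range, n_null_snps = as.integer(n_null_snps),
    ld_block_spec = ld_block_spec,
    adjacency_gammas = adjacency_gammas,
    mt_expr_noise_sd = mt_expr_noise_sd,
    mediator_noise_sd = mediator_noise_sd,
    n_noise_genes = as.integer(n_noise_genes),
    expr_batch_loading = expr_batch_loading,
    n_cis_null_genes = as.integer(n_cis_null_genes),
    qc_fail_counts = qc_fail_counts,
    catalogue_traits = catalogue_traits,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals <= 0L) stop("configuration error: n_individuals must be positive")
  if (cfg$n_datasets <= 0L || cfg$n_tissues <= 0L)
    stop("configuration error: n_datasets and n_tissues must be positive")
  probs <- c(cfg$site_means, cfg$e_mod, cfg$e_seq, cfg$seq_error_low_qual_frac)
  if (any(probs < 0 | probs > 1)) stop("configuration error: probabilities must lie in [0,1]")
  if (cfg$coverage_mean <= 0) stop("configuration error: coverage_mean must be > 0")
  if (cfg$n_null_snps < 0L) stop("configuration error: n_null_snps must be >= 0")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || diff(cfg$maf_range) < 0)
    stop("configuration error: maf_range must be within (0, 0.5]")
  mafs <- c(cfg$causal_effects$maf, cfg$mediation_specs$maf)
  if (length(mafs) && any(mafs <= 0 | mafs > 0.5))
    stop("configuration error: planted SNP MAFs must be within (0, 0.5]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_datasets, "dataset(s) x", x$n_tissues,
      "tissue(s) x", x$n_individuals, "individuals, seed", x$seed, "\n")
  cat("  planted SNPs:", length(unique(c(x$causal_effects$snp, x$mediation_specs$snp))),
      "| null SNPs:", x$n_null_snps,
      "| e_mod:", x$e_mod, "| e_seq:", x$e_seq, "\n")
  invisible(x)
}

# Planted SNP table (causal + mediation), unique by id.
planted_snps <- function(cfg) {
  a <- unique(cfg$causal_effects[, c("snp", "chr", "pos", "maf")])
  b <- unique(cfg$mediation_specs[, c("snp", "chr", "pos", "maf")])
  out <- rbind(a, b)
  out[!duplicated(out$snp), , drop = FALSE]
}
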