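#' Simulate true modification levels with a shared latent factor
#'
#' Draws the ground-truth modification level for every individual, site
#' and tissue of one dataset under the latent linear model described in
#' [sim_config()]: site mean, a standard-normal factor shared across P9
#' sites within an individual (and across that individual's tissues), an
#' individual-by-site component shared across tissues, planted additive
#' SNP effects, mediated effects through simulated mediator-gene
#' expression, and independent tissue-level noise, clamped to \[0, 1\].
#' A warning is raised if more than 10\% of draws are clamped, which
#' indicates mis-scaled means or effects.
#'
#' @param genotypes A \code{genotype_set} for the same dataset; every
#'   planted SNP must be present.
#' @param config A [sim_config()].
#' @return An object of class \code{truth_set}: list with \code{levels}
#'   (individuals x 15 sites x tissues array), \code{factor} (the shared
#'   latent factor per individual), \code{mediator_expr} (individuals x
#'   mediator genes), planted-effect tables, \code{clamped_fraction} and
#'   the dataset index.
#' @export
simulate_methylation <- function(genotypes, config, dataset = genotypes$dataset) {
  validate_sim_config(config)
  need <- unique(c(config$causal_effects$snp, config$mediation_specs$snp))
  missing_snp <- setdiff(need, genotypes$snps$id)
  if (length(missing_snp))
    stop("causal SNP(s) absent from genotypes: ", paste(missing_snp, collapse = ", "))
  set.seed(config$seed + 2000L + 1000L * as.integer(dataset))
  n <- length(genotypes$samples)
  sites <- names(config$site_means)
  n_t <- config$n_tissues
  mu <- config$site_means
  lam <- config$shared_factor_loadings
  # non-shared noise: 60% individual-by-site (tissue-shared), 40% tissue level
  sd_u <- sqrt(0.6) * config$noise_cv * mu
  sd_e <- sqrt(0.4) * config$noise_cv * mu

  F_i <- stats::rnorm(n)
  u <- sapply(seq_along(sites), function(j) stats::rnorm(n, 0, sd_u[j]))
  colnames(u) <- sites

  med <- config$mediation_specs
  E <- NULL
  if (nrow(med)) {
    E <- sapply(seq_len(nrow(med)), function(k) {
      med$a[k] * genotypes$dosage[, med$snp[k]] +
        stats::rnorm(n, 0, config$mediator_noise_sd)
    })
    colnames(E) <- med$gene
    rownames(E) <- genotypes$samples
  }

  base <- matrix(rep(mu, each = n), n, length(sites),
                 dimnames = list(genotypes$samples, sites))
  base <- base + outer(F_i, lam) + u
  ce <- config$causal_effects
  for (k in seq_len(nrow(ce))) {
    base[, ce$phenotype[k]] <- base[, ce$phenotype[k]] +
      ce$beta[k] * genotypes$dosage[, ce$snp[k]]
  }
  for (k in seq_len(nrow(med))) {
    base[, med$phenotype[k]] <- base[, med$phenotype[k]] +
      med$b[k] * E[, k] + med$direct[k] * genotypes$dosage[, med$snp[k]]
  }

  levels <- array(NA_real_, c(n, length(sites), n_t),
                  dimnames = list(genotypes$samples, sites,
                                  paste0("T", seq_len(n_t))))
  n_clamped <- 0L
  for (t in seq_len(n_t)) {
    eps <- sapply(seq_along(sites), function(j) stats::rnorm(n, 0, sd_e[j]))
    raw <- base + eps
    n_clamped <- n_clamped + sum(raw < 0 | raw > 1)
    levels[, , t] <- clamp01(raw)
  }
  frac_clamped <- n_clamped / length(levels)
  if (frac_clamped > 0.10)
    warning(sprintf("%.1f%% of modification-level draws were clamped to [0,1]; site means or effect sizes look mis-scaled", 100 * frac_clamped))

  structure(list(levels = levels, factor = F_i, mediator_expr = E,
                 causal_effects = ce, mediation_specs = med,
                 clamped_fraction = frac_clamped, dataset = dataset,
                 seed = config$seed),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  d <- dim(x$levels)
  cat("truth_set: dataset", x$dataset, "-", d[1], "individuals x", d[2],
      "sites x", d[3], "tissue(s)\n")
  cat("  planted effects:", nrow(x$causal_effects), "causal +",
      nrow(x$mediation_specs), "mediated; clamped fraction",
      signif(x$clamped_fraction, 3), "\n")
  invisible(x)
}

#' Serialise a truth set to JSON
#'
#' Full-precision JSON round-trip of the ground-truth quantities used in
#' recovery tests (levels, shared factor, mediator expression, planted
#' effect tables, QC metrics when attached).
#'
#' @param truth A \code{truth_set}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    dataset = truth$dataset, seed = truth$seed,
    clamped_fraction = truth$clamped_fraction,
    dim = dim(truth$levels), dimnames = dimnames(truth$levels),
    levels = as.numeric(truth$levels),
    factor = truth$factor,
    mediator_genes = colnames(truth$mediator_expr),
    mediator_expr = if (is.null(truth$mediator_expr)) NULL else as.numeric(truth$mediator_expr),
    causal_effects = truth$causal_effects,
    mediation_specs = truth$mediation_specs,
    qc_metrics = truth$qc_metrics)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a truth set back from JSON
#' @param path JSON path written by [write_truth_json()].
#' @return A \code{truth_set}.
#' @export
read_truth_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  levels <- array(p$levels, dim = p$dim, dimnames = p$dimnames)
  E <- NULL
  if (!is.null(p$mediator_expr)) {
    E <- matrix(p$mediator_expr, nrow = p$dim[1],
                dimnames = list(p$dimnames[[1]], p$mediator_genes))
  }
  structure(list(levels = levels, factor = p$factor, mediator_expr = E,
                 causal_effects = as.data.frame(p$causal_effects),
                 mediation_specs = as.data.frame(p$mediation_specs),
                 clamped_fraction = p$clamped_fraction,
                 dataset = p$dataset, seed = p$seed,
                 qc_metrics = if (is.null(p$qc_metrics)) NULL else as.data.frame(p$qc_metrics)),
            class = "truth_set")
}
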