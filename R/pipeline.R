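#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the analysis chain with its default
#' value, the stage toggles and the synthetic-cohort configuration. The
#' defaults are the thresholds the analysis is defined by: base quality
#' Phred 13 and coverage 20x for mismatch quantification, a 1\% site-mean
#' evidence rule, 3-SD outlier masking, MAF 5\% / missingness 5\% / HWE
#' P 0.001 genotype QC, genome-wide 5e-8 corrected by 16 phenotypes and
#' 46 dataset-tissue analyses, a 1 Mb cis window, 1000 bootstrap
#' replicates, D' 0.9 and a 500 kb overlap window.
#'
#' @param out_dir Run directory.
#' @param seed Master seed.
#' @param n_individuals,n_datasets,n_tissues Cohort shape passed to
#'   [sim_config()] (defaults 250 x 2 datasets x 2 tissues: 500
#'   individuals).
#' @param stages Named logical toggles; any of \code{simulate},
#'   \code{quantify}, \code{qc}, \code{qtl}, \code{meta}, \code{mediate},
#'   \code{consequences}, \code{overlap}.
#' @param thresholds Named list overriding any analysis threshold.
#' @param sim Optional pre-built [sim_config()] (overrides the shape
#'   arguments).
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(out_dir = "mitomodqtl_run", seed = 1L,
                       n_individuals = 250, n_datasets = 2, n_tissues = 2,
                       stages = list(), thresholds = list(), sim = NULL) {
  th <- utils::modifyList(list(
    min_phred = 13, min_cov = 20, site_mean_threshold = 0.01, mask_sd = 3,
    maf_min = 0.05, missing_max = 0.05, hwe_p_min = 0.001,
    genomewide = 5e-8, n_phenotypes = 16, n_analyses = 46,
    peak_window = 500000, cis_window = 1e6, n_boot = 1000,
    dprime_min = 0.9, overlap_window = 500000, n_genetic_pcs = 5),
    thresholds)
  st <- utils::modifyList(
    list(simulate = TRUE, quantify = TRUE, qc = TRUE, qtl = TRUE,
         meta = TRUE, mediate = TRUE, consequences = TRUE, overlap = TRUE),
    stages)
  if (is.null(sim)) {
    sim <- sim_config(n_individuals = n_individuals,
                      n_datasets = n_datasets, n_tissues = n_tissues,
                      seed = seed)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 thresholds = th, stages = st, sim = sim),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with any of the [run_config()] fields
#'   (\code{out_dir}, \code{seed}, \code{n_individuals}, ...,
#'   \code{stages}, \code{thresholds}).
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
                                  names(formals(run_config)))])
}

config_header <- function(config) {
  c(paste0("seed: ", config$seed),
    paste0("thresholds: ",
           paste(names(config$thresholds), unlist(config$thresholds),
                 sep = "=", collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, quantify, qc, qtl,
#' meta, mediate, consequences, overlap — writing plain-text TSV outputs
#' (with commented provenance headers) and a JSON manifest carrying the
#' seed, per-stage row counts and MD5 hashes of every emitted file. A
#' stage failure halts the run naming the failing stage; outputs of
#' completed stages are retained. Disabling a stage skips its outputs but
#' lets later stages run from whatever inputs exist.
#'
#' @param config A [run_config()].
#' @return The run directory, invisibly; the manifest is
#'   \code{<out_dir>/manifest.json}.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  sim <- config$sim
  manifest <- list(seed = config$seed, package = "mitomodqtl",
                   version = as.character(utils::packageVersion("mitomodqtl")),
                   stages = list())
  state <- new.env(parent = emptyenv())
  note_stage <- function(name, counts) {
    manifest$stages[[name]] <<- counts
  }
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      message("[mitomodqtl] stage ", name, ": disabled, skipping")
      manifest$stages[[name]] <<- list(enabled = FALSE)
      return(invisible(NULL))
    }
    message("[mitomodqtl] stage ", name, ": running")
    counts <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    note_stage(name, c(list(enabled = TRUE), counts))
  }

  run_stage("simulate", function() {
    state$genotypes <- list(); state$truth <- list()
    n_files <- 0L
    for (d in seq_len(sim$n_datasets)) {
      g <- simulate_genotypes(sim, dataset = d)
      tr <- simulate_methylation(g, sim, dataset = d)
      ddir <- file.path(config$out_dir, sprintf("d%d", d))
      dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
      write_genotypes_vcf(g, file.path(ddir, "genotypes.vcf"))
      write_haplotypes_tsv(g, file.path(ddir, "haplotypes.tsv"))
      for (t in seq_len(sim$n_tissues)) {
        tdir <- file.path(ddir, sprintf("t%d", t))
        tr <- simulate_pileups(tr, sim, dir = file.path(tdir, "pileups"),
                               tissue = t)
        tr$pileup_truth_by_tissue[[t]] <- tr$pileup_truth
        tr <- simulate_expression(tr, sim, tissue = t)
        write_expression_tsv(tr$expression[[t]],
                             file.path(tdir, "expression.tsv"))
        n_files <- n_files + length(tr$pileup_files) + 1L
      }
      tr <- simulate_qc_metrics(tr, sim)
      write_tsv_commented(tr$qc_metrics, file.path(ddir, "qc_metrics.tsv"),
                          config_header(config))
      tr <- simulate_gwas_catalogue(tr, g, sim)
      write_truth_json(tr, file.path(ddir, "truth.json"))
      state$genotypes[[d]] <- g
      state$truth[[d]] <- tr
    }
    write_tsv_commented(state$truth[[1]]$gwas_catalogue,
                        file.path(config$out_dir, "gwas_catalogue.tsv"),
                        config_header(config))
    list(n_datasets = sim$n_datasets, n_files = n_files)
  })

  run_stage("quantify", function() {
    state$meth <- list()
    n_cells <- 0L
    for (d in seq_len(sim$n_datasets)) {
      state$meth[[d]] <- list()
      for (t in seq_len(sim$n_tissues)) {
        pdir <- file.path(config$out_dir, sprintf("d%d", d), sprintf("t%d", t),
                          "pileups")
        files <- list.files(pdir, pattern = "\\.pileup$", full.names = TRUE)
        recs <- do.call(rbind, lapply(files, function(f) {
          parse_pileup_file(f, sample = sub("\\.pileup$", "", basename(f)),
                            min_phred = th$min_phred)
        }))
        mm <- build_methylation_matrix(recs, min_cov = th$min_cov,
                                       site_mean_threshold = th$site_mean_threshold,
                                       dataset = sprintf("d%d", d),
                                       tissue = sprintf("t%d", t))
        mm <- average_p9(mm)
        mm <- mask_outliers(mm, k = th$mask_sd)
        state$meth[[d]][[t]] <- mm
        out <- data.frame(sample = rownames(mm$values), mm$values,
                          check.names = FALSE)
        write_tsv_commented(out, file.path(config$out_dir, sprintf("d%d", d),
                                           sprintf("t%d", t), "methylation.tsv"),
                            config_header(config))
        st_df <- data.frame(sample = rownames(mm$state), mm$state,
                            check.names = FALSE)
        write_tsv_commented(st_df, file.path(config$out_dir, sprintf("d%d", d),
                                             sprintf("t%d", t),
                                             "methylation_states.tsv"),
                            config_header(config))
        n_cells <- n_cells + sum(mm$state == "value")
      }
    }
    list(n_value_cells = n_cells)
  })

  run_stage("qc", function() {
    state$kept <- list(); state$gqc <- list(); state$gpcs <- list()
    n_removed <- 0L
    for (d in seq_len(sim$n_datasets)) {
      fs <- filter_samples(state$truth[[d]]$qc_metrics)
      state$kept[[d]] <- fs$kept
      n_removed <- n_removed + nrow(fs$removed)
      g <- state$genotypes[[d]]
      keep_idx <- match(fs$kept, g$samples)
      g$samples <- g$samples[keep_idx]
      g$dosage <- g$dosage[keep_idx, , drop = FALSE]
      hap_idx <- as.vector(rbind(2L * keep_idx - 1L, 2L * keep_idx))
      g$haplotypes <- g$haplotypes[hap_idx, , drop = FALSE]
      g <- filter_snps(g, maf_min = th$maf_min, missing_max = th$missing_max,
                       hwe_p_min = th$hwe_p_min)
      state$gqc[[d]] <- g
      pcs <- genetic_pcs(g, k = th$n_genetic_pcs)
      state$gpcs[[d]] <- pcs
      write_tsv_commented(data.frame(sample = rownames(pcs), pcs),
                          file.path(config$out_dir, sprintf("d%d", d),
                                    "genetic_pcs.tsv"),
                          config_header(config))
      qc_log <- attr(g, "qc_log")
      write_tsv_commented(qc_log, file.path(config$out_dir, sprintf("d%d", d),
                                            "snp_qc_log.tsv"),
                          config_header(config))
    }
    list(n_samples_removed = n_removed,
         n_snps_kept = nrow(state$gqc[[1]]$snps))
  })

  run_stage("qtl", function() {
    state$scans <- list()
    n_tests <- 0L
    for (d in seq_len(sim$n_datasets)) {
      g <- state$gqc[[d]]
      state$scans[[d]] <- list()
      for (t in seq_len(sim$n_tissues)) {
        mm <- state$meth[[d]][[t]]
        tpm <- state$truth[[d]]$expression[[t]]$tpm[, g$samples, drop = FALSE]
        hf <- hidden_factors(tpm)
        covar <- cbind(state$gpcs[[d]], hf)
        res <- list()
        for (ph in colnames(mm$values)) {
          y <- mm$values[g$samples, ph]
          if (all(is.na(y))) next
          res[[ph]] <- qtl_scan(y, g, covariates = covar,
                                phenotype_name = ph)
        }
        scan <- do.call(rbind, res)
        rownames(scan) <- NULL
        state$scans[[d]][[t]] <- scan
        n_tests <- n_tests + nrow(scan)
        write_tsv_commented(scan, file.path(config$out_dir, sprintf("d%d", d),
                                            sprintf("t%d", t),
                                            "qtl_scan.tsv"),
                            config_header(config))
      }
    }
    list(n_tests = n_tests)
  })

  run_stage("meta", function() {
    thr <- significance_threshold(th$n_phenotypes, th$n_analyses,
                                  th$genomewide)
    state$meta <- list()
    for (t in seq_len(sim$n_tissues)) {
      per_ds <- lapply(seq_len(sim$n_datasets), function(d) state$scans[[d]][[t]])
      state$meta[[t]] <- fixed_effects_meta(per_ds)
      write_tsv_commented(state$meta[[t]],
                          file.path(config$out_dir,
                                    sprintf("meta_t%d.tsv", t)),
                          config_header(config))
    }
    disc <- state$meta[[1]]
    peaks <- do.call(rbind, lapply(split(disc, disc$phenotype),
                                   select_peaks, threshold = thr,
                                   window_bp = th$peak_window))
    rownames(peaks) <- NULL
    state$peaks <- peaks
    write_tsv_commented(peaks, file.path(config$out_dir, "peaks.tsv"),
                        config_header(config))
    # replication of discovery-tissue peaks in the other tissues
    if (sim$n_tissues > 1L && nrow(peaks)) {
      others <- stats::setNames(
        lapply(seq(2L, sim$n_tissues), function(t) state$meta[[t]]),
        sprintf("t%d", seq(2L, sim$n_tissues)))
      rep_tab <- replication_test(peaks, others)
      state$replication <- rep_tab
      write_tsv_commented(rep_tab, file.path(config$out_dir, "replication.tsv"),
                          config_header(config))
    }
    # additive two-locus tests for phenotypes with two same-sign peaks
    add_rows <- list()
    for (ph in unique(peaks$phenotype)) {
      pp <- peaks[peaks$phenotype == ph, , drop = FALSE]
      if (nrow(pp) < 2L) next
      pp <- pp[order(-abs(pp$beta)), , drop = FALSE]
      for (i in 1:(nrow(pp) - 1L)) for (j in (i + 1L):nrow(pp)) {
        if (sign(pp$beta[i]) != sign(pp$beta[j])) next
        g <- state$gqc[[1]]
        mafs <- colMeans(g$dosage[, c(pp$snp[i], pp$snp[j])]) / 2
        mafs <- pmin(mafs, 1 - mafs)
        hi <- if (mafs[1] >= mafs[2]) c(i, j) else c(j, i)
        y <- state$meth[[1]][[1]]$values[g$samples, ph]
        tt <- additive_two_locus_test(y, g$dosage[, pp$snp[hi[1]]],
                                      g$dosage[, pp$snp[hi[2]]])
        if (tt$status != "tested") next
        add_rows[[length(add_rows) + 1L]] <- data.frame(
          phenotype = ph, snp_a = pp$snp[hi[1]], snp_b = pp$snp[hi[2]],
          diff = tt$diff, t = tt$t, p = tt$p, stringsAsFactors = FALSE)
      }
    }
    if (length(add_rows)) {
      add_tab <- do.call(rbind, add_rows)
      add_tab$p_bonferroni <- pmin(1, add_tab$p * nrow(add_tab))
      state$additive <- add_tab
      write_tsv_commented(add_tab, file.path(config$out_dir, "additive.tsv"),
                          config_header(config))
    }
    list(threshold = thr, n_peaks = nrow(peaks))
  })

  run_stage("mediate", function() {
    peaks <- state$peaks
    g <- state$gqc[[1]]
    ex <- state$truth[[1]]$expression[[1]]
    tpm <- ex$tpm[, g$samples, drop = FALSE]
    hf <- hidden_factors(tpm)
    covar <- cbind(state$gpcs[[1]], hf)
    rows <- list()
    done <- character(0)
    for (i in seq_len(nrow(peaks))) {
      pk <- peaks[i, ]
      if (pk$snp %in% done) next
      done <- c(done, pk$snp)
      cand <- cis_gene_candidates(g$dosage[, pk$snp], pk$chr, pk$pos,
                                  tpm, ex$genes, covariates = covar,
                                  window = th$cis_window)
      kept <- cand[cand$kept, , drop = FALSE]
      for (k in seq_len(nrow(kept))) {
        y <- state$meth[[1]][[1]]$values[g$samples, pk$phenotype]
        med <- bootstrap_acme(g$dosage[, pk$snp], tpm[kept$gene[k], ], y,
                              covariates = covar, n_boot = th$n_boot,
                              seed = config$seed + 17L * i + k)
        rows[[length(rows) + 1L]] <- data.frame(
          snp = pk$snp, gene = kept$gene[k], phenotype = pk$phenotype,
          a = med$a, b = med$b, acme = med$acme, ci_low = med$ci[1],
          ci_high = med$ci[2], p_boot = med$p_boot,
          p_adjusted = min(1, med$p_boot * kept$n_cis_tested[k]),
          n = med$n, seed = med$seed, stringsAsFactors = FALSE)
      }
    }
    med_tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(snp = character(), gene = character())
    state$mediation <- med_tab
    write_tsv_commented(med_tab, file.path(config$out_dir, "mediation.tsv"),
                        config_header(config))
    list(n_mediations = nrow(med_tab))
  })

  run_stage("consequences", function() {
    g <- state$gqc[[1]]
    ex <- state$truth[[1]]$expression[[1]]
    tpm <- ex$tpm[, g$samples, drop = FALSE]
    hf <- hidden_factors(tpm)
    covar <- cbind(state$gpcs[[1]], hf)
    mm <- state$meth[[1]][[1]]
    reg <- upstream_expression_regression(mm$values[g$samples, , drop = FALSE],
                                          tpm, covariates = covar)
    state$consequences <- reg
    write_tsv_commented(reg, file.path(config$out_dir, "consequences.tsv"),
                        config_header(config))
    list(n_pairs_tested = sum(reg$status == "tested"))
  })

  run_stage("overlap", function() {
    peaks <- state$peaks
    catalogue <- state$truth[[1]]$gwas_catalogue
    ov <- gwas_overlap(peaks, catalogue, state$gqc[[1]],
                       dprime_min = th$dprime_min,
                       window = th$overlap_window,
                       gw_p = th$genomewide)
    state$overlap <- ov
    write_tsv_commented(ov, file.path(config$out_dir, "overlap.tsv"),
                        config_header(config))
    list(n_overlaps = nrow(ov))
  })

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", config$out_dir, "/?"), "", names(hashes))
  manifest$file_md5 <- as.list(hashes)
  manifest$thresholds <- th
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
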