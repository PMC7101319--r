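#' Parse samtools pileup text into per-site base counts
#'
#' Reads 6-column samtools pileup text (chromosome, 1-based position,
#' reference base, depth, base string, quality string with Phred+33
#' encoding) and returns quality-filtered base counts per line. The base
#' string escape grammar is handled in full: \code{.}/\code{,} count as the
#' reference base (strands combined), \code{ACGTacgt} as mismatches,
#' \code{^} plus the following mapping-quality character and \code{$} are
#' skipped, \code{+n}/\code{-n} indel runs are skipped entirely, and
#' \code{*}, \code{>}, \code{<} and \code{N} consume a quality character
#' but carry no base call, so they enter neither the numerator nor the
#' denominator of the mismatch proportion. Only bases with Phred quality at
#' or above \code{min_phred} are counted.
#'
#' @param path Path to a pileup text file.
#' @param sample Sample identifier attached to every record.
#' @param min_phred Minimum base quality (default 13).
#' @return A data.frame with columns \code{sample}, \code{chrom},
#'   \code{position}, \code{ref}, \code{A}, \code{C}, \code{G}, \code{T},
#'   \code{filtered_depth} (sum of the four counts) and \code{raw_depth}
#'   (base calls seen before quality filtering).
#' @export
parse_pileup_file <- function(path, sample = basename(path), min_phred = 13) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(sample = character(), chrom = character(),
                      position = integer(), ref = character(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), filtered_depth = integer(),
                      raw_depth = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stop("pileup parse error: line ", which(nf != 6L)[1L],
         " does not have 6 tab-separated columns")
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  counts <- parse_pileup_calls(m[, 5L], m[, 6L], m[, 3L], as.integer(min_phred))
  data.frame(sample = sample, chrom = m[, 1L],
             position = as.integer(m[, 2L]), ref = toupper(m[, 3L]),
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
             T = counts[, "T"], filtered_depth = counts[, "filtered_depth"],
             raw_depth = counts[, "raw_depth"], stringsAsFactors = FALSE)
}

#' Parse a single pileup line
#'
#' Convenience wrapper around the same parser as [parse_pileup_file()].
#'
#' @param line One pileup text line.
#' @param sample Sample identifier.
#' @param min_phred Minimum base quality.
#' @return A one-row data.frame as in [parse_pileup_file()].
#' @export
parse_pileup_line <- function(line, sample = "sample", min_phred = 13) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) == 1L) f <- strsplit(trimws(line), "[ \t]+")[[1L]]
  if (length(f) != 6L) stop("pileup parse error: line 1 does not have 6 columns")
  counts <- parse_pileup_calls(f[5L], f[6L], f[3L], as.integer(min_phred))
  data.frame(sample = sample, chrom = f[1L], position = as.integer(f[2L]),
             ref = toupper(f[3L]), A = counts[, "A"], C = counts[, "C"],
             G = counts[, "G"], T = counts[, "T"],
             filtered_depth = counts[, "filtered_depth"],
             raw_depth = counts[, "raw_depth"], stringsAsFactors = FALSE)
}

#' Mismatch proportion at a modified site
#'
#' The modification-level proxy: the proportion of quality-passing base
#' calls that differ from the reference base, computed only where the
#' quality-filtered coverage reaches \code{min_cov} (20x by default);
#' lower-coverage records give \code{NA}.
#'
#' @param rec One or more rows as returned by [parse_pileup_file()].
#' @param min_cov Minimum filtered coverage (default 20).
#' @return Numeric vector of mismatch proportions in \[0, 1\], \code{NA}
#'   where coverage is insufficient.
#' @export
site_mismatch_rate <- function(rec, min_cov = 20) {
  bases <- c("A", "C", "G", "T")
  if (any(!rec$ref %in% bases)) {
    stop("unknown reference base: ", paste(unique(setdiff(rec$ref, bases)), collapse = ","))
  }
  cnt <- as.matrix(rec[, bases])
  refn <- cnt[cbind(seq_len(nrow(rec)), match(rec$ref, bases))]
  depth <- rec$filtered_depth
  rate <- ifelse(depth >= min_cov, (depth - refn) / depth, NA_real_)
  as.numeric(rate)
}

#' Build the samples-by-phenotypes methylation matrix
#'
#' Assembles per-sample mismatch proportions at the annotated modified
#' sites into a matrix, applying the coverage rule per cell and the
#' site-evidence rule per column: a site is retained in a dataset-tissue
#' only if its mean mismatch proportion across samples with data exceeds
#' \code{site_mean_threshold} (1\%), since below that level modification is
#' indistinguishable from sequencing error. Excluded columns keep no
#' values. Each cell carries a state: \code{value},
#' \code{missing_low_coverage}, \code{masked_outlier} (after
#' [mask_outliers()]) or \code{site_excluded}.
#'
#' @param records Data.frame of parsed pileup records for one
#'   dataset-tissue (all samples).
#' @param sites Site annotation as from [mod_sites()].
#' @param min_cov Minimum filtered coverage per cell (default 20).
#' @param site_mean_threshold Minimum dataset mean mismatch proportion for
#'   a site to show evidence of methylation (default 0.01).
#' @param dataset,tissue Labels stored on the object.
#' @return An object of class \code{methylation_matrix}: a list with
#'   \code{values} (numeric matrix, samples x phenotypes), \code{state}
#'   (character matrix), \code{premask} (values before outlier masking),
#'   \code{excluded_sites} (named reasons) and labels.
#' @export
build_methylation_matrix <- function(records, sites = mod_sites(),
                                     min_cov = 20,
                                     site_mean_threshold = 0.01,
                                     dataset = "dataset1",
                                     tissue = "tissue1") {
  samples <- sort(unique(records$sample))
  site_cols <- paste0("p", sites$position)
  values <- matrix(NA_real_, length(samples), nrow(sites),
                   dimnames = list(samples, site_cols))
  state <- matrix("missing_low_coverage", length(samples), nrow(sites),
                  dimnames = list(samples, site_cols))
  rec_site <- match(records$position, sites$position)
  keep <- !is.na(rec_site)
  rec <- records[keep, , drop = FALSE]
  rec_site <- rec_site[keep]
  rate <- site_mismatch_rate(rec, min_cov = min_cov)
  ij <- cbind(match(rec$sample, samples), rec_site)
  values[ij] <- rate
  state[ij] <- ifelse(is.na(rate), "missing_low_coverage", "value")
  excluded <- character(0)
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    if (all(is.na(v))) {
      excluded[site_cols[j]] <- "no samples with data"
    } else if (mean(v, na.rm = TRUE) <= site_mean_threshold) {
      excluded[site_cols[j]] <- sprintf("dataset mean %.4g <= %.3g",
                                        mean(v, na.rm = TRUE),
                                        site_mean_threshold)
    }
  }
  if (length(excluded)) {
    jj <- match(names(excluded), site_cols)
    values[, jj] <- NA_real_
    state[, jj] <- "site_excluded"
  }
  structure(list(values = values, state = state, premask = values,
                 excluded_sites = excluded, sites = sites,
                 dataset = dataset, tissue = tissue),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "phenotypes (", x$dataset, "/", x$tissue, ")\n")
  cat("  values present:", sum(x$state == "value"),
      "| low coverage:", sum(x$state == "missing_low_coverage"),
      "| masked:", sum(x$state == "masked_outlier"),
      "| excluded columns:", length(x$excluded_sites), "\n")
  invisible(x)
}

#' Append the averaged P9 phenotype
#'
#' Per sample, the arithmetic mean of the available (non-missing,
#' non-masked) values among the 11 averaged mt-tRNA P9 sites; \code{NA}
#' when fewer than \code{min_sites} contribute.
#'
#' @param mat A \code{methylation_matrix}.
#' @param min_sites Minimum contributing sites (default 1).
#' @return The matrix with a \code{P9_avg} column appended.
#' @export
average_p9 <- function(mat, min_sites = 1) {
  cols <- paste0("p", mat$sites$position[mat$sites$in_p9_average])
  cols <- intersect(cols, colnames(mat$values))
  sub <- mat$values[, cols, drop = FALSE]
  n_avail <- rowSums(!is.na(sub))
  avg <- ifelse(n_avail >= min_sites, rowMeans(sub, na.rm = TRUE), NA_real_)
  mat$values <- cbind(mat$values, P9_avg = avg)
  mat$premask <- cbind(mat$premask, P9_avg = avg)
  mat$state <- cbind(mat$state,
                     P9_avg = ifelse(is.na(avg), "missing_low_coverage", "value"))
  mat
}

#' Mask outlying methylation values
#'
#' Single-pass outlier masking per phenotype column: the column mean and
#' standard deviation are computed once over the non-missing pre-mask
#' values, and cells more than \code{k} standard deviations from that mean
#' are masked so that association results are not driven by extreme
#' values. Masked cells retain their pre-mask value in \code{premask} for
#' audit. Columns with zero or undefined spread are left unchanged.
#'
#' @param mat A \code{methylation_matrix}.
#' @param k Number of standard deviations (default 3).
#' @return The matrix with outliers masked (state \code{masked_outlier}).
#' @export
mask_outliers <- function(mat, k = 3) {
  for (j in seq_len(ncol(mat$values))) {
    v <- mat$premask[, j]
    mu <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) next
    out <- !is.na(v) & abs(v - mu) > k * sdv
    mat$values[out, j] <- NA_real_
    mat$state[out, j] <- "masked_outlier"
  }
  mat
}

#' Pairwise correlations of P9 methylation levels within individuals
#'
#' Pearson correlation between each unordered pair of the 13 tRNA P9
#' phenotypes plus the averaged P9 measure (91 comparisons), computed over
#' pairwise-complete samples, with Bonferroni correction over the number of
#' pairs actually compared.
#'
#' @param mat A \code{methylation_matrix} (after [average_p9()]).
#' @param min_pairs Minimum complete pairs per comparison (default 3).
#' @return Data.frame with columns \code{site_a}, \code{site_b}, \code{n},
#'   \code{r}, \code{p}, \code{p_bonferroni}, \code{note}.
#' @export
pairwise_site_correlations <- function(mat, min_pairs = 3) {
  cols <- c(paste0("p", mat$sites$position[mat$sites$category == "tRNA_P9"]),
            "P9_avg")
  cols <- intersect(cols, colnames(mat$values))
  pairs <- utils::combn(cols, 2L)
  res <- data.frame(site_a = pairs[1L, ], site_b = pairs[2L, ],
                    n = NA_integer_, r = NA_real_, p = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- mat$values[, pairs[1L, i]]
    b <- mat$values[, pairs[2L, i]]
    ok <- !is.na(a) & !is.na(b)
    res$n[i] <- sum(ok)
    if (sum(ok) < min_pairs) {
      res$note[i] <- sprintf("skipped: %d complete pairs < %d", sum(ok), min_pairs)
      next
    }
    ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
    res$r[i] <- unname(ct$estimate)
    res$p[i] <- ct$p.value
  }
  n_tests <- sum(res$note == "")
  res$p_bonferroni <- pmin(1, res$p * n_tests)
  res
}

#' Cross-tissue correlations of methylation at the same position
#'
#' For each phenotype measured in two tissues of the same individuals,
#' Pearson correlation across shared samples, computed only where both
#' tissues show a mean inferred methylation level of at least
#' \code{min_mean} at the site and at least \code{min_pairs} shared data
#' points; Bonferroni correction over the comparisons made.
#'
#' @param mats Named list of \code{methylation_matrix} objects, one per
#'   tissue, with individual ids as rownames.
#' @param min_mean Minimum per-tissue mean level (default 0.01).
#' @param min_pairs Minimum shared data points (default 100).
#' @return Data.frame with \code{phenotype}, \code{tissue_a},
#'   \code{tissue_b}, \code{n}, \code{r}, \code{p}, \code{p_bonferroni}.
#' @export
cross_tissue_correlations <- function(mats, min_mean = 0.01, min_pairs = 100) {
  tissues <- names(mats)
  stopifnot(length(tissues) >= 2L)
  phen <- Reduce(intersect, lapply(mats, function(m) colnames(m$values)))
  out <- list()
  for (ph in phen) {
    for (i in seq_along(tissues)[-length(tissues)]) {
      for (j in seq((i + 1L), length(tissues))) {
        a <- mats[[i]]$values[, ph]
        b <- mats[[j]]$values[, ph]
        if (mean(a, na.rm = TRUE) < min_mean || all(is.na(a))) next
        if (mean(b, na.rm = TRUE) < min_mean || all(is.na(b))) next
        shared <- intersect(rownames(mats[[i]]$values)[!is.na(a)],
                            rownames(mats[[j]]$values)[!is.na(b)])
        if (length(shared) < min_pairs) next
        ct <- stats::cor.test(mats[[i]]$values[shared, ph],
                              mats[[j]]$values[shared, ph])
        out[[length(out) + 1L]] <- data.frame(
          phenotype = ph, tissue_a = tissues[i], tissue_b = tissues[j],
          n = length(shared), r = unname(ct$estimate), p = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(phenotype = character(), tissue_a = character(),
                      tissue_b = character(), n = integer(), r = numeric(),
                      p = numeric(), p_bonferroni = numeric()))
  }
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res
}
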