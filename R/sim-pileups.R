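#' Simulate samtools-pileup text from true modification levels
#'
#' For each sample and modified site, read depth is drawn from a negative
#' binomial, and each read mismatches the reference with probability
#' \eqn{m \cdot e_{mod} + (1 - m) e_{seq}}: a read covering a methylated
#' template misincorporates with efficiency \code{e_mod} (the
#' reverse-transcriptase signature), an unmethylated one with the
#' sequencing error rate \code{e_seq}. Mismatch bases are uniform over the
#' three non-reference bases. Base qualities are high-Phred (30-40) for
#' matches and misincorporation mismatches; sequencing-error bases draw
#' from a mixture including Phred < 13 so the quality filter is exercised.
#' The emitted text uses the full pileup escape grammar (strand symbols,
#' \code{^}/\code{$} markers, indel runs, placeholder calls), and the
#' exact quality-passing counts of every draw are recorded in the returned
#' truth so the parser can be checked for byte-exact recovery.
#'
#' @param truth A \code{truth_set} from [simulate_methylation()].
#' @param config The same [sim_config()].
#' @param dir Directory to write one \code{<sample>.pileup} file per
#'   sample (created if needed); \code{NULL} skips writing and only
#'   returns the lines.
#' @param tissue Tissue index of \code{truth$levels} to emit (default 1).
#' @return The \code{truth_set} with \code{$pileup_truth} (a data.frame
#'   per sample-site: depths, post-filter base counts, emitted line) and
#'   \code{$pileup_files} attached.
#' @export
simulate_pileups <- function(truth, config, dir = NULL, tissue = 1L) {
  sites <- mod_sites()
  site_cols <- colnames(truth$levels)
  pos <- as.integer(sub("^p", "", site_cols))
  missing_site <- setdiff(pos, sites$position)
  if (length(missing_site))
    stop("site(s) absent from reference annotation: ",
         paste(missing_site, collapse = ", "))
  ref <- sites$ref[match(pos, sites$position)]
  samples <- dimnames(truth$levels)[[1]]
  set.seed(config$seed + 5000L + 1000L * as.integer(truth$dataset) +
             37L * as.integer(tissue))

  bases <- c("A", "C", "G", "T")
  hi_q <- 30:40
  lo_q <- 2:12
  n_lines <- length(samples) * length(site_cols)
  rec <- data.frame(sample = rep(samples, each = length(site_cols)),
                    position = rep(pos, length(samples)),
                    ref = rep(ref, length(samples)),
                    true_level = NA_real_, depth_total = NA_integer_,
                    raw_bases = NA_integer_, A = NA_integer_,
                    C = NA_integer_, G = NA_integer_, T = NA_integer_,
                    stringsAsFactors = FALSE)
  lines <- character(n_lines)
  for (k in seq_len(n_lines)) {
    s <- rec$sample[k]; j <- match(rec$position[k], pos)
    m <- truth$levels[s, j, tissue]
    rb <- ref[j]
    d_total <- max(1L, as.integer(stats::rnbinom(1L, size = config$coverage_size,
                                                 mu = config$coverage_mean)))
    n_ph <- stats::rbinom(1L, d_total, 0.01)     # placeholder calls (* > < N)
    d_eff <- d_total - n_ph
    n_mod <- stats::rbinom(1L, d_eff, m)
    n_mm_mod <- stats::rbinom(1L, n_mod, config$e_mod)
    n_err <- stats::rbinom(1L, d_eff - n_mod, config$e_seq)
    n_match <- d_eff - n_mm_mod - n_err

    alt <- setdiff(bases, rb)
    call <- c(rep(rb, n_match),
              sample(alt, n_mm_mod, replace = TRUE),
              sample(alt, n_err, replace = TRUE))
    phred <- c(sample(hi_q, n_match, replace = TRUE),
               sample(hi_q, n_mm_mod, replace = TRUE),
               ifelse(stats::runif(n_err) < config$seq_error_low_qual_frac,
                      sample(lo_q, max(n_err, 1L), replace = TRUE)[seq_len(n_err)],
                      sample(hi_q, max(n_err, 1L), replace = TRUE)[seq_len(n_err)]))
    # truth: quality-passing counts per base, before any text encoding
    pass <- phred >= 13L
    cnt <- vapply(bases, function(b) sum(call == b & pass), integer(1L))
    rec$true_level[k] <- m
    rec$depth_total[k] <- d_total
    rec$raw_bases[k] <- d_eff
    rec[k, bases] <- as.list(cnt)

    # encode: strand, escapes, placeholders
    rev_strand <- stats::runif(d_eff) < 0.5
    sym <- ifelse(call == rb, ifelse(rev_strand, ",", "."),
                  ifelse(rev_strand, tolower(call), call))
    if (n_ph > 0L) {
      sym <- c(sym, sample(c("*", "N", ">", "<"), n_ph, replace = TRUE))
      phred <- c(phred, sample(hi_q, n_ph, replace = TRUE))
    }
    ord <- sample.int(d_total)
    sym <- sym[ord]; phred_o <- phred[ord]
    pre <- ifelse(stats::runif(d_total) < 0.05,
                  paste0("^", intToUtf8(sample(33:90, d_total, replace = TRUE),
                                        multiple = TRUE)), "")
    post <- ifelse(stats::runif(d_total) < 0.05, "$", "")
    has_indel <- stats::runif(d_total) < 0.02
    indel <- rep("", d_total)
    if (any(has_indel)) {
      n_i <- sum(has_indel)
      ilen <- sample(1:3, n_i, replace = TRUE)
      iseq <- vapply(ilen, function(L) paste(sample(c(bases, tolower(bases)),
                                                    L, replace = TRUE),
                                             collapse = ""), character(1L))
      indel[has_indel] <- paste0(sample(c("+", "-"), n_i, replace = TRUE),
                                 ilen, iseq)
    }
    base_str <- paste0(pre, sym, post, indel, collapse = "")
    qual_str <- intToUtf8(phred_o + 33L)
    lines[k] <- paste("MT", rec$position[k], rb, d_total, base_str, qual_str,
                      sep = "\t")
  }
  rec$line <- lines
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(samples, function(s) {
      path <- file.path(dir, paste0(s, ".pileup"))
      writeLines(rec$line[rec$sample == s], path)
      path
    }, character(1L))
  }
  truth$pileup_truth <- rec
  truth$pileup_files <- files
  truth$pileup_tissue <- tissue
  truth
}
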