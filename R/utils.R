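# shared helpers

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Rank-based inverse-normal transform
#'
#' Maps a numeric vector to normal quantiles of (rank - 0.5)/n, the
#' quantile normalisation applied to expression phenotypes before eQTL and
#' consequence regressions. Missing values stay missing; ties get average
#' ranks.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
rank_inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n > 0L) out[ok] <- stats::qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  out
}

# Write a TSV with '# key: value' provenance header lines.
write_tsv_commented <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# OLS via QR on complete cases; returns coef table for one named predictor.
# X: design matrix WITHOUT intercept column; an intercept is always added.
ols_term <- function(y, x, covariates = NULL, term_name = "x") {
  X <- cbind(`(Intercept)` = 1, x = x)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  keep <- stats::complete.cases(cbind(y, X))
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n <= p) return(NULL)
  qrX <- qr(X)
  if (qrX$rank < p) return(NULL)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  list(beta = unname(beta[2L]), se = unname(se[2L]), t = unname(tval[2L]),
       p = unname(pval[2L]), n = n, df = n - p, n_covar = p - 2L,
       coef = beta, residuals = as.numeric(res))
}
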