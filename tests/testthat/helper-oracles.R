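# Independent oracles used across tests. These deliberately use different
# numerical routes than the package implementations.

# HWE exact P by direct enumeration with log-factorials (the package uses
# the recurrence over heterozygote counts instead).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2L * n_aa + n_Aa
  n_A <- 2L * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0L) return(1.0)
  hets <- seq(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    naa <- (rare - h) / 2
    nAA <- n - h - naa
    lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1L))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# brute-force OLS through the normal equations
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(s2 * diag(XtXi))
  tv <- beta / se
  list(beta = unname(beta[2]), se = unname(se[2]), t = unname(tv[2]),
       p = unname(2 * pt(abs(tv[2]), df = length(y) - ncol(X),
                         lower.tail = FALSE)))
}

# a sim_config with no planted genetic effects
no_effect_config <- function(...) {
  sim_config(
    causal_effects = data.frame(snp = character(), chr = character(),
                                pos = integer(), maf = numeric(),
                                phenotype = character(), beta = numeric(),
                                stringsAsFactors = FALSE),
    mediation_specs = data.frame(snp = character(), chr = character(),
                                 pos = integer(), maf = numeric(),
                                 gene = character(), gene_pos = integer(),
                                 phenotype = character(), a = numeric(),
                                 b = numeric(), direct = numeric(),
                                 stringsAsFactors = FALSE),
    ...)
}

p9_columns <- function() {
  s <- mod_sites()
  paste0("p", s$position[s$category == "tRNA_P9"])
}
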