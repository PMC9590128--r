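# Small in-code fixtures shared across test files.

tiny_geno <- function(n = 12, m = 5, seed = 101, missing_rate = 0,
                      maf = NULL) {
  simulate_genotypes(sim_spec(n = n, m = m, genes = max(1, m %/% 2),
                              missing_rate = missing_rate, maf = maf,
                              seed = seed))
}

tiny_cohort <- function(n = 60, m = 10, seed = 202, ...) {
  spec <- sim_spec(n = n, m = m, genes = max(1, m %/% 5), seed = seed, ...)
  geno <- simulate_genotypes(spec)
  pheno <- simulate_phenotypes(geno, spec)
  merge_pheno_geno(pheno, geno)
}

# Independent longhand Cochran-Armitage statistic (textbook form with the
# variance accounting for fixed genotype-column totals).
trend_stat_oracle <- function(cases, controls, scores = 0:2) {
  n_i <- cases + controls
  N <- sum(n_i); R <- sum(cases)
  num <- sum(scores * (cases - n_i * R / N))
  p <- R / N
  var <- p * (1 - p) * (sum(scores^2 * n_i) - sum(scores * n_i)^2 / N)
  num^2 / var
}

# Brute-force two-sided Fisher p by enumerating all tables with the
# observed margins (point-probability rule).
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(a)
    stats::dhyper(a, r1, r2, c1), 0)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Hand-rolled OLS via the normal equations.
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  bt <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bt
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  tt <- bt / se
  list(beta = as.vector(bt), se = se, t = as.vector(tt),
       p = 2 * stats::pt(-abs(as.vector(tt)), df = length(y) - ncol(X)))
}
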