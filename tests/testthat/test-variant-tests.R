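test_that("genetic-model encoding is elementwise with missing passthrough", {
  expect_equal(encode_model(c(0L, 1L, 2L), "dom"), c(0L, 1L, 1L))
  expect_equal(encode_model(c(0L, 1L, 2L), "rec"), c(0L, 0L, 1L))
  expect_equal(encode_model(c(2L, NA, 0L), "add"), c(2L, NA, 0L))
  expect_equal(encode_model(c(2L, NA, 0L), "rec"), c(1L, NA, 0L))
})

test_that("Fisher exact p equals full-table enumeration", {
  # the [[5,0],[0,5]] table: 2/252 under the point-probability rule
  tab <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(stats::fisher.test(tab)$p.value, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_enum_oracle(tab), 2 / 252, tolerance = 1e-12)
  # random small tables vs the enumeration oracle
  set.seed(14)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_enum_oracle(tab),
                 tolerance = 1e-9)
  }
  # symmetry: identical allele counts in cases and controls -> p = 1
  expect_equal(stats::fisher.test(matrix(c(6, 4, 6, 4), 2))$p.value, 1)
})

test_that("fisher/chisq records report allelic tables and sample OR", {
  set.seed(21)
  ad <- tiny_cohort(n = 50, m = 6, missing_rate = 0.1)
  fa <- functional_analysis(ad, method = "fisher", outcome = "y",
                            threshold = 1)
  expect_true(all(fa$assoc$NMISS <= 50))
  expect_true(all(fa$assoc$P > 0 & fa$assoc$P <= 1, na.rm = TRUE))
  expect_true(all(fa$assoc$OR > 0, na.rm = TRUE))
  ch <- functional_analysis(ad, method = "chisq", outcome = "y",
                            threshold = 1)
  # chi-square equals the longhand sum((O-E)^2/E) on a checked variant
  j <- which(!is.na(ch$assoc$P))[1]
  g <- ad$geno$dosage[, j]; y <- ad$pheno$y
  ok <- !is.na(g)
  a1c <- sum(g[ok & y == 1]); a1u <- sum(g[ok & y == 0])
  tab <- matrix(c(a1c, 2 * sum(ok & y == 1) - a1c,
                  a1u, 2 * sum(ok & y == 0) - a1u), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(ch$assoc$STAT[j], sum((tab - E)^2 / E), tolerance = 1e-10)
})

test_that("balanced and diagonal 2x2 tables give the closed-form chi-square", {
  tab <- matrix(c(10, 10, 10, 10), 2)
  ct <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(unname(ct$statistic), 0)
  expect_equal(ct$p.value, 1)
  tab <- matrix(c(20, 0, 0, 20), 2)
  expect_equal(unname(stats::chisq.test(tab, correct = FALSE)$statistic),
               40)
})

test_that("Cochran-Armitage trend matches an independent scores oracle", {
  cases <- c(1, 2, 7); controls <- c(7, 2, 1)
  tt <- suppressWarnings(
    stats::prop.trend.test(cases, cases + controls, score = 0:2))
  expect_equal(unname(tt$statistic),
               trend_stat_oracle(cases, controls), tolerance = 1e-10)
  # symmetry under case/control swap
  tt2 <- suppressWarnings(
    stats::prop.trend.test(controls, cases + controls, score = 0:2))
  expect_equal(tt$p.value, tt2$p.value, tolerance = 1e-12)
  # through the scan interface, including monomorphic skip
  set.seed(33)
  ad <- tiny_cohort(n = 80, m = 5)
  fa <- functional_analysis(ad, method = "trend", outcome = "y",
                            threshold = 1)
  for (j in which(!is.na(fa$assoc$P))) {
    g <- ad$geno$dosage[, j]; y <- ad$pheno$y
    ok <- !is.na(g)
    cs <- vapply(0:2, function(k) sum(y[ok][g[ok] == k]), 0)
    ct <- vapply(0:2, function(k) sum(g[ok] == k) - cs[k + 1], 0)
    expect_equal(fa$assoc$STAT[j], trend_stat_oracle(cs, ct),
                 tolerance = 1e-8)
  }
})

test_that("logistic scan: stat/p consistency, skips, and covariates", {
  set.seed(44)
  ad <- tiny_cohort(n = 120, m = 8, missing_rate = 0.05)
  fa <- functional_analysis(ad, method = "glm", outcome = "y",
                            covariates = c("sex", "age"), threshold = 1)
  ok <- !is.na(fa$assoc$P)
  expect_true(any(ok))
  expect_equal(fa$assoc$P[ok], 2 * pnorm(-abs(fa$assoc$STAT[ok])),
               tolerance = 1e-12)
  expect_true(all(fa$assoc$NMISS[ok] <= 120))
  # constant genotype is skipped, not tested
  ad2 <- ad
  ad2$geno$dosage[, 1] <- 1L
  fa2 <- functional_analysis(ad2, method = "glm", outcome = "y",
                             threshold = 1)
  expect_true(is.na(fa2$assoc$P[1]))
  expect_match(fa2$assoc$SKIP[1], "variance")
})

test_that("linear scan matches a hand-rolled normal-equations OLS", {
  set.seed(55)
  ad <- tiny_cohort(n = 10, m = 3, outcome = "continuous",
                    missing_rate = 0, maf = rep(0.4, 3))
  fa <- functional_analysis(ad, method = "lm", outcome = "y",
                            threshold = 1)
  polym <- which(apply(ad$geno$dosage, 2, function(x)
    length(unique(x)) > 1))
  expect_gte(length(polym), 2)
  for (j in polym) {
    o <- ols_oracle(ad$pheno$y, ad$geno$dosage[, j])
    expect_equal(fa$assoc$BETA[j], o$beta[2], tolerance = 1e-10)
    expect_equal(fa$assoc$STAT[j], o$t[2], tolerance = 1e-10)
    expect_equal(fa$assoc$P[j], o$p[2], tolerance = 1e-10)
  }
  # affine invariance: shifting the outcome leaves beta and p unchanged
  ad3 <- ad
  ad3$pheno$y <- ad$pheno$y + 100
  fa3 <- functional_analysis(ad3, method = "lm", outcome = "y",
                             threshold = 1)
  expect_equal(fa3$assoc$BETA, fa$assoc$BETA, tolerance = 1e-9)
  expect_equal(fa3$assoc$P, fa$assoc$P, tolerance = 1e-9)
  # outcome = 2 * dosage recovers beta 2 at the numerical floor
  j1 <- polym[1]
  ad4 <- ad
  ad4$pheno$y <- 2 * ad$geno$dosage[, j1]
  fa4 <- suppressWarnings(    # "essentially perfect fit" by design
    functional_analysis(ad4, method = "lm", outcome = "y",
                        threshold = 1))
  expect_equal(fa4$assoc$BETA[j1], 2, tolerance = 1e-8)
  expect_lt(fa4$assoc$P[j1], 1e-12)
})

test_that("survival scans: log-rank, Cox HR recovery, and no-event skip", {
  set.seed(66)
  ad <- tiny_cohort(n = 150, m = 4, outcome = "survival",
                    missing_rate = 0)
  fa <- functional_analysis(ad, method = "survfit", model = "dom",
                            outcome = c("time", "event"), threshold = 1)
  expect_true(all(fa$assoc$P > 0 & fa$assoc$P <= 1, na.rm = TRUE))
  fc <- functional_analysis(ad, method = "coxph", outcome =
                              c("time", "event"), threshold = 1)
  okc <- !is.na(fc$assoc$P)
  expect_equal(fc$assoc$P[okc], 2 * pnorm(-abs(fc$assoc$STAT[okc])),
               tolerance = 1e-12)
  expect_true(all(fc$assoc$HR[okc] > 0))
  # null HR estimates center on 1 across replicates
  hrs <- replicate(60, {
    adn <- tiny_cohort(n = 150, m = 1, outcome = "survival",
                       missing_rate = 0, seed = sample.int(1e6, 1))
    f <- functional_analysis(adn, method = "coxph",
                             outcome = c("time", "event"), threshold = 1)
    f$assoc$HR[1]
  })
  expect_equal(mean(log(hrs), na.rm = TRUE), 0, tolerance = 0.12)
  # all-censored data -> skip with reason
  ad$pheno$event <- 0L
  fe <- functional_analysis(ad, method = "coxph",
                            outcome = c("time", "event"), threshold = 1)
  expect_true(all(is.na(fe$assoc$P)))
  expect_match(fe$assoc$SKIP[1], "no events")
})

test_that("p-values are invariant under sample reordering", {
  set.seed(77)
  ad <- tiny_cohort(n = 70, m = 5)
  perm <- sample(70)
  ad2 <- ad
  ad2$pheno <- ad$pheno[perm, , drop = FALSE]
  ad2$geno$dosage <- ad$geno$dosage[perm, , drop = FALSE]
  ad2$geno$samples <- ad$geno$samples[perm]
  for (mth in c("fisher", "chisq", "trend", "glm")) {
    p1 <- functional_analysis(ad, method = mth, outcome = "y",
                              threshold = 1)$assoc$P
    p2 <- functional_analysis(ad2, method = mth, outcome = "y",
                              threshold = 1)$assoc$P
    expect_equal(p1, p2, tolerance = 1e-10)
  }
})

test_that("threshold filtering is a strict p < threshold subset", {
  set.seed(88)
  ad <- tiny_cohort(n = 60, m = 10)
  fa1 <- functional_analysis(ad, method = "glm", outcome = "y",
                             threshold = 1)
  expect_equal(nrow(fa1$filtered), sum(!is.na(fa1$assoc$P)))
  fa0 <- functional_analysis(ad, method = "glm", outcome = "y",
                             threshold = 0)
  expect_equal(nrow(fa0$filtered), 0)
  expect_named(fa1$assoc,
               c("CHR", "SNP", "BP", "A1", "TEST", "NMISS", "OR",
                 "STAT", "P", "SKIP"))
})

test_that("genomic lambda: definition, calibration and scale equivariance", {
  expect_equal(genomic_lambda(rep(0.5, 7)), 1, tolerance = 1e-12)
  set.seed(99)
  p <- runif(10000)
  lam <- genomic_lambda(p)
  expect_gt(lam, 0.95); expect_lt(lam, 1.05)
  # doubling every chi-square doubles lambda
  chisq <- qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chisq, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2), 2 * lam, tolerance = 1e-9)
  expect_error(genomic_lambda(numeric(0)), "no p-values")
})
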