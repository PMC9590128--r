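test_that("null model gives closed-form fits and orthogonal residuals", {
  y <- c(rep(1, 40), rep(0, 42))
  null <- fit_null_model(y, out_type = "D")
  expect_equal(null$mu, rep(40 / 82, 82), tolerance = 1e-8)
  set.seed(1)
  yc <- rnorm(50)
  nc <- fit_null_model(yc, out_type = "C")
  expect_equal(nc$mu, rep(mean(yc), 50))
  expect_equal(nc$sigma2, var(yc), tolerance = 1e-12)
  # residual orthogonality to covariates under the model weighting
  Z <- data.frame(a = rnorm(200), b = rbinom(200, 1, 0.4))
  yb <- rbinom(200, 1, plogis(0.3 * Z$a))
  nb <- fit_null_model(yb, Z, out_type = "D")
  expect_lt(max(abs(crossprod(nb$X, nb$residuals))), 1e-6)
  ycc <- rnorm(200) + Z$a
  ncc <- fit_null_model(ycc, Z, out_type = "C")
  expect_lt(max(abs(crossprod(ncc$X, ncc$residuals))), 1e-6)
})

test_that("gene QC imputes to 2*MAF and drops monomorphic variants", {
  G <- cbind(c(0, 1, 2, NA, 1), rep(0, 5), c(2, 2, 2, 2, 2),
             c(0, 0, 1, 0, NA))
  u <- gene_qc(G)
  expect_equal(u$markers_all, 4)
  expect_equal(u$markers_tested, 2)   # two monomorphic columns dropped
  expect_equal(u$G[4, 1], mean(c(0, 1, 2, 1)))  # imputed = 2 * MAF
  expect_equal(u$G[5, 2], 1 / 4)
  u2 <- gene_qc(matrix(c(0, 1, 2, 1), 4))
  expect_equal(u2$markers_tested, u2$markers_all)
})

test_that("Q statistic: rank-1 closed form and kernel/score identity", {
  set.seed(2)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  null <- fit_null_model(y, out_type = "D")
  g <- rbinom(n, 2, 0.2)
  u <- gene_qc(matrix(g, n), weights = 0.7)
  expect_equal(skat_statistic(u, null),
               0.7^2 * sum(g * null$residuals)^2, tolerance = 1e-10)
  # zero residuals -> Q = 0
  null0 <- null; null0$residuals <- rep(0, n)
  expect_equal(skat_statistic(u, null0), 0)
  # kernel (n x n) route equals the score (m-vector) route
  G <- matrix(rbinom(n * 6, 2, 0.25), n)
  w <- runif(6, 0.2, 2)
  uu <- gene_qc(G, w)
  K <- uu$G %*% diag(uu$weights^2) %*% t(uu$G)
  r <- null$residuals
  expect_equal(skat_statistic(uu, null),
               as.numeric(t(r) %*% K %*% r), tolerance = 1e-8)
})

test_that("mixture eigenvalues: scalar case, trace identity, moment check", {
  set.seed(3)
  n <- 150
  y <- rbinom(n, 1, 0.4)
  null <- fit_null_model(y, out_type = "D")
  g <- rbinom(n, 2, 0.3)
  u <- gene_qc(matrix(g, n), weights = 1.3)
  lam <- mixture_lambdas(u, null)
  v <- null$v; X <- null$X
  P0g <- v * g - v * X %*% solve(crossprod(X, v * X), crossprod(v * X, g))
  expect_equal(lam, 1.3^2 * sum(g * P0g), tolerance = 1e-8)
  # trace identity for a multi-variant unit
  G <- matrix(rbinom(n * 8, 2, 0.2), n)
  uu <- gene_qc(G, runif(8, 0.5, 1.5))
  lams <- mixture_lambdas(uu, null)
  GW <- sweep(uu$G, 2, uu$weights, `*`)
  P0GW <- v * GW - v * X %*% solve(crossprod(X, v * X),
                                   crossprod(v * X, GW))
  expect_equal(sum(lams), sum(diag(crossprod(GW, P0GW))),
               tolerance = 1e-8)
  # E[Q] ~ sum(lambda) under the null outcome distribution
  mu <- null$mu
  Qs <- replicate(2000, {
    yy <- rbinom(n, 1, mu)
    nn <- fit_null_model(yy, out_type = "D")
    skat_statistic(uu, nn)
  })
  expect_equal(mean(Qs), sum(lams), tolerance = 0.1 * sum(lams))
})

test_that("quadform tail reduces to chi-square for degenerate mixtures", {
  expect_equal(as.numeric(quadform_tail(1, qchisq(0.95, 1))), 0.05,
               tolerance = 1e-9)
  expect_equal(as.numeric(quadform_tail(c(1, 1, 1), qchisq(0.95, 3))),
               0.05, tolerance = 1e-9)
  expect_equal(as.numeric(quadform_tail(rep(2.5, 4),
                                        2.5 * qchisq(0.99, 4))), 0.01,
               tolerance = 1e-9)
  expect_equal(as.numeric(quadform_tail(c(1, 2), 0)), 1)
  expect_error(quadform_tail(c(0, 0), 3), "zero")
})

test_that("davies engine agrees with Monte-Carlo and Ruben oracles", {
  set.seed(4)
  nbad_mc <- 0
  for (i in 1:40) {
    m <- sample(2:20, 1)
    lam <- rexp(m)^2          # adversarial spread
    q <- sum(lam) * runif(1, 0.2, 4)
    pd <- quadform_tail(lam, q, "davies")
    pm <- quadform_tail(lam, q, "montecarlo", B = 1e5)
    se <- sqrt(max(pm * (1 - pm), 1e-7) / 1e5)
    if (abs(pd - pm) > 3 * se) nbad_mc <- nbad_mc + 1
    pl <- quadform_tail(lam, q, "liu")
    expect_lt(abs(pd - pl), 0.05)  # Liu's true mid-p accuracy band
  }
  expect_lte(nbad_mc, 2)
  # deep tail against the exact mixture-series representation
  set.seed(5)
  for (i in 1:10) {
    lam <- runif(sample(3:10, 1), 0.3, 2)
    q <- sum(lam) * runif(1, 3, 7)
    pd <- quadform_tail(lam, q, "davies")
    pr <- skatpipe:::ruben_tail(lam, q)
    expect_equal(as.numeric(pd), pr, tolerance = 1e-3)
  }
})

test_that("weight scaling and continuous-outcome affine maps leave p fixed", {
  set.seed(6)
  n <- 200
  Z <- data.frame(a = rnorm(n))
  G <- matrix(rbinom(n * 7, 2, runif(7, 0.02, 0.3)), n, byrow = FALSE)
  w <- beta_weight(pmin(colMeans(G) / 2, 0.5))
  y <- rbinom(n, 1, 0.5)
  null <- fit_null_model(y, Z, out_type = "D")
  u1 <- gene_qc(G, w); u2 <- gene_qc(G, 7.3 * w)
  p1 <- quadform_tail(mixture_lambdas(u1, null), skat_statistic(u1, null))
  p2 <- quadform_tail(mixture_lambdas(u2, null), skat_statistic(u2, null))
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-10)
  # continuous outcome: y -> a*y + b leaves p unchanged
  yc <- rnorm(n)
  nc1 <- fit_null_model(yc, Z, out_type = "C")
  nc2 <- fit_null_model(3.1 * yc - 40, Z, out_type = "C")
  pc1 <- quadform_tail(mixture_lambdas(u1, nc1),
                       skat_statistic(u1, nc1))
  pc2 <- quadform_tail(mixture_lambdas(u1, nc2),
                       skat_statistic(u1, nc2))
  expect_equal(as.numeric(pc1), as.numeric(pc2), tolerance = 1e-9)
})

test_that("permutation oracle agrees with the analytic tail", {
  set.seed(7)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  null <- fit_null_model(y, out_type = "D")
  nbad <- 0
  for (i in 1:8) {
    G <- matrix(rbinom(n * 5, 2, runif(5, 0.05, 0.4)), n)
    u <- gene_qc(G, beta_weight(pmin(colMeans(G) / 2, 0.5)))
    pa <- quadform_tail(mixture_lambdas(u, null),
                        skat_statistic(u, null))
    pp <- permutation_pvalue(u, null, B = 999)
    se <- sqrt(pa * (1 - pa) / 999)
    if (abs(pa - pp) > 3 * se + 1 / 1000) nbad <- nbad + 1
  }
  expect_lte(nbad, 1)
  expect_error(permutation_pvalue(u, fit_null_model(y, data.frame(
    z = rnorm(n)), out_type = "D")), "intercept-only")
  # bounds
  expect_gte(permutation_pvalue(u, null, B = 99), 1 / 100)
})

test_that("skat_assoc produces the canonical per-gene table", {
  set.seed(8)
  ad <- tiny_cohort(n = 150, m = 30, missing_rate = 0.05)
  setid <- data.frame(
    set_id = rep(paste0("GENE", 1:6), each = 5),
    variant_id = ad$geno$variants$rsid, stringsAsFactors = FALSE)
  res <- skat_assoc(ad, setid, outcome = "y", out_type = "D",
                    covariates = c("sex", "age"))
  expect_equal(names(res)[1:4],
               c("SetID", "P.value", "N.Marker.All", "N.Marker.Test"))
  expect_equal(nrow(res), 6)
  expect_true(all(res$N.Marker.Test <= res$N.Marker.All))
  expect_true(!is.unsorted(res$P.value, na.rm = TRUE))
  expect_true(all(res$P.value > 0 & res$P.value <= 1, na.rm = TRUE))
  # CSV schema
  td <- withr::local_tempdir()
  f <- file.path(td, "skat.csv")
  write_skat(res, f)
  expect_equal(names(utils::read.csv(f)),
               c("SetID", "P.value", "N.Marker.All", "N.Marker.Test"))
  # unknown set member logged, not fatal
  setid2 <- rbind(setid, data.frame(set_id = "GENE1",
                                    variant_id = "rsNOPE"))
  expect_message(res2 <- skat_assoc(ad, setid2, outcome = "y",
                                    out_type = "D"), "not in the genotype")
  expect_equal(res2$N.Marker.All[res2$SetID == "GENE1"], 5)
})

test_that("single-variant sets approximate the single-variant score test", {
  set.seed(9)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  null <- fit_null_model(y, out_type = "D")
  for (i in 1:5) {
    g <- rbinom(n, 2, runif(1, 0.1, 0.4))
    u <- gene_qc(matrix(g, n), weights = 1)
    p_skat <- quadform_tail(mixture_lambdas(u, null),
                            skat_statistic(u, null))
    U <- sum(g * null$residuals)
    X <- null$X; v <- null$v
    gp <- g - X %*% solve(crossprod(X, v * X), crossprod(v * X, g))
    p_score <- pchisq(U^2 / sum(v * g * gp), 1, lower.tail = FALSE)
    expect_gt(p_skat / p_score, 0.8)
    expect_lt(p_skat / p_score, 1.25)
  }
})
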