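#' Fit the null model for the kernel association test
#'
#' Regresses the outcome on covariates only (intercept always included):
#' logistic IRLS for a dichotomous outcome, ordinary least squares for a
#' continuous one. The fitted means, residuals and variance structure feed
#' the score statistic and its reference distribution.
#'
#' @param outcome numeric vector; 0/1 for `out_type = "D"`.
#' @param covariates optional data.frame / matrix of covariates (no
#'   intercept column).
#' @param out_type `"D"` dichotomous or `"C"` continuous.
#' @return object of class `skat_null_model` with elements `mu`,
#'   `residuals`, `X` (design incl. intercept), `v` (per-sample variance,
#'   dichotomous), `sigma2` (continuous), `out_type`, `n`.
#' @export
fit_null_model <- function(outcome, covariates = NULL,
                           out_type = c("D", "C")) {
  out_type <- match.arg(out_type)
  y <- as.numeric(outcome)
  ok <- !is.na(y) & (if (is.null(covariates)) TRUE
                     else stats::complete.cases(covariates))
  if (!all(ok)) stop("missing values in outcome/covariates; subset first")
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, stats::model.matrix(~ ., data =
                    as.data.frame(covariates))[, -1, drop = FALSE])
  colnames(X)[1] <- "(Intercept)"
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank-deficient")
  if (out_type == "D") {
    if (!all(y %in% c(0, 1))) stop("out_type 'D' needs a 0/1 outcome")
    if (length(unique(y)) < 2) stop("outcome is constant")
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = list(epsilon = 1e-10, maxit = 50)))
    if (!fit$converged) stop("logistic null model did not converge")
    mu <- fit$fitted.values
    if (any(mu < 1e-10 | mu > 1 - 1e-10))
      stop("fitted probabilities at 0/1: separation in the null model")
    obj <- list(mu = mu, residuals = y - mu, X = X, v = mu * (1 - mu),
                sigma2 = NULL, out_type = "D", n = n)
  } else {
    fit <- stats::lm.fit(X, y)
    mu <- fit$fitted.values
    r <- y - mu
    obj <- list(mu = mu, residuals = r, X = X, v = NULL,
                sigma2 = sum(r^2) / (n - ncol(X)),
                out_type = "C", n = n)
  }
  structure(obj, class = "skat_null_model")
}

#' Quality control of a gene's genotype submatrix
#'
#' Mean-imputes missing dosages to twice the in-sample MAF and drops
#' variants that are monomorphic after imputation. `markers_all` counts
#' the input variants, `markers_tested` the survivors.
#'
#' @param G samples x variants dosage matrix, entries `{0, 1, 2, NA}`.
#' @param weights per-variant weight vector (length `ncol(G)`).
#' @param impute `"mean"` (default) or `"complete"` — complete-case drops
#'   samples with any missing dosage instead of imputing.
#' @return list of class `gene_unit` with `G` (numeric, imputed),
#'   `weights`, `markers_all`, `markers_tested`, `kept` (column index),
#'   `sample_keep` (row index).
#' @export
gene_qc <- function(G, weights = NULL, impute = c("mean", "complete")) {
  impute <- match.arg(impute)
  G <- as.matrix(G)
  m_all <- ncol(G)
  weights <- weights %||% rep(1, m_all)
  stopifnot(length(weights) == m_all)
  keep_rows <- seq_len(nrow(G))
  if (impute == "complete") {
    keep_rows <- which(stats::complete.cases(G))
    G <- G[keep_rows, , drop = FALSE]
  } else if (anyNA(G)) {
    mean_dos <- colMeans(G, na.rm = TRUE)   # = 2 * in-sample MAF
    mean_dos[is.nan(mean_dos)] <- 0
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mean_dos[idx[, 2]]
  }
  vvar <- apply(G, 2, stats::var)
  kept <- which(!is.na(vvar) & vvar > 0 & weights > 0)
  structure(list(G = G[, kept, drop = FALSE], weights = weights[kept],
                 markers_all = m_all, markers_tested = length(kept),
                 kept = kept, sample_keep = keep_rows),
            class = "gene_unit")
}

#' Kernel score statistic for a gene unit
#'
#' `Q = r' G W^2 G' r` with `W = diag(weights)` and `r` the null-model
#' residuals; for continuous outcomes Q is divided by the residual
#' variance so the same eigenvalue reference distribution applies.
#'
#' @param unit a `gene_unit` from [gene_qc()].
#' @param null a `skat_null_model`.
#' @return the scalar Q.
#' @export
skat_statistic <- function(unit, null) {
  r <- null$residuals[unit$sample_keep]
  s <- as.vector(crossprod(unit$G, r)) * unit$weights  # W G' r
  Q <- sum(s^2)
  if (null$out_type == "C") Q <- Q / null$sigma2
  Q
}

#' Eigenvalues of the kernel under the null
#'
#' Returns the eigenvalues of `W G' P0 G W`, where `P0` is the
#' projection/variance matrix of the null model: for a dichotomous
#' outcome `P0 = V - V X (X' V X)^{-1} X' V` with `V = diag(mu(1-mu))`;
#' for a continuous outcome `P0 = I - X (X'X)^{-1} X'` (matching the
#' variance-scaled Q). Negative numerical eigenvalues below
#' `1e-10 * max` are clipped to zero.
#'
#' @param unit a `gene_unit`.
#' @param null a `skat_null_model`.
#' @return non-negative eigenvalues, decreasing.
#' @export
mixture_lambdas <- function(unit, null) {
  G <- unit$G
  if (length(unit$sample_keep) != null$n) {
    stop("complete-case gene QC is incompatible with a prefit null; ",
         "refit the null on the retained samples")
  }
  GW <- sweep(G, 2, unit$weights, `*`)
  X <- null$X
  if (null$out_type == "D") {
    v <- null$v
    VG <- GW * v
    VX <- X * v
    XtVX <- crossprod(X, VX)
    B <- crossprod(VX, GW)                 # X' V (GW)
    M <- crossprod(GW, VG) - t(B) %*% solve(XtVX, B)
  } else {
    H <- crossprod(X, GW)                  # X'(GW)
    M <- crossprod(GW) - t(H) %*% solve(crossprod(X), H)
  }
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev, 0)
  ev[ev < 1e-10 * mx] <- 0
  ev[ev > 0]
}

## ---- tail probability of a weighted chi-square mixture -----------------

# Imhof-form characteristic-function inversion:
# P(Q > q) = 1/2 + (1/pi) * Int_0^Inf sin(theta(u)) / (u * rho(u)) du
# with theta(u) = 0.5 * sum(atan(lambda u)) - 0.5 q u and
# rho(u) = prod(1 + lambda^2 u^2)^(1/4).
#
# The envelope 1/(u rho(u)) decays like u^(-(1 + m/2)), too slowly for
# infinite-range quadrature when few eigenvalues dominate, so we
# integrate a finite interval [0, U] and add the first-order
# integration-by-parts tail correction cos(theta(U)) h(U) / theta'(U);
# the remaining tail is second order in 1/(qU) and U is grown until its
# bound is below tol.
imhof_tail <- function(lambdas, q, abs.tol = 1e-10) {
  m <- length(lambdas)
  theta_f <- function(u) 0.5 * colSums(atan(outer(lambdas, u))) -
    0.5 * q * u
  h_f <- function(u) exp(-log(u) - 0.25 *
                           colSums(log1p(outer(lambdas^2, u^2))))
  integrand <- function(u) {
    out <- sin(theta_f(u)) * h_f(u)
    out[u == 0] <- 0.5 * (sum(lambdas) - q)
    out
  }
  # grow U until the post-correction tail bound is negligible
  U <- max(16 / sqrt(2 * sum(lambdas^2)), 1 / max(lambdas))
  tol <- abs.tol
  for (i in 1:60) {
    bound <- (1 + m / 2) * h_f(U) * 8 / (U * q^2)
    if (bound < tol || U > 1e8) break
    U <- U * 1.7
  }
  for (opts in list(list(tol = abs.tol, sub = 3000L),
                    list(tol = 1e-8, sub = 8000L))) {
    int <- stats::integrate(integrand, 0, U, abs.tol = opts$tol,
                            rel.tol = 1e-10, subdivisions = opts$sub,
                            stop.on.error = FALSE)
    if (int$message == "OK") {
      thp <- 0.5 * sum(lambdas / (1 + lambdas^2 * U^2)) - 0.5 * q
      tail_corr <- cos(theta_f(U)) * h_f(U) / thp
      return(0.5 + (int$value + tail_corr) / pi)
    }
  }
  structure(NA_real_, error = int$message)
}

# Ruben/Farebrother series: Q/beta is a mixture of central chi-squares
# chisq_{m+2k} with nonnegative weights a_k summing to 1 when
# 0 < beta <= min(lambda). Truncation error is bounded by the unassigned
# mixture weight. Converges slowly when max(lambda)/min(lambda) is large,
# so it serves as a small-m backstop behind the Imhof integral.
ruben_tail <- function(lambdas, q, eps = 1e-10, max_terms = 3000) {
  m <- length(lambdas)
  beta <- 0.90625 * min(lambdas)
  ratio <- 1 - beta / lambdas
  # geometric convergence at rate max(ratio); skip if hopeless
  if (max(ratio) > 0 && log(eps) / log(max(ratio)) > max_terms)
    return(NA_real_)
  a <- numeric(max_terms)
  a[1] <- exp(0.5 * sum(log(beta / lambdas)))
  b <- numeric(max_terms)
  wsum <- a[1]
  k <- 1
  while (wsum < 1 - eps && k < max_terms) {
    b[k] <- 0.5 * sum(ratio^k)
    a[k + 1] <- sum(b[1:k] * a[k:1]) / k
    wsum <- wsum + a[k + 1]
    k <- k + 1
  }
  if (wsum < 1 - 1e-6) return(NA_real_)  # series too slow; give up
  ks <- 0:(k - 1)
  lower <- sum(a[1:k] * stats::pchisq(q / beta, df = m + 2 * ks))
  # unassigned weight contributes at most (1 - wsum) to the lower tail
  p <- 1 - lower
  max(p - (1 - wsum), 0)
}

# Liu-Tang-Zhang four-moment chi-square matching.
liu_tail <- function(lambdas, q) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  muX <- l + delta
  sigmaX <- sqrt(2) * sqrt(l + 2 * delta)
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sigmaX + muX, df = l, ncp = delta,
                lower.tail = FALSE)
}

mc_tail <- function(lambdas, q, B = 1e6, chunk = 2e5) {
  m <- length(lambdas)
  hits <- 0; done <- 0
  while (done < B) {
    b <- min(chunk, B - done)
    Qs <- colSums(lambdas * matrix(stats::rchisq(m * b, df = 1), nrow = m))
    hits <- hits + sum(Qs > q)
    done <- done + b
  }
  hits / B
}

#' Tail probability of a weighted mixture of 1-df chi-squares
#'
#' `p = P(sum_j lambda_j chisq_1j > q)`. The `davies` engine inverts the
#' characteristic function numerically (Imhof integral, absolute accuracy
#' ~1e-9); `liu` matches four moments to a noncentral chi-square;
#' `montecarlo` draws from the mixture (oracle use). A `davies` result
#' that fails to converge or falls outside `(0, 1]` triggers an automatic
#' `liu` fallback, recorded in the `method` attribute.
#'
#' @param lambdas non-negative mixture weights, not all zero.
#' @param q observed statistic (`>= 0`).
#' @param engine `"davies"`, `"liu"` or `"montecarlo"`.
#' @param B Monte-Carlo draws (montecarlo engine).
#' @return the p-value, with attribute `method` naming the engine that
#'   produced it.
#' @export
quadform_tail <- function(lambdas, q, engine = c("davies", "liu",
                                                 "montecarlo"), B = 1e6) {
  engine <- match.arg(engine)
  lambdas <- lambdas[lambdas > 0]
  if (!length(lambdas)) stop("all mixture weights are zero")
  if (q < 0) stop("q must be >= 0")
  if (q == 0) return(structure(1, method = engine))
  method <- engine
  if (engine == "davies") {
    # exactly reducible mixtures first
    if (length(lambdas) == 1 ||
        diff(range(lambdas)) < 1e-12 * max(lambdas)) {
      p <- stats::pchisq(q / max(lambdas), df = length(lambdas),
                         lower.tail = FALSE)
    } else {
      p <- imhof_tail(lambdas, q)
      if (!is.na(p) && p > 0 && p < 1e-7) {
        # absolute quadrature tolerance limits relative accuracy deep in
        # the tail; the Ruben series is exact there when it converges
        pr <- ruben_tail(lambdas, q)
        if (!is.na(pr)) p <- pr
      } else if (is.na(p) || p <= 0 || p > 1) {
        p <- ruben_tail(lambdas, q)
        if (is.na(p)) {
          p <- liu_tail(lambdas, q)
          method <- "liu"
        }
      }
    }
  } else {
    p <- switch(engine,
      liu = liu_tail(lambdas, q),
      montecarlo = mc_tail(lambdas, q, B = B))
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(p, method = method)
}

#' Permutation p-value for a gene unit (oracle)
#'
#' Recomputes Q under outcome permutations. Valid only for an
#' intercept-only null (exchangeability); refuses covariate-adjusted
#' models.
#'
#' @param unit a `gene_unit`.
#' @param null an intercept-only `skat_null_model`.
#' @param B number of permutations (default 1999).
#' @return `p = (1 + #\{Q_perm >= Q_obs\}) / (B + 1)`.
#' @export
permutation_pvalue <- function(unit, null, B = 1999) {
  if (ncol(null$X) > 1)
    stop("permutation p-value requires an intercept-only null model")
  r <- null$residuals[unit$sample_keep]
  A <- t(sweep(unit$G, 2, unit$weights, `*`))   # m x n
  Qobs <- sum((A %*% r)^2)
  n <- length(r)
  Rperm <- vapply(seq_len(B), function(b) r[sample.int(n)],
                  numeric(n))
  Qperm <- colSums((A %*% Rperm)^2)
  (1 + sum(Qperm >= Qobs)) / (B + 1)
}

#' Gene-level kernel association scan
#'
#' For every gene unit in the SetID map, assembles the genotype
#' submatrix, applies QC, computes the weighted kernel score statistic
#' and its mixture-of-chi-square p-value against the covariate-adjusted
#' null model. Without a weight table, Beta(1, 25) weights on the
#' in-sample MAF are used.
#'
#' @param ad an `analysis_dataset` from [merge_pheno_geno()], or a
#'   [genotype_dataset] together with `outcome_values`.
#' @param setid data.frame from [read_setid()] / [genemap_to_setid()].
#' @param outcome outcome column name in the phenotype table.
#' @param out_type `"D"` dichotomous, `"C"` continuous.
#' @param covariates covariate column names (optional).
#' @param weights optional weight table from [get_logistic_weights()]
#'   (matched by variant key, falling back to rsid), or a numeric vector
#'   named by variant ID.
#' @param engine tail engine passed to [quadform_tail()].
#' @return data.frame of class `skat_result` with columns SetID, P.value,
#'   N.Marker.All, N.Marker.Test, Q, method; sorted by P.value.
#' @export
skat_assoc <- function(ad, setid, outcome, out_type = c("D", "C"),
                       covariates = NULL, weights = NULL,
                       engine = "davies") {
  out_type <- match.arg(out_type)
  stopifnot(inherits(ad, "analysis_dataset"))
  geno <- ad$geno
  y <- ad$pheno[[outcome]]
  if (is.null(y)) stop("no such outcome column: ", outcome)
  Z <- get_covariate_frame(ad, covariates)
  null <- fit_null_model(y, Z, out_type)

  v <- geno$variants
  vkey <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  maf <- sample_maf(geno)

  # per-variant weight lookup
  wvec <- beta_weight(pmin(pmax(maf, 0), 0.5))
  if (!is.null(weights)) {
    if (is.data.frame(weights)) {
      wkey <- variant_key(weights$chr, weights$pos, weights$ref,
                          weights$alt)
      idx <- match(vkey, wkey)
      if ("rsid" %in% names(weights)) {
        miss <- is.na(idx)
        idx[miss] <- match(v$rsid[miss], weights$rsid)
      }
      hit <- !is.na(idx)
      wvec[hit] <- weights$weight[idx[hit]]
    } else {
      idx <- match(v$rsid, names(weights))
      hit <- !is.na(idx)
      wvec[hit] <- weights[idx[hit]]
    }
  }

  sets <- split(setid$variant_id, setid$set_id)
  rows <- lapply(names(sets), function(sid) {
    ids <- sets[[sid]]
    j <- match(ids, v$rsid)
    j2 <- match(ids, vkey)
    j[is.na(j)] <- j2[is.na(j)]
    unknown <- sum(is.na(j))
    if (unknown)
      message("set ", sid, ": ", unknown,
              " member variant(s) not in the genotype data")
    j <- j[!is.na(j)]
    if (!length(j))
      return(data.frame(SetID = sid, P.value = NA_real_,
                        N.Marker.All = 0L, N.Marker.Test = 0L,
                        Q = NA_real_, method = NA_character_,
                        stringsAsFactors = FALSE))
    unit <- gene_qc(geno$dosage[, j, drop = FALSE], wvec[j])
    if (unit$markers_tested == 0)
      return(data.frame(SetID = sid, P.value = NA_real_,
                        N.Marker.All = unit$markers_all,
                        N.Marker.Test = 0L, Q = NA_real_,
                        method = "all markers failed QC",
                        stringsAsFactors = FALSE))
    Q <- skat_statistic(unit, null)
    lam <- mixture_lambdas(unit, null)
    p <- quadform_tail(lam, Q, engine = engine)
    data.frame(SetID = sid, P.value = as.numeric(p),
               N.Marker.All = unit$markers_all,
               N.Marker.Test = unit$markers_tested, Q = Q,
               method = attr(p, "method"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$P.value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("skat_result", "data.frame")
  out
}

#' Write a gene-level result table as CSV
#'
#' Canonical column layout SetID, P.value, N.Marker.All, N.Marker.Test.
#'
#' @param skat a `skat_result` data.frame.
#' @param path output CSV.
#' @export
write_skat <- function(skat, path) {
  utils::write.csv(
    skat[, c("SetID", "P.value", "N.Marker.All", "N.Marker.Test")],
    path, row.names = FALSE)
  invisible(path)
}
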