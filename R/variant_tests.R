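#' Encode dosages under a genetic model
#'
#' Additive keeps 0/1/2 copies of the counted allele, dominant codes
#' presence of at least one copy, recessive codes homozygosity. Missing
#' entries stay missing.
#'
#' @param dosages vector or matrix with entries in `{0, 1, 2, NA}`.
#' @param model `"add"`, `"dom"` or `"rec"`.
#' @return same shape as `dosages`, recoded.
#' @export
encode_model <- function(dosages, model = c("add", "dom", "rec")) {
  model <- match.arg(model)
  switch(model,
         add = dosages,
         dom = ifelse(is.na(dosages), NA_integer_,
                      as.integer(dosages >= 1L)),
         rec = ifelse(is.na(dosages), NA_integer_,
                      as.integer(dosages == 2L)))
}

# 2x2 allele-count table (rows: control/case, cols: other/A1 allele);
# each non-missing genotype contributes two alleles.
allele_table <- function(dosage, y) {
  ok <- !is.na(dosage) & !is.na(y)
  d <- dosage[ok]; yy <- y[ok]
  a1_ctl <- sum(d[yy == 0]); a1_cas <- sum(d[yy == 1])
  oth_ctl <- 2 * sum(yy == 0) - a1_ctl
  oth_cas <- 2 * sum(yy == 1) - a1_cas
  list(tab = matrix(c(a1_cas, oth_cas, a1_ctl, oth_ctl), nrow = 2,
                    byrow = TRUE,
                    dimnames = list(c("case", "control"), c("A1", "other"))),
       nmiss = sum(ok))
}

# sample odds ratio with Haldane-Anscombe +0.5 when any cell is zero
sample_or <- function(tab) {
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

assoc_record <- function(chrom, rsid, bp, a1, test, nmiss,
                         effect = NA_real_, stat = NA_real_, p = NA_real_,
                         skip = NA_character_) {
  data.frame(CHR = chrom, SNP = rsid, BP = bp, A1 = a1, TEST = test,
             NMISS = nmiss, EFFECT = effect, STAT = stat, P = p,
             SKIP = skip, stringsAsFactors = FALSE)
}

variant_meta <- function(geno, j) geno$variants[j, , drop = FALSE]

# Per-variant allelic tests on a binary outcome ------------------------

fisher_one <- function(dosage, y, meta) {
  at <- allele_table(dosage, y)
  if (at$nmiss == 0)
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        "FISHER", 0L, skip = "all genotypes missing"))
  ft <- stats::fisher.test(at$tab)
  assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1, "FISHER",
               at$nmiss, effect = sample_or(at$tab), stat = NA_real_,
               p = ft$p.value)
}

chisq_one <- function(dosage, y, meta, correct = FALSE) {
  at <- allele_table(dosage, y)
  if (at$nmiss == 0 || any(rowSums(at$tab) == 0) || any(colSums(at$tab) == 0))
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        "CHISQ", at$nmiss, skip = "zero margin"))
  ct <- suppressWarnings(stats::chisq.test(at$tab, correct = correct))
  assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1, "CHISQ",
               at$nmiss, effect = sample_or(at$tab),
               stat = unname(ct$statistic), p = ct$p.value)
}

trend_one <- function(dosage, y, meta) {
  ok <- !is.na(dosage) & !is.na(y)
  d <- dosage[ok]; yy <- y[ok]
  counts <- table(factor(d, levels = 0:2))
  if (sum(counts > 0) < 2 || length(unique(yy)) < 2)
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        "TREND", sum(ok), skip = "monomorphic"))
  cases <- tapply(yy, factor(d, levels = 0:2), sum)
  cases[is.na(cases)] <- 0
  tt <- suppressWarnings(
    stats::prop.trend.test(cases, as.integer(counts), score = 0:2))
  assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1, "TREND",
               sum(ok), effect = NA_real_, stat = unname(tt$statistic),
               p = tt$p.value)
}

# Regression scans ------------------------------------------------------

scan_one_glm <- function(g, y, Z, meta, model_label) {
  ok <- !is.na(g) & !is.na(y) & (if (is.null(Z)) TRUE else
                                 stats::complete.cases(Z))
  g <- g[ok]; yy <- y[ok]
  nmiss <- sum(ok)
  if (length(unique(g)) < 2)
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        model_label, nmiss, skip = "no genotype variance"))
  dat <- data.frame(.y = yy, .g = g)
  if (!is.null(Z)) dat <- cbind(dat, Z[ok, , drop = FALSE])
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 25)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (!".g" %in% rownames(co) || !fit$converged || sep)
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        model_label, nmiss,
                        skip = if (sep) "separation" else "non-convergence"))
  b <- co[".g", "Estimate"]; se <- co[".g", "Std. Error"]
  z <- b / se
  assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1, model_label,
               nmiss, effect = exp(b), stat = z, p = 2 * stats::pnorm(-abs(z)))
}

scan_one_lm <- function(g, y, Z, meta, model_label) {
  ok <- !is.na(g) & !is.na(y) & (if (is.null(Z)) TRUE else
                                 stats::complete.cases(Z))
  g <- g[ok]; yy <- y[ok]
  nmiss <- sum(ok)
  if (length(unique(g)) < 2)
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        model_label, nmiss, skip = "no genotype variance"))
  dat <- data.frame(.y = yy, .g = g)
  if (!is.null(Z)) dat <- cbind(dat, Z[ok, , drop = FALSE])
  fit <- stats::lm(.y ~ ., data = dat)
  co <- summary(fit)$coefficients
  if (!".g" %in% rownames(co) || anyNA(stats::coef(fit)))
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        model_label, nmiss, skip = "rank-deficient design"))
  b <- co[".g", "Estimate"]; tval <- co[".g", "t value"]
  assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1, model_label,
               nmiss, effect = b, stat = tval, p = co[".g", "Pr(>|t|)"])
}

scan_one_surv <- function(g, time, event, Z, meta, model_label,
                          method = c("coxph", "logrank")) {
  method <- match.arg(method)
  ok <- !is.na(g) & !is.na(time) & !is.na(event) &
    (if (is.null(Z)) TRUE else stats::complete.cases(Z))
  g <- g[ok]; tt <- time[ok]; ev <- event[ok]
  nmiss <- sum(ok)
  if (sum(ev) == 0)
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        model_label, nmiss, skip = "no events"))
  if (length(unique(g)) < 2)
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        model_label, nmiss, skip = "no genotype variance"))
  if (method == "logrank") {
    sd <- survival::survdiff(survival::Surv(tt, ev) ~ factor(g))
    df <- length(sd$n) - 1
    p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        model_label, nmiss, effect = NA_real_,
                        stat = unname(sd$chisq), p = p))
  }
  dat <- data.frame(.g = g)
  if (!is.null(Z)) dat <- cbind(dat, Z[ok, , drop = FALSE])
  fit <- tryCatch(
    survival::coxph(survival::Surv(tt, ev) ~ ., data = dat,
                    ties = "breslow"),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit)[".g"]))
    return(assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1,
                        model_label, nmiss, skip = "non-convergence"))
  co <- summary(fit)$coefficients
  b <- co[".g", "coef"]; z <- co[".g", "z"]
  assoc_record(meta$chrom, meta$rsid, meta$pos, meta$a1, model_label,
               nmiss, effect = exp(b), stat = z,
               p = 2 * stats::pnorm(-abs(z)))
}

scan_table <- function(ad, model, fun) {
  geno <- ad$geno
  m <- nrow(geno$variants)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    g <- encode_model(geno$dosage[, j], model)
    rows[[j]] <- fun(g, j)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

get_covariate_frame <- function(ad, covariates) {
  if (is.null(covariates) || !length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(ad$pheno))
  if (length(miss)) stop("covariate column(s) not in phenotype table: ",
                         paste(miss, collapse = ", "))
  ad$pheno[, covariates, drop = FALSE]
}

#' Per-variant association scan and clinical pre-filter
#'
#' Runs the chosen single-variant test across all variants under a genetic
#' model and returns the full association table plus the subset with
#' `P < threshold` — the clinically filtered variant list consumed by the
#' annotation, weighting and SKAT stages.
#'
#' Methods: `fisher` and `chisq` are allelic 2x2 tests (each non-missing
#' genotype contributes two alleles), `trend` is the Cochran-Armitage
#' test, `glm` logistic regression (Wald), `lm` linear regression,
#' `survfit` the log-rank test and `coxph` Cox regression (Breslow ties).
#'
#' @param ad an `analysis_dataset` from [merge_pheno_geno()].
#' @param method one of `"fisher"`, `"chisq"`, `"trend"`, `"glm"`, `"lm"`,
#'   `"survfit"`, `"coxph"`.
#' @param model genetic model `"add"`, `"dom"` or `"rec"` (regression and
#'   trend tests; allelic tests ignore it).
#' @param outcome name of the outcome column; for survival methods a
#'   length-2 vector `c(time, event)`.
#' @param covariates character vector of covariate column names (regression
#'   methods only).
#' @param threshold significance threshold for the filtered list
#'   (default 0.05).
#' @return list of class `functional_analysis`: `assoc` (full table with
#'   columns CHR, SNP, BP, A1, TEST, NMISS, effect, STAT, P and a SKIP
#'   reason for untested variants), `filtered` (rows with `P < threshold`),
#'   `threshold`, `method`, `model`.
#' @export
functional_analysis <- function(ad,
                                method = c("glm", "fisher", "chisq", "trend",
                                           "lm", "survfit", "coxph"),
                                model = c("add", "dom", "rec"),
                                outcome = NULL, covariates = NULL,
                                threshold = 0.05) {
  method <- match.arg(method)
  model <- match.arg(model)
  stopifnot(inherits(ad, "analysis_dataset"))
  if (!(threshold >= 0 && threshold <= 1)) stop("threshold must be in [0, 1]")
  geno <- ad$geno
  model_label <- toupper(model)
  Z <- get_covariate_frame(ad, covariates)

  if (method %in% c("survfit", "coxph")) {
    if (is.null(outcome) || length(outcome) != 2)
      stop("survival methods need outcome = c(time_col, event_col)")
    tt <- ad$pheno[[outcome[1]]]; ev <- ad$pheno[[outcome[2]]]
    if (any(tt <= 0, na.rm = TRUE)) stop("survival times must be positive")
    if (!all(ev %in% c(0, 1, NA))) stop("event indicator must be 0/1")
    fun <- function(g, j) scan_one_surv(
      g, tt, ev, Z, variant_meta(geno, j), model_label,
      method = if (method == "survfit") "logrank" else "coxph")
  } else {
    if (is.null(outcome)) stop("outcome column name is required")
    y <- ad$pheno[[outcome]]
    if (is.null(y)) stop("no such outcome column: ", outcome)
    if (method %in% c("fisher", "chisq", "trend", "glm")) {
      if (!all(y %in% c(0, 1, NA)))
        stop("method '", method, "' needs a binary 0/1 outcome")
    } else if (!is.numeric(y)) {
      stop("method 'lm' needs a numeric outcome")
    }
    fun <- switch(method,
      fisher = function(g, j) fisher_one(g, y, variant_meta(geno, j)),
      chisq  = function(g, j) chisq_one(g, y, variant_meta(geno, j)),
      trend  = function(g, j) trend_one(g, y, variant_meta(geno, j)),
      glm    = function(g, j) scan_one_glm(g, y, Z, variant_meta(geno, j),
                                           model_label),
      lm     = function(g, j) scan_one_lm(g, y, Z, variant_meta(geno, j),
                                          model_label))
  }
  assoc <- scan_table(ad, if (method %in% c("fisher", "chisq")) "add"
                      else model, fun)
  effect_name <- switch(method, glm = "OR", fisher = "OR", chisq = "OR",
                        lm = "BETA", coxph = "HR", "STATONLY")
  names(assoc)[names(assoc) == "EFFECT"] <-
    if (effect_name == "STATONLY") "EFFECT" else effect_name
  filtered <- assoc[!is.na(assoc$P) & assoc$P < threshold, , drop = FALSE]
  structure(list(assoc = assoc, filtered = filtered, threshold = threshold,
                 method = method, model = model),
            class = "functional_analysis")
}

#' @export
print.functional_analysis <- function(x, ...) {
  cat("functional_analysis (", x$method, ", ", x$model, "): ",
      nrow(x$assoc), " variants tested, ", nrow(x$filtered),
      " with P < ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Write an association table as CSV
#'
#' Column layout CHR, SNP, BP, A1, TEST, NMISS, effect (OR/BETA/HR),
#' STAT, P; the SKIP bookkeeping column is omitted.
#'
#' @param fa a `functional_analysis` result (or its `$assoc` data.frame).
#' @param path output CSV.
#' @param filtered write the filtered subset instead of the full table.
#' @export
write_assoc <- function(fa, path, filtered = FALSE) {
  df <- if (inherits(fa, "functional_analysis")) {
    if (filtered) fa$filtered else fa$assoc
  } else fa
  df <- df[, setdiff(names(df), "SKIP"), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; values near 1
#' indicate a well-calibrated scan, values well above 1 systematic
#' inflation.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]` (NAs dropped).
#' @return the inflation factor.
#' @export
genomic_lambda <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
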