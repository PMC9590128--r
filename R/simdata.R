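#' Specification of a synthetic cohort
#'
#' Defines the generator for a case-control (or continuous / survival)
#' cohort with independent Hardy-Weinberg genotypes: per variant
#' `dosage ~ Binomial(2, MAF_j)`, optional block LD via Markov allele
#' copying, masked missingness, and an outcome drawn from the chosen
#' model with sex and age covariates.
#'
#' @param n samples (default 500).
#' @param m variants (default 200).
#' @param genes number of gene units; variants are split evenly across
#'   genes (default `max(1, m %/% 10)`).
#' @param maf_range MAF spectrum, uniform between the bounds
#'   (default `c(0.005, 0.35)`).
#' @param maf explicit per-variant MAF vector (overrides `maf_range`).
#' @param missing_rate fraction of dosages masked as missing
#'   (default 0.02).
#' @param outcome `"binary"`, `"continuous"` or `"survival"`.
#' @param beta per-variant log-effect vector (length `m` or scalar;
#'   default 0 = null model).
#' @param alpha intercept (default 0: ~50% cases under the null binary
#'   model, mirroring a severity-split clinical cohort).
#' @param gamma covariate effects, length 2 `(sex, age_std)`.
#' @param sigma residual SD for the continuous model (default 1).
#' @param censor_rate uniform censoring fraction for survival
#'   (default 0.3).
#' @param ld_blocks number of LD blocks (0 = independent variants);
#'   within a block adjacent variants copy alleles with probability
#'   `ld_rho`.
#' @param ld_rho within-block copying probability (default 0.8).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n = 500, m = 200, genes = max(1L, m %/% 10L),
                     maf_range = c(0.005, 0.35), maf = NULL,
                     missing_rate = 0.02,
                     outcome = c("binary", "continuous", "survival"),
                     beta = 0, alpha = 0, gamma = c(0.2, 0.1), sigma = 1,
                     censor_rate = 0.3, ld_blocks = 0, ld_rho = 0.8,
                     seed) {
  outcome <- match.arg(outcome)
  if (missing(seed)) stop("seed is mandatory")
  if (!is.null(maf)) {
    if (length(maf) != m) stop("maf vector must have length m")
    if (any(maf <= 0 | maf > 0.5)) stop("maf must be in (0, 0.5]")
  } else if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must lie in (0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  beta <- rep_len(beta, m)
  structure(list(n = n, m = m, genes = genes, maf_range = maf_range,
                 maf = maf, missing_rate = missing_rate,
                 outcome = outcome, beta = beta, alpha = alpha,
                 gamma = gamma, sigma = sigma, censor_rate = censor_rate,
                 ld_blocks = ld_blocks, ld_rho = ld_rho, seed = seed),
            class = "sim_spec")
}

sim_variant_table <- function(spec) {
  m <- spec$m
  chrom <- as.character(sort(rep_len(1:22, m)))[seq_len(m)]
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(5e7, length(idx)))
  }
  ra <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE),
               ncol = 2)
  same <- ra[, 1] == ra[, 2]
  ra[same, 2] <- vapply(ra[same, 1], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  data.frame(chrom = chrom, pos = pos, ref = ra[, 1], alt = ra[, 2],
             rsid = sprintf("rs%06d", seq_len(m)), a1 = ra[, 2],
             stringsAsFactors = FALSE)
}

#' Simulate a genotype matrix
#'
#' Independent Hardy-Weinberg sampling per variant; with `ld_blocks > 0`
#' a Markov allele-copying scheme induces correlation between adjacent
#' variants of a block. Deterministic under the spec's seed.
#'
#' @param spec a [sim_spec()].
#' @return a [genotype_dataset] (true MAFs in attribute `true_maf`).
#' @export
simulate_genotypes <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n; m <- spec$m
  maf <- spec$maf %||% stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  # two allele draws per sample/variant; block LD copies the previous
  # variant's allele with probability ld_rho
  h1 <- matrix(stats::rbinom(n * m, 1, rep(maf, each = n)), n, m)
  h2 <- matrix(stats::rbinom(n * m, 1, rep(maf, each = n)), n, m)
  if (spec$ld_blocks > 0 && m >= 2) {
    block <- rep(seq_len(spec$ld_blocks), length.out = m)
    block <- sort(block)
    for (j in 2:m) {
      if (block[j] == block[j - 1]) {
        copy1 <- stats::runif(n) < spec$ld_rho
        copy2 <- stats::runif(n) < spec$ld_rho
        h1[copy1, j] <- h1[copy1, j - 1]
        h2[copy2, j] <- h2[copy2, j - 1]
      }
    }
  }
  dosage <- h1 + h2
  if (spec$missing_rate > 0) {
    mask <- stats::runif(n * m) < spec$missing_rate
    dosage[matrix(mask, n, m)] <- NA_integer_
  }
  variants <- sim_variant_table(spec)
  samples <- sprintf("IND%04d", seq_len(n))
  geno <- genotype_dataset(dosage, samples, variants,
                           recode_minor = FALSE)
  geno$variants$a1 <- geno$variants$alt
  attr(geno, "true_maf") <- maf
  geno
}

#' Simulate phenotypes for a genotype dataset
#'
#' Binary: `P(y = 1) = expit(alpha + G beta + Z gamma)`; continuous:
#' `y = alpha + G beta + Z gamma + N(0, sigma^2)`; survival: exponential
#' times with rate `exp(G beta)` and independent uniform censoring.
#' Missing dosages contribute their expected value (2 x true MAF) to the
#' linear predictor.
#'
#' @param geno a [genotype_dataset] from [simulate_genotypes()].
#' @param spec the same [sim_spec()].
#' @return data.frame: `sample_id`, `sex` (0/1), `age`, and `y` (binary /
#'   continuous) or `time` + `event` (survival); attribute
#'   `id_col = "sample_id"`.
#' @export
simulate_phenotypes <- function(geno, spec) {
  set.seed(spec$seed + 1L)
  n <- length(geno$samples)
  sex <- stats::rbinom(n, 1, 0.5)
  age <- stats::rnorm(n, 45, 12)
  G <- geno$dosage
  if (anyNA(G)) {
    tm <- attr(geno, "true_maf") %||% (colMeans(G, na.rm = TRUE) / 2)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- 2 * tm[idx[, 2]]
  }
  eta_g <- as.vector(G %*% spec$beta)
  Z <- cbind(sex, scale(age)[, 1])
  eta <- spec$alpha + eta_g + as.vector(Z %*% spec$gamma)
  out <- data.frame(sample_id = geno$samples, sex = sex,
                    age = round(age, 1), stringsAsFactors = FALSE)
  if (spec$outcome == "binary") {
    out$y <- stats::rbinom(n, 1, stats::plogis(eta))
  } else if (spec$outcome == "continuous") {
    out$y <- eta + stats::rnorm(n, 0, spec$sigma)
  } else {
    tt <- stats::rexp(n, rate = exp(eta_g))
    cmax <- stats::quantile(tt, 1 - spec$censor_rate / 2)
    cens <- stats::runif(n, 0, 2 * as.numeric(cmax))
    out$time <- pmin(tt, cens)
    out$event <- as.integer(tt <= cens)
  }
  attr(out, "id_col") <- "sample_id"
  out
}

sim_gene_table <- function(geno, spec) {
  m <- nrow(geno$variants)
  gene_of <- sort(rep_len(seq_len(spec$genes), m))
  v <- geno$variants
  genes <- lapply(split(seq_len(m), gene_of), function(idx) {
    data.frame(gene = sprintf("GENE%03d", gene_of[idx[1]]),
               chrom = v$chrom[idx[1]],
               start = max(1L, min(v$pos[idx]) - 500L),
               end = max(v$pos[idx]) + 500L, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, genes)
  rownames(tab) <- NULL
  list(intervals = tab, gene_of = gene_of)
}

#' Write a coherent synthetic input bundle
#'
#' Emits every file the four-stage pipeline consumes: PLINK trio plus an
#' identical VCF, phenotype CSV, gene BED, GMT gene sets, SetID, and a
#' reference MAF TSV (true simulation MAFs perturbed by binomial
#' resampling at `ref_n` chromosomes, emulating an external population
#' panel).
#'
#' @param dir output directory (created if needed).
#' @param spec a [sim_spec()]; default is a 500-sample, 5000-variant,
#'   100-gene null cohort.
#' @param ref_n reference-panel chromosome count for MAF resampling
#'   (default 10000).
#' @return invisibly, a named list of the written paths.
#' @export
make_fixture_suite <- function(dir,
                               spec = sim_spec(n = 500, m = 5000,
                                               genes = 100, seed = 1234),
                               ref_n = 10000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geno <- simulate_genotypes(spec)
  pheno <- simulate_phenotypes(geno, spec)
  gt <- sim_gene_table(geno, spec)
  v <- geno$variants

  paths <- list(
    plink = file.path(dir, "geno"),
    vcf = file.path(dir, "geno.vcf"),
    pheno = file.path(dir, "pheno.csv"),
    bed = file.path(dir, "genes.bed"),
    gmt = file.path(dir, "genesets.gmt"),
    setid = file.path(dir, "gene.SetID"),
    maf = file.path(dir, "ref_maf.tsv"))

  write_plink(geno, paths$plink)
  write_vcf(geno, paths$vcf)
  utils::write.csv(pheno, paths$pheno, row.names = FALSE)
  iv <- gt$intervals
  utils::write.table(
    data.frame(iv$chrom, iv$start - 1L, iv$end, iv$gene),
    paths$bed, quote = FALSE, sep = "\t", row.names = FALSE,
    col.names = FALSE)

  gene_names <- unique(iv$gene)
  set.seed(spec$seed + 2L)
  n_sets <- max(2L, length(gene_names) %/% 5L)
  sets <- lapply(seq_len(n_sets), function(i)
    sort(sample(gene_names, max(2L, length(gene_names) %/% 10L))))
  names(sets) <- sprintf("PATHWAY_%02d", seq_len(n_sets))
  write_gmt(sets, paths$gmt)

  setid <- data.frame(set_id = iv$gene[gt$gene_of],
                      variant_id = v$rsid, stringsAsFactors = FALSE)
  write_setid(setid, paths$setid)

  true_maf <- attr(geno, "true_maf")
  ref_maf <- stats::rbinom(length(true_maf), ref_n, true_maf) / ref_n
  ref_maf <- pmin(pmax(ref_maf, 1 / ref_n), 0.5)
  utils::write.table(
    data.frame(chr = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               maf = ref_maf),
    paths$maf, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(paths)
}
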