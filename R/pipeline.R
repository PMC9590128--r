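#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list) and checks every invariant
#' before any computation: referenced paths exist, the method keyword is
#' on the menu, the threshold lies in (0, 1], and the weighting scheme
#' has the inputs it needs. Defaults are filled for omitted optional
#' fields.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  err <- function(field, msg) stop("config field '", field, "': ", msg,
                                   call. = FALSE)
  need_path <- function(field, optional = FALSE) {
    p <- cfg[[field]]
    if (is.null(p)) {
      if (!optional) err(field, "is required")
      return(NULL)
    }
    if (!file.exists(p) && !file.exists(paste0(p, ".bed")))
      err(field, paste0("path does not exist: ", p))
    p
  }
  cfg$genotype <- need_path("genotype")
  cfg$phenotype <- need_path("phenotype")
  cfg$annotation <- need_path("annotation")
  cfg$gmt <- need_path("gmt", optional = TRUE)
  cfg$setid <- need_path("setid", optional = TRUE)
  cfg$output_dir <- cfg$output_dir %||% err("output_dir", "is required")

  cfg$method <- cfg$method %||% "glm"
  menu <- c("fisher", "chisq", "lm", "glm", "survfit", "coxph", "trend")
  if (!cfg$method %in% menu)
    err("method", paste0("unknown keyword '", cfg$method, "'; valid: ",
                         paste(menu, collapse = ", ")))
  cfg$model <- cfg$model %||% "add"
  if (!cfg$model %in% c("add", "dom", "rec"))
    err("model", "must be add, dom or rec")
  cfg$threshold <- cfg$threshold %||% 0.05
  if (!(cfg$threshold > 0 && cfg$threshold <= 1))
    err("threshold", "must be in (0, 1]")
  if (is.null(cfg$outcome)) err("outcome", "is required")

  cfg$scheme <- cfg$scheme %||% "logistic"
  if (!cfg$scheme %in% c("logistic", "beta", "none"))
    err("scheme", "must be logistic, beta or none")
  if (cfg$scheme == "logistic" && is.null(cfg$maf_table))
    err("maf_table", "required when scheme = logistic")
  cfg$maf_table <- if (!is.null(cfg$maf_table)) need_path("maf_table")
  cfg$w1 <- cfg$w1 %||% 0.07
  cfg$w2 <- cfg$w2 %||% 150
  cfg$out_type <- cfg$out_type %||% "D"
  if (!cfg$out_type %in% c("C", "D")) err("out_type", "must be C or D")
  cfg$flank_bp <- cfg$flank_bp %||% 0
  cfg$covariates <- cfg$covariates %||% NULL
  cfg$seed <- cfg$seed %||% 1234
  cfg$sig_val <- cfg$sig_val %||% 3
  cfg$geno_val <- cfg$geno_val %||% 5
  cfg$bar_pval <- cfg$bar_pval %||% 1e-4
  structure(cfg, class = "pipeline_config")
}

read_genotype_any <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_vcf(path)
  else read_plink(sub("\\.bed$", "", path))
}

#' Run the four-stage pipeline
#'
#' Variant screen (stage 1) -> gene mapping and over-representation
#' (stage 2) -> reference-MAF collapsing weights (stage 3) -> gene-level
#' kernel association (stage 4), writing each stage's CSV, the figures,
#' and a run manifest with the counts at every stage. Any stage error
#' aborts with the stage name; completed outputs are preserved.
#'
#' @param config a `pipeline_config` (or path / list accepted by
#'   [validate_config()]).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  figdir <- file.path(cfg$output_dir, "figures")
  dir.create(figdir, showWarnings = FALSE)
  set.seed(cfg$seed)
  out <- function(f) file.path(cfg$output_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(package_version = as.character(
    utils::packageVersion("skatpipe")), seed = cfg$seed, stages = list())

  # stage 1: variant screen
  fa <- stage("functional_analysis", {
    geno <- read_genotype_any(cfg$genotype)
    pheno <- read_phenotypes(cfg$phenotype)
    ad <- merge_pheno_geno(pheno, geno)
    functional_analysis(ad, method = cfg$method, model = cfg$model,
                        outcome = cfg$outcome,
                        covariates = cfg$covariates,
                        threshold = cfg$threshold)
  })
  ad <- local({ # keep the merged dataset for later stages
    geno <- read_genotype_any(cfg$genotype)
    merge_pheno_geno(read_phenotypes(cfg$phenotype), geno)
  })
  write_assoc(fa, out("step1_assoc.csv"))
  plot_manhattan(fa, file.path(figdir, "manhattan.png"),
                 sig_val = cfg$sig_val, geno_val = cfg$geno_val)
  plot_qq(fa, file.path(figdir, "qq.png"))
  manifest$stages$functional_analysis <- list(
    variants_in = nrow(fa$assoc), filtered = nrow(fa$filtered),
    threshold = cfg$threshold)
  if (!nrow(fa$filtered))
    stop("pipeline stage 'map_snps_to_genes' failed: no variants passed ",
         "the stage-1 threshold", call. = FALSE)

  # stage 2: gene mapping + ORA
  filt_idx <- match(fa$filtered$SNP, ad$geno$variants$rsid)
  filt_var <- ad$geno$variants[filt_idx, , drop = FALSE]
  gm <- stage("map_snps_to_genes", {
    intervals <- if (grepl("\\.gtf(\\.gz)?$", cfg$annotation))
      read_gene_gtf(cfg$annotation) else read_gene_bed(cfg$annotation)
    map_snps_to_genes(filt_var, intervals, flank_bp = cfg$flank_bp)
  })
  utils::write.csv(gm$mapped, out("step2_genemap.csv"), row.names = FALSE)
  manifest$stages$map_snps_to_genes <- list(
    mapped_assignments = nrow(gm$mapped),
    mapped_variants = length(unique(gm$mapped$SNP)),
    unmapped = nrow(gm$unmapped),
    genes = length(unique(gm$mapped$Gene)))
  if (!is.null(cfg$gmt)) {
    ora <- stage("ora_test", {
      sets <- read_gmt(cfg$gmt)
      ora_test(unique(gm$mapped$Gene), sets)
    })
    utils::write.csv(ora, out("step2_pathways.csv"), row.names = FALSE)
    manifest$stages$ora_test <- list(sets_reported = nrow(ora))
  }

  # stage 3: collapsing weights
  wt <- NULL
  if (cfg$scheme != "none") {
    wt <- stage("get_logistic_weights", {
      smaf <- sample_maf(ad$geno)
      names(smaf) <- variant_key(ad$geno$variants$chrom,
                                 ad$geno$variants$pos,
                                 ad$geno$variants$ref,
                                 ad$geno$variants$alt)
      if (!is.null(cfg$maf_table)) {
        mt <- read_maf_reference(cfg$maf_table)
        get_logistic_weights(filt_var, mt, scheme = cfg$scheme,
                             w1 = cfg$w1, w2 = cfg$w2,
                             sample_maf = smaf)
      } else {
        key <- variant_key(filt_var$chrom, filt_var$pos, filt_var$ref,
                           filt_var$alt)
        data.frame(chr = filt_var$chrom, pos = filt_var$pos,
                   ref = filt_var$ref, alt = filt_var$alt,
                   maf = unname(smaf[key]), rsid = filt_var$rsid,
                   weight = beta_weight(unname(smaf[key])),
                   source = "sample", stringsAsFactors = FALSE)
      }
    })
    write_weights(wt, out("step3_weights.csv"))
    manifest$stages$weights <- list(
      weighted = nrow(wt),
      fallback = sum(wt$source == "fallback"))
  }

  # stage 4: gene-level kernel association on the filtered variants
  sk <- stage("skat_assoc", {
    setid <- if (!is.null(cfg$setid)) read_setid(cfg$setid)
             else genemap_to_setid(gm$mapped)
    setid <- setid[setid$variant_id %in% fa$filtered$SNP, , drop = FALSE]
    if (!nrow(setid)) stop("no gene unit contains a filtered variant")
    skat_assoc(ad, setid, outcome = cfg$outcome, out_type = cfg$out_type,
               covariates = cfg$covariates, weights = wt)
  })
  write_skat(sk, out("step4_skat.csv"))
  try(plot_gene_bar(sk, file.path(figdir, "gene_bar.png"),
                    pval = cfg$bar_pval), silent = TRUE)
  manifest$stages$skat_assoc <- list(
    genes_tested = sum(sk$N.Marker.Test > 0),
    liu_fallbacks = sum(sk$method == "liu", na.rm = TRUE))

  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(manifest)
}
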