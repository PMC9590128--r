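#' Genotype container
#'
#' A `genotype_dataset` holds a sample-by-variant matrix of minor-allele
#' dosages together with variant and sample metadata. Dosages count copies
#' of the A1 (counted) allele and take values 0, 1, 2 or `NA` (missing).
#'
#' @param dosage integer matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples character vector of unique sample IDs (row order).
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `rsid`, `a1` (one row per column of `dosage`).
#' @param recode_minor if `TRUE` (default) recompute A1 as the in-sample
#'   minor allele and flip dosages where needed; a tie (allele frequency
#'   exactly 0.5) keeps the supplied A1.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosage, samples, variants, recode_minor = TRUE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample IDs must be unique")
  if (nrow(dosage) != length(samples))
    stop("dosage rows (", nrow(dosage), ") != number of samples (",
         length(samples), ")")
  if (ncol(dosage) != nrow(variants))
    stop("dosage columns (", ncol(dosage), ") != number of variants (",
         nrow(variants), ")")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "rsid", "a1")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants is missing columns: ",
                         paste(miss, collapse = ", "))
  variants$chrom <- normalize_chrom(variants$chrom)
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt must differ")
  obj <- structure(
    list(dosage = dosage, samples = samples, variants = variants),
    class = "genotype_dataset")
  if (recode_minor) obj <- recode_to_minor(obj)
  obj
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  cat("missing entries:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosage)

# Strip "chr" prefixes and canonicalize mitochondrial labels so "chr1"
# and "1" compare equal across genotype, annotation and MAF inputs.
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  x[x == "M"] <- "MT"
  x
}

#' Composite variant key "chrom:pos:ref:alt"
#'
#' Exact match on all four fields; used for MAF lookups and weight joins.
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), as.integer(pos),
        toupper(ref), toupper(alt), sep = ":")
}

# In-sample frequency of the currently counted allele; NA if all missing.
counted_allele_freq <- function(dosage) {
  colMeans(dosage, na.rm = TRUE) / 2
}

recode_to_minor <- function(geno) {
  af <- counted_allele_freq(geno$dosage)
  flip <- which(!is.na(af) & af > 0.5)
  if (length(flip)) {
    geno$dosage[, flip] <- 2L - geno$dosage[, flip]
    old_a1 <- geno$variants$a1[flip]
    other <- ifelse(old_a1 == geno$variants$ref[flip],
                    geno$variants$alt[flip], geno$variants$ref[flip])
    geno$variants$a1[flip] <- other
  }
  geno
}

#' In-sample minor allele frequency per variant
#'
#' @param geno a [genotype_dataset].
#' @return numeric vector of MAFs in `[0, 0.5]` (NA if all genotypes missing).
#' @export
sample_maf <- function(geno) {
  maf <- counted_allele_freq(geno$dosage)
  pmin(maf, 1 - maf)
}

## ---- PLINK binary trio -----------------------------------------------

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b))

#' Read a PLINK 1.9 binary trio (.bed/.bim/.fam)
#'
#' Decodes the variant-major 2-bit encoding: `00` = homozygous A1
#' (dosage 2), `10` = heterozygous (1), `11` = homozygous A2 (0),
#' `01` = missing. Sample-major files (mode byte 0x00) are rejected.
#'
#' @param prefix path prefix (`prefix.bed` etc.), or give the three paths.
#' @param bed,bim,fam explicit file paths (override `prefix`).
#' @param recode_minor recompute A1 as the in-sample minor allele.
#' @return a [genotype_dataset].
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL,
                       recode_minor = TRUE) {
  if (!is.null(prefix)) {
    bed <- bed %||% paste0(prefix, ".bed")
    bim <- bim %||% paste0(prefix, ".bim")
    fam <- fam %||% paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)

  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "rsid", "cm", "pos", "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam_df); m <- nrow(bim_df)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:2], PLINK_MAGIC))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  mode <- as.integer(raw[3])
  if (mode == 0L)
    stop("sample-major .bed (mode byte 0x00) is not supported; ",
         "re-export in variant-major order")
  if (mode != 1L) stop("unknown .bed mode byte: ", mode)
  bpv <- ceiling(n / 4)  # bytes per variant
  if (length(raw) - 3L != bpv * m)
    stop("truncated or oversized .bed payload: expected ", bpv * m,
         " bytes for ", n, " samples x ", m, " variants, found ",
         length(raw) - 3L)

  # 2-bit fields, little-endian within each byte
  codes <- matrix(0L, nrow = 4L * bpv, ncol = m)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv)
  codes[seq(1, by = 4, length.out = bpv), ] <- body %% 4L
  codes[seq(2, by = 4, length.out = bpv), ] <- (body %/% 4L) %% 4L
  codes[seq(3, by = 4, length.out = bpv), ] <- (body %/% 16L) %% 4L
  codes[seq(4, by = 4, length.out = bpv), ] <- (body %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- c(2L, NA_integer_, 1L, 0L)[codes + 1L]
  dim(dosage) <- c(n, m)

  variants <- data.frame(
    chrom = as.character(bim_df$chrom), pos = bim_df$pos,
    ref = bim_df$a2, alt = bim_df$a1, rsid = bim_df$rsid,
    a1 = bim_df$a1, stringsAsFactors = FALSE)
  genotype_dataset(dosage, fam_df$iid, variants, recode_minor = recode_minor)
}

#' Write a PLINK 1.9 binary trio
#'
#' Inverse of [read_plink()]; padding bits of partial bytes are written as
#' zero. A1 in the .bim is the dataset's counted allele.
#'
#' @param geno a [genotype_dataset].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_plink <- function(geno, prefix) {
  n <- length(geno$samples); m <- nrow(geno$variants)
  v <- geno$variants
  a2 <- ifelse(v$a1 == v$ref, v$alt, v$ref)
  utils::write.table(
    data.frame(v$chrom, v$rsid, 0L, v$pos, v$a1, a2),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(geno$samples, geno$samples, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)

  bpv <- ceiling(n / 4)
  code <- matrix(1L, nrow = 4L * bpv, ncol = m)  # padding encodes as 0 below
  d <- geno$dosage
  cd <- ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])  # dosage->2-bit code
  code[seq_len(n), ] <- cd
  code[setdiff(seq_len(4L * bpv), seq_len(n)), ] <- 0L  # zero padding bits
  i1 <- seq(1, by = 4, length.out = bpv)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1L, , drop = FALSE] +
    16L * code[i1 + 2L, , drop = FALSE] + 64L * code[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(PLINK_MAGIC, as.raw(0x01), as.raw(bytes)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

## ---- VCF --------------------------------------------------------------

#' Read genotypes from a VCF file
#'
#' Parses GT fields (`0/0`, `0/1`, `1/1`, `./.`, phased `|` accepted) into
#' alt-allele dosages, then recodes so that dosage counts the in-sample
#' minor allele. Multi-allelic records are rejected unless `allow_multi`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param allow_multi keep multi-allelic records by treating any non-ref
#'   allele as alt; default `FALSE` (error).
#' @param recode_minor recompute A1 as the in-sample minor allele.
#' @return a [genotype_dataset].
#' @export
read_vcf <- function(path, allow_multi = FALSE, recode_minor = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!"FORMAT" %in% colnames(v@gt))
    stop("VCF has no FORMAT/genotype columns: ", path)
  if (!all(grepl("(^|:)GT($|:)", v@gt[, "FORMAT"])))
    stop("VCF records without a GT field: ", path)
  multi <- grepl(",", fix$ALT)
  if (any(multi) && !allow_multi)
    stop(sum(multi), " multi-allelic record(s); split them or set ",
         "allow_multi = TRUE")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  alt_dosage <- function(g) {
    if (is.na(g) || g %in% c("./.", ".")) return(NA_integer_)
    al <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(as.integer(al) > 0L)
  }
  dosage <- t(apply(gt, 1, function(row) vapply(row, alt_dosage, 0L)))
  if (nrow(gt) == 1) dosage <- matrix(dosage, nrow = 1)
  dosage <- t(dosage)  # samples x variants
  alt1 <- vapply(strsplit(fix$ALT, ","), `[`, "", 1)
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = alt1,
    rsid = ifelse(is.na(fix$ID) | fix$ID == ".",
                  variant_key(fix$CHROM, fix$POS, fix$REF, alt1), fix$ID),
    a1 = alt1, stringsAsFactors = FALSE)
  genotype_dataset(dosage, colnames(gt), variants,
                   recode_minor = recode_minor)
}

#' Write a minimal uncompressed VCF 4.2 (GT only)
#'
#' @param geno a [genotype_dataset].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  # emit alt-allele dosage: flip back where the counted allele is ref
  d <- geno$dosage
  is_ref <- v$a1 == v$ref
  if (any(is_ref)) d[, is_ref] <- 2L - d[, is_ref]
  gt_map <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$samples), collapse = "\t"))
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_map[d[ok] + 1L]
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$rsid[j], v$ref[j], v$alt[j], ".",
            "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

## ---- phenotype, merge -------------------------------------------------

#' Read a phenotype table (CSV with header)
#'
#' First column (or `id_col`) is the sample ID; remaining columns are the
#' outcome and covariates. Validates uniqueness of IDs.
#'
#' @param path CSV file.
#' @param id_col name of the sample-ID column (default: first column).
#' @return data.frame with attribute `id_col`.
#' @export
read_phenotypes <- function(path, id_col = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  id_col <- id_col %||% names(df)[1]
  if (!id_col %in% names(df)) stop("no such ID column: ", id_col)
  df[[id_col]] <- as.character(df[[id_col]])
  if (anyDuplicated(df[[id_col]]))
    stop("duplicated sample IDs in phenotype file")
  attr(df, "id_col") <- id_col
  df
}

#' Merge phenotypes with genotypes on sample ID
#'
#' Inner join; samples missing from either side are dropped with a warning.
#' Row order follows the phenotype table.
#'
#' @param pheno data.frame from [read_phenotypes()] (or any data.frame with
#'   an ID column).
#' @param geno a [genotype_dataset].
#' @param id_col phenotype ID column (default: `attr(pheno, "id_col")` or
#'   the first column).
#' @return list of class `analysis_dataset` with elements `pheno`, `geno`
#'   (subset, phenotype order) and `dropped` (IDs discarded on each side).
#' @export
merge_pheno_geno <- function(pheno, geno, id_col = NULL) {
  id_col <- id_col %||% attr(pheno, "id_col") %||% names(pheno)[1]
  ids <- as.character(pheno[[id_col]])
  shared <- ids[ids %in% geno$samples]
  if (!length(shared))
    stop("no overlapping sample IDs between phenotype (e.g. ",
         paste(utils::head(ids, 3), collapse = ", "), ") and genotype (e.g. ",
         paste(utils::head(geno$samples, 3), collapse = ", "), ")")
  dropped <- list(pheno = setdiff(ids, shared),
                  geno = setdiff(geno$samples, shared))
  n_drop <- length(dropped$pheno) + length(dropped$geno)
  if (n_drop)
    warning(length(dropped$pheno), " phenotype and ", length(dropped$geno),
            " genotype sample(s) had no match and were dropped")
  keep_p <- pheno[ids %in% shared, , drop = FALSE]
  idx <- match(shared, geno$samples)
  sub <- geno
  sub$dosage <- geno$dosage[idx, , drop = FALSE]
  sub$samples <- geno$samples[idx]
  structure(list(pheno = keep_p, geno = sub, id_col = id_col,
                 dropped = dropped),
            class = "analysis_dataset")
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("analysis_dataset:", nrow(x$pheno), "samples,",
      nrow(x$geno$variants), "variants,",
      ncol(x$pheno) - 1L, "phenotype columns\n")
  invisible(x)
}

## ---- SetID ------------------------------------------------------------

#' Read / write a SetID file (gene-unit membership of variants)
#'
#' Two whitespace-delimited columns: set ID, variant ID. Duplicate
#' (set, variant) pairs are dropped with a warning.
#'
#' @param path file path.
#' @return data.frame with columns `set_id`, `variant_id`.
#' @export
read_setid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("SetID parse error at line ", bad[1], ": expected 2 fields, got ",
         length(parts[[bad[1]]]))
  df <- data.frame(set_id = vapply(parts, `[`, "", 1),
                   variant_id = vapply(parts, `[`, "", 2),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sum(dup), " duplicate (set, variant) pair(s) removed")
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' @rdname read_setid
#' @param setid data.frame with columns `set_id`, `variant_id`.
#' @export
write_setid <- function(setid, path) {
  utils::write.table(setid[, c("set_id", "variant_id")], path,
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- reference-population MAF table ------------------------------------

#' Read a reference-population MAF table
#'
#' TSV with header columns `chr`, `pos`, `ref`, `alt`, `maf`. Values in
#' `(0.5, 1]` are interpreted as allele frequencies and folded to
#' `1 - maf` with a warning; duplicate variant keys are an error.
#'
#' @param path TSV file.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `maf`,
#'   `key`; attribute `by_key` is a named MAF vector for lookup.
#' @export
read_maf_reference <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("chr", "pos", "ref", "alt", "maf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("MAF table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$maf < 0 | df$maf > 1))
    stop("maf outside [0, 1] in ", path)
  fold <- df$maf > 0.5
  if (any(fold)) {
    warning(sum(fold), " frequency value(s) > 0.5 folded to the minor ",
            "allele (allele frequency, not MAF, supplied)")
    df$maf[fold] <- 1 - df$maf[fold]
  }
  out <- data.frame(chrom = normalize_chrom(df$chr), pos = as.integer(df$pos),
                    ref = toupper(df$ref), alt = toupper(df$alt),
                    maf = df$maf, stringsAsFactors = FALSE)
  out$key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  if (anyDuplicated(out$key))
    stop("duplicated variant key in MAF table: ",
         out$key[duplicated(out$key)][1])
  by_key <- out$maf
  names(by_key) <- out$key
  attr(out, "by_key") <- by_key
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
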