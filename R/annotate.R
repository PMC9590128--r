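#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; coordinates are converted to 1-based
#' inclusive on read. Columns: chrom, start, end, name (4th column is the
#' gene symbol; required).
#'
#' @param path BED file.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `strand` if a 6th column is present.
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("gene BED needs >= 4 columns (4th = gene name)")
  out <- data.frame(gene = df[[4]], chrom = normalize_chrom(df[[1]]),
                    start = df[[2]] + 1L, end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 6) out$strand <- df[[6]]
  if (any(out$start > out$end)) stop("interval with start > end in ", path)
  dup <- duplicated(out[, c("gene", "chrom", "start", "end")])
  out[!dup, , drop = FALSE]
}

#' Read gene intervals from a GTF file
#'
#' Keeps `gene` features (or collapses transcripts when absent) and
#' extracts `gene_name`/`gene_id` attributes. Requires the rtracklayer
#' package.
#'
#' @param path GTF file.
#' @return data.frame as in [read_gene_bed()].
#' @export
read_gene_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene"))
    gr <- gr[md$type == "gene"]
  md <- S4Vectors::mcols(gr)
  gene <- if ("gene_name" %in% names(md)) md$gene_name else md$gene_id
  out <- data.frame(gene = as.character(gene),
                    chrom = normalize_chrom(as.character(
                      GenomicRanges::seqnames(gr))),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("gene", "chrom", "start", "end")])
  out[!dup, , drop = FALSE]
}

#' Map variants to overlapping genes
#'
#' A variant maps to every gene whose interval, extended by `flank_bp` on
#' both sides, contains its position. Chromosome labels are normalized
#' ("chr1" and "1" match). Overlap is computed with GenomicRanges.
#'
#' @param variants data.frame with columns `chrom`, `pos` and (optionally)
#'   `rsid`, `ref`, `alt` — e.g. the `variants` table of a
#'   [genotype_dataset] or the filtered rows of [functional_analysis()].
#' @param intervals data.frame from [read_gene_bed()] /
#'   [read_gene_gtf()] (columns `gene`, `chrom`, `start`, `end`).
#' @param flank_bp non-negative flank added to each gene interval
#'   (default 0: strict gene-body overlap).
#' @return list with `mapped` (data.frame SNP, Chr, Position, Ref, Alt,
#'   Gene; one row per variant-gene assignment) and `unmapped`
#'   (variants overlapping no gene).
#' @export
map_snps_to_genes <- function(variants, intervals, flank_bp = 0L) {
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!"pos" %in% names(v) && "BP" %in% names(v)) v$pos <- v$BP
  if (!"chrom" %in% names(v) && "CHR" %in% names(v)) v$chrom <- v$CHR
  if (!"rsid" %in% names(v) && "SNP" %in% names(v)) v$rsid <- v$SNP
  stopifnot(all(c("chrom", "pos") %in% names(v)))
  v$chrom <- normalize_chrom(v$chrom)
  v$rsid <- v$rsid %||% paste0("var", seq_len(nrow(v)))
  v$ref <- if ("ref" %in% names(v)) v$ref else NA_character_
  v$alt <- if ("alt" %in% names(v)) v$alt else NA_character_

  iv <- intervals
  iv$chrom <- normalize_chrom(iv$chrom)
  lv <- union(unique(v$chrom), unique(iv$chrom))
  vgr <- GenomicRanges::GRanges(factor(v$chrom, levels = lv),
                                IRanges::IRanges(v$pos, v$pos))
  igr <- GenomicRanges::GRanges(factor(iv$chrom, levels = lv),
    IRanges::IRanges(pmax(1L, iv$start - flank_bp), iv$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(vgr, igr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  mapped <- data.frame(SNP = v$rsid[qi], Chr = v$chrom[qi],
                       Position = v$pos[qi], Ref = v$ref[qi],
                       Alt = v$alt[qi], Gene = iv$gene[si],
                       stringsAsFactors = FALSE)
  mapped <- mapped[order(qi, mapped$Gene), , drop = FALSE]
  mapped <- mapped[!duplicated(mapped[, c("SNP", "Position", "Gene")]), ,
                   drop = FALSE]
  rownames(mapped) <- NULL
  un <- setdiff(seq_len(nrow(v)), unique(qi))
  unmapped <- data.frame(SNP = v$rsid[un], Chr = v$chrom[un],
                         Position = v$pos[un], Ref = v$ref[un],
                         Alt = v$alt[un], stringsAsFactors = FALSE)
  list(mapped = mapped, unmapped = unmapped)
}

#' Build a SetID map from a variant-to-gene map
#'
#' @param genemap the `mapped` data.frame from [map_snps_to_genes()].
#' @return data.frame with columns `set_id` (gene), `variant_id` (SNP).
#' @export
genemap_to_setid <- function(genemap) {
  df <- data.frame(set_id = genemap$Gene, variant_id = genemap$SNP,
                   stringsAsFactors = FALSE)
  df[!duplicated(df), , drop = FALSE]
}

## ---- gene sets --------------------------------------------------------

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes (tab-separated).
#' Duplicate members within a set are dropped.
#'
#' @param path GMT file.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT parse error at line ", bad[1], ": fewer than 3 fields")
  sets <- lapply(parts, function(p) {
    g <- unique(p[-(1:2)])
    attr(g, "description") <- p[2]
    g
  })
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description") %||% "na"
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## ---- over-representation analysis --------------------------------------

# Storey's q-value with a smoothed pi0 estimate over a lambda grid.
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  if (m < 2 || max(p) < max(lambda)) {
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    sp <- try(stats::smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
    pi0 <- if (inherits(sp, "try-error")) min(pi0_l)
           else stats::predict(sp, x = max(lambda))$y
    pi0 <- min(max(pi0, 0), 1)
    if (pi0 <= 0) pi0 <- min(pi0_l[pi0_l > 0], 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pmin(1, cummin(p[o] * m / rank(p, ties.method = "max")[o]))
  q[ro]
}

#' Gene-set over-representation analysis (hypergeometric test)
#'
#' For each set, tests whether the overlap between the query genes and the
#' set exceeds chance when drawing `n` query genes from a universe of `N`
#' genes of which `M` are set members:
#' `p = P(X >= k), X ~ Hypergeometric(N, M, n)`. Benjamini-Hochberg
#' adjustment and a Storey q-value are appended. Sets with no overlap are
#' omitted.
#'
#' @param query_genes character vector of query gene IDs.
#' @param gene_sets named list from [read_gmt()].
#' @param universe background gene universe; default: union of all genes
#'   in `gene_sets`.
#' @param min_overlap report sets with at least this overlap (default 1).
#' @return data.frame with columns ID, GeneRatio ("k/n"), BgRatio
#'   ("M/N"), pvalue, p.adjust, qvalue, geneID ("/"-separated), Count;
#'   sorted by pvalue.
#' @export
ora_test <- function(query_genes, gene_sets, universe = NULL,
                     min_overlap = 1L) {
  universe <- unique(universe %||% unlist(gene_sets, use.names = FALSE))
  N <- length(universe)
  query <- unique(intersect(query_genes, universe))
  n <- length(query)
  if (n == 0) {
    warning("no query genes in the universe; empty result")
    return(data.frame(ID = character(), GeneRatio = character(),
                      BgRatio = character(), pvalue = numeric(),
                      p.adjust = numeric(), qvalue = numeric(),
                      geneID = character(), Count = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(gene_sets[[id]], universe)
    M <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    if (M == 0 || k < min_overlap) return(NULL)
    p <- stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
    data.frame(ID = id, GeneRatio = paste0(k, "/", n),
               BgRatio = paste0(M, "/", N), pvalue = p,
               geneID = paste(sort(hit), collapse = "/"), Count = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no gene set overlaps the query")
    return(data.frame(ID = character(), GeneRatio = character(),
                      BgRatio = character(), pvalue = numeric(),
                      p.adjust = numeric(), qvalue = numeric(),
                      geneID = character(), Count = integer(),
                      stringsAsFactors = FALSE))
  }
  out$p.adjust <- stats::p.adjust(out$pvalue, method = "BH")
  out$qvalue <- storey_qvalue(out$pvalue)
  out <- out[order(out$pvalue),
             c("ID", "GeneRatio", "BgRatio", "pvalue", "p.adjust",
               "qvalue", "geneID", "Count")]
  rownames(out) <- NULL
  out
}
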