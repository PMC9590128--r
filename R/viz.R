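# Plot functions. Every plot writes an image plus a sidecar CSV of the
# plotted coordinates so numeric checks never depend on rendered pixels.

plot_sidecar <- function(file) {
  paste0(tools::file_path_sans_ext(file), "_data.csv")
}

save_plot <- function(p, file, data, width = 8, height = 5) {
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
  utils::write.csv(data, plot_sidecar(file), row.names = FALSE)
  invisible(list(file = file, data = data))
}

chrom_order <- function(chr) {
  lv <- c(as.character(1:22), "X", "Y", "MT")
  factor(normalize_chrom(chr), levels = c(lv, setdiff(unique(
    normalize_chrom(chr)), lv)))
}

#' Manhattan plot of a variant association scan
#'
#' x: cumulative genomic position grouped by chromosome (1..22, X, Y);
#' y: `-log10(P)`; horizontal lines mark the suggestive (`sig_val`) and
#' genome-wide (`geno_val`) thresholds on the `-log10` scale (defaults 3
#' and 5, i.e. p = 1e-3 and 1e-5).
#'
#' @param assoc a `functional_analysis` result or data.frame with columns
#'   CHR, BP, P (SNP optional).
#' @param file output image path (.png/.svg); a sidecar `*_data.csv`
#'   holds the plotted coordinates.
#' @param sig_val,geno_val threshold lines, `-log10 p` units.
#' @return invisibly, `list(file, data)`.
#' @export
plot_manhattan <- function(assoc, file, sig_val = 3, geno_val = 5) {
  if (geno_val < sig_val) stop("geno_val must be >= sig_val")
  df <- if (inherits(assoc, "functional_analysis")) assoc$assoc else assoc
  df <- df[!is.na(df$P), , drop = FALSE]
  if (!nrow(df)) stop("no p-values to plot")
  df$chrom_f <- chrom_order(df$CHR)
  df <- df[order(df$chrom_f, df$BP), , drop = FALSE]
  offs <- c(0, cumsum(tapply(as.numeric(df$BP), df$chrom_f, max,
                             default = 0)))
  names(offs) <- c(levels(df$chrom_f), "end")
  df$x <- as.numeric(df$BP) + offs[as.character(df$chrom_f)]
  df$y <- -log10(df$P)
  data <- data.frame(SNP = df$SNP %||% NA, CHR = as.character(df$chrom_f),
                     BP = df$BP, P = df$P, x = df$x, y = df$y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$chrom_f)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = sig_val, colour = "purple",
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = geno_val, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "genomic position", y = expression(-log[10](P))) +
    ggplot2::theme_minimal()
  save_plot(p, file, data)
}

#' Quantile-quantile plot of association p-values
#'
#' Expected `-log10` uniform quantiles `(i - 0.5)/n` against sorted
#' observed values, annotated with the genomic inflation factor from
#' [genomic_lambda()].
#'
#' @inheritParams plot_manhattan
#' @return invisibly, `list(file, data, lambda)`.
#' @export
plot_qq <- function(assoc, file) {
  df <- if (inherits(assoc, "functional_analysis")) assoc$assoc else assoc
  p <- df$P[!is.na(df$P)]
  if (!length(p)) stop("no p-values to plot")
  n <- length(p)
  obs <- -log10(sort(p))
  exp <- -log10((seq_len(n) - 0.5) / n)
  lambda <- genomic_lambda(p)
  data <- data.frame(expected = exp, observed = obs)
  g <- ggplot2::ggplot(data, ggplot2::aes(x = .data$expected,
                                          y = .data$observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::annotate("text", x = max(exp) * 0.15, y = max(obs) * 0.95,
                      label = sprintf("lambda == %.3f", lambda),
                      parse = TRUE) +
    ggplot2::labs(x = expression(Expected ~ -log[10](P)),
                  y = expression(Observed ~ -log[10](P))) +
    ggplot2::theme_minimal()
  out <- save_plot(g, file, data, width = 5, height = 5)
  out$lambda <- lambda
  invisible(out)
}

#' Pairwise linkage-disequilibrium heatmap
#'
#' r-squared is the squared Pearson correlation of dosage vectors
#' (complete cases per pair), computed for variants whose association
#' p-value passes `p_threshold`, rendered in genomic order.
#'
#' @param geno a [genotype_dataset].
#' @param assoc association table with columns SNP and P (optional; when
#'   omitted all variants enter).
#' @param file output image path.
#' @param p_threshold p cutoff for variants entering the panel
#'   (default 0.001).
#' @return invisibly, `list(file, data, r2)` where `r2` is the matrix.
#' @export
plot_ld <- function(geno, assoc = NULL, file, p_threshold = 0.001) {
  keep <- seq_len(nrow(geno$variants))
  if (!is.null(assoc)) {
    df <- if (inherits(assoc, "functional_analysis")) assoc$assoc else assoc
    ok <- df$SNP[!is.na(df$P) & df$P < p_threshold]
    keep <- which(geno$variants$rsid %in% ok)
  }
  if (length(keep) < 2)
    stop("fewer than 2 variants pass the LD p-value threshold")
  v <- geno$variants[keep, , drop = FALSE]
  ord <- order(chrom_order(v$chrom), v$pos)
  keep <- keep[ord]; v <- v[ord, , drop = FALSE]
  D <- geno$dosage[, keep, drop = FALSE]
  r2 <- suppressWarnings(
    stats::cor(D, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  dimnames(r2) <- list(v$rsid, v$rsid)
  data <- data.frame(snp1 = rep(v$rsid, times = ncol(r2)),
                     snp2 = rep(v$rsid, each = nrow(r2)),
                     r2 = as.vector(r2))
  g <- ggplot2::ggplot(data, ggplot2::aes(
         x = factor(.data$snp1, levels = v$rsid),
         y = factor(.data$snp2, levels = v$rsid), fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
  out <- save_plot(g, file, data, width = 6, height = 5.5)
  out$r2 <- r2
  invisible(out)
}

#' Bar plot of significant gene-level results
#'
#' One bar per gene with `P.value < pval`, height `-log10(P.value)`.
#'
#' @param skat a `skat_result` data.frame.
#' @param file output image path.
#' @param pval gene significance cutoff (default 1e-4).
#' @param width,space bar width and spacing.
#' @return invisibly, `list(file, data)`.
#' @export
plot_gene_bar <- function(skat, file, pval = 1e-4, width = 0.5,
                          space = 1) {
  if (!nrow(skat)) stop("empty result table")
  df <- skat[!is.na(skat$P.value) & skat$P.value < pval, , drop = FALSE]
  if (!nrow(df)) {
    warning("no genes pass the p-value cutoff; writing an empty plot")
    df <- skat[0, , drop = FALSE]
  }
  data <- data.frame(gene = df$SetID, P = df$P.value,
                     height = -log10(df$P.value))
  g <- ggplot2::ggplot(data, ggplot2::aes(
         x = stats::reorder(.data$gene, -.data$height),
         y = .data$height)) +
    ggplot2::geom_col(width = width / (width + space) , fill = "steelblue") +
    ggplot2::labs(x = NULL, y = expression(-log[10](P))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  save_plot(g, file, data, width = 6, height = 4)
}
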