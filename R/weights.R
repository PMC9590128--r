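#' Logistic collapsing weight from a reference-population MAF
#'
#' `weight = exp(-x1) / (1 + exp(-x1))` with `x1 = (maf - w1) * w2`: a
#' numerically stable sigmoid that equals 0.5 at `maf = w1`, approaches 1
#' for rare variants and 0 for common ones. Defaults `w1 = 0.07`,
#' `w2 = 150` put the transition midpoint at 7% MAF with weight > 0.99
#' below ~3.7% and < 0.01 above ~10.3%.
#'
#' @param maf minor allele frequency / frequencies in `[0, 0.5]` (fold
#'   allele frequencies first).
#' @param w1 transition midpoint on the MAF scale (default 0.07).
#' @param w2 slope, dimensionless and positive (default 150).
#' @return weights in `(0, 1)`.
#' @export
logistic_weight <- function(maf, w1 = 0.07, w2 = 150) {
  if (w2 <= 0) stop("w2 must be positive")
  if (w1 < 0 || w1 > 0.5) stop("w1 must be in [0, 0.5]")
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("maf must be in [0, 0.5]; fold allele frequencies first")
  stats::plogis(-(maf - w1) * w2)
}

#' Beta-density collapsing weight
#'
#' The Beta(1, 25) density evaluated at the MAF, the conventional
#' default weighting of the sequence kernel association test.
#'
#' @param maf MAF in `(0, 0.5]` (0 allowed when `a >= 1`).
#' @param a,b Beta shape parameters (defaults 1 and 25).
#' @return density weights (positive).
#' @export
beta_weight <- function(maf, a = 1, b = 25) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("maf must be in [0, 0.5]")
  if (a < 1 && any(maf == 0, na.rm = TRUE))
    stop("maf = 0 with shape a < 1 gives an infinite weight")
  stats::dbeta(maf, a, b)
}

#' Per-variant collapsing weights from a reference-population MAF table
#'
#' Looks each variant up in the reference table by (chrom, pos, ref, alt);
#' if unmatched, retries with ref/alt swapped and the frequency folded
#' (allele orientation differs across population resources). Variants
#' still unmatched are handled per `fallback`:
#' `"sample_maf"` (default) uses the supplied in-sample MAF, `"exclude"`
#' drops the variant, `"unit_weight"` assigns weight 1. Output is sorted
#' by weight, descending.
#'
#' @param variants data.frame with columns `chrom`/`chr`, `pos`, `ref`,
#'   `alt` (the stage-1 filtered list), optionally `rsid`.
#' @param maf_table result of [read_maf_reference()].
#' @param scheme `"logistic"` (default) or `"beta"`.
#' @param w1,w2 logistic parameters (see [logistic_weight()]).
#' @param a,b Beta shapes (see [beta_weight()]).
#' @param fallback policy for variants absent from the table.
#' @param sample_maf named numeric vector of in-sample MAFs keyed by
#'   [variant_key()] (required when `fallback = "sample_maf"` and any
#'   variant is unmatched).
#' @return data.frame with columns `chr`, `pos`, `ref`, `alt`, `maf`,
#'   `weight`, `source` ("reference", "reference_swapped" or "fallback"),
#'   sorted by descending weight.
#' @export
get_logistic_weights <- function(variants, maf_table,
                                 scheme = c("logistic", "beta"),
                                 w1 = 0.07, w2 = 150, a = 1, b = 25,
                                 fallback = c("sample_maf", "exclude",
                                              "unit_weight"),
                                 sample_maf = NULL) {
  scheme <- match.arg(scheme)
  fallback <- match.arg(fallback)
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if ("chr" %in% names(v) && !"chrom" %in% names(v)) v$chrom <- v$chr
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(v)))
  if (!nrow(v)) stop("empty variant list")
  lookup <- attr(maf_table, "by_key")
  key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  key_sw <- variant_key(v$chrom, v$pos, v$alt, v$ref)
  maf <- unname(lookup[key])
  source <- ifelse(is.na(maf), NA_character_, "reference")
  sw <- is.na(maf) & key_sw %in% names(lookup)
  # the table stores folded MAFs, so a swapped match needs no re-fold
  maf[sw] <- unname(lookup[key_sw[sw]])
  source[sw] <- "reference_swapped"

  un <- is.na(maf)
  weight_unit <- rep(NA_real_, nrow(v))
  if (any(un)) {
    if (fallback == "exclude") {
      message(sum(un), " variant(s) absent from the MAF table excluded")
    } else if (fallback == "sample_maf") {
      if (is.null(sample_maf))
        stop(sum(un), " variant(s) absent from the MAF table; supply ",
             "sample_maf or choose another fallback")
      maf[un] <- unname(sample_maf[key[un]])
      if (anyNA(maf[un]))
        stop("no in-sample MAF available for ",
             key[un][is.na(maf[un])][1])
      source[un] <- "fallback"
      warning(sum(un), " variant(s) weighted from the in-sample MAF")
    } else { # unit_weight
      weight_unit[un] <- 1
      source[un] <- "fallback"
      warning(sum(un), " variant(s) assigned unit weight")
    }
  }
  keep <- if (fallback == "exclude") !un else rep(TRUE, nrow(v))
  out <- data.frame(chr = v$chrom[keep], pos = v$pos[keep],
                    ref = v$ref[keep], alt = v$alt[keep],
                    maf = maf[keep], stringsAsFactors = FALSE)
  if ("rsid" %in% names(v)) out$rsid <- v$rsid[keep]
  w <- ifelse(!is.na(weight_unit[keep]), weight_unit[keep],
              if (scheme == "logistic") logistic_weight(out$maf, w1, w2)
              else beta_weight(out$maf, a, b))
  out$weight <- w
  out$source <- source[keep]
  out <- out[order(-out$weight), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a weight table as CSV
#'
#' @param weights data.frame from [get_logistic_weights()].
#' @param path output CSV.
#' @param pop_label column label for the weight column (e.g. the
#'   reference-population name); default `"weights"`.
#' @export
write_weights <- function(weights, path, pop_label = "weights") {
  df <- weights[, c("chr", "pos", "ref", "alt", "weight")]
  names(df)[5] <- pop_label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
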