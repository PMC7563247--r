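#' Transcripts-per-million normalization of a count matrix
#'
#' Per sample, each gene's count is divided by its length to give a read
#' rate, and rates are rescaled to sum to 10^6:
#' `TPM_g = 1e6 * (count_g / length_g) / sum_g' (count_g' / length_g')`.
#' The denominator runs over ALL genes in the matrix, annotated or not.
#' A sample with zero total counts yields an all-zero column, not NaN.
#'
#' @param counts Numeric gene x sample matrix (row names = gene ids).
#'   Non-negative; fractional counts are accepted.
#' @param genes Gene catalog data frame with `gene_id` and `length` (bp,
#'   > 0) covering every row of `counts`.
#' @return Gene x sample TPM matrix with the same dimnames.
#' @examples
#' m <- matrix(c(10, 10), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
#' compute_tpm(m, data.frame(gene_id = c("g1", "g2"), length = c(100, 400)))
#' @export
compute_tpm <- function(counts, genes) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts", call. = FALSE)
  len <- genes$length[match(rownames(counts), genes$gene_id)]
  if (anyNA(len)) {
    stop("genes without a length: ",
         paste(utils::head(rownames(counts)[is.na(len)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(len <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  rate <- counts / len
  tot <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm[, tot == 0] <- 0
  tpm
}

#' Aggregate gene-level TPM into KO functional profiles
#'
#' Sums member-gene TPM per KO and sample. Genes without a KO contribute to
#' no row of the profile but remain in the TPM denominator upstream, so
#' per-sample KO totals are below 10^6 whenever unannotated genes exist.
#'
#' @param tpm Gene x sample TPM matrix.
#' @param genes Gene catalog with `gene_id` and `ko` (`NA` = unannotated).
#' @return KO x sample matrix (rows sorted by KO).
#' @export
aggregate_by_ko_tpm <- function(tpm, genes) {
  ko <- genes$ko[match(rownames(tpm), genes$gene_id)]
  keep <- !is.na(ko) & nzchar(ko)
  if (!any(keep)) {
    return(matrix(numeric(0), nrow = 0, ncol = ncol(tpm),
                  dimnames = list(character(0), colnames(tpm))))
  }
  sub <- tpm[keep, , drop = FALSE]
  out <- rowsum(sub, group = ko[keep], reorder = TRUE)
  as.matrix(out)
}

#' RNA:DNA expression ratios per KO
#'
#' Elementwise `RNA_TPM / DNA_TPM` over the union of the two KO universes
#' (a KO absent from one profile counts as 0 there). A zero DNA TPM makes
#' the ratio undefined: those entries are `NA`, never infinite. Zero RNA
#' over positive DNA is 0.
#'
#' Columns are paired positionally: the i-th RNA library is divided by the
#' i-th DNA library (metagenome and metatranscriptome libraries of the same
#' biological sample carry different library ids). The result keeps the RNA
#' column names.
#'
#' @param rna,dna KO x sample TPM matrices with equally many, positionally
#'   paired sample columns.
#' @return KO x sample ratio matrix over the union of KOs.
#' @export
expression_ratio <- function(rna, dna) {
  if (ncol(rna) != ncol(dna)) {
    stop("RNA and DNA profiles must have equally many, positionally paired ",
         "sample columns", call. = FALSE)
  }
  kos <- sort(union(rownames(rna), rownames(dna)))
  full <- function(m) {
    out <- matrix(0, nrow = length(kos), ncol = ncol(m),
                  dimnames = list(kos, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  r <- full(rna); d <- full(dna)
  ratio <- r / d
  ratio[d == 0] <- NA_real_
  ratio
}

#' Restrict a functional profile to catalog KOs
#'
#' @param profile KO x sample matrix.
#' @param catalog MRG catalog; row order of the result follows the catalog.
#' @return The restricted matrix (catalog KOs present in the profile, in
#'   catalog order).
#' @export
mrg_subset_profile <- function(profile, catalog) {
  keep <- catalog$ko[catalog$ko %in% rownames(profile)]
  profile[keep, , drop = FALSE]
}

#' Fraction of annotated genes that are MRGs
#'
#' Of the KO-annotated genes, the proportion whose KO belongs to the MRG
#' catalog. With `denominator = "all"` the denominator is instead every
#' gene in the catalog table (both readings of "annotated genes" are
#' defensible; the KO-annotated denominator is the default).
#'
#' @param genes Gene catalog with `ko` column.
#' @param catalog MRG catalog.
#' @param denominator `"ko_annotated"` (default) or `"all"`.
#' @return A proportion in `[0, 1]`.
#' @export
annotated_fraction <- function(genes, catalog,
                               denominator = c("ko_annotated", "all")) {
  denominator <- match.arg(denominator)
  annotated <- !is.na(genes$ko) & nzchar(genes$ko)
  if (!any(annotated)) {
    stop("no KO-annotated genes", call. = FALSE)
  }
  n_mrg <- sum(genes$ko[annotated] %in% catalog$ko)
  denom <- if (denominator == "ko_annotated") sum(annotated) else nrow(genes)
  n_mrg / denom
}

#' Roll MRG TPM up to (domain, mechanism) cells
#'
#' Sums the TPM of catalog member genes into domain x mechanism cells per
#' sample. Totals are conserved: summing the rollup per sample equals the
#' per-sample total of [mrg_subset_profile()] applied to the KO profile.
#'
#' @param tpm Gene x sample TPM matrix.
#' @param genes Gene catalog with `gene_id`, `ko`, `domain`.
#' @param catalog MRG catalog (`ko`, `mechanism`).
#' @return Long-format data frame: `domain`, `mechanism`, one column per
#'   sample.
#' @export
domain_mechanism_rollup <- function(tpm, genes, catalog) {
  idx <- match(rownames(tpm), genes$gene_id)
  ko <- genes$ko[idx]
  domain <- genes$domain[idx]
  in_cat <- !is.na(ko) & ko %in% catalog$ko
  if (!any(in_cat)) {
    return(data.frame(domain = character(), mechanism = character()))
  }
  no_dom <- in_cat & (is.na(domain) | !nzchar(domain))
  if (any(no_dom)) {
    stop("profiled gene(s) without a domain label: ",
         paste(utils::head(rownames(tpm)[no_dom]), collapse = ", "),
         call. = FALSE)
  }
  mech <- catalog$mechanism[match(ko[in_cat], catalog$ko)]
  key <- paste(domain[in_cat], mech, sep = "\r")
  sums <- rowsum(tpm[in_cat, , drop = FALSE], group = key, reorder = TRUE)
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  out <- data.frame(domain = parts[, 1], mechanism = parts[, 2],
                    as.matrix(sums), check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sign of the expression-vs-concentration trend
#'
#' Ordinary least-squares slope of expression ratio against concentration
#' across layers; only the sign is reported (no significance is implied).
#' Slopes with magnitude below `tol` are `"flat"`. Layers with undefined
#' expression are dropped; at least two defined points are required (with
#' exactly two, the slope is the difference quotient).
#'
#' @param expression Named numeric vector of expression ratios per layer.
#' @param concentration Named numeric vector of concentrations (ug/L) per
#'   layer; names must cover those of `expression`.
#' @param tol Flatness threshold on |slope| (default 1e-12).
#' @return `"positive"`, `"negative"` or `"flat"`.
#' @examples
#' slope_sign(c(a = 1, b = 2, c = 3), c(a = 10, b = 20, c = 30))
#' @export
slope_sign <- function(expression, concentration, tol = 1e-12) {
  ok <- !is.na(expression)
  if (sum(ok) < 2) {
    stop("need at least two layers with defined expression", call. = FALSE)
  }
  y <- expression[ok]
  x <- concentration[names(y)]
  if (anyNA(x)) stop("missing concentration for a layer", call. = FALSE)
  slope <- coef(lm(y ~ x))[["x"]]
  if (is.na(slope) || abs(slope) < tol) "flat"
  else if (slope > 0) "positive"
  else "negative"
}
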