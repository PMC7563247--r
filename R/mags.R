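#' MIMAG quality tier of a genome bin
#'
#' Classifies (completeness, contamination) pairs: `"failed"` when
#' contamination >= 10%, `"low"` below 50% completeness, `"medium"` at
#' >= 50% completeness and < 10% contamination. The `"high"` tier
#' additionally requires >= 90% completeness, < 5% contamination AND
#' rRNA/tRNA evidence; without that evidence the tier is capped at
#' `"medium"` regardless of the numbers.
#'
#' @param completeness Completeness %, in `[0, 100]` (vectorized).
#' @param contamination Contamination %, >= 0 (vectorized).
#' @param has_rrna_trna_info Logical: is the 16S/23S/5S rRNA + tRNA
#'   evidence for the high tier available? Default `FALSE`.
#' @return Character vector in `{"high", "medium", "low", "failed"}`.
#' @examples
#' classify_mimag(100, 1)    # "medium" (no rRNA/tRNA evidence)
#' classify_mimag(40, 2)     # "low"
#' @export
classify_mimag <- function(completeness, contamination,
                           has_rrna_trna_info = FALSE) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE) ||
      anyNA(completeness)) {
    stop("completeness must lie in [0, 100]", call. = FALSE)
  }
  if (any(contamination < 0, na.rm = TRUE) || anyNA(contamination)) {
    stop("contamination must be >= 0", call. = FALSE)
  }
  n <- max(length(completeness), length(contamination))
  completeness <- rep_len(completeness, n)
  contamination <- rep_len(contamination, n)
  has_rrna_trna_info <- rep_len(has_rrna_trna_info, n)
  out <- rep("medium", n)
  out[completeness < 50] <- "low"
  out[contamination >= 10] <- "failed"
  high <- completeness >= 90 & contamination < 5 & has_rrna_trna_info &
    out == "medium"
  out[high] <- "high"
  out
}

#' Split MAGs by mapped-mRNA read count
#'
#' MAGs with fewer than `min_reads` mapped mRNA reads carry too little
#' transcriptional signal for expression analysis and are excluded
#' ("less than" is strict: a MAG at exactly the threshold is kept).
#'
#' @param mags Data frame with `mag_id` and `mrna_reads`.
#' @param min_reads Minimum mapped mRNA reads (default 500).
#' @return A list with `kept` and `excluded` data frames.
#' @export
filter_by_mrna <- function(mags, min_reads = 500) {
  stopifnot(all(c("mag_id", "mrna_reads") %in% names(mags)))
  keep <- !is.na(mags$mrna_reads) & mags$mrna_reads >= min_reads
  list(kept = mags[keep, , drop = FALSE],
       excluded = mags[!keep, , drop = FALSE])
}

#' Greedy ANI dereplication of MAGs
#'
#' Keeps one representative per species-level cluster: candidates are
#' visited in descending quality score (`completeness - 5 * contamination`,
#' ties broken by `mag_id`) and kept only when their ANI to every
#' already-kept representative is below the threshold. The score is a
#' deliberate simplification of full dereplication scoring, adequate for
#' the selection rule itself.
#'
#' @param mags Data frame with `mag_id`, `completeness`, `contamination`.
#' @param ani Square symmetric ANI matrix (%) with dimnames matching
#'   `mags$mag_id`; diagonal 100.
#' @param threshold Species boundary ANI % (default 96.5); pairs at or
#'   above it are treated as the same species-level unit.
#' @return The kept rows of `mags`, ordered by descending score.
#' @export
dereplicate_by_ani <- function(mags, ani, threshold = 96.5) {
  ids <- mags$mag_id
  if (!is.matrix(ani) || nrow(ani) != ncol(ani) ||
      !setequal(rownames(ani), ids) || !setequal(colnames(ani), ids)) {
    stop("ANI matrix dimnames must match mags$mag_id", call. = FALSE)
  }
  if (max(abs(ani - t(ani))) > 1e-6) {
    stop("ANI matrix must be symmetric", call. = FALSE)
  }
  score <- mags$completeness - 5 * mags$contamination
  ord <- order(-score, ids)
  kept <- character(0)
  for (i in ord) {
    id <- ids[i]
    if (length(kept) == 0 || all(ani[id, kept] < threshold)) {
      kept <- c(kept, id)
    }
  }
  out <- mags[match(kept, ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-MAG MRG gene, transcript and expression matrices
#'
#' For each MAG, TPM is computed over that MAG's own genes only (so rows
#' are comparable across MAGs of different sizes), aggregated per KO,
#' restricted to the MRG catalog, and the RNA:DNA ratio is formed as in
#' [expression_ratio()]. Single-sample count vectors are expected (one DNA
#' and one mRNA library mapped per MAG).
#'
#' @param genes Gene catalog with `gene_id`, `length`, `ko`, `mag_id`.
#' @param dna_counts,rna_counts Gene x 1 count matrices (or named vectors)
#'   covering the genes.
#' @param catalog MRG catalog.
#' @return A list of MAG x KO matrices `gene_tpm`, `transcript_tpm`,
#'   `expression` (KO columns follow catalog order; expression is `NA`
#'   where the gene TPM is 0).
#' @export
per_mag_mrg_matrix <- function(genes, dna_counts, rna_counts, catalog) {
  as_col <- function(x) {
    if (is.matrix(x)) x[, 1, drop = FALSE]
    else matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
  }
  dna <- as_col(dna_counts)
  rna <- as_col(rna_counts)
  binned <- genes[!is.na(genes$mag_id) & nzchar(genes$mag_id), , drop = FALSE]
  mag_ids <- sort(unique(binned$mag_id))
  kos <- catalog$ko
  shape <- function() {
    matrix(NA_real_, nrow = length(mag_ids), ncol = length(kos),
           dimnames = list(mag_ids, kos))
  }
  gene_tpm <- shape(); transcript_tpm <- shape(); expression <- shape()
  for (mg in mag_ids) {
    sub <- binned[binned$mag_id == mg, , drop = FALSE]
    dn <- dna[sub$gene_id, , drop = FALSE]
    rn <- rna[sub$gene_id, , drop = FALSE]
    if (sum(dn) == 0) {
      warning("MAG ", mg, " has zero total DNA counts; all-zero row",
              call. = FALSE)
    }
    d_ko <- aggregate_by_ko_tpm(compute_tpm(dn, sub), sub)
    r_ko <- aggregate_by_ko_tpm(compute_tpm(rn, sub), sub)
    fill <- function(m) {
      v <- setNames(rep(0, length(kos)), kos)
      hit <- intersect(rownames(m), kos)
      v[hit] <- m[hit, 1]
      v
    }
    gene_tpm[mg, ] <- fill(d_ko)
    transcript_tpm[mg, ] <- fill(r_ko)
    ex <- transcript_tpm[mg, ] / gene_tpm[mg, ]
    ex[gene_tpm[mg, ] == 0] <- NA_real_
    expression[mg, ] <- ex
  }
  list(gene_tpm = gene_tpm, transcript_tpm = transcript_tpm,
       expression = expression)
}
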