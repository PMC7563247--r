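# Small in-code fixtures shared across test files.

# minimal two-component thermo set (activities optional), M2+ + L2- <-> ML
toy_thermo <- function(log10_K = 3) {
  list(components = c(M = 2, L = -2),
       complexes = list(list(name = "ML",
                             stoichiometry = c(M = 1, L = 1),
                             log10_K = log10_K, charge = 0)))
}

# closed-form free-metal concentration for M + L <-> ML without activities:
# K l^2 + (1 + K (M_T - L_T)) l - L_T = 0, m = M_T / (1 + K l)
quadratic_free_metal <- function(K, M_T, L_T) {
  a <- K
  b <- 1 + K * (M_T - L_T)
  cc <- -L_T
  l <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  M_T / (1 + K * l)
}

toy_gene_catalog <- function() {
  data.frame(
    gene_id = paste0("g", 1:6),
    length = c(100, 400, 200, 200, 500, 250),
    ko = c("K00001", "K00001", "K00002", NA, "K00003", "K00002"),
    evalue = 1e-10,
    domain = c("Bacteria", "Bacteria", "Archaea", "Bacteria", "Eukaryota",
               "Archaea"),
    mag_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

toy_counts <- function(genes = toy_gene_catalog(), values = NULL) {
  if (is.null(values)) values <- seq_len(2 * nrow(genes))
  matrix(values, nrow = nrow(genes), ncol = 2,
         dimnames = list(genes$gene_id, c("s1", "s2")))
}

# brute-force KO aggregation oracle: explicit loops, no shared code path
brute_force_ko_sum <- function(tpm, genes) {
  kos <- sort(unique(genes$ko[!is.na(genes$ko)]))
  out <- matrix(0, length(kos), ncol(tpm), dimnames = list(kos, colnames(tpm)))
  for (k in kos) {
    for (s in colnames(tpm)) {
      tot <- 0
      for (g in rownames(tpm)) {
        gko <- genes$ko[genes$gene_id == g]
        if (!is.na(gko) && gko == k) tot <- tot + tpm[g, s]
      }
      out[k, s] <- tot
    }
  }
  out
}

# brute-force group-by for BacMet-style KO aggregation
brute_force_aggregate <- function(bacmet, hits) {
  kos <- sort(unique(hits$ko))
  rows <- lapply(kos, function(k) {
    ids <- hits$subject_id[hits$ko == k]
    symbols <- character(0); comps <- character(0)
    for (id in ids) {
      rec <- bacmet[bacmet$bacmet_id == id, ]
      symbols <- c(symbols, rec$gene_symbol)
      comps <- c(comps, trimws(strsplit(rec$compounds, ",")[[1]]))
    }
    data.frame(ko = k,
               gene_symbols = paste(sort(unique(symbols)), collapse = ","),
               compounds = paste(sort(unique(comps)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
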