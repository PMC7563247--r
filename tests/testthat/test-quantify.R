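test_that("TPM matches the hand-computed two-gene example", {
  genes <- data.frame(gene_id = c("g1", "g2"), length = c(100, 400))
  m <- matrix(c(10, 10), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- compute_tpm(m, genes)
  # rates 0.1 and 0.025 -> shares 0.8 / 0.2
  expect_equal(unname(tpm[, 1]), c(800000, 200000))
})

test_that("TPM normalization edge cases behave", {
  genes <- data.frame(gene_id = "g1", length = 300)
  one <- matrix(7, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(unname(compute_tpm(one, genes)[1, 1]), 1e6)
  # all-zero sample gives zeros, never NaN
  genes2 <- data.frame(gene_id = c("g1", "g2"), length = c(100, 200))
  z <- matrix(c(5, 3, 0, 0), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2")))
  tpm <- compute_tpm(z, genes2)
  expect_equal(unname(tpm[, "s2"]), c(0, 0))
  expect_equal(sum(tpm[, "s1"]), 1e6)
  expect_error(compute_tpm(z, data.frame(gene_id = "g1", length = 100)),
               "without a length")
  genes2$length[1] <- 0
  expect_error(compute_tpm(z, genes2), "> 0")
})

test_that("TPM columns sum to 1e6 whenever a sample has reads", {
  set.seed(3)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      length = sample(100:5000, 200, TRUE))
  counts <- matrix(rpois(200 * 4, 50), 200, 4,
                   dimnames = list(genes$gene_id, paste0("s", 1:4)))
  tpm <- compute_tpm(counts, genes)
  expect_equal(unname(colSums(tpm)), rep(1e6, 4), tolerance = 1e-6)
})

test_that("KO aggregation sums member genes and drops unannotated ones", {
  genes <- toy_gene_catalog()
  tpm <- compute_tpm(toy_counts(genes), genes)
  prof <- aggregate_by_ko_tpm(tpm, genes)
  expect_setequal(rownames(prof), c("K00001", "K00002", "K00003"))
  # mass conservation over annotated genes
  annotated <- genes$gene_id[!is.na(genes$ko)]
  expect_equal(colSums(prof), colSums(tpm[annotated, ]))
  # g4 (no KO) contributes to no row but stays in the denominator
  expect_lt(sum(prof[, 1]), 1e6)
})

test_that("KO aggregation equals the brute-force oracle on a toy table", {
  set.seed(21)
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    length = sample(200:2000, 20),
    ko = sample(c("K00001", "K00002", "K00003", "K00004", NA), 20, TRUE)
  )
  tpm <- compute_tpm(matrix(rpois(40, 30), 20, 2,
                            dimnames = list(genes$gene_id, c("a", "b"))),
                     genes)
  expect_equal(aggregate_by_ko_tpm(tpm, genes),
               brute_force_ko_sum(tpm, genes))
})

test_that("gene order never changes TPM or KO profiles", {
  genes <- toy_gene_catalog()
  counts <- toy_counts(genes)
  set.seed(5)
  perm <- sample(nrow(genes))
  tpm1 <- compute_tpm(counts, genes)
  tpm2 <- compute_tpm(counts[perm, ], genes[perm, ])
  expect_equal(tpm2[rownames(tpm1), ], tpm1)
  expect_equal(aggregate_by_ko_tpm(tpm2, genes[perm, ]),
               aggregate_by_ko_tpm(tpm1, genes))
})

test_that("expression ratios handle zero denominators as missing", {
  rna <- matrix(c(500, 300, 0), 3, 1,
                dimnames = list(c("K00001", "K00002", "K00003"), "s1"))
  dna <- matrix(c(500, 0, 200), 3, 1,
                dimnames = list(c("K00001", "K00002", "K00003"), "s1"))
  ex <- expression_ratio(rna, dna)
  expect_equal(ex["K00001", 1], 1.0)
  expect_true(is.na(ex["K00002", 1]))   # RNA without DNA: undefined
  expect_equal(ex["K00003", 1], 0)      # DNA without RNA: zero
  expect_false(any(is.infinite(ex)))
})

test_that("expression ratio outer-joins the KO universes", {
  rna <- matrix(10, 1, 1, dimnames = list("K00001", "s1"))
  dna <- matrix(20, 1, 1, dimnames = list("K00002", "s1"))
  ex <- expression_ratio(rna, dna)
  expect_setequal(rownames(ex), c("K00001", "K00002"))
  expect_true(is.na(ex["K00001", 1]))  # DNA absent = 0 -> missing
  expect_equal(ex["K00002", 1], 0)
  expect_error(expression_ratio(rna, cbind(dna, dna)),
               "equally many")
})

test_that("MRG subsetting follows catalog order", {
  prof <- matrix(1:5, 5, 1,
                 dimnames = list(paste0("K0000", 1:5), "s1"))
  cat2 <- data.frame(ko = c("K00004", "K00002"))
  sub <- mrg_subset_profile(prof, cat2)
  expect_equal(rownames(sub), c("K00004", "K00002"))
  expect_equal(nrow(mrg_subset_profile(prof, data.frame(ko = character(0)))),
               0)
})

test_that("annotated MRG fraction counts catalog KOs among annotated genes", {
  genes <- data.frame(gene_id = paste0("g", 1:4),
                      ko = c("K00001", "K00002", NA, "K00003"))
  cat3 <- data.frame(ko = c("K00001", "K00002", "K00003"))
  expect_equal(annotated_fraction(genes, cat3), 1.0)
  expect_equal(annotated_fraction(genes, data.frame(ko = "K99999")), 0.0)
  expect_equal(annotated_fraction(genes, data.frame(ko = "K00001")), 1 / 3)
  expect_equal(annotated_fraction(genes, data.frame(ko = "K00001"),
                                  denominator = "all"), 1 / 4)
  expect_error(annotated_fraction(data.frame(gene_id = "g", ko = NA),
                                  cat3), "no KO-annotated")
})

test_that("domain-mechanism rollup matches a hand-computed 2x2 table", {
  genes <- data.frame(
    gene_id = paste0("g", 1:5),
    length = 100,
    ko = c("K00001", "K00002", "K00001", "K00002", NA),
    domain = c("Bacteria", "Bacteria", "Archaea", "Archaea", "Bacteria")
  )
  cat2 <- data.frame(ko = c("K00001", "K00002"),
                     mechanism = c("Export", "Import"))
  tpm <- matrix(c(100, 200, 300, 400, 500), 5, 1,
                dimnames = list(genes$gene_id, "s1"))
  roll <- domain_mechanism_rollup(tpm, genes, cat2)
  get <- function(d, m) roll$s1[roll$domain == d & roll$mechanism == m]
  expect_equal(get("Bacteria", "Export"), 100)
  expect_equal(get("Bacteria", "Import"), 200)
  expect_equal(get("Archaea", "Export"), 300)
  expect_equal(get("Archaea", "Import"), 400)
  # conservation against the KO-level subset profile
  prof <- aggregate_by_ko_tpm(tpm, genes)
  expect_equal(sum(roll$s1), sum(mrg_subset_profile(prof, cat2)))
})

test_that("rollup validates domain labels", {
  genes <- data.frame(gene_id = "g1", length = 100, ko = "K00001",
                      domain = NA_character_)
  tpm <- matrix(10, 1, 1, dimnames = list("g1", "s1"))
  expect_error(domain_mechanism_rollup(tpm, genes,
                                       data.frame(ko = "K00001",
                                                  mechanism = "Export")),
               "domain label")
})

test_that("slope sign reflects the regression trend only", {
  expect_equal(slope_sign(c(a = 1, b = 2, c = 3), c(a = 10, b = 20, c = 30)),
               "positive")
  expect_equal(slope_sign(c(a = 3, b = 2, c = 1), c(a = 10, b = 20, c = 30)),
               "negative")
  expect_equal(slope_sign(c(a = 1, b = 1, c = 1), c(a = 10, b = 20, c = 30)),
               "flat")
  # two points reduce to the difference quotient
  expect_equal(slope_sign(c(a = 1, b = 5), c(a = 100, b = 10)), "negative")
  # undefined layers are dropped before fitting
  expect_equal(slope_sign(c(a = 1, b = NA, c = 3), c(a = 1, b = 2, c = 3)),
               "positive")
  expect_error(slope_sign(c(a = 1, b = NA), c(a = 1, b = 2)),
               "at least two")
})
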