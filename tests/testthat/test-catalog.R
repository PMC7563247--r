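test_that("KO identifiers are strictly K + five digits", {
  expect_true(all(is_valid_ko(c("K00001", "K23242"))))
  expect_false(any(is_valid_ko(c("K1234", "K123456", "k00001", "X00001",
                                 "K0000a"))))
})

test_that("best-hit selection keeps one top-scoring hit per subject", {
  ann <- data.frame(
    subject_id = c("b1", "b1", "b2", "b3", "b4"),
    ko = c("K00001", "K00002", "K00003", "K00004", "K00005"),
    score = c(80, 40, 50, 60, 70),
    above_threshold = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    evalue = c(1e-10, 1e-20, 1e-3, 1e-10, 1e-5)
  )
  out <- select_best_hits(ann)
  # b1 keeps the score-80 hit; b2 fails the E-value cutoff (1e-3 >= 1e-4,
  # boundary exclusive); b3 is below threshold; b4 survives at 1e-5
  expect_equal(out$subject_id, c("b1", "b4"))
  expect_equal(out$ko[out$subject_id == "b1"], "K00001")
  expect_equal(nrow(select_best_hits(ann[0, ])), 0)
})

test_that("E-value boundary is exclusive", {
  ann <- data.frame(subject_id = "b1", ko = "K00001", score = 10,
                    above_threshold = TRUE, evalue = 1e-4)
  expect_equal(nrow(select_best_hits(ann)), 0)
  ann$evalue <- 9.9e-5
  expect_equal(nrow(select_best_hits(ann)), 1)
})

test_that("KO aggregation unions compounds and symbols per KO", {
  bacmet <- data.frame(
    bacmet_id = c("BAC1", "BAC2"),
    gene_symbol = c("copA", "copA2"),
    compounds = c("Cu", "Cu, Ag")
  )
  hits <- data.frame(subject_id = c("BAC1", "BAC2"),
                     ko = c("K17686", "K17686"))
  out <- aggregate_by_ko(bacmet, hits)
  expect_equal(nrow(out), 1)
  expect_equal(out$compounds, "Ag,Cu")
  expect_equal(out$gene_symbols, "copA,copA2")
  # distinct KOs never merge
  hits$ko <- c("K17686", "K01533")
  expect_equal(nrow(aggregate_by_ko(bacmet, hits)), 2)
  # dangling subject reference is a schema error
  expect_error(aggregate_by_ko(bacmet,
                               data.frame(subject_id = "BAC9", ko = "K17686")),
               "unknown record")
})

test_that("KO aggregation equals the brute-force group-by on a toy table", {
  set.seed(11)
  bacmet <- data.frame(
    bacmet_id = sprintf("BAC%02d", 1:10),
    gene_symbol = sample(c("geneA", "geneB", "geneC", "geneD"), 10, TRUE),
    compounds = replicate(10, paste(
      sample(c("Cu", "Zn", "Ni", "As", "tetracycline"),
             sample(1:3, 1)), collapse = ", "))
  )
  hits <- data.frame(subject_id = bacmet$bacmet_id,
                     ko = sample(c("K00001", "K00002", "K00003"), 10, TRUE))
  got <- aggregate_by_ko(bacmet, hits)
  oracle <- brute_force_aggregate(bacmet, hits)
  expect_equal(got$ko, oracle$ko)
  expect_equal(got$compounds, oracle$compounds)
  expect_equal(got$gene_symbols, oracle$gene_symbols)
})

test_that("metal-only filtering needs a metal compound AND curator approval", {
  rows <- data.frame(
    ko = c("K00001", "K00002", "K00003"),
    gene_symbols = "g",
    compounds = c("tetracycline", "Cu,sodium acetate", "Zn"),
    n_members = 1
  )
  flags <- c(K00001 = TRUE, K00002 = TRUE, K00003 = FALSE)
  out <- filter_metal_only(rows, curator_flags = flags)
  # antibiotic-only removed; mixed-compound row kept (a metal is present);
  # curator veto removes the third regardless of its metal
  expect_equal(out$ko, "K00002")
  expect_error(filter_metal_only(rows, metal_vocabulary = character(0)),
               "non-empty")
})

test_that("catalog merge keeps unique KOs with source precedence", {
  a <- data.frame(ko = c("K00001", "K00002", "K00003"), gene_symbol = "x",
                  metals = "Cu", mechanism = "Export", specific = TRUE,
                  source = "BacMet")
  b <- data.frame(ko = c("K00004", "K00005"), gene_symbol = "y",
                  metals = "Zn", mechanism = "Import", specific = TRUE,
                  source = "literature")
  out <- merge_catalog(bacmet_derived = a, literature = b, quiet = TRUE)
  expect_equal(nrow(out), 5)
  dup <- b; dup$ko <- c("K00001", "K00005"); dup$mechanism <- "Export"
  dup$metals <- "Cu"
  out2 <- merge_catalog(bacmet_derived = a, literature = dup, quiet = TRUE)
  expect_equal(nrow(out2), 4)
  expect_equal(out2$source[out2$ko == "K00001"], "BacMet")
  # conflicting mechanisms for one KO must fail loudly
  bad <- b; bad$ko <- c("K00001", "K00005"); bad$mechanism <- "Regulation"
  expect_error(merge_catalog(bacmet_derived = a, literature = bad,
                             quiet = TRUE), "conflicting mechanism")
})

TABLE3_KOS <- c(
  "K03327", "K17686", "K01533", "K19591", "K22552", "K07665", "K07787",
  "K07798", "K07810", "K07213", "K07243", "K13283", "K02012", "K02011",
  "K18683", "K03711", "K00522", "K02217", "K03594", "K23242", "K03322",
  "K11924", "K01534", "K09815", "K09816", "K09817", "K15726", "K15727",
  "K15725", "K16264", "K21903", "K03709", "K15584", "K15586", "K07785",
  "K08970", "K03325", "K01551", "K03893", "K03741", "K22547", "K08355",
  "K02038", "K02036", "K02037", "K02040", "K03892", "K09043")

test_that("the metal marker fixture holds exactly the 48 expected KOs once each", {
  t3 <- load_table3_fixture()
  expect_equal(nrow(t3), 48)
  expect_setequal(t3$ko, TABLE3_KOS)
  expect_false(any(duplicated(t3$ko)))
  expect_setequal(unique(t3$metal_group),
                  c("Al", "Cu", "Fe", "Mn", "Zn", "Ni", "As"))
})

test_that("marker fixture entries carry the expected annotations", {
  t3 <- load_table3_fixture()
  acr3 <- t3[t3$ko == "K03325", ]
  expect_equal(acr3$gene_symbol, "acr3")
  expect_equal(acr3$metals, "As")
  expect_equal(acr3$mechanism, "Export")
  expect_true(acr3$specific)
  fief <- t3[t3$ko == "K13283", ]
  expect_equal(fief$gene_symbol, "fieF")
  expect_false(fief$specific)
  expect_equal(fief$mechanism, "Export")
})

test_that("the EPS marker fixture holds 16 sequestration proxies", {
  t4 <- load_table4_fixture()
  expect_equal(nrow(t4), 16)
  expect_setequal(unique(t4$pathway),
                  c("Wzx-Wzy", "ABC-transport", "Glycosyltransferase"))
  expect_true(all(t4$mechanism == "Extracellular Sequestration"))
  expect_equal(t4$pathway[t4$ko == "K16557"], "Glycosyltransferase")
  expect_equal(t4$gene_symbol[t4$ko == "K16557"], "exoA")
  expect_equal(t4$pathway[t4$ko == "K09689"], "ABC-transport")
  expect_equal(t4$gene_symbol[t4$ko == "K09689"], "kpsT")
})

test_that("metals_for_ko looks up the catalog and rejects unknown KOs", {
  cat64 <- load_mrg_catalog()
  expect_equal(metals_for_ko(cat64, "K23242"), "Mn")
  czcA <- metals_for_ko(cat64, "K15726")
  expect_gt(length(czcA), 1)
  expect_false(cat64$specific[cat64$ko == "K15726"])
  expect_error(metals_for_ko(cat64, "K99999"), "not in catalog")
})

test_that("catalog TSV round-trips identically", {
  cat64 <- load_mrg_catalog()
  tmp <- tempfile(fileext = ".tsv")
  write_mrg_catalog(cat64, tmp)
  back <- read_mrg_catalog(tmp)
  expect_equal(as.data.frame(back), as.data.frame(cat64))
})
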