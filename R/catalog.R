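#' Validate KEGG Orthology identifiers
#'
#' A KO identifier is the letter `K` followed by exactly five digits.
#' Strict validation catches table-transcription errors early.
#'
#' @param ko Character vector.
#' @return Logical vector.
#' @export
is_valid_ko <- function(ko) {
  grepl("^K[0-9]{5}$", ko)
}

assert_valid_ko <- function(ko, what = "ko") {
  bad <- unique(ko[!is.na(ko) & !is_valid_ko(ko)])
  if (length(bad)) {
    stop("invalid KO identifier(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Select best above-threshold KO annotations
#'
#' Keeps annotations flagged above the annotator's adaptive score threshold
#' with an E-value strictly below `evalue_max`, then retains the single
#' highest-scoring annotation per subject (ties broken by smaller E-value,
#' then by KO for determinism).
#'
#' @param annotations Data frame with `subject_id`, `ko`, `score`,
#'   `above_threshold` (logical), `evalue`.
#' @param evalue_max Exclusive E-value cutoff (default `1e-4`).
#' @return Filtered data frame, one row per surviving subject.
#' @export
select_best_hits <- function(annotations, evalue_max = 1e-4) {
  need <- c("subject_id", "ko", "score", "above_threshold", "evalue")
  stopifnot(all(need %in% names(annotations)))
  if (nrow(annotations) == 0) return(annotations)
  assert_valid_ko(annotations$ko, "annotations")
  keep <- annotations[annotations$above_threshold &
                        annotations$evalue < evalue_max, , drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  ord <- order(keep$subject_id, -keep$score, keep$evalue, keep$ko)
  keep <- keep[ord, , drop = FALSE]
  keep <- keep[!duplicated(keep$subject_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

split_compounds <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ","), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_set <- function(v) paste(sort(unique(v)), collapse = ",")

#' Aggregate resistance-gene records by KO
#'
#' Resistance databases list the same function under several accessions
#' (one per source organism). After KO assignment, records sharing a KO are
#' collapsed to one row whose compound set and gene-symbol set are the
#' unions over members.
#'
#' @param bacmet Data frame with `bacmet_id`, `gene_symbol`, `compounds`
#'   (comma-separated string).
#' @param hits KO assignments: data frame with `subject_id` (a `bacmet_id`)
#'   and `ko`, e.g. output of [select_best_hits()].
#' @return Data frame with one row per KO: `ko`, `gene_symbols`,
#'   `compounds` (both comma-joined sorted unions), `n_members`.
#' @export
aggregate_by_ko <- function(bacmet, hits) {
  stopifnot(all(c("bacmet_id", "gene_symbol", "compounds") %in% names(bacmet)),
            all(c("subject_id", "ko") %in% names(hits)))
  dangling <- setdiff(hits$subject_id, bacmet$bacmet_id)
  if (length(dangling)) {
    stop("hits reference unknown record(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  assert_valid_ko(hits$ko, "hits")
  idx <- match(hits$subject_id, bacmet$bacmet_id)
  rows <- lapply(split(idx, hits$ko), function(members) {
    comp <- unlist(split_compounds(bacmet$compounds[members]))
    data.frame(
      gene_symbols = join_set(bacmet$gene_symbol[members]),
      compounds = join_set(comp),
      n_members = length(members),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(ko = names(rows), out)
  out <- out[order(out$ko), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep KO rows curated as metal-resistance only
#'
#' A row survives when its compound set intersects the metal vocabulary AND
#' its curator flag is `TRUE`. The flag externalizes the manual judgment
#' that the source-database gene description matches the KO description --
#' a step that cannot be automated reliably -- making the curation explicit
#' and auditable.
#'
#' @param rows Output of [aggregate_by_ko()].
#' @param metal_vocabulary Character vector of metal/metalloid labels.
#' @param curator_flags Named logical vector (by KO). KOs absent from the
#'   map default to `FALSE` (not confirmed).
#' @return The surviving rows.
#' @export
filter_metal_only <- function(rows, metal_vocabulary = mrg_metal_vocabulary(),
                              curator_flags = NULL) {
  if (length(metal_vocabulary) == 0) {
    stop("metal vocabulary must be non-empty", call. = FALSE)
  }
  has_metal <- vapply(split_compounds(rows$compounds), function(comp) {
    any(comp %in% metal_vocabulary)
  }, TRUE)
  confirmed <- if (is.null(curator_flags)) rep(TRUE, nrow(rows)) else {
    flags <- curator_flags[rows$ko]
    !is.na(flags) & flags
  }
  out <- rows[has_metal & confirmed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default metal and metalloid vocabulary
#'
#' Element labels recognized as metals/metalloids when screening compound
#' annotations; includes the metalloids As, Sb and Te. Compound strings in
#' resistance databases are heterogeneous, so the vocabulary is a plain
#' editable list rather than a parser.
#'
#' @return Character vector.
#' @export
mrg_metal_vocabulary <- function() {
  c("Ag", "Al", "As", "Au", "Bi", "Cd", "Co", "Cr", "Cu", "Fe", "Ga", "Hg",
    "Mn", "Mo", "Ni", "Pb", "Sb", "Te", "Tl", "V", "W", "Zn")
}

MECHANISMS <- c("Export", "Import", "Biochemical Transformation",
                "Regulation", "Intracellular Accumulation",
                "Extracellular Sequestration")

validate_catalog <- function(catalog) {
  need <- c("ko", "gene_symbol", "metals", "mechanism", "specific", "source")
  missing <- setdiff(need, names(catalog))
  if (length(missing)) {
    stop("catalog lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  assert_valid_ko(catalog$ko, "catalog")
  dup <- unique(catalog$ko[duplicated(catalog$ko)])
  if (length(dup)) {
    stop("duplicate KO(s) in catalog: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_mech <- setdiff(unique(catalog$mechanism), MECHANISMS)
  if (length(bad_mech)) {
    stop("unknown mechanism label(s): ", paste(bad_mech, collapse = ", "),
         call. = FALSE)
  }
  no_metal <- !nzchar(ifelse(is.na(catalog$metals), "", catalog$metals)) &
    catalog$source != "EPS"
  if (any(no_metal)) {
    stop("non-EPS entries without metals: ",
         paste(catalog$ko[no_metal], collapse = ", "), call. = FALSE)
  }
  invisible(catalog)
}

#' Merge MRG catalog sources
#'
#' Combines catalog fragments (database-derived, EPS proxies, literature
#' additions) into one catalog with unique KOs. When the same KO arrives
#' from several sources the database-derived entry wins for provenance;
#' conflicting mechanism labels for one KO are a validation error.
#'
#' @param bacmet_derived,eps,literature Data frames in catalog layout
#'   (`ko`, `gene_symbol`, `metals`, `mechanism`, `specific`, `source`,
#'   optional `pathway`, `metal_group`); any may be `NULL`.
#' @param quiet Suppress the per-source count message.
#' @return The merged catalog data frame (class `mrg_catalog`).
#' @export
merge_catalog <- function(bacmet_derived = NULL, eps = NULL,
                          literature = NULL, quiet = FALSE) {
  parts <- Filter(Negate(is.null), list(BacMet = bacmet_derived, EPS = eps,
                                        literature = literature))
  if (length(parts) == 0) stop("no catalog sources given", call. = FALSE)
  cols <- c("ko", "gene_symbol", "metal_group", "metals", "mechanism",
            "specific", "source", "pathway")
  parts <- lapply(parts, function(p) {
    for (cc in setdiff(cols, names(p))) p[[cc]] <- NA
    p[, cols]
  })
  # precedence: BacMet-derived first, then EPS, then literature
  all <- do.call(rbind, parts)
  dup <- duplicated(all$ko)
  if (any(dup)) {
    for (k in unique(all$ko[dup])) {
      mech <- unique(all$mechanism[all$ko == k])
      if (length(mech) > 1) {
        stop("conflicting mechanism labels for KO ", k, ": ",
             paste(mech, collapse = " vs "), call. = FALSE)
      }
    }
    all <- all[!dup, , drop = FALSE]
  }
  rownames(all) <- NULL
  validate_catalog(all)
  if (!quiet) {
    counts <- table(all$source)
    message("merged catalog: ", nrow(all), " KOs (",
            paste(names(counts), counts, sep = " = ", collapse = ", "), ")")
  }
  structure(all, class = c("mrg_catalog", "data.frame"))
}

#' Packaged marker-gene fixtures
#'
#' `load_table3_fixture()` returns the 48 marker KOs for resistance to the
#' seven highest-toxicity metal(loid)s (Al, Cu, Fe, Mn, Zn, Ni, As), with
#' per-KO metal lists, mechanism assignments and the specificity flag
#' (`FALSE` = non-specific, i.e. the gene is noted to interact with more
#' than one element). `load_table4_fixture()` returns the 16 marker KOs for
#' synthesis, assembly and transport of extracellular and capsular
#' polysaccharides, used as proxies for extracellular metal sequestration
#' (mechanism `Extracellular Sequestration`, source `EPS`).
#'
#' @return A catalog-layout data frame (48 and 16 rows respectively).
#' @export
load_table3_fixture <- function() {
  tab <- read_tsv_strict(amdtox_extdata("mrg_table3.tsv"))
  tab$specific <- as.logical(tab$specific)
  if (nrow(tab) != 48) {
    stop("packaging error: metal marker fixture must have 48 entries, found ",
         nrow(tab), call. = FALSE)
  }
  validate_catalog(tab)
  tab
}

#' @rdname load_table3_fixture
#' @export
load_table4_fixture <- function() {
  tab <- read_tsv_strict(amdtox_extdata("mrg_table4.tsv"))
  if (nrow(tab) != 16) {
    stop("packaging error: EPS marker fixture must have 16 entries, found ",
         nrow(tab), call. = FALSE)
  }
  tab$metal_group <- NA_character_
  tab$metals <- ""
  tab$mechanism <- "Extracellular Sequestration"
  tab$specific <- FALSE
  tab$source <- "EPS"
  tab[, c("ko", "gene_symbol", "metal_group", "metals", "mechanism",
          "specific", "source", "pathway")]
}

#' Packaged 64-KO metal resistance catalog
#'
#' The merged fixture catalog: 48 metal-specific marker KOs plus 16 EPS
#' proxy KOs.
#'
#' @param quiet Suppress the merge message (default `TRUE`).
#' @return An `mrg_catalog` data frame with 64 unique KOs.
#' @export
load_mrg_catalog <- function(quiet = TRUE) {
  merge_catalog(bacmet_derived = load_table3_fixture(),
                eps = load_table4_fixture(), quiet = quiet)
}

#' Metals associated with a catalog KO
#'
#' @param catalog An `mrg_catalog` (or catalog-layout data frame).
#' @param ko A single KO identifier present in the catalog.
#' @return Character vector of element labels (empty for EPS proxies).
#' @examples
#' metals_for_ko(load_mrg_catalog(), "K23242")   # "Mn"
#' @export
metals_for_ko <- function(catalog, ko) {
  stopifnot(length(ko) == 1)
  i <- match(ko, catalog$ko)
  if (is.na(i)) stop("KO not in catalog: ", ko, call. = FALSE)
  split_compounds(catalog$metals[i])[[1]]
}

#' Read / write an MRG catalog TSV
#'
#' Round-trip safe: writing a catalog and reading it back yields an
#' identical catalog.
#'
#' @param path File path.
#' @return `read_mrg_catalog()` returns an `mrg_catalog` data frame.
#' @export
read_mrg_catalog <- function(path) {
  tab <- read_tsv_strict(path)
  tab$specific <- as.logical(tab$specific)
  if ("metals" %in% names(tab)) tab$metals[is.na(tab$metals)] <- ""
  for (cc in intersect(c("pathway", "metal_group"), names(tab))) {
    tab[[cc]][tab[[cc]] %in% ""] <- NA
  }
  validate_catalog(tab)
  structure(tab, class = c("mrg_catalog", "data.frame"))
}

#' @rdname read_mrg_catalog
#' @param catalog Catalog data frame.
#' @export
write_mrg_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
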