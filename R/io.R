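#' Locate a packaged fixture file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path to the file.
#' @keywords internal
amdtox_extdata <- function(file) {
  path <- system.file("extdata", file, package = "amdtox", mustWork = FALSE)
  if (!nzchar(path)) {
    stop("packaging error: fixture '", file, "' not found", call. = FALSE)
  }
  path
}

read_tsv_strict <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "")
}

#' Lake water chemistry fixture
#'
#' Per-layer dissolved metal(loid) concentrations for the three layers of the
#' study lake (upper oxic layer at 3 m, chemocline at 11 m, deep anoxic layer
#' at 35 m). Concentrations are historical May means in ug/L. Redox species
#' (Fe(II)/Fe(III), As(III)/As(V)) are assigned per layer as measured;
#' species not present in a layer simply have no row.
#'
#' @return A data frame with columns `layer`, `element`, `conc_ug_per_L`.
#' @seealso [load_cm_standards()], [tpf_table()]
#' @export
load_cm_chemistry <- function() {
  read_tsv_strict(amdtox_extdata("cm_water_chemistry.tsv"))
}

#' Lake layer physical properties fixture
#'
#' @return A data frame with `layer`, `depth_m`, `pH`, `orp_mV`, `sc_mS_cm`,
#'   `temperature_C`.
#' @export
load_cm_layer_properties <- function() {
  read_tsv_strict(amdtox_extdata("cm_layer_properties.tsv"))
}

#' USEPA NAWQC-CCCF in-stream standards fixture
#'
#' Chronic-exposure (constant contact concentration factor) water-quality
#' criteria in ug/L. No hardness-based adjustment is applied. Manganese has
#' no published CCCF criterion; by convention its standard is derived as the
#' iron standard divided by six (the concentration ratio of the USEPA
#' drinking-water standards), see [derive_mn_standard()].
#'
#' @param derive_mn If `TRUE` (default) append the derived Mn standard
#'   (kept at full precision, not rounded).
#' @return A data frame with columns `element`, `cccf_ug_per_L`.
#' @export
load_cm_standards <- function(derive_mn = TRUE) {
  std <- read_tsv_strict(amdtox_extdata("cm_standards.tsv"))
  if (derive_mn) {
    fe <- std$cccf_ug_per_L[std$element == "Fe"]
    std <- rbind(std, data.frame(element = "Mn",
                                 cccf_ug_per_L = derive_mn_standard(fe)))
  }
  std
}

#' Free-cation fractions and predominant species fixture
#'
#' Speciation summary for each (layer, element): the free-cation percentage
#' and the predominant dissolved species with its percentage. Arsenic rows
#' carry `NA` free percentages because arsenic is not cationic under these
#' conditions (As(III) is a neutral acid, As(V) an oxyanion).
#'
#' @return A data frame with `layer`, `element`, `free_percent`,
#'   `predominant_species`, `predominant_percent`.
#' @export
load_cm_free_fractions <- function() {
  read_tsv_strict(amdtox_extdata("cm_free_fractions.tsv"))
}

#' Published toxic potency factors fixture
#'
#' The reported per-layer TPF-1 and TPF-2 values, as printed (mixed
#' precision: two significant figures in some cells, integers in others).
#' Used for cross-checking [tpf_table()] output and for reproducing the
#' per-layer toxicity rankings.
#'
#' @return A data frame with `layer`, `element`, `tpf1`, `tpf2` (`NA` for
#'   arsenic, which has no TPF-2).
#' @export
load_cm_printed_tpf <- function() {
  read_tsv_strict(amdtox_extdata("cm_tpf_printed.tsv"))
}

#' Published per-layer toxicity ranking strings fixture
#'
#' @return A data frame with `layer`, `tpf_type` (`"tpf1"` or `"tpf2"`) and
#'   the `ranking` string (elements joined by `>`, `>>` or `~`).
#' @export
load_cm_rankings <- function() {
  read_tsv_strict(amdtox_extdata("cm_rankings.tsv"))
}

#' Deep-layer MAG metadata fixture
#'
#' The thirteen metagenome-assembled genomes recovered from the deep anoxic
#' layer: GTDB lineage, relative abundance (% of mapped DNA reads),
#' CheckM completeness/contamination. Mapped-mRNA read counts were not
#' published per MAG and are `NA` in the fixture.
#'
#' @return A data frame with `mag_id`, `taxonomy`, `rel_abundance`,
#'   `completeness`, `contamination`, `mrna_reads`.
#' @export
load_cm_mags <- function() {
  read_tsv_strict(amdtox_extdata("cm_mags.tsv"))
}

#' Read / write a gene catalog table
#'
#' Gene catalogs are TSV tables with columns `gene_id`, `length`, `ko`
#' (empty/NA when unannotated), `evalue`, `domain`, `mag_id` (empty/NA when
#' unbinned).
#'
#' @param path File path.
#' @return `read_gene_catalog()` returns the catalog data frame.
#' @export
read_gene_catalog <- function(path) {
  genes <- read_tsv_strict(path)
  required <- c("gene_id", "length")
  missing <- setdiff(required, names(genes))
  if (length(missing)) {
    stop("gene catalog lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("ko", "domain", "mag_id")) {
    if (col %in% names(genes)) genes[[col]][genes[[col]] %in% ""] <- NA
  }
  genes
}

#' @rdname read_gene_catalog
#' @param genes Gene catalog data frame.
#' @export
write_gene_catalog <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read / write a count matrix
#'
#' Count tables are TSV files with a `gene_id` column followed by one column
#' per sample. Counts may be integers or non-negative reals (fractional
#' multi-mapping allowances upstream are accepted).
#'
#' @param path File path.
#' @return `read_count_matrix()` returns a numeric matrix with gene ids as
#'   row names and sample ids as column names.
#' @export
read_count_matrix <- function(path) {
  tab <- read_tsv_strict(path)
  if (names(tab)[1] != "gene_id") {
    stop("count table must start with a 'gene_id' column", call. = FALSE)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative counts", call. = FALSE)
  m
}

#' @rdname read_count_matrix
#' @param counts Numeric gene x sample matrix with dimnames.
#' @export
write_count_matrix <- function(counts, path) {
  tab <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
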