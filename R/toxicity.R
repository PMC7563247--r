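#' Derive the manganese in-stream standard
#'
#' Manganese has no published NAWQC-CCCF criterion. Its standard is derived
#' as the iron standard divided by six, the concentration ratio of the USEPA
#' drinking-water standards for the two elements. The exact quotient is
#' returned; round to the nearest integer for reporting (1000 -> 166.67,
#' reported 167).
#'
#' @param fe_standard Iron CCCF standard, ug/L (must be > 0).
#' @return The derived Mn standard, ug/L, at full precision.
#' @export
derive_mn_standard <- function(fe_standard) {
  if (!is.numeric(fe_standard) || length(fe_standard) != 1 ||
      is.na(fe_standard) || fe_standard <= 0) {
    stop("fe_standard must be a single positive number", call. = FALSE)
  }
  fe_standard / 6
}

#' Toxic potency factor from total dissolved concentration (TPF-1)
#'
#' `TPF-1 = measured dissolved concentration / CCCF standard`, dimensionless.
#' Speciation is deliberately ignored. Report at two significant figures via
#' [round_sigfig()].
#'
#' @param concentration Dissolved concentration, ug/L (>= 0, vectorized).
#' @param standard CCCF standard, ug/L (> 0).
#' @return Dimensionless TPF-1, exact quotient.
#' @examples
#' compute_tpf1(6010, 9.0)   # 667.8
#' @export
compute_tpf1 <- function(concentration, standard) {
  if (any(standard <= 0, na.rm = TRUE) || anyNA(standard)) {
    stop("standard must be > 0", call. = FALSE)
  }
  if (any(concentration < 0, na.rm = TRUE)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  concentration / standard
}

#' Toxic potency factor from free-cation activity (TPF-2)
#'
#' `TPF-2 = free cation activity / CCCF standard`, with the free-cation
#' activity taken as `concentration x free_fraction x gamma`. The default
#' `gamma = 1` equates activity with the free-ion concentration; the
#' coefficient is an explicit hook for a stricter activity definition.
#' Not defined for non-cationic elements (arsenic) -- pass those through
#' [tpf_table()], which marks them `NA`.
#'
#' @param concentration Total dissolved concentration, ug/L.
#' @param free_fraction Free-cation fraction in `[0, 1]`.
#' @param gamma Activity coefficient (> 0), default 1.
#' @param standard CCCF standard, ug/L (> 0).
#' @return Dimensionless TPF-2.
#' @examples
#' compute_tpf2(6010, 0.66, standard = 9.0)   # 440.7
#' @export
compute_tpf2 <- function(concentration, free_fraction, gamma = 1, standard) {
  if (any(free_fraction < 0 | free_fraction > 1, na.rm = TRUE)) {
    stop("free_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(gamma <= 0, na.rm = TRUE)) stop("gamma must be > 0", call. = FALSE)
  compute_tpf1(concentration, standard) * free_fraction * gamma
}

#' Round to n significant figures, half away from zero
#'
#' Reporting convention for potency factors (two significant figures by
#' default): 1609.2 -> 1600, 4820.8 -> 4800. Unlike [signif()], exact
#' halves round away from zero.
#'
#' @param x Numeric vector.
#' @param n Number of significant figures (>= 1).
#' @return Rounded vector; zeros and `NA`s pass through.
#' @export
round_sigfig <- function(x, n = 2) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  out <- x
  idx <- which(!is.na(x) & x != 0)
  if (length(idx)) {
    xx <- x[idx]
    mag <- floor(log10(abs(xx)))
    f <- 10^(mag - n + 1)
    out[idx] <- sign(xx) * floor(abs(xx) / f + 0.5) * f
  }
  out
}

# elements whose dissolved forms are not cationic under acidic conditions;
# they get no TPF-2
NON_CATIONIC <- c("As")

base_element <- function(element) sub("\\(.*\\)$", "", element)

#' Per-layer toxic potency factor table
#'
#' Joins a chemistry table with the standards table (matching redox-labelled
#' elements such as `Fe(II)` to their base-element standard) and, when a
#' free-cation fraction table is supplied, computes TPF-2 alongside TPF-1.
#' Elements without a standard (e.g. SO4 at these levels, nutrient species)
#' are skipped with a warning. Arsenic rows get `tpf2 = NA` because arsenic
#' is not cationic.
#'
#' @param chem Data frame `layer`, `element`, `conc_ug_per_L`.
#' @param standards Data frame `element`, `cccf_ug_per_L`.
#' @param fractions Optional data frame `layer`, `element`, `free_percent`
#'   (0-100; `NA` for non-cationic elements) and optionally `gamma`.
#' @param warn Emit a warning listing skipped elements (default `TRUE`).
#' @return A data frame with one row per (layer, element): `layer`,
#'   `element`, `conc_ug_per_L`, `standard_ug_per_L`, `tpf1`,
#'   `tpf1_reported`, `free_fraction`, `gamma`, `tpf2`, `tpf2_reported`.
#' @examples
#' tpf <- tpf_table(load_cm_chemistry(), load_cm_standards(),
#'                  load_cm_free_fractions())
#' subset(tpf, layer == "deep")
#' @export
tpf_table <- function(chem, standards, fractions = NULL, warn = TRUE) {
  stopifnot(all(c("layer", "element", "conc_ug_per_L") %in% names(chem)))
  if (nrow(chem) == 0) {
    return(data.frame(layer = character(), element = character(),
                      conc_ug_per_L = numeric(), standard_ug_per_L = numeric(),
                      tpf1 = numeric(), tpf1_reported = numeric(),
                      free_fraction = numeric(), gamma = numeric(),
                      tpf2 = numeric(), tpf2_reported = numeric()))
  }
  std <- setNames(standards$cccf_ug_per_L, standards$element)
  lookup <- ifelse(chem$element %in% names(std), chem$element,
                   base_element(chem$element))
  have <- lookup %in% names(std) & !is.na(chem$conc_ug_per_L)
  skipped <- unique(chem$element[!have & !is.na(chem$conc_ug_per_L)])
  if (warn && length(skipped)) {
    warning("skipping element(s) without a CCCF standard: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out <- chem[have, c("layer", "element", "conc_ug_per_L")]
  out$standard_ug_per_L <- unname(std[lookup[have]])
  out$tpf1 <- compute_tpf1(out$conc_ug_per_L, out$standard_ug_per_L)
  out$tpf1_reported <- round_sigfig(out$tpf1, 2)

  out$free_fraction <- NA_real_
  out$gamma <- 1
  if (!is.null(fractions)) {
    key <- paste(fractions$layer, fractions$element)
    idx <- match(paste(out$layer, out$element), key)
    out$free_fraction <- fractions$free_percent[idx] / 100
    if ("gamma" %in% names(fractions)) {
      g <- fractions$gamma[idx]
      out$gamma <- ifelse(is.na(g), 1, g)
    }
  }
  out$free_fraction[base_element(out$element) %in% NON_CATIONIC] <- NA_real_
  has_frac <- !is.na(out$free_fraction)
  out$tpf2 <- NA_real_
  out$tpf2[has_frac] <- compute_tpf2(
    out$conc_ug_per_L[has_frac], out$free_fraction[has_frac],
    out$gamma[has_frac], out$standard_ug_per_L[has_frac])
  out$tpf2_reported <- round_sigfig(out$tpf2, 2)
  rownames(out) <- NULL
  out
}

#' Render a toxicity ranking string
#'
#' Sorts elements by descending potency (ties broken alphabetically) and
#' joins them with `~` (near-equal: symmetric relative difference
#' `2|a-b|/(a+b) <= tie_tol`), `>>` (dominant: `a/b >= big_factor`) or `>`
#' otherwise. The two separator thresholds are configurable heuristics --
#' published rankings place `~` and `>>` partly by author judgment, so only
#' the element order (and `>>` after a clearly dominant leader) should be
#' relied upon.
#'
#' @param tpfs Named numeric vector of potency factors (>= 0, non-empty).
#' @param tie_tol Near-equality tolerance on the symmetric relative
#'   difference (default 0.05).
#' @param big_factor Ratio marking dominance (default 5).
#' @return A single ranking string, e.g. `"Fe(II) >> Zn > Mn"`.
#' @examples
#' rank_elements(c(`Fe(II)` = 6300, Zn = 910, Mn = 700))
#' @export
rank_elements <- function(tpfs, tie_tol = 0.05, big_factor = 5) {
  if (length(tpfs) == 0) stop("empty potency map", call. = FALSE)
  if (any(tpfs < 0, na.rm = TRUE) || anyNA(tpfs)) {
    stop("potency values must be non-negative and non-missing", call. = FALSE)
  }
  ord <- order(-tpfs, names(tpfs))
  v <- tpfs[ord]
  nm <- names(v)
  if (length(v) == 1) return(nm)
  seps <- character(length(v) - 1)
  for (i in seq_along(seps)) {
    a <- v[i]; b <- v[i + 1]
    sym <- if (a + b == 0) 0 else 2 * abs(a - b) / (a + b)
    seps[i] <- if (sym <= tie_tol) "~"
      else if (b == 0 || a / b >= big_factor) ">>"
      else ">"
  }
  paste0(nm[1], paste0(" ", seps, " ", nm[-1], collapse = ""))
}

#' Parse a toxicity ranking string
#'
#' Inverse of [rank_elements()]: splits a ranking string into its ordered
#' element labels and separators. Rendering the parse back yields the
#' original string.
#'
#' @param ranking Ranking string, elements joined by `>`, `>>` or `~`.
#' @return A list with `elements` (character) and `separators` (character,
#'   one fewer than elements).
#' @export
parse_ranking <- function(ranking) {
  tokens <- strsplit(trimws(ranking), "\\s+")[[1]]
  is_sep <- tokens %in% c(">", ">>", "~")
  if (!all(is_sep == (seq_along(tokens) %% 2 == 0))) {
    stop("malformed ranking string: ", ranking, call. = FALSE)
  }
  list(elements = tokens[!is_sep], separators = tokens[is_sep])
}

#' @rdname parse_ranking
#' @param parsed A list as returned by `parse_ranking()`.
#' @export
render_ranking <- function(parsed) {
  if (length(parsed$elements) == 1) return(parsed$elements)
  paste0(parsed$elements[1],
         paste0(" ", parsed$separators, " ", parsed$elements[-1],
                collapse = ""))
}

#' Per-layer ranking strings from a TPF table
#'
#' @param tpf Output of [tpf_table()].
#' @param type `"tpf1"` or `"tpf2"` (elements with `NA` TPF-2 are dropped
#'   from TPF-2 rankings).
#' @param ... Passed to [rank_elements()].
#' @return Named character vector of ranking strings, one per layer.
#' @export
rank_layers <- function(tpf, type = c("tpf1", "tpf2"), ...) {
  type <- match.arg(type)
  layers <- unique(tpf$layer)
  out <- vapply(layers, function(ly) {
    sub <- tpf[tpf$layer == ly & !is.na(tpf[[type]]), ]
    rank_elements(setNames(sub[[type]], sub$element), ...)
  }, "")
  setNames(out, layers)
}
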