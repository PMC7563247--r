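#' Simulation configuration
#'
#' Validates and assembles the parameters of the synthetic community
#' generator. Defaults emulate the study conditions: two replicate samples
#' per layer, about half of predicted genes carrying a KO annotation, ~3%
#' of KO-annotated genes being metal resistance genes, heavy-tailed
#' (log-normal) gene abundances, and negative-binomial mapped-read counts
#' whose means scale with abundance times gene length.
#'
#' @param n_genes Number of genes in the simulated catalog.
#' @param n_samples Samples (replicates) per count matrix.
#' @param domain_mix Named proportions over Bacteria/Archaea/Eukaryota;
#'   must sum to 1.
#' @param mrg_fraction Proportion of KO-annotated genes whose KO is drawn
#'   from the MRG catalog.
#' @param ko_fraction Proportion of genes carrying any KO annotation.
#' @param length_log_mean,length_log_sd Log-scale parameters of the
#'   log-normal gene-length distribution (bp).
#' @param dna_depth,rna_depth Expected total mapped reads per sample.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param expression_effects Named numeric vector KO -> true RNA:DNA
#'   multiplier (default multiplier 1 for KOs not listed).
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       n_samples = 2,
                       domain_mix = c(Bacteria = 0.5, Archaea = 0.3,
                                      Eukaryota = 0.2),
                       mrg_fraction = 0.03,
                       ko_fraction = 0.5,
                       length_log_mean = log(900),
                       length_log_sd = 0.5,
                       dna_depth = 1e7,
                       rna_depth = 1e7,
                       dispersion = 0.3,
                       expression_effects = NULL,
                       seed = 1L) {
  stopifnot(n_genes >= 0, n_samples >= 1)
  if (abs(sum(domain_mix) - 1) > 1e-8 || any(domain_mix < 0)) {
    stop("domain_mix must be non-negative proportions summing to 1",
         call. = FALSE)
  }
  if (!setequal(names(domain_mix), c("Bacteria", "Archaea", "Eukaryota"))) {
    stop("domain_mix must be named Bacteria/Archaea/Eukaryota", call. = FALSE)
  }
  if (mrg_fraction < 0 || mrg_fraction > 1 || ko_fraction < 0 ||
      ko_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (dna_depth <= 0 || rna_depth <= 0) stop("depths must be > 0",
                                             call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (!is.null(expression_effects)) {
    if (is.null(names(expression_effects)) ||
        any(expression_effects <= 0)) {
      stop("expression_effects must be a named vector of positive multipliers",
           call. = FALSE)
    }
    assert_valid_ko(names(expression_effects), "expression_effects")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    domain_mix = domain_mix, mrg_fraction = mrg_fraction,
    ko_fraction = ko_fraction, length_log_mean = length_log_mean,
    length_log_sd = length_log_sd, dna_depth = dna_depth,
    rna_depth = rna_depth, dispersion = dispersion,
    expression_effects = expression_effects, seed = as.integer(seed)
  ), class = "sim_config")
}

# run code under a private RNG stream, restoring the caller's stream after
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic gene catalog
#'
#' Draws `n_genes` gene records: log-normal lengths (floored at 100 bp),
#' domains from `domain_mix`, KO annotations for a `ko_fraction` share of
#' genes, and -- among annotated genes -- a binomial `mrg_fraction` share
#' whose KO is sampled from the MRG catalog (the rest get background KOs
#' disjoint from the catalog).
#'
#' @param config A [sim_config()].
#' @param catalog MRG catalog supplying the planted KOs; must be non-empty
#'   whenever `mrg_fraction > 0`.
#' @return Gene catalog data frame: `gene_id`, `length`, `ko`, `evalue`,
#'   `domain`, `mag_id` (all `NA`, binning is simulated separately).
#' @export
gen_gene_catalog <- function(config, catalog = load_mrg_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mrg_fraction > 0 &&
      (is.null(catalog) || nrow(catalog) == 0)) {
    stop("empty catalog with mrg_fraction > 0", call. = FALSE)
  }
  n <- config$n_genes
  if (n == 0) {
    return(data.frame(gene_id = character(), length = integer(),
                      ko = character(), evalue = numeric(),
                      domain = character(), mag_id = character()))
  }
  background_kos <- setdiff(sprintf("K%05d", 60000:69999), catalog$ko)
  local_seed(config$seed, {
    len <- pmax(100L, as.integer(round(
      rlnorm(n, config$length_log_mean, config$length_log_sd))))
    domain <- sample(names(config$domain_mix), n, replace = TRUE,
                     prob = config$domain_mix)
    annotated <- runif(n) < config$ko_fraction
    is_mrg <- annotated & runif(n) < config$mrg_fraction
    ko <- rep(NA_character_, n)
    ko[is_mrg] <- sample(catalog$ko, sum(is_mrg), replace = TRUE)
    n_bg <- sum(annotated & !is_mrg)
    ko[annotated & !is_mrg] <- sample(background_kos, n_bg, replace = TRUE)
    evalue <- rep(NA_real_, n)
    evalue[annotated] <- 10^-runif(sum(annotated), 5, 30)
    data.frame(
      gene_id = sprintf("gene_%06d", seq_len(n)),
      length = len, ko = ko, evalue = evalue, domain = domain,
      mag_id = NA_character_, stringsAsFactors = FALSE
    )
  })
}

#' Generate DNA and RNA count matrices with known expression ground truth
#'
#' Per-gene relative abundances are log-normal. The DNA mean count of gene
#' g is proportional to `abundance_g * length_g`, scaled so each sample's
#' expected total equals `dna_depth`; RNA means are additionally multiplied
#' by the KO's planted expression multiplier (default 1). Counts are
#' negative-binomial with the configured dispersion (Poisson when 0).
#'
#' Because TPM is compositional, the realized RNA:DNA TPM ratio of a KO is
#' its multiplier times a common normalization constant shared by all KOs;
#' the returned ground truth records this realized expected ratio next to
#' the raw multiplier.
#'
#' @param genes Gene catalog from [gen_gene_catalog()] (non-empty).
#' @param config The same [sim_config()].
#' @return A list: `dna` and `rna` (gene x sample integer matrices),
#'   `truth` (data frame `ko`, `multiplier`, `true_expression`),
#'   `abundance` (the latent per-gene relative abundances).
#' @export
gen_count_tables <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"), nrow(genes) > 0)
  n <- nrow(genes)
  samples_dna <- sprintf("dna_%d", seq_len(config$n_samples))
  samples_rna <- sprintf("rna_%d", seq_len(config$n_samples))
  local_seed(config$seed + 1L, {
    abun <- rlnorm(n, meanlog = 0, sdlog = 1)
    effect <- rep(1, n)
    if (!is.null(config$expression_effects)) {
      idx <- match(genes$ko, names(config$expression_effects))
      effect[!is.na(idx)] <- config$expression_effects[idx[!is.na(idx)]]
    }
    w_dna <- abun * genes$length
    w_rna <- abun * genes$length * effect
    mu_dna <- config$dna_depth * w_dna / sum(w_dna)
    mu_rna <- config$rna_depth * w_rna / sum(w_rna)
    draw <- function(mu, samples) {
      m <- matrix(0, nrow = n, ncol = length(samples),
                  dimnames = list(genes$gene_id, samples))
      for (j in seq_along(samples)) {
        m[, j] <- if (config$dispersion == 0) stats::rpois(n, mu)
          else rnbinom(n, mu = mu, size = 1 / config$dispersion)
      }
      m
    }
    dna <- draw(mu_dna, samples_dna)
    rna <- draw(mu_rna, samples_rna)

    # realized expected per-KO TPM ratio: multiplier times the shared
    # compositional constant sum(abun) / sum(abun * effect)
    annotated <- !is.na(genes$ko)
    const <- sum(abun) / sum(abun * effect)
    per_ko_mult <- vapply(split(seq_len(n)[annotated], genes$ko[annotated]),
                          function(ix) {
                            sum(abun[ix] * effect[ix]) / sum(abun[ix])
                          }, 0)
    truth <- data.frame(
      ko = names(per_ko_mult),
      multiplier = unname(vapply(
        split(effect[annotated], genes$ko[annotated]),
        function(e) e[1], 0)),
      true_expression = unname(per_ko_mult * const),
      stringsAsFactors = FALSE
    )
    list(dna = dna, rna = rna, truth = truth, abundance = abun)
  })
}

#' Generate a synthetic water-chemistry table
#'
#' Log-uniform concentrations per element within user-supplied bounds, one
#' row per (layer, element); schema identical to the packaged chemistry
#' fixture.
#'
#' @param n_layers Number of layers.
#' @param ranges Data frame `element`, `lower`, `upper` (ug/L, positive;
#'   `lower <= upper`). Defaults to bounds spanning the magnitudes observed
#'   in stratified acidic pit lakes.
#' @param seed Integer seed.
#' @return Data frame `layer`, `element`, `conc_ug_per_L`.
#' @export
gen_water_chemistry <- function(n_layers, ranges = default_chem_ranges(),
                                seed = 1L) {
  stopifnot(n_layers >= 1)
  if (any(ranges$lower <= 0) || any(ranges$upper <= 0)) {
    stop("bounds must be positive", call. = FALSE)
  }
  if (any(ranges$lower > ranges$upper)) {
    stop("lower bound exceeds upper bound for: ",
         paste(ranges$element[ranges$lower > ranges$upper], collapse = ", "),
         call. = FALSE)
  }
  local_seed(seed, {
    layers <- sprintf("layer_%d", seq_len(n_layers))
    out <- expand.grid(layer = layers, element = ranges$element,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(out$element, ranges$element)
    out$conc_ug_per_L <- exp(runif(nrow(out), log(ranges$lower[i]),
                                   log(ranges$upper[i])))
    # degenerate bounds pin the value exactly (no exp/log round-trip noise)
    fixed <- ranges$lower[i] == ranges$upper[i]
    out$conc_ug_per_L[fixed] <- ranges$lower[i][fixed]
    out[order(out$layer, out$element), ]
  })
}

#' @rdname gen_water_chemistry
#' @export
default_chem_ranges <- function() {
  data.frame(
    element = c("Al", "As(III)", "Co", "Cu", "Fe(II)", "Mn", "Ni", "Zn",
                "SO4", "Cl"),
    lower = c(5e3, 1e2, 1e3, 5e1, 1e5, 1e4, 4e2, 1e4, 2e6, 1e4),
    upper = c(2e5, 2e4, 3e3, 7e3, 7e6, 2e5, 1e3, 2e5, 2e7, 3e4),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic MAG table with planted structure
#'
#' Produces MAG records (completeness in [50, 100], contamination in
#' [0, 10]), a symmetric ANI matrix with unit (100%) diagonal, and a
#' gene-to-MAG assignment. Optionally plants near-duplicate MAG pairs at a
#' chosen ANI (to exercise dereplication) and MAGs with sub-threshold
#' mapped-mRNA counts (to exercise the minimum-mRNA filter).
#'
#' @param n_mags Number of MAGs (>= 1).
#' @param seed Integer seed.
#' @param n_duplicate_pairs Number of planted same-species pairs.
#' @param duplicate_ani ANI % given to planted pairs (default 99).
#' @param n_low_mrna Number of MAGs planted with fewer than 500 mapped
#'   mRNA reads.
#' @param genes_per_mag Genes assigned to each MAG.
#' @return A list: `mags` (data frame `mag_id`, `taxonomy`,
#'   `rel_abundance`, `completeness`, `contamination`, `mrna_reads`),
#'   `ani` (matrix), `assignment` (data frame `gene_id`, `mag_id`).
#' @export
gen_mag_table <- function(n_mags, seed = 1L, n_duplicate_pairs = 0,
                          duplicate_ani = 99, n_low_mrna = 0,
                          genes_per_mag = 50) {
  stopifnot(n_mags >= 1, 2 * n_duplicate_pairs <= n_mags,
            n_low_mrna <= n_mags)
  local_seed(seed, {
    ids <- sprintf("MAG_%02d", seq_len(n_mags))
    domains <- sample(c("Bacteria", "Archaea"), n_mags, replace = TRUE,
                      prob = c(0.6, 0.4))
    rel <- rlnorm(n_mags, 0, 1)
    mags <- data.frame(
      mag_id = ids,
      taxonomy = paste0("d__", domains),
      rel_abundance = round(100 * rel / sum(rel), 2),
      completeness = round(runif(n_mags, 50, 100), 1),
      contamination = round(runif(n_mags, 0, 10 - 1e-9), 1),
      mrna_reads = as.integer(round(runif(n_mags, 500, 50000))),
      stringsAsFactors = FALSE
    )
    if (n_low_mrna > 0) {
      low <- sample(n_mags, n_low_mrna)
      mags$mrna_reads[low] <- as.integer(round(runif(n_low_mrna, 0, 499)))
    }
    ani <- matrix(runif(n_mags^2, 75, 90), n_mags, n_mags,
                  dimnames = list(ids, ids))
    ani <- (ani + t(ani)) / 2
    diag(ani) <- 100
    if (n_duplicate_pairs > 0) {
      for (p in seq_len(n_duplicate_pairs)) {
        i <- 2 * p - 1; j <- 2 * p
        ani[i, j] <- ani[j, i] <- duplicate_ani
      }
    }
    assignment <- data.frame(
      gene_id = sprintf("mg_%s_%03d", rep(ids, each = genes_per_mag),
                        rep(seq_len(genes_per_mag), n_mags)),
      mag_id = rep(ids, each = genes_per_mag),
      stringsAsFactors = FALSE
    )
    list(mags = mags, ani = ani, assignment = assignment)
  })
}
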