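# amdtox

Metal toxicity and metal resistance gene (MRG) profiling for stratified
acidic pit lakes and similar acid mine drainage systems.

Meromictic acidic pit lakes hold extreme dissolved metal(loid) loads with
sharp vertical gradients — an oxic acidic surface layer, a chemocline, and a
metal-rich anoxic deep layer. `amdtox` is for geomicrobiologists and
environmental engineers who want to connect that geochemistry to microbial
gene content and expression from shotgun metagenomes and metatranscriptomes.
It implements, as tested reusable functions:

* **Toxic potency factors.** For element *e* with dissolved concentration
  *C<sub>e</sub>* (µg/L) and USEPA NAWQC-CCCF chronic criterion
  *S<sub>e</sub>* (µg/L, no hardness adjustment):

  TPF-1 = *C<sub>e</sub>* / *S<sub>e</sub>*  and  TPF-2 =
  *C<sub>e</sub>* · *f<sub>e</sub>* · *γ<sub>e</sub>* / *S<sub>e</sub>*,

  where *f<sub>e</sub>* is the free-cation fraction and *γ<sub>e</sub>* an
  optional activity coefficient (default 1). Per-layer rankings render as
  strings such as `Fe(II) >> Zn > Mn`. Arsenic gets no TPF-2 (not cationic);
  the Mn criterion is derived as the Fe criterion / 6.
* **Equilibrium speciation.** A damped fixed-point solver for
  metal–sulfate/chloride complexation in acidic water with Davies activity
  coefficients, fixed measured pH, and an editable thermodynamic constant
  file. Supplies free-ion fractions and predominant species per layer.
* **MRG catalog curation.** Best-hit selection (E-value < 10⁻⁴),
  KO-level aggregation with compound-set unions, metal-vocabulary plus
  curator-flag filtering, and source-precedence merging. Ships a 64-KO
  fixture catalog: 48 metal-specific marker KOs plus 16 exopolysaccharide
  (EPS) KOs used as extracellular-sequestration proxies.
* **Functional profiles.** Gene-level TPM (denominator over *all* predicted
  genes), KO aggregation, RNA:DNA expression ratios (zero-DNA entries are
  missing, never infinite), domain × mechanism rollups, and per-MAG profiles
  normalized within each MAG.
* **MAG filters.** MIMAG quality tiers, a ≥ 500 mapped-mRNA-reads rule, and
  greedy ANI dereplication at the 96.5% species boundary.
* **Synthetic data.** Negative-binomial count simulation over a generated
  gene catalog with planted MRG KOs and per-KO expression multipliers, so
  every stage runs and is testable with known ground truth and no downloads.

Fixture tables for a well-studied three-layer acidic pit lake (water
chemistry, criteria, speciation summaries, published potency values and
rankings, 13 deep-layer MAGs) ship under `inst/extdata/`.

## Worked example

Potency factors and ranking for the deep anoxic layer:

```r
library(amdtox)
tpf <- tpf_table(load_cm_chemistry(), load_cm_standards(),
                 load_cm_free_fractions(), warn = FALSE)
subset(tpf, layer == "deep",
       select = c(element, tpf1_reported, tpf2_reported))
#>  element tpf1_reported tpf2_reported
#>      SO4       4.8e+01            NA
#>       Cl       9.6e-02            NA
#>       Al       5.9e+01           3.5
#>  As(III)       1.1e+02            NA
#>    As(V)       8.7e-04            NA
#>       Co       1.1e+02          86.0
#>       Cu       5.6e+00           2.5
#>   Fe(II)       6.3e+03        4800.0
#>       Mn       7.0e+02         570.0
#>       Ni       1.8e+01           7.8
#>       Zn       9.1e+02         130.0
```

Fe(II) is by far the most potent stressor at depth — its dissolved
concentration sits 6300× above the chronic criterion, and still 4800× after
discounting to the free Fe²⁺ fraction. The ranking string makes the
dominance explicit (`>>` marks a ≥ 5-fold gap, `~` a ≤ 5% tie):

```r
rank_layers(tpf, "tpf1")[["deep"]]
#> [1] "Fe(II) >> Zn > Mn >> As(III) > Co > Al > SO4 > Ni > Cu >> Cl >> As(V)"
```

A synthetic community run end to end — simulate a 2000-gene catalog with 3%
planted MRGs, draw DNA/RNA counts, and profile expression:

```r
cat64 <- load_mrg_catalog()
cfg <- sim_config(n_genes = 2000, seed = 1)
genes <- gen_gene_catalog(cfg, cat64)
sim <- gen_count_tables(genes, cfg)
dna <- aggregate_by_ko_tpm(compute_tpm(sim$dna, genes), genes)
rna <- aggregate_by_ko_tpm(compute_tpm(sim$rna, genes), genes)
ex  <- expression_ratio(rna, dna)
annotated_fraction(genes, cat64)
#> [1] 0.03706468
round(ex[1:3, ], 3)
#>        rna_1 rna_2
#> K00522 0.176 7.642
#> K02037 0.256 0.684
#> K02038 0.204 0.975
```

The recovered MRG share (3.7%) sits within binomial noise of the planted 3%,
and the expression matrix gives per-KO RNA:DNA ratios per replicate (ratios
scatter around 1 here because no multiplier was planted; at the default
10⁷-read depth with multipliers planted via `expression_effects`, they are
recovered with ~7% median error).

See the vignette (`vignettes/metal-toxicity-profiling.Rmd`) for the models,
assumptions, numerical choices and limitations.

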