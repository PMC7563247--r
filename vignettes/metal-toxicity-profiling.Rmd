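---
title: "Metal toxicity and resistance-gene profiling in stratified acidic pit lakes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metal toxicity and resistance-gene profiling in stratified acidic pit lakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdtox)
```

## The scientific problem

Meromictic (permanently stratified) acidic pit lakes expose their microbial
communities to some of the highest dissolved metal(loid) concentrations found
in nature, with strong vertical gradients: an oxic, very acidic upper layer; a
sharp chemocline; and a deep anoxic layer where iron, zinc, manganese and
arsenite accumulate to g/L levels. `amdtox` implements the quantitative chain
needed to relate that geochemistry to community-level gene content and
expression:

1. **Which metal is most toxic in each layer?** Toxic potency factors from
   water-quality criteria, with equilibrium speciation supplying free-ion
   fractions.
2. **Which genes confer metal resistance?** A curated, KEGG-Orthology-keyed
   catalog of metal resistance genes (MRGs).
3. **How abundant and how expressed are they?** TPM-normalized functional
   profiles from metagenome/metatranscriptome read counts and RNA:DNA
   expression ratios, at the whole-community and per-MAG level.
4. **Does it all hold together?** A synthetic-data generator with known
   ground truth so the entire chain is testable without sequencing data.

## Toxic potency factors

For element $e$ with dissolved concentration $C_e$ (µg/L) and chronic
water-quality criterion $S_e$ (USEPA NAWQC constant contact concentration
factor, µg/L, no hardness adjustment):

$$\mathrm{TPF1}_e = \frac{C_e}{S_e}, \qquad
  \mathrm{TPF2}_e = \frac{C_e \, f_e \, \gamma_e}{S_e},$$

where $f_e$ is the free-cation fraction from speciation and $\gamma_e$ an
optional activity coefficient. TPF-2 reflects the free-ion activity model of
toxicity: the uncomplexed cation is the bioavailable, toxic form. Reconstructing
published potency tables shows that reported "free cation activity" values
equal concentration × free-ion percent, so `compute_tpf2()` defaults to
$\gamma = 1$ and keeps the coefficient as an explicit hook for a stricter
definition. Arsenic gets no TPF-2: under acidic conditions As(III) is a
neutral acid (H$_3$AsO$_3$) and As(V) an oxyanion, not a cation.

Manganese lacks a published criterion; its standard is derived as the iron
standard divided by six (the ratio of the two drinking-water standards),
kept at full precision in computation and rounded only for reporting.

Reported values use two significant figures, rounding half away from zero
(`round_sigfig()`); rankings join elements with `~` when the symmetric
relative difference is ≤ 0.05 and `>>` when the ratio is ≥ 5. Published
rankings place `~` and `>>` partly by author judgment — no single threshold
reproduces every mark — so only the element *order* (and `>>` after a clearly
dominant leader) should be treated as reproducible. The packaged fixtures
reproduce all six layer-by-type ranking orders exactly.

```{r tpf}
tpf <- tpf_table(load_cm_chemistry(), load_cm_standards(),
                 load_cm_free_fractions(), warn = FALSE)
subset(tpf, layer == "deep",
       select = c(element, tpf1_reported, tpf2_reported))
rank_layers(tpf, "tpf1")[["deep"]]
```

## Equilibrium speciation

`solve_speciation()` distributes each component total over its free form and
a declared set of complexes so that mass action (on activities) and mass
balance hold simultaneously:

* **Activity model.** Davies equation,
  $\log_{10}\gamma = -A z^2\!\left(\frac{\sqrt I}{1+\sqrt I} - 0.3 I\right)$
  with $A = 0.509$ fixed at its 25 °C value — lake temperatures of
  12.5–18.3 °C shift $A$ by under 2%, far below other uncertainties.
  Molarity is treated as molality (dilute approximation). The equation is
  trustworthy to $I \approx 0.5$ mol/L; the deep layer sits near
  $I \approx 0.25$, inside but not comfortably inside that range.
* **Solver.** A damped multiplicative fixed point on the free component
  concentrations (damping exponent 0.5, tolerance $10^{-10}$, 500-iteration
  cap), with ionic strength and all coefficients recomputed each sweep.
  Because every component stoichiometry is positive, the free form can never
  exceed its total; the update is clamped accordingly, which prevents the
  activity-coefficient feedback from diverging on concentrated compositions.
  Against the closed-form quadratic for any single-complex system the solver
  agrees to $10^{-10}$ relative.
* **Fixed pH, fixed redox.** Proton activity is $10^{-\mathrm{pH}}$ from the
  measured pH (no proton or charge balance), and redox couples
  (Fe(II)/Fe(III), As(III)/As(V)) enter as separate measured components —
  matching how field measurements are used. Mineral saturation and surface
  complexation are out of scope.
* **Constants.** The shipped complex set
  (`inst/extdata/thermo_default.yaml`) covers 1:1 and 1:2 metal–sulfate and
  metal–chloride pairs, bisulfate, and arsenic protonation states, with
  generic MINTEQ-family constants. **These constants are reference
  compilation values, not site-specific data**, and the file is editable.

A consequence worth stating plainly: published speciation percentages for
this lake came from PHREEQC with an unstated database and a fuller analyte
list (including Mg, Ca and Na, which pair with sulfate and thereby *raise*
free-metal fractions). With the shipped generic set and the metal-only
chemistry table, the deep-layer free Fe$^{2+}$ fraction computes to ~49%
versus the published 76.4%. The package therefore treats speciation
percentages as approximate, uses the *published* free-ion fractions (shipped
as a fixture) for TPF-2 reproduction, and holds the solver to internal
consistency (mass balance, oracle equivalence, monotonicity) rather than to
golden percentages.

```{r speciation}
deep <- speciate_layers(load_cm_chemistry())$deep
head(free_cation_table(deep))
```

## The MRG catalog

The catalog-building operations mirror a reproducible curation pipeline:

* `select_best_hits()` — keep annotations above the annotator's adaptive
  score threshold with E-value < 10⁻⁴ (boundary exclusive), one best hit per
  subject;
* `aggregate_by_ko()` — collapse database records sharing a KO, taking set
  unions of compounds and gene symbols;
* `filter_metal_only()` — keep KOs whose compounds intersect a metal
  vocabulary **and** whose curator flag is true. The flag externalizes the
  manual "gene description matches KO description" judgment: no text-matching
  heuristic can reproduce expert curation, so the package makes that step an
  explicit, auditable input column instead;
* `merge_catalog()` — combine database-derived, EPS-proxy and literature
  entries with unique KOs (database provenance wins on duplicates;
  conflicting mechanism labels are an error).

Because the upstream resistance-gene database is licensed data and not
bundled, the full pipeline is validated on toy tables, and the package ships
as ground truth the two printed marker sets: 48 KOs covering the seven
highest-toxicity metals (Al, Cu, Fe, Mn, Zn, Ni, As) across export, import,
biochemical transformation, regulation and intracellular accumulation, plus
16 exopolysaccharide (EPS) synthesis/assembly/transport KOs used as proxies
for extracellular metal sequestration — 64 KOs total via
`load_mrg_catalog()`.

```{r catalog}
cat64 <- load_mrg_catalog()
table(cat64$mechanism)
metals_for_ko(cat64, "K15726")   # czcA, a multi-metal efflux pump
```

## TPM profiles and expression ratios

For gene $g$ with length $L_g$ and mapped-read count $c_{gs}$ in sample $s$:

$$\mathrm{TPM}_{gs} = 10^6 \,
  \frac{c_{gs}/L_g}{\sum_{g'} c_{g's}/L_{g'}},$$

with the denominator over **all** predicted genes, annotated or not — so KO
profiles sum to less than 10⁶ whenever unannotated genes exist. KO profiles
are sums of member-gene TPM; expression is RNA TPM over DNA TPM per KO, with
zero-DNA entries *missing* (a ratio with a zero denominator is undefined —
it is neither infinity nor zero, and plots should show blanks). Replicates
stay separate samples; DNA and RNA libraries are paired positionally since
the two libraries of one biological sample carry different ids.
`slope_sign()` reports only the sign of the expression-versus-concentration
regression slope across layers — no statistical significance is implied.

Per-MAG profiles repeat the same chain *within* each MAG (the TPM denominator
is that MAG's own genes), which makes rows comparable across genomes of
different sizes. MAG selection applies the MIMAG tiers (medium = ≥ 50%
complete, < 10% contaminated; the high tier additionally needs rRNA/tRNA
evidence, so tables without it cap at medium), a minimum of 500 mapped mRNA
reads ("less than 500" is strict — exactly 500 is kept), and greedy ANI
dereplication at the 96.5% species boundary using the score
completeness − 5 × contamination. That score is a deliberate simplification
of full dereplication scoring, adequate for testing the selection rule; it is
not a reimplementation of dRep.

## The synthetic-data generator

The generator exists so every downstream stage has known ground truth:

* **Defaults are the study conditions.** Two replicate samples; ~50% of
  genes KO-annotated; 3% of annotated genes planted as catalog MRGs;
  log-normal gene lengths (median 900 bp, σ = 0.5 on the log scale);
  log-normal per-gene abundances (heavy-tailed community structure);
  10⁷ expected mapped reads per sample; negative-binomial counts with
  dispersion 0.3 (variance $\mu + 0.3\mu^2$), Poisson in the
  dispersion-zero limit.
* **Count model.** DNA means are proportional to abundance × length, so TPM
  recovery is exact in expectation; RNA means carry an extra per-KO
  multiplier. Because TPM is compositional, the realized RNA:DNA ratio of a
  KO is its multiplier times a constant shared by all KOs
  ($\sum_g a_g / \sum_g a_g m_{ko(g)}$); the generator records this realized
  expected ratio as the ground truth, not the raw multiplier.
* **Determinism.** Every stochastic operation takes an explicit seed and
  runs under a private, restored RNG stream, so identical configurations
  give byte-identical outputs. (R's base RNG is stream-based rather than
  counter-based; the private-stream wrapper delivers the same reproducibility
  guarantee.)
* **What it does not emulate.** Sequences, read-level error, assembly and
  binning artifacts, phylogenetic correlation among genes, and compositional
  coupling between layers. Passing recovery tests therefore certify the
  *quantification chain* — TPM, aggregation, ratios, filters — not the
  upstream bioinformatics.

Under the default conditions (10 000 genes, 200 planted KOs, depth 10⁷, two
replicates), planted expression multipliers are recovered with a median
absolute relative error of about 7%, and the planted 3% MRG share is
recovered inside its binomial 99% interval.

## Numerical choices and degenerate inputs

* All-zero count samples give all-zero TPM columns, never NaN.
* Mass-balance tolerance 10⁻⁸ relative; solver tolerance 10⁻¹⁰ (tightenable
  via `tol` for oracle-grade comparisons).
* Ranking ties break alphabetically, making output independent of input
  order; dereplication score ties break by MAG id for the same reason.
* Potency reporting rounds half away from zero (`signif()` banker-rounds).
* Elements without a criterion (SO₄, Cl at these levels, nutrient species)
  are skipped with a warning, not errored.
* Validation tolerance against published potency tables is 5% relative,
  because the published table rounds inconsistently (two significant figures
  in some cells, integers in others); two TPF-2 cells whose published
  free-ion percentages are coarsely rounded are checked at a documented
  looser bound.

## Problem sizes

The test suite and examples run at deliberately desk-scale sizes — 10⁴ genes,
200 KOs, 13 MAGs, depth 10⁷ — chosen so the full suite completes in seconds
while keeping every statistical check (binomial intervals, median recovery
error) well-powered. The real study's metagenomes (~10⁸ reads per layer) are
inputs the package deliberately does not consume.

## Known limitations

* Speciation percentages depend on the constant set; exact reproduction of
  database-specific published percentages is not promised (see above).
* The 222-KO full catalog and the 134-gene database intersection depend on a
  live database export and annotator version and are not reproduced; the
  procedure is, on toy tables.
* The Davies model degrades above $I \approx 0.5$ mol/L; for brines a Pitzer
  approach would be required.
* `~`/`>>` ranking separators beyond the dominant deep-layer leader are
  heuristics, not reproducible facts.
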