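# chemassembly

Molecular-formula ecology of rhizodeposits and null-model inference of
community assembly for rhizosphere studies.

## The problem

Plant roots release a chemically diverse pool of organic compounds
(rhizodeposits) that feeds the rhizosphere microbiome. Ultra-high
resolution mass spectrometry (FTICR-MS) resolves that pool into
thousands of molecular formulas, and DNA stable-isotope probing
(DNA-SIP) identifies the microbes that actively consume it. Linking the
two sides — does the chemistry assemble deterministically while the
microbes drift, and do the two covary? — requires a chain of
non-standard analyses: formula-level chemistry, presence/absence
ecology, mass-difference transformation networks, metabolite
"phylogenies", and phylogenetic null models applied to both datasets on
an equal footing. `chemassembly` implements that chain for R users
working on rhizosphere (or any soil/sediment) metabolome–microbiome
designs, together with seeded synthetic-data generators so every stage
has a ground-truthed recovery test.

## What it computes

* **Formula chemistry** — monoisotopic mass, O/C, H/C, DBE
  (= 1 + (2C − H + N + P)/2), modified aromaticity index, NOSC
  (= 4 − (4C + H − 3N − 2O + 5P − 2S)/C), and van Krevelen compound
  classes from an editable rectangle table.
* **Metabolome ecology** — chemodiversity (effective peak count),
  Sørensen distance 1 − 2|A∩B|/(|A|+|B|), compound-class relative
  abundances; intensities are never used.
* **Transformation networks** — pairwise mass differences matched
  against a reference list of biochemical deltas (±0.001 Da default);
  per-sample transformation counts and per-peak profiles.
* **Relational dendrograms** — MCD (molecular characteristics), TD
  (transformation-network shortest paths), TWCD
  (transformation-weighted characteristics), each via standardized
  Euclidean distance + deterministic UPGMA, serialized as newick.
* **Assembly null models** — betaMNTD
  bMNTD(k,l) = ½[Σᵢfᵢₖ minⱼ dᵢⱼ + Σⱼfⱼₗ minᵢ dᵢⱼ] and
  betaNTI = (bMNTD_obs − mean(bMNTD_null))/sd(bMNTD_null) under the
  taxa-shuffle null (999 replicates), with |betaNTI| > 2 classified as
  variable (+) or homogeneous (−) selection and |betaNTI| ≤ 2 as
  stochastic; Mantel coupling between metabolite and microbial betaNTI
  matrices.
* **Community statistics** — Shannon/richness, Bray–Curtis, PCoA,
  sequential two-way PERMANOVA, Mantel tests, exact two-tailed
  Wilcoxon enrichment with Benjamini–Hochberg FDR — all implemented
  from first principles and cross-checked against independent oracles
  (vegan, picante, base R) in the test suite.
* **¹³C accounting and SIP** — VPDB atom-percent conversion, excess
  ¹³C per compartment, allocation percentages, and heavy-fraction
  detection from density-resolved qPCR profiles.
* **Synthetic data** — generators for every input with controllable
  ground truth (treatment filtering strength, assembly mode, SIP
  density shift, planted allocations).

## Worked example

Generate a strongly filtered synthetic metabolome, build its MCD
dendrogram, and ask whether its assembly is deterministic; then do the
same for a neutrally assembled community on its phylogeny:

```r
library(chemassembly)

gm <- gen_metabolome(n_formulas = 300, strength = 1, detect_prob = 0.9,
                     stages = "W6", stage_effect = 0, n_replicates = 4,
                     seed = 7)
tapply(chemodiversity(gm$metabolome), gm$metadata$treatment, mean)
#>    P1   P10    P5
#> 29.75 17.00 25.50

mcd <- build_mcd(gm$metabolome$formulas)
bn <- beta_nti(gm$metabolome, mcd, n_null = 999, seed = 8)
bn
#> betaNTI matrix over 12 samples ( MCD , presence mode, 999 nulls, seed 8 )
#>   median betaNTI: 10.74606
round(classify_assembly(bn)$fractions, 3)
#>    variable_selection homogeneous_selection            stochastic
#>                 0.727                 0.106                 0.167

gc_ <- gen_community(n_tips = 200, mode = "drift", depth = 500, seed = 9)
bnc <- beta_nti(gc_$counts, gc_$tree, n_null = 999, seed = 10)
round(classify_assembly(bnc)$fractions, 3)
#>    variable_selection homogeneous_selection            stochastic
#>                     0                     0                     1
```

Chemodiversity declines along the mono-cropping gradient (29.8 → 17.0
formulas); the filtered metabolome is dominated by variable selection
(median betaNTI ≈ 10.7, 73% of pairs > +2), while the drift community
is 100% stochastic — the contrast the null models are designed to
detect. The ¹³C side works the same way:

```r
gi <- gen_isotope(seed = 11)
round(allocation_fractions(gi$pools[gi$pools$treatment == "P1", ]), 1)
#> shoot  root  soil
#>  16.2   8.2  75.6
```

(planted truth: 16/8/76% of photosynthesized C).

The full pipeline — simulate, metabolome, transformations, dendrograms,
assembly, community statistics, isotope, SIP — runs from one seeded
config and writes all tables/trees to a directory:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "demo_out")
```

A thin CLI wrapper with the same stages lives at
`inst/cli/chemassembly`.

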