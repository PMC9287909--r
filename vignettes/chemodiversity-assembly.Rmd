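---
title: "Chemodiversity and assembly of rhizodeposits and active microbiomes: methods"
author: "chemassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemodiversity and assembly: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemassembly)
```

# Scope

`chemassembly` implements the molecular-formula ecology of rhizodeposits
(root-derived organic compounds) and the null-model inference of
community assembly for both metabolite and active-microbial data, plus
the ^13^C accounting used in pulse-labelling / DNA-SIP experiments. It
consumes *assigned* molecular formulas (FTICR-MS peak tables with
element counts), count tables with a phylogeny, density-resolved qPCR
fraction tables and isotope pool tables. Raw-spectrum processing,
formula assignment from m/z, and amplicon/metagenome read processing
are out of scope and assumed done upstream.

# Molecular formula characteristics

For a formula C~c~H~h~O~o~N~n~S~s~P~p~ (c >= 1) the package computes the
monoisotopic mass (atomic masses fixed to 7 decimals in `ATOMIC_MASS`),
the van Krevelen axes O/C and H/C, and:

* DBE = 1 + (2c − h + n + p)/2, the ring-plus-double-bond count with
  trivalent N and P. A half-integer DBE marks a radical-inconsistent
  formula; it is flagged (`dbe_radical`), never dropped.
* AImod = (1 + c − 0.5o − s − 0.5h) / (c − 0.5o − n − s − p), the
  modified aromaticity index, set to 0 when the denominator is <= 0.
  Negative values (saturated, oxygen-rich formulas such as sugars) are
  kept as computed rather than floored at zero — they carry ordering
  information for the characteristics-based dendrogram, and flooring
  would create an artificial point mass at 0.
* NOSC = 4 − (4c + h − 3n − 2o + 5p − 2s)/c, the nominal oxidation
  state of carbon.

Compound classes use the widely adopted rectangular O/C x H/C windows
(seven classes: lipids, proteins/amino sugars, carbohydrates,
unsaturated hydrocarbons, lignins, tannins, condensed aromatics). The
boundary table ships as editable CSV (`inst/extdata/vk_classes.csv`);
intervals are half-open on documented sides so the classes are disjoint
and classification is a total, deterministic function with
"unclassified" as the fallback.

# Presence/absence ecology

All metabolite statistics are computed on binary incidence: peak
intensities are retained on import but never consulted, because charge
competition makes FTICR-MS intensities only semi-quantitative.
Chemodiversity is the effective peak count per sample (row sum of the
incidence matrix); sample dissimilarity is Sørensen's distance
d(A,B) = 1 − 2|A∩B|/(|A|+|B|).

# Transformation networks

Putative biochemical transformations are detected as pairwise peak mass
differences matching a reference list of element-count deltas
(functional groups and the full amino-acid residue set; bundled as an
editable CSV with masses recomputed from the counts, never trusted from
the file). The default tolerance is 0.001 Da, suited to FTICR-MS mass
accuracy; a ppm mode is available. Matching is within-sample for the
per-sample transformation counts; the pooled all-sample network feeds
the TD dendrogram. A pair matching k reference entries yields k
parallel edges, counted separately.

# The three relational dendrograms

The metabolite null models need tip-to-tip distances playing the role
of a phylogeny. Three constructions are provided:

* **MCD** — standardize the characteristics matrix (element counts,
  mass, O/C, H/C, DBE, AImod, NOSC) to zero mean/unit variance
  (constant columns dropped with a message), Euclidean distance, UPGMA.
* **TD** — unweighted shortest-path length in the pooled transformation
  network, restricted to the largest connected component (dropped tips
  are recorded in the construction record so downstream analyses use
  the reduced formula set consistently), then UPGMA.
* **TWCD** — standardized characteristics concatenated with the
  standardized per-peak transformation-count profile (intersection of
  the formula sets), Euclidean, UPGMA. With an all-constant profile the
  TWCD degenerates exactly to the MCD.

The reference method for these dendrograms is not printed in full
anywhere we could consult, so the construction above is a committed,
fully documented choice with each knob (scaling, linkage, component
policy) exposed. TD edges are unweighted by transformation frequency by
default; weighting is a plausible alternative, but an unweighted path
length is the simplest interpretable metric.

UPGMA is implemented in the package (rather than through `hclust`) so
that merge ties are broken deterministically: among equal-distance
candidate pairs the one with the lexicographically smallest cluster
representative labels is merged. This makes all three dendrograms
invariant to input row order and reproducible bit-for-bit, which
matters because the TD path-length matrix is integer-valued and full of
ties. The trees are ultrametric by construction, serialize to newick
losslessly (cophenetic distances preserved to 1e−9), and are
cross-checked in the tests against a brute-force pairwise-average
agglomeration oracle.

# betaMNTD, betaNTI, and process classification

For communities k, l with tip distances d:

bMNTD(k,l) = 0.5 [ Σ~i∈k~ f~ik~ min~j∈l~ d~ij~ + Σ~j∈l~ f~jl~ min~i∈k~ d~ij~ ]

with weights f either relative abundances (microbial default) or
1/richness (presence mode; forced for metabolite incidence data). The
null model is the standard taxa shuffle: tip labels of the distance
matrix are permuted uniformly at random, bMNTD recomputed, and

betaNTI = (bMNTD~obs~ − mean(bMNTD~null~)) / sd(bMNTD~null~)

with the sample standard deviation over replicates (default 999,
minimum 99; the seed is mandatory). |betaNTI| > 2 is read as
deterministic assembly (positive: variable selection, negative:
homogeneous selection), |betaNTI| <= 2 as stochastic; the threshold is
the conventional two-sigma rule and is exposed as a parameter.
Degenerate nulls (sd = 0, e.g. on a star tree or when two samples share
an identical feature set) yield NaN, never ±Inf; all downstream
statistics exclude NaN pairs listwise and report the count. Whether the
reference studies abundance-weighted their microbial bMNTD is not
stated; abundance weighting is the declared default and switchable.
Raup–Crick partitioning of the stochastic fraction is deliberately not
implemented.

Coupling between metabolite and microbial betaNTI matrices uses a
Mantel test (Pearson on upper-triangle entries, NaN pairs excluded,
one-sided p with the add-one rule).

# Permutation statistics

All permutation p-values use (exceedances + 1)/(n~perm~ + 1) and can
never be zero. Two-way PERMANOVA uses the Gower-centred inner-product
matrix with sequential (Type-I-like) projection of factor A then B, no
interaction term, residual df N − a − b + 1, and free permutation of
the distance-matrix rows; the one-way special case reduces exactly to
the classical between/within decomposition of pairwise distances
(verified against that identity, and against `vegan::adonis2` for the
sequential two-way case). Shannon diversity uses the natural log.
Wilcoxon enrichment is exact by full enumeration of rank assignments
(valid under ties) whenever both groups have <= 10 samples, otherwise a
tie-corrected normal approximation; multiplicity is handled by
Benjamini–Hochberg. Note that duplicating every sample of a balanced
design doubles all PERMANOVA sums of squares and leaves their ratio
invariant, but scales the pseudo-F through the residual df — the F
statistic itself is not duplication-invariant.

# Isotope accounting and SIP

Atom percent ^13^C follows the VPDB formulation: R = R~VPDB~(δ/1000 + 1)
with R~VPDB~ = 0.0111802, atom% = 100R/(1+R). Excess ^13^C per
compartment is (atom%~labeled~ − atom%~control~)/100 × (mass × C
concentration); negative excess is preserved and flagged, not clamped.
Allocation is each compartment's share of total excess; it is
scale-invariant and sums to 100%. The exact heavy-fraction selection
rule of the reference experiments is not published, so the committed
rule is: normalize copies to proportion-of-total per gradient,
interpolate the control onto the labeled densities, and take the
maximal contiguous run of fractions with density >= 1.72 g/mL and
labeled/control ratio >= 1.5 (ties broken toward the denser run); both
thresholds are parameters, and an empty result is reported as "no
detectable labeling".

# The synthetic-data generators

The generators define the conditions under which every stage is
testable without the original raw data; their defaults mirror a
3-treatment (mono-cropping duration) × 2-stage × 4-replicate design.
They emulate:

* **Formula space** (`gen_formulas`): seed formulas drawn from a
  mixture of compound-class archetypes (lignins 35%, lipids 28%,
  proteins/amino sugars 13%, the rest minor — the dominance order
  reported for rhizodeposit spectra), grown into homologous series by
  applying common biochemical deltas (H2, CH2, O, NH3, H2O, CO, CH2O,
  C2H2O, CO2). Two facts of real FTICR data motivate the two steps:
  chemistry is clustered by compound class (so the characteristics
  matrix must have low-dimensional structure — independent uniform
  element counts instead produce a near-star UPGMA tree in which no
  filtering signal can register), and spectra are dominated by
  homologous series (so exact-delta pairs must be common, otherwise
  the transformation network is empty and the TD dendrogram
  undefined).
* **Metabolome treatment structure** (`gen_metabolome`): each formula's
  latent treatment affinity is its score on the first principal
  component of the standardized characteristics — the dominant axis of
  chemical variation. Treatments filter through Gaussian niches
  (width 0.25 trait SD) at well-separated optima (trait quantiles
  0.05/0.5/0.95 for three treatments). Detection is
  density-calibrated (divided by the niche's total filter mass) so
  niche placement does not confound expected chemodiversity, then
  multiplied by a geometric decline (15% per treatment step, active
  only when `strength > 0`) so chemodiversity falls monotonically in
  expectation along the treatment order. At `strength = 0` all
  treatments share one detection probability. The first growth stage
  detects 15% fewer peaks, mirroring lower early-season deposition.
* **Communities** (`gen_community`): a pure-birth tree with a
  Brownian-motion trait. Selection mode places Gaussian niches on the
  trait with treatment-specific optima; drift mode draws every sample
  from one shared lognormal metacommunity (multinomial at the stated
  depth).
* **SIP gradients** (`gen_sip`): a Gaussian control profile over 15
  fractions (1.66–1.78 g/mL) and a labeled profile mixing the control
  with a +0.03 g/mL-shifted component (half of the DNA, roughly a
  moderately labeled community), with 5% multiplicative lognormal qPCR
  noise. The planted heavy window is the selection rule applied to the
  noiseless profiles.
* **Isotope pools** (`gen_isotope`): planted allocation fractions per
  treatment (defaults emulate a belowground share falling from 76% to
  43% across treatments) converted back to labeled δ^13^C with 2‰
  Gaussian noise.

Ground-truth objects accompany every generated dataset and are consumed
only by tests, never by pipeline stages.

## What the generators do and do not emulate

They reproduce treatment-structured incidence, phylogenetically
structured counts, density-shifted gradients and enriched isotope
pools, with controllable truth. They do not emulate peak alignment
error, intensity-dependent detection, compositional sequencing
artefacts, chimeras/contaminants, spatial or temporal autocorrelation,
or covariance between the metabolite and microbial sides beyond the
shared design. A passing recovery test therefore shows the estimators
detect the planted signal class under realistic-but-idealized noise; it
does not certify performance on any particular real dataset.

## Calibration regimes worth knowing

Two properties of the taxa-shuffle null observed while designing the
recovery tests are documented here because they apply to real data as
well:

* At sequencing depth high relative to the species pool, samples
  saturate (every taxon present everywhere), bMNTD collapses to ~0
  under any labelling and the null degenerates (NaN betaNTI).
* In a single metacommunity realization, chance phylogenetic
  clustering of the dominant taxa can push all pairwise betaNTI in one
  direction even under pure drift.

The drift recovery condition therefore uses sparse sampling (200 tips,
depth 500, 8 samples), where the null is well calibrated; the
strong-selection condition uses 400 formulas, full filter strength,
in-niche detection 0.95, 3 treatments × 4 replicates at one stage, 999
nulls.

# Numerical choices

* Monoisotopic masses to 7 decimals; mass-consistency tolerance for
  peak tables 0.005 Da (flag, don't drop; dropping is opt-in).
* Computed reference delta masses must agree with any user-supplied
  values to 1e−5 Da.
* UPGMA merge ties resolved lexicographically (see above); merge
  candidates equal within 1e−12 are treated as tied.
* PCoA axes are reported for eigenvalues above 1e−10 of the largest;
  each axis's sign is fixed by making its largest-magnitude loading
  positive; negative eigenvalues are reported, their axes omitted.
* betaNTI null variances are computed from running sums; tiny negative
  variances from cancellation are truncated at 0 (degenerate-null
  path).
* Pipeline outputs are written with 17 significant digits so repeated
  runs are byte-identical.

# Problem sizes

The demo configuration (`default_config()`) uses 200 formulas, a
120-tip phylogeny at depth 2000, 24 samples and 999 null/permutation
replicates — a scale chosen so the full pipeline completes in well
under a minute while every statistic still behaves as at full scale.
The recovery tests use the condition sizes listed above; oracle
cross-checks run on instances of up to 20 features / 10 samples where
brute force is exact and fast.

# Known limitations

* The dendrogram constructions and the heavy-fraction rule are
  committed interpretations of methods whose originals are not fully
  published; both are parameterized so alternative published lists or
  thresholds drop in without code changes.
* Metabolite "communities" violate several assumptions microbial null
  models were built for (formulas are not replicating units); the
  package follows the meta-metabolome ecology convention of treating
  them analogously, which is exactly what the betaNTI-on-dendrogram
  machinery expresses — interpretation of metabolite "selection" is the
  user's burden.
* The two-way PERMANOVA has no interaction term (matching the
  main-effects-only reporting convention it implements) and uses free
  permutation; restricted permutation schemes for nested or repeated
  designs are not provided.
* RCbray / per-clade process partitioning is out of scope.
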