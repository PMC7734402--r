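---
title: "Methods: thermal-adaptation signatures and their models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-adaptation signatures and their models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotrace)
```

This vignette is the package's own account of what it computes, which
choices were open, and how they were resolved. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The signatures

Growth at high temperature leaves measurable marks on a genome. The ones
this package computes, per genome, are:

- **Genomic G+C**, whole and in sliding windows. `gc_content()` is
  `(G+C)/(A+C+G+T)` with IUPAC ambiguity codes excluded from numerator and
  denominator; an all-ambiguous sequence is an error, not a zero. Genomic
  G+C is *not* generally correlated with OGT — it is reported because
  low-G+C outliers are taxonomically informative, not as a thermometer.
- **16S rRNA G+C** (`gc_16s`, the mean over gene copies): stems of the rRNA
  secondary structure must stay base-paired at growth temperature, so this
  fraction does track OGT across prokaryotes.
- **CvP bias**: `100 * (fD+fE+fK+fR - (fN+fQ+fS+fT))` in percentage points,
  range [-100, 100]. Charged-vs-polar surface residues stabilize folds
  through ion pairs at high temperature. Histidine is excluded from the
  charged set, matching the index's established convention; both residue
  sets are arguments and can be overridden.
- **IVYWREL fraction**: `fI+fV+fY+fW+fR+fE+fL`, range [0, 1], approximately
  linear in OGT across large prokaryote panels.
- **rRNA operon count and minimum pairwise 16S copy identity**: multiplicity
  is ecologically informative, and inter-copy identity bounds how much
  intragenomic 16S heterogeneity could confound placement.
- **AT3/GC3**: the fraction of *sense* codons with A/T (resp. G/C) at the
  third position; stop codons are counted separately and excluded, codons
  containing ambiguity symbols are excluded everywhere. AT3 + GC3 = 1 by
  construction. This diagnoses whether a low genomic G+C is driven by
  synonymous third positions.

### The membrane filter

Integral membrane proteins are enriched in hydrophobics for reasons
unrelated to temperature, so both composition indices are computed after
removing proteins with **2 or more** predicted transmembrane helices
(`filter_soluble()`, keep `tm_helix_count < 2`). Dedicated TM-topology
predictors are external web tools, so the package provides two routes:

1. an **external table** of per-protein helix counts produced by any
   predictor (`add_tm_helix_counts(proteins, external = ...)`), which is the
   higher-fidelity route; or
2. a **hydropathy surrogate** (`count_tm_helices()`): sliding-window mean
   Kyte–Doolittle hydropathy (window 19 residues, odd and ≥ 7 enforced),
   one helix per maximal run of window positions with mean ≥ 1.6, runs
   closer than 10 residues merged, proteins shorter than the window
   scoring 0. Window 19 approximates the membrane-spanning helix length;
   1.6 is the classical cutoff for candidate TM segments on this scale.
   Selenocysteine is scored as cysteine; letters without a scale value
   score 0.

The surrogate is a deliberately simple heuristic: it finds unambiguous
hydrophobic stretches and nothing more. Expect it to disagree with HMM-based
predictors near the margin; when per-protein counts from such a predictor
are available, supply them.

### Translation and exclusions

CDS are translated with NCBI genetic code table 11 (alternative initiator
codons become Met). Proteins are flagged and excluded from all composition
statistics when their CDS length is not a multiple of 3, when an in-frame
stop occurs before the final codon, or when more than 5% of residues are X
(translated from ambiguous codons; threshold configurable). X/U/B/Z residues
are excluded from composition numerators and denominators. Coordinates are
0-based half-open internally, converted once from GenBank's 1-based
inclusive convention on read; `join()` locations become multi-interval
features whose parts are concatenated before (reverse-complemented)
translation, which also handles genes spanning a circular origin.

## Regression against optimum growth temperature

`fit_linear_model()` is ordinary least squares with the metric on the y axis
and OGT (°C) on the x axis (`metric_on_ogt`), matching how such comparative
panels are conventionally drawn; the inverse orientation is available for
direct OGT prediction, and `predict_ogt()` inverts a `metric_on_ogt` line
(zero slope is a non-invertibility error). `ogt_residual()` is the observed
metric minus the line's prediction at the observed OGT: positive means "more
thermophile-like than the growth temperature predicts". `compare_profiles()`
flags species whose |residual| exceeds 2 fitted residual SDs (the `flag_sd`
argument) — that flag is how a retained ancestral signature shows up.

Published regression lines from large prokaryote panels are useful
references, but their coefficients are not redistributable facts this
package can vouch for; they are therefore supplied by the user through a
flat `key=value` config (`read_model_config()`), and the example config the
package ships contains clearly labelled synthetic placeholders. Fitted and
literature residuals are reported side by side.

Correlation tests (`correlate_metric_ogt()`) use `cor.test()` with Pearson
or Spearman, two-sided, on pairwise-complete rows per metric — species
tables routinely have missing fields, and complete-case deletion across all
metrics would discard usable pairs.

**Open choice, resolved:** whether proteome composition should pool residues
across the proteome or average per-protein frequency vectors is genuinely
ambiguous in the literature ("average CvP" can mean either). The package
defaults to pooled counts — it matches the index definitions, which are
stated over residue frequencies of the protein set — and exposes
`per_protein_mean` so both can be reported when it matters. The two differ
whenever composition covaries with protein length.

## Phylogenetic placement

Pairwise identity uses affine-gap global alignment
(`global_align()`, match +1, mismatch −1, gap open 5, gap extend 1, a gap of
length L costing `open + L·extend`; N scores 0 against everything).
`percent_identity()` defaults to excluding columns containing a gap or N
from the comparison, so "identity" means identity over confidently compared
columns; `include_gaps` is available for the stricter convention. The two
conventions differ most for partial sequences, which is why the default is
the forgiving one.

Distances (`distance_matrix()`) are p-distances with **pairwise** gap
deletion (a column is dropped only for pairs it affects, the common CLUSTAL
behavior), optionally Jukes–Cantor corrected,
`d = -(3/4)·ln(1 - 4p/3)`. JC is undefined at `p ≥ 0.75`; that raises an
error naming the saturated pair rather than returning NaN, because a
saturated pair invalidates the tree, not just one entry.

`neighbor_joining()` is the standard Saitou–Nei agglomeration: join the pair
minimizing `Q(i,j) = (r−2)·d(i,j) − R_i − R_j`. Two numerical policies are
fixed: ties in Q are broken deterministically toward the earliest-created
pair of nodes (so equidistant, star-like matrices always produce the same
topology), and negative estimated branch lengths — which NJ can produce on
noisy matrices — are clamped to 0 with the deficit transferred to the sister
branch, preserving the path length between the joined pair. On additive
matrices the algorithm reproduces every leaf-to-leaf path exactly; the test
suite checks this on 200 random additive matrices of 4–12 taxa, and
`ape::nj()` serves as an independent topology cross-check.

Bootstrap support (`build_nj_tree()`) resamples alignment columns with
replacement (default 100 replicates, seeded), rebuilds the tree per
replicate, and labels internal nodes with the percentage of replicates
recovering each clade. Multiple-sequence alignment is intentionally **not**
implemented: rRNA alignment is curation work done by dedicated tools; the
package consumes pre-aligned FASTA.

## The synthetic-data generator

The generator exists so every stage has inputs with known truth. Its
defaults are fixed study conditions, not tuning knobs:

- `genome_spec()`: 100 kb circular chromosome, G+C target 0.258, 60 CDS of
  300–900 bp, 6 rRNA (16S-like) gene copies at 0.1% per-site divergence.
  These emulate, at one twenty-fifth scale, a low-G+C genome with an
  unusually high rRNA operon count; 100 kb keeps the binomial noise on
  realized G+C near 0.0013, comfortably inside the ±0.005 recovery
  tolerance, while profiling stays fast enough to run on a grid in the
  test suite.
- CDS are generated protein-first: residues are drawn i.i.d. from a
  composition solved to meet the spec's CvP and IVYWREL targets (see below),
  then back-translated by sampling synonymous codons with weights from
  independent base probabilities at a solved G+C level — chosen by root
  finding so the expected CDS G+C matches the genome target where the
  amino-acid composition permits, and saturating at the composition-implied
  bound otherwise (a realistic effect: coding sequence cannot be as AT-rich
  as intergenic background). The i.i.d. background then compensates the
  realized feature G+C so the whole genome hits its target in expectation.
  A consequence worth noting: in low-G+C specs the synonymous weighting
  drives third positions strongly toward A/T, so AT3 > GC3 by construction.
- The composition solver (`solve_composition()`) splits mass evenly within
  residue groups: charged {D,E,K,R}, polar {N,Q,S,T}, the IVYWREL-only
  residues {I,V,Y,W,L}, and the remainder. Because E and R belong to both
  the charged and IVYWREL sets, an even split makes some target pairs
  jointly infeasible (CvP +100 with IVYWREL 0, for instance); infeasibility
  errors name the binding constraint. Solving a composition rather than
  rejection-sampling keeps the generator fast and unbiased.
- Membrane-like proteins (`tm_protein_fraction`) receive a two-helix insert:
  two 25-residue hydrophobic stretches flanking a 40-residue polar linker.
  Two helices, not one, because the soluble filter keeps single-pass
  proteins (< 2 helices); a multi-pass insert is what the filter is defined
  to remove. Note that with an IVYWREL target of 0.40 the background
  composition is itself hydrophobic enough that a few percent of proteins
  without inserts cross the surrogate's threshold — the generator controls
  the *excess* removal, exactly as in real proteomes.
- The 16S-like template is a fixed packaged 1,500-base random sequence
  (G+C 0.5), deliberately *not* a biological 16S: tests need structure
  (copy count, divergence, strand placement), not homology. Copies mutate
  per site with the spec's divergence, uniformly over the three other bases.
- `generate_species_table()` draws OGTs uniformly on a range (default
  20–100 °C) and sets `metric = intercept + slope·OGT + N(0, noise_sd)`,
  keeping the noiseless truth alongside.

Every generator is a pure function of its spec including the seed, and
restores the caller's RNG state.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: operon architecture (16S genes are generated
solo, so "operon count" is the 16S copy count), codon usage beyond a single
G+C-driven bias (no amino-acid-specific codon preferences, no expression
covariates), indels in rRNA copies (copies are equal length, though the
identity machinery aligns them anyway), compositional heterogeneity along
the chromosome (background is i.i.d., so windowed G+C is flat up to noise),
lateral gene transfer, and any phylogenetic covariance between species in
the regression tables (points are independent, which real lineages are
not — phylogenetically corrected regression is out of scope).

## Numerical choices and degenerate inputs

- **Windowed G+C tails**: a final window shorter than the window size is
  emitted as its own window for linear genomes, which makes the
  length-weighted mean of window values equal the whole-genome G+C to
  1e-12 (a property the tests enforce). For circular genomes the final
  window wraps past the origin to full length; when the length is not a
  multiple of the step the wrapped bases are then counted twice in a
  weighted mean, so the conservation identity holds only in the linear
  or evenly dividing cases. A window larger than the genome degrades to a
  single whole-genome window with a warning.
- **mol% formatting**: output tables print G+C as percent with one decimal
  (the precision such values are conventionally reported at); all index
  columns print with four decimals so identical runs give byte-identical
  files.
- **Degenerate regressions**: fewer than 2 points or constant x is an
  error; constant metrics in `compare_profiles()` are skipped with a
  warning rather than failing the whole panel.
- **Profile failures**: `profile_genomes()` isolates per-genome errors
  (stage-labelled) into NA rows with warnings, so one malformed record does
  not kill a batch run.
- **Problem sizes in the checks**: the acceptance computations use a 100-kb
  genome, 500 proteins of 300 residues, 500 regression replicates of 20
  species (1,000 for the null), 200 additive matrices of 4–12 taxa, and 100
  random genomes for the window identity — sizes at which every stochastic
  tolerance has ≥3σ headroom.

## Known limitations

- The TM surrogate is a hydropathy heuristic, not a topology model; use an
  external predictor's counts for publication-grade filtering.
- Identity values depend on the alignment scoring scheme; published
  similarity percentages computed with other aligners or curation-based
  alignments will not reproduce exactly. Genus-level arguments should rest
  on robust bounds (e.g. "below 90%"), not on matching a third decimal.
- NJ is a distance method; for contentious placements, treat the tree as a
  placement sketch and corroborate with model-based inference (out of
  scope here).
- Regression across species ignores phylogenetic non-independence; slopes
  are descriptive, and residual flags are screening devices rather than
  hypothesis tests.
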