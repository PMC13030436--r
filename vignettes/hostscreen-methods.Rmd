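---
title: "Methods: germplasm diversity assessment and entropy-weighted TOPSIS host screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germplasm diversity assessment and entropy-weighted TOPSIS host screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostscreen)
```

# Scope and scientific setting

`hostscreen` implements an integrated germplasm-evaluation workflow for
screening elite host genotypes in parasitic-plant cultivation, modelled on
the fourwing saltbush (*Atriplex canescens*) / desert broomrape
(*Cistanche deserticola*) system. The workflow has four analytical layers
plus a simulator:

1. **Sequence diversity** (`seqdiv` functions): intraspecific variation at
   the nuclear ribosomal ITS locus — GC content, segregating and
   per-genotype polymorphic sites, nucleotide diversity (pi), haplotype
   collapse and diversity (Hd), pairwise genetic distances, a
   neighbor-joining tree and a minimum-spanning haplotype network.
2. **Phenotype statistics**: monthly growth rates with phase labels,
   coefficients of variation, the Shannon–Wiener phenotypic diversity
   index, leaf-size classification, group contrasts between historically
   parasitised (P) and non-parasitised (NP) genotypes, and one-way ANOVA
   with Duncan's multiple range test.
3. **Correlation screening**: a Pearson matrix with t-based p-values and
   Benjamini–Hochberg FDR control applied jointly over all tested pairs.
4. **Multi-criteria ranking**: min–max normalisation, entropy weighting
   with information utility, weighted-Euclidean TOPSIS closeness to the
   ideal solution, CRITIC weighting as an independent cross-check, and
   Spearman rank agreement between the two rankings.

Because raw field measurements for this system are not publicly deposited,
the package ships a seeded synthetic-data generator whose **defaults are
the study conditions**: a 31-accession ITS panel of ~644 bp with GC
fraction 0.5835, 22 haplotypes sharing accessions as
{5, 3, 2, 2, 2} + 17 singletons, 1-bp and 2-bp deletions; and a
17-genotype evaluation panel (7 P, 10 NP) measured July–October with 10
replicates. Accession and genotype IDs follow the planting row–column
scheme of the study panels (`sequencing_panel()`, `evaluation_panel()`).

# The synthetic generator

## ITS alignments

`generate_its_alignment()` must produce an alignment whose *collapse*
under the default gap policy recovers exactly the configured haplotype
sharing. The construction is deliberately combinatorial rather than
evolutionary:

* The consensus is built with an **exact GC count** (`round(gc * L)`
  positions drawn at random receive G or C), so the consensus GC tracks
  the target to within 1/L rather than binomially. Substituted bases are
  drawn from the target composition, preserving GC in expectation.
* Every non-reference haplotype carries a configurable number of
  **private substitution sites** (disjoint site sets). Disjointness
  guarantees pairwise distinctness of all haplotypes with the minimum
  possible number of variable columns (k − 1 for k haplotypes), and makes
  the per-genotype polymorphic-site count (differences from the majority
  consensus) equal to the haplotype's private-site count — mirroring how
  the dominant haplotype's accessions show zero polymorphic sites while
  extreme accessions can be configured to carry, say, 13.
* Deletions are realised as `-` runs (1 or 2 bp) in carrier haplotypes
  only; the study reports only deletions, so insertions are not modelled.
* The total number of variable columns in the real alignment is not
  published; it is exposed as `n_variable_sites` (default 40, enough to
  give every one of the 21 non-reference haplotypes one to two private
  sites) rather than guessed at.

The generator returns the ground-truth assignment labelled by first
occurrence, so tests can compare collapse output to truth exactly.

## Trait tables

`generate_trait_tables()` emulates the trait structure the downstream
statistics assume, not the biology that produced it:

* **Agronomic traits** (H cm, BN, NN, SBD mm) follow non-decreasing
  monthly mean trajectories back-calculated from the published monthly
  relative growth rates anchored at the October means (27.6 cm, 3.22,
  16.6, 6.5 mm). Each genotype carries a multiplicative lognormal effect
  (mean-one) on the CV scale plus replicate noise, so the genotype-level
  CV is roughly `sqrt(cv_genotype^2 + cv_resid^2)` in every month.
* **Group effects** are additive offsets on trait means for a named group
  (optionally month-restricted). Defaults: node number +3.3 for the P
  group in September–October, and P advantages of 0.0108 / 0.0308 /
  0.0296 on Fv/Fm, Y(II) and qP (the fluorescence block means are the NP
  baselines). Only group mean *differences* are reported for the study
  system; an additive model is the least-committal generative reading.
* **Leaf morphology and chlorophyll fluorescence** are drawn from latent
  multivariate Gaussians located at the published means/SDs. The target
  correlation is imposed on both the between-genotype and within-genotype
  components, so the observation-level correlation converges to the
  target at large n (verified by Monte-Carlo test at ~5000 draws,
  tolerance 0.05). Correlation targets are validated for symmetry, unit
  diagonal and positive semi-definiteness, with the offending eigenvalue
  named otherwise.
* One default was forced by geometry: leaf area correlates 0.88 with
  length and 0.66 with width, which is only embeddable if length–width
  correlate at least ~0.23. The reported length–width association is weak
  and non-significant, so the default is set to **0.30** — the smallest
  round value compatible with positive semi-definiteness and still
  non-significant at n = 17.
* Unit-interval traits (SC and the fluorescence ratios) are clamped to
  `[0, 1]`, other traits at 0; with the default parameters clamping is a
  rare tail event and does not visibly distort correlations.

What the generator does **not** emulate: coalescent or substitution-model
ITS evolution, rate heterogeneity, recombination, measurement drift
across months, genotype-by-month interaction beyond the shared
trajectory, or any actual parasitism outcome. Passing tests therefore
demonstrate correctness of the *statistics* under a controlled data
model, not biological realism of the inputs.

# Sequence-diversity choices

* **Gap policy.** The default (`exclude_gap_columns`) removes any column
  containing `-` or `N` from *all* statistics, matching the
  complete-deletion default of the standard population-genetics tools
  this layer mirrors. `include_gaps` treats the gap as a fifth state for
  haplotype identity only, letting the 1–2 bp deletions distinguish
  haplotypes when that is wanted.
* **Per-genotype polymorphic sites** are not well defined without a
  reference; the package counts differences from the strict-majority
  consensus with ties broken to the alphabetically first base. This is
  the only reading that yields per-accession counts (0 for accessions of
  the dominant haplotype, up to 13 for extreme accessions).
* **Distances.** p-distance is the default; Kimura two-parameter is
  optional, with an explicit domain error naming the saturated pair
  instead of silent `NaN`s. Both are computed on the shared
  analysed-column set so pi equals the mean pairwise p-distance exactly
  (a cross-operation invariant under test). The published distance range
  (0–0.0245) is data-dependent and is not a target.
* **Neighbor joining** uses the Saitou–Nei Q-criterion agglomeration
  (via `ape::nj`). Negative branch lengths — a known NJ artefact — are
  clamped to zero with the deficit transferred to the adjacent branch
  (descendant edges, else the sibling), preserving path lengths
  approximately. On additive matrices no negatives arise and recovery is
  exact (property-tested over random 5–8 leaf trees).
* **Haplotype network.** The epsilon = 0 minimum-spanning network: an
  edge is retained iff its endpoints are disconnected among strictly
  lighter edges, i.e. exactly the edges belonging to at least one minimum
  spanning tree. This is deterministic and testable by spanning-tree
  enumeration; median-joining with epsilon > 0 is out of scope, and the
  qualitative "clusters" of a network figure have no quantitative
  definition and are not labelled.

# Phenotype-statistics choices

* **Growth phases.** The stagnation threshold is 12% (the study's stated
  criterion); the maximal month-pair rate is labelled "rapid", everything
  else "stable", with stagnation taking precedence. Two totals are
  reported: the overall relative change `100 (m_last − m_first)/m_first`
  (which matches the study's narrative totals, e.g. ~168% for height) and
  the additive sum of monthly rates. The study's own summary row is
  internally inconsistent with both aggregations and is not reproduced.
* **CV** uses the sample SD (n − 1) throughout; CVs are reported to two
  decimals, or rounded to integers when matching integer-printed summary
  tables.
* **Shannon–Wiener H′.** The class count and binning rule behind
  published germplasm H′ values are almost never stated. The package uses
  the convention common in crop germplasm studies — `n_classes` (default
  10) equal-width classes spanning `[mean − 2 SD, mean + 2 SD]` with
  open-ended extreme classes — and exposes both the class count and
  explicit breaks. Printed H′ values are consequently not acceptance
  targets; the invariants (H′ = 0 for constant data,
  H′ ≤ ln n_classes with equality at uniform occupancy) are.
* **Leaf classification** uses leaf area alone (large ≥ 2.50 cm²,
  small < 1.80 cm², boundary inclusive for large), because leaf area
  drives the size narrative; the shape-coefficient ranges are reported as
  a consistency flag, not a second classifier, since the two criteria can
  disagree.
* **Proportion above the overall mean** is computed over genotype-level
  means, not individual plants: the published group sizes (7 and 10)
  match the genotype counts, not the replicate counts.
* **Duncan's multiple range test** is implemented classically:
  studentized-range critical values at protection levels
  `alpha_p = 1 − (1 − alpha)^(p−1)`, standard error from the harmonic
  mean of group sizes, and the shielding rule that a non-significant
  range is not subdivided. Letters come from the maximal homogeneous
  intervals of the ordered means. Zero residual variance is an error
  (F undefined) rather than a fabricated letter display.

# Correlation and ranking choices

* Pearson p-values use the t transform with n − 2 df (the standard
  inference; the source analysis does not state its test), pairwise-
  complete observations, and BH-FDR applied jointly over the upper
  triangle as one family, as the screened panel is interpreted as a
  single figure-level family. Stars mark q < 0.01 and q < 0.001.
* **Normalisation** is min–max (benefit: `(x − min)/(max − min)`; cost
  reversed). Entropy proportions require non-negative entries summing per
  column, which min–max guarantees; the scheme behind the published
  weights is unstated, and min–max is the standard choice for
  entropy-weighted TOPSIS. Constant columns normalise to zero, are
  flagged, and carry zero weight in both weighting methods.
* **Indicator directions** default to all-benefit; a user may declare,
  e.g., the regulated-dissipation yield Y(NPQ) cost-type in the
  configuration. The indicator set entering the published evaluation is
  listed only in an unavailable appendix, so the pipeline takes the set
  from configuration and makes no claim to reproduce the printed
  closeness range (0.1556–0.7577) or the printed agreement rho (0.928).
* **TOPSIS** applies weights before the distance computation
  (`v = w * z`), since the weights were explicitly "applied" in the
  evaluation; the distance formulas themselves are written on the
  normalised matrix, and `weighted = FALSE` reproduces that unweighted
  reading exactly. `Ci = D⁻/(D⁺ + D⁻)`; identical alternatives (both
  distances zero) get Ci = 0.5 with a warning. Ties rank by alternative
  ID for determinism.
* **CRITIC** uses sample SD times summed conflict `(1 − r)`. When all
  live columns are perfectly correlated the conflict vanishes everywhere
  and the weight is shared equally among them — the symmetric limit of
  the formula.

# Numerical and degenerate-input conventions

* `0 · ln 0 := 0` in both the entropy and Shannon computations.
* Entropy columns with zero sum, and constant indicator columns, get
  weight 0 with a warning; an all-degenerate matrix is an error.
* Consensus ties break to the alphabetically first base; Q-matrix ties
  inside neighbor joining are resolved deterministically; network
  construction, ranking and letters are all deterministic given inputs.
* Every stochastic entry point takes an explicit integer seed and uses a
  scoped RNG (`withr::with_seed`), so fixed seeds give byte-identical
  FASTA, trait tables and report bundles without touching the caller's
  RNG state.

# Problem sizes used in the test suite

The suite exercises the full study-sized configuration (31 accessions ×
644 bp; 17 genotypes × 4 months × 10 replicates) for the structural
checks, and deliberately small fixtures elsewhere: 100 random 5–8 leaf
trees for NJ round-trips, ~5,000 draws for the correlation-target
Monte-Carlo, toy 3×2 / 4×3 matrices for the hand-worked TOPSIS, entropy
and CRITIC oracles. These sizes give stable checks at sub-minute runtime
and were chosen as the package's own testing conventions.

# Known limitations

* The simulator validates the *mechanics* of every statistic; it cannot
  validate field conclusions about host suitability, and data-dependent
  published values (distance maxima, correlation coefficients, Ci range,
  rank-agreement rho) are emulated in sign and structure only.
* The ITS layer performs no alignment, chromatogram processing, model
  selection or bootstrap; inputs must already be aligned.
* Monthly comparisons are treated as independent one-way layouts (as in
  the source analysis); no repeated-measures or mixed modelling.
* Median-joining networks, AMOVA, partial correlations and fuzzy/AHP
  variants of the ranking layer are intentionally out of scope.
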