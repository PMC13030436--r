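# hostscreen

Integrated germplasm evaluation for screening elite host genotypes in
parasitic-plant cultivation systems, built around the fourwing saltbush
(*Atriplex canescens*) / desert broomrape (*Cistanche deserticola*) host
system. The package is aimed at researchers evaluating candidate host
germplasm who need to combine marker-based diversity, phenotype
dispersion and an objective multi-criteria ranking into one reproducible
pipeline.

## What it computes

**Sequence diversity (ITS panel).** From a gapped alignment: GC content,
segregating sites *S*, per-genotype polymorphic sites (differences from
the majority consensus), nucleotide diversity

π = 2/(n(n−1)) · Σ_{i<j} d_ij / L,

haplotype collapse with diversity Hd = n/(n−1)·(1 − Σ p_i²), p- or
Kimura-2-parameter distances, a neighbor-joining tree, and the ε = 0
minimum-spanning haplotype network (the union of all minimum spanning
trees under mutational-step weights).

**Phenotype statistics.** Monthly relative growth rates
100·(m_{t+1} − m_t)/m_t with rapid / stable / stagnation phases
(stagnation below 12%), coefficients of variation CV% = 100·SD/AVG,
the Shannon–Wiener phenotypic diversity index H′ = −Σ P_i ln P_i over
equal-width trait classes, leaf-size classification (large ≥ 2.50 cm²,
small < 1.80 cm²), P/NP group contrasts with the proportion of genotypes
above the overall mean, and one-way ANOVA with Duncan's multiple range
test letters.

**Correlation screening.** Pearson matrix with two-sided t-based
p-values and Benjamini–Hochberg FDR control applied over all tested
pairs as one family; Spearman rank correlation with midranks.

**Multi-criteria ranking (the headline).** Min–max normalisation to Z,
entropy weights w_j ∝ 1 − e_j with
e_j = −(1/ln n) Σ_i p_ij ln p_ij, then weighted-Euclidean TOPSIS:

D⁺_i = √Σ_j (Zmax_j − v_ij)², D⁻_i = √Σ_j (v_ij − Zmin_j)²,
C_i = D⁻_i / (D⁺_i + D⁻_i),

ranked by descending C_i, cross-validated with CRITIC weights
(w_j ∝ σ_j·Σ_k (1 − r_jk)) and the Spearman agreement between the two
rankings.

**Synthetic data.** A seeded generator reproduces the study structure —
31 ITS accessions (~644 bp, GC 0.5835, 22 haplotypes shared as
{5, 3, 2, 2, 2} + 17 singletons, 1-bp and 2-bp deletions) and a
17-genotype trait panel (7 P / 10 NP, July–October, 10 replicates) with
correlated leaf and chlorophyll-fluorescence blocks — so the entire
pipeline is testable without field data.

## Worked example

```r
library(hostscreen)

## 31-accession synthetic ITS panel under the study sharing structure
sim <- generate_its_alignment(haplo_config(seed = 1))
seqdiv_summary(sim$alignment)
#> Sequence diversity summary
#>   mean GC:            0.5837
#>   segregating sites:  40
#>   nucleotide div. pi: 0.00495
#>   haplotypes:         22 (Hd = 0.9656)

## 17-genotype trait panel; height growth phases
tt <- generate_trait_tables(trait_gen_config(seed = 1))
monthly_growth_rates(tt, "H")
#>        from        to      rate      phase
#> 1      July    August 77.349223      rapid
#> 2    August September 43.744196     stable
#> 3 September   October  3.651728 stagnation

## entropy-weighted TOPSIS with CRITIC cross-check
dm <- decision_matrix_from_traits(
  tt, c("H", "BN", "NN", "SBD", "LA", "Fv/Fm", "Y(II)", "qP"))
evaluate_genotypes(dm)
#> Entropy-weighted TOPSIS ranking (top 3):
#>   alternative    d_plus   d_minus        ci rank
#> 1        P3.7 0.1669393 0.2801176 0.6265816    1
#> 2      NP2.20 0.1548295 0.2519061 0.6193363    2
#> 3       NP2.2 0.1906776 0.2552138 0.5723677    3
#> Rank agreement with CRITIC weighting: Spearman rho = 0.809
```

The diversity summary shows the generator hitting the configured
structure: 22 haplotypes over 31 accessions (Hd = 0.9656 is the exact
value for that sharing multiset) and mean GC within a fraction of a
percent of the 58.35% target. The growth-rate table labels the
July–August jump as the rapid phase and the final month pair (3.7%,
below the 12% threshold) as stagnation. The ranking table gives each
genotype's distances to the ideal (D⁺) and worst (D⁻) points in weighted
indicator space and the closeness C_i ∈ [0, 1]; the Spearman rho of 0.81
between entropy- and CRITIC-weighted rankings indicates the ranking is
robust to the weighting choice on this synthetic draw.

The full pipeline — simulation, diversity, phenotype tables, correlation
matrices, weights, ranking and a JSON manifest — runs from one seeded
configuration:

```r
run_pipeline(default_run_config(seed = 1), "out/")
```

or from the shell via the thin wrapper
`Rscript inst/cli/hostscreen.R all --out out --seed 1`
(subcommands: simulate, seqdiv, pheno, assoc, rank, all; YAML configs via
`--config`).

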