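# snarc — regional constraint scanning and burden testing for small non-coding RNA genes

`snarc` finds pathogenic sub-regions of short non-coding genes (snRNAs
and similar loci) and quantifies their disease relevance. It is built for
the situation where a dominant disorder is driven not by a whole gene but
by a few dozen bases of it — for example, a structural element of a
spliceosomal RNA — and where conventional exome-style constraint models
cannot be applied because the genes are ~141 bp long and extremely
mutable.

The package is aimed at statistical geneticists working with large
population variant tables (UK-Biobank/gnomAD-scale), rare-disease trio
cohorts with de novo calls, and phenotype-term annotations.

## What it computes

**Sliding-window depletion scan.** For each gene, the proportion of
possible SNVs (3 per base) observed in the population is computed in
18-bp windows advanced 1 bp at a time, and normalised by subtracting the
per-gene median:

p̃ₒ = (#observed distinct SNVs in window)/(3·18) − median over windows.

Depleted (constrained) regions are maximal runs of windows with
p̃ₒ ≤ −0.2, reported with their minimum normalised proportion as depth.

**Intergenic null.** Gene-level summaries (median window proportion) are
compared against 1,000 random non-overlapping intergenic regions of the
same length (≥10 kbp from any transcript) with a one-sided Monte-Carlo
Fisher–Pitman permutation test (add-one corrected, p = 1/1001 at
complete separation with 1,000 permutations).

**Exact burden statistics.** Case/control and de novo 2×2 tables are
tested with Fisher's exact test; odds ratios are conditional maximum
likelihood estimates (the convention of R's `fisher.test`, distinct from
the sample cross-product ratio) with exact confidence bounds. A
gene/region screen applies a ≥2 case-DNV inclusion rule and Bonferroni
correction; a recurrent-DNV screen retains case variants with allele
count ≥3, absent from comparator cohorts and at AF ≤0.5% in the
population reference.

**Phenotype enrichment.** HPO/ICD-10 codes are collapsed into phenotype
groups via an explicit map; groups observed in ≥5 carriers are tested
carrier-versus-comparator with the same exact test.

**Synthetic cohorts.** `simulation_config()` / `simulate_cohorts()`
generate population, trio and phenotype tables with a planted constrained
region (observation probabilities 0.26 inside vs 0.78 outside), a
dominant recurrent insertion (77.3% of in-region case variants), rare
allele frequencies (max AF 0.025%) and phenotype odds ratios — so the
entire pipeline runs and is validated end-to-end without access to
controlled datasets. Coordinate utilities handle VCF↔HGVS-like `n.`
mapping on minus-strand genes (e.g. `chr12:120291839:T:TA` ↔
`n.64_65insT`).

## Worked example

```r
library(snarc)

# exact burden test: 60 region carriers among 8,841 case probands
# versus 39 among 490,132 population individuals
fisher_exact(60, 8841 - 60, 39, 490132 - 39)
#> Fisher exact test: OR = 85.76 (95% CI 56.41-131.6), p = 1.84e-78

carrier_fraction(60, 8841)            # % of case probands carrying
#> [1] 0.68
extrapolated_prevalence(60, 8841, 0.4)  # % of the full disease population,
#> [1] 0.41                             #   at a 40% upstream diagnostic rate

# constraint scan on a simulated population over the bundled
# synthetic 141-bp minus-strand gene (planted depletion at n.62-79)
gene <- rnu4_like_gene()
pop  <- simulate_population(simulation_config(seed = 7), seed = 7)
prof <- normalise_profile(sliding_window_profile(gene, pop))
call_depleted_regions(prof, gene = gene)
#>   gene_id n_start n_end min_normalised n_windows chromosome     start       end
#> 1  RNU4L2      49    90     -0.6111111        25      chr12 120291814 120291855
region_summary(gene, pop)             # median window proportion observed
#> [1] 0.778
```

The exact test reads: carriers are 85.8 times more likely (CI 56.4–132)
among cases than in the population. The scan recovers a depleted region
overlapping the planted n.62–79 core (union extents deliberately
over-cover the core by up to a window on each side; the most depleted
window marks the core), 0.61 below the gene's median observed proportion
of 0.778.

A full synthetic run — scan, null test, burden screens, recurrent screen,
phenotype enrichment, with TSV/JSON/BED outputs and a manifest — is:

```r
report <- run_pipeline(run_config(seed = 7), "runs/demo")
```

or from the shell, `Rscript inst/scripts/snarc-run.R --preset synthetic
--seed 7 --out runs/demo`.

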