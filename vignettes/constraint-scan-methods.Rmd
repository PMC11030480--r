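---
title: "Regional constraint scanning in small non-coding genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional constraint scanning in small non-coding genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snarc)
```

## The problem

Small nuclear RNA (snRNA) genes are short (~100–200 bp), highly expressed,
non-coding spliceosome components. Standard exome-based constraint metrics
(pLI/LOEUF-style expected-versus-observed models) do not apply to them:
they are too short for gene-level statistics, and their extreme mutability
makes genome-wide mutational-rate models poorly calibrated. Yet dominant
pathogenic variants in these genes can cluster in sub-regions of a few
dozen bases — for example, regions whose RNA structure is loaded into the
spliceosomal helicase machinery.

`snarc` implements a pipeline for localising such sub-regions and testing
their disease relevance:

1. a **sliding-window depletion scan** of standing variation in a large
   population cohort;
2. a **random intergenic null** with a Monte-Carlo Fisher–Pitman
   permutation test, establishing that a gene's overall variant density is
   far above intergenic background (so a *local* deficit is informative);
3. **exact case/control and de novo burden statistics** (conditional-MLE
   odds ratios with exact CIs);
4. a **recurrent de novo variant screen**; and
5. **phenotype-group enrichment** among carriers.

A first-class synthetic-data module generates population, trio and
phenotype tables with the statistical structure the analysis assumes, so
the whole pipeline is exercisable and testable without access-controlled
cohort data.

## The constraint statistic

For a gene of length $L$ and a window of $w$ bases starting at transcript
position $o$, the statistic is

$$ p_o \;=\; \frac{\#\{\text{distinct SNVs observed in the window}\}}{3w}, $$

the proportion of *possible* SNVs (three alternates per reference base)
that are actually observed in the population table. Indels are excluded
from the numerator — insertion burden is a case/control question, not a
constraint input — and each distinct alternate allele counts once.
Windows advance in 1-bp steps, giving $L - w + 1$ windows.

Each window is then **normalised to the per-gene median**:
$\tilde p_o = p_o - \operatorname{median}_o(p_o)$. This within-gene
normalisation is what makes the scan robust to the (very large)
between-gene differences in mutability: a depleted region is a window run
whose observed proportion falls well below *its own gene's* typical level.

**Depleted regions** are maximal groups of overlapping-or-abutting
windows with $\tilde p_o \le -0.2$; each group is reported as one region
spanning the union of its windows' extents, with the minimum normalised
value recorded as its depth.

### Parameter choices

* **Window size `window = 18` bp.** The size of the depleted region in
  the gene that motivated the method; it is the resolution at which the
  scan trades sensitivity against localisation. At 18 bp a window has 54
  possible SNVs, so single-window noise is
  $\sqrt{q(1-q)/54} \approx 0.06$ at typical observation rates.
* **Threshold `threshold = 0.2`.** A window must fall at least 20
  percentage points below the gene median. The comparison is *inclusive*
  ($\le -0.2$): the definition is "a deviation of at least 20%", and the
  boundary case belongs in the region. `inclusive = FALSE` restores a
  strict comparison.
* **Step 1 bp.** Windows are "sliding"; region boundaries are reported at
  single-base resolution.
* **Union extents.** A region is what its qualifying windows *span*.
  Because every qualifying window is $w$ bp wide, union extents
  deliberately over-cover the true depleted core by up to $w$ minus the
  qualifying-overlap on each side; an `extent = "intersection"` mode
  (the bases shared by all qualifying windows) under-covers it
  symmetrically. Union is the default because a discovery region should
  err towards containing the functional element. Users should treat the
  *most depleted window*, not the region edges, as the best point
  estimate of the core.
* **No allele-frequency filter** on observed population variants: a
  variant's presence, however rare, counts as observation. Selection
  shows up as absence, not as rarity.

## The intergenic null

The scan's interpretation leans on the gene being *saturated* with
variation outside constrained sub-regions. This is established per
chromosome by comparing gene-level summaries (the median window
proportion) against 1,000 random regions of the same length drawn from
intergenic sequence:

* the **pool** is the complement of all annotated transcripts padded by
  10 kbp, minus exclusions such as the centromere, keeping pieces of at
  least the region length;
* **sampling** places fixed-length regions without overlap, by
  placement-weighted rejection sampling under a fixed seed (a simpler
  scheme than two-stage per-interval generation, with the same uniform
  non-overlapping result);
* the **Fisher–Pitman permutation test** compares the group of gene
  summaries against the 1,000 region summaries. The statistic is the
  difference in group *means* (the classical Fisher–Pitman statistic);
  the per-region summary being a median does not make the test statistic
  a median. A `statistic = "median"` option is provided for sensitivity
  analysis. With two gene values against 1,000 region values and complete
  separation, the add-one Monte-Carlo estimate is
  $p = 1/(B+1) = 1/1001 < 0.001$ at $B = 1000$ permutations — the
  resolution limit of the Monte-Carlo design, reported as such.
  Exhaustive enumeration replaces sampling automatically when
  $\binom{n}{n_a}$ is small (`exhaustive_cap`).

## Exact burden statistics

All 2×2 association tests use Fisher's exact test as implemented in R
(`stats::fisher.test`), wrapped by `fisher_exact()`. Two conventions
matter and are deliberately pinned:

* the **odds ratio is the conditional maximum-likelihood estimate** under
  the noncentral hypergeometric model, not the sample cross-product
  ratio. On sparse tables the two differ materially (the package reports
  the cross-product as a secondary `or_sample` field);
* the **two-sided p-value** sums the probabilities of all tables (given
  the margins) no more probable than the observed one.

The test suite cross-checks this wrapper against an independent
brute-force oracle — log-space hypergeometric weights assembled from
`lchoose`, direct tail summation, and a Newton/uniroot solve of the
conditional mean equation — exhaustively over all tables with margins up
to 30. One caveat surfaced by that sweep: on extreme tables
(conditional-MLE OR in the hundreds), `fisher.test`'s internal
root-finding tolerance limits its estimate to roughly 1% relative
precision; the oracle comparison allows for exactly that solver
tolerance and nothing more.

Comparator tables are built by **subtracting carriers** from cohort
totals (carriers versus non-carriers), and cohort-level helpers follow
the same fixed conventions: carrier fractions as percentages of probands;
prevalence extrapolation to the full disease population as
$100\,c/(N_u/(1-r))$ for an upstream diagnostic rate $r$; Bonferroni
correction as $\alpha/n_\text{tests}$ with $n_\text{tests}$ the number of
units passing the inclusion rule (at least two case de novo variants).

The recurrent de novo screen retains variants that are recurrent in cases
(allele count ≥ 3), absent from every other cohort, and rare in the
population reference (AF ≤ 0.5%); variants missing from the reference are
treated as AF 0.

## HGVS-like n. coordinates on minus-strand genes

Transcript (`n.`) coordinates run 5'→3' along the RNA. On a minus-strand
gene, genomic position $g$ maps to $n = \text{end} - g + 1$, substitution
alleles are complemented, and a VCF-anchored insertion after plus-strand
position $g$ lands between $n(g+1)$ and $n(g)$ with the inserted bases
reverse-complemented. **No 3'-shift normalisation is applied**: variants
are described at their literal (arithmetic) positions even inside
homopolymers. This is a deliberate deviation from strict HGVS
normalisation, chosen because the fixed nomenclature used for recurrent
variants in this field is the direct arithmetic mapping; shifting would
rename the canonical hotspot insertion. Mappings round-trip exactly
(`transcript_to_genomic(genomic_to_transcript(v)) == v`), which the suite
checks property-style over random loci on both strands.

## The synthetic-data generator

`simulation_config()` fixes the generative model; its defaults *are* the
study conditions the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `q_out` / `q_in` | 0.78 / 0.26 | probability each possible SNV is observed outside / inside the constrained region |
| constrained region | n.62–79 | planted 18-bp region in the target and its paralog |
| `af_max` | 2.5×10⁻⁴ | cap on simulated allele frequency |
| `population_size` | 490,640 | population cohort size |
| `n_case` / `n_control` | 8,841 / 4,776 | undiagnosed-NDD and comparator proband counts |
| `dnv_rate` | 3×10⁻⁴ | baseline de novo variants per proband per gene |
| `region_enrichment` | 100 | case in-region de novo rate multiplier |
| `insertion_weight` | 0.773 | fraction of in-region case variants that are the fixed hotspot insertion |
| `intergenic_q` | 0.13 | per-possible-SNV observation probability in intergenic regions |
| `phenotype_baseline`, `phenotype_ors` | 0.2; 2.55–19.2 | comparator phenotype prevalence and carrier odds ratios |

`dnv_rate` and `region_enrichment` have no published values; they were
fixed once so that a 141-bp gene accrues a handful (~2–3) of case de novo
variants at baseline — the scale at which a screen's two-variant
inclusion rule starts to bite — and the enriched region accrues ~30 case
variants against ~0 comparator variants, the regime the region-level
burden test is meant to detect. Allele counts for observed population
variants follow a geometric tail truncated at `af_max` (only the maximum
is constrained by the emulated data; the site-frequency-spectrum shape is
a modelling choice). Decoy genes with `q_in = q_out` give the screens
true negatives. The default gene set is **synthetic**: the target's
sequence is seeded-random with a handful of positions pinned so the
canonical nomenclature examples hold; it is not the real U4 sequence.

What the generator does **not** emulate: sequence-context mutation-rate
variation (every possible SNV inside/outside the region is exchangeable),
linkage between variants, call-quality artefacts, relatedness, or a
mechanistic model of why one insertion dominates (the hotspot is a
planted weight, not a secondary-structure simulation). Passing recovery
tests therefore show that the *estimators* recover what the generative
model plants at realistic sizes — not that real cohorts satisfy the
model.

## Numerical and degenerate-input choices

* Window proportions are exact rationals $k/3w$ accumulated by cumulative
  sums; normalisation is a single median subtraction, so
  `max - min` of a profile is invariant under it (tested).
* Threshold comparisons happen at `<=` on doubles; the threshold is a
  user-supplied literal, and profile values are multiples of $1/3w$, so
  boundary ties are not a floating-point lottery in practice.
* Permutation p-values use the add-one correction in Monte-Carlo mode and
  the exact tail fraction in exhaustive mode; a pooled sample with all
  values identical yields p = 1 with a warning.
* All-zero 2×2 tables error; zero cells and zero margins do not (bounds
  become 0 or infinite).
* `sample_regions()` errors with the achievable maximum when the pool
  cannot host the request; empty pools error at sampling time.
* Every stochastic function takes an explicit `seed` and restores the
  caller's RNG state, so library use never clobbers a session's stream.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the generator at the
full configured cohort sizes (they are cheap: cost scales with variant
counts, not proband counts) but keep replicate counts modest by design:
100 seeds for region-recovery rates, 50 seeds for CI-coverage
properties, 500 replicates for permutation-test calibration, and the
exhaustive oracle sweep over all 2×2 tables with margins ≤ 30. These
sizes give the assertions binomial slack well beyond their thresholds
(e.g. a ≥95/100 recovery criterion observed at 100/100 in development).

## Known limitations

* The scan localises depletion at window resolution; region edges
  inherit up-to-window-size uncertainty from the union-extent definition
  (see above). Do not interpret called boundaries as base-precise.
* The per-gene median normalisation assumes most of a gene is
  unconstrained; a gene constrained along most of its length would hide
  its own signal.
* The Fisher–Pitman comparison treats region summaries as exchangeable;
  with only one or two gene values the test is effectively a rank
  statement, and its p-value is floored at $1/(B+1)$.
* Phenotype enrichment applies no multiple-testing correction (matching
  the reporting convention it emulates); downstream users should apply
  their own when screening many groups.
* No liftover, no full HGVS grammar, no mutational-rate covariates in
  the null — all deliberately out of scope.
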