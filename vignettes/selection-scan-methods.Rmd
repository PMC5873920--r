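---
title: "Methods: detecting recent selective sweeps with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting recent selective sweeps with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sweepscan)
```

## The problem

Immune-related gene families — the motivating case is the human sialic acid
biology genes, spanning biosynthesis, activation/transport/transfer,
recognition and recycling/degradation functions — are candidates for recent
positive selection. A selective sweep leaves characteristic footprints in
population sequence data: reduced diversity and an excess of rare alleles
(hard sweeps, detectable for ~250,000 years), allele-frequency differences
between populations after local adaptation (post out-of-Africa), one dominant
extended haplotype (recent sweeps, ~20,000 years), or several co-elevated
haplotypes (soft sweeps). None of these signatures is exclusive to selection:
bottlenecks, expansions and drift mimic them. The package therefore scores
genes with five statistics and calibrates each against neutral coalescent
simulations under an explicit demographic model, so that demography is part
of the null rather than a confounder.

## Statistics

For a phased haplotype sample (rows = haplotypes, columns = biallelic SNPs):

* **π** — mean pairwise Hamming distance across all haplotype pairs; reported
  per bp of gene length. Descriptive only (no p-value).
* **Tajima's D** — `(π − S/a1) / sqrt(e1 S + e2 S (S−1))` with the 1989
  normalization constants, computed on the pooled three-population sample.
  Negative D = excess of rare variants.
* **Weir–Cockerham FST** — the 1984 variance-components estimator applied to
  haplotypes (haploid reduction: the within-individual component is zero).
  Both the ratio-of-sums ("weighted") and mean-of-ratios forms are computed;
  the global k = 3 estimate is the default for significance, with all
  pairwise values reported, because the study's text says "between all three
  ethnic groups" while its figure legend says "pairwise comparisons" — both
  are exposed and the choice is configurable.
* **nSL** — for each site passing the MAF cutoff, haplotypes are split by
  ancestral/derived allele; the mean pairwise shared-tract length (in
  segregating sites, counting the focal site, truncated at the window edge
  and capped at 100 sites per side, the scan tool's default) gives `SL_A`
  and `SL_D`, and `nsl = log(SL_A/SL_D)`, unstandardized. Per gene, the
  summary is the maximum |nSL| over the gene ± 100 kb window, computed per
  population. Sites lacking ancestral-allele annotation are skipped in
  strict mode (nSL is the only polarity-dependent statistic; polarity-free
  statistics keep those sites); lenient mode assumes REF is ancestral.
* **H12** — haplotypes grouped by exact identity over the gene's retained
  SNPs; with sorted frequencies `p1 ≥ p2 ≥ …`,
  `H12 = (p1+p2)^2 + Σ_{i≥3} pi^2`. Pooling the top two haplotypes gives
  power against soft sweeps. Exact matching (no mismatch tolerance) is used;
  the "modified" script of the original study is unavailable, so the cited
  statistic's published definition is implemented instead.

Monomorphic regions yield `NaN`, never 0, and `NaN` propagates to a
"not testable" p-value.

## The neutral null

Significance is assessed by empirical p-values — the proportion of simulated
neutral values equal to or more extreme than the observation — against nulls
simulated at each gene's exact length (gene + 200 kb for nSL). Defaults are
5,000 replicates per length (2,500 for nSL), α = 0.05, and no multiple-testing
correction across genes (the study corrects only the category comparisons).
Tail conventions, which the study does not state: D is two-sided around the
null median (hard sweeps push D negative, balancing selection positive); FST,
H12 and max|nSL| are upper-tailed, since only elevation indicates selection.
These are declared package choices, configurable per run.

The demographic model is a three-population out-of-Africa history: ancestral
size 7,310 expanding to 14,474 at 148 kya; an out-of-Africa lineage splitting
at 51 kya; a Eurasian split at 23 kya with a European bottleneck to 1,032
followed by exponential growth (0.0038/generation in Europeans,
0.0048 in East Asians); mutation rate 2.36e-8 and recombination rate 1.0e-8
per bp per generation; 25 years per generation; no migration (the study lists
none). Two parameters the study omits are taken from the demographic
inference it cites (Gravel et al. 2011) and are **not from the study
itself**: the out-of-Africa bottleneck size (1,861) and the East Asian
founding size (554). Both are arguments of `demographic_model()`.

The engine is a Hudson-style backwards coalescent with recombination
(implemented in C++), not the forward simulator the study used: the neutral
expectations are identical and the coalescent is orders of magnitude cheaper.
Correctness is established two ways: closed-form calibration (mean S against
Watterson's `θ·a1`, mean π against θ, the 1/i site-frequency-spectrum
weighting) and a distributional cross-check of S and π under the full
three-population model against msprime configured identically (KS tests;
oracle use only). Exponential epochs use exact analytic inversion of the
integrated coalescence intensity, so no time-discretization error is
introduced. Mutations are infinite-sites, placed uniformly; after
discretization to integer bp, position collisions are resolved by redraw.

## Category comparisons

Per statistic, the per-gene values of the four functional categories are
compared with exact two-sided Mann–Whitney U tests:
`U = #{x_i > y_j} + ½·#{ties}` and the p-value is the exact conditional
permutation probability of a U at least as far from `n1·n2/2` as observed,
computed by dynamic programming over tied value groups (identical to full
enumeration, which the tests verify, but affordable at category sizes).
The six pairwise p-values within one statistic form the Bonferroni family
(multiplier 6, capped at 1; reduced if a category is empty).

## Synthetic data: what it emulates and what it does not

`generate_study()` builds a complete study — phased VCF with ancestral-allele
tags, panel, gene table, truth table — from neutral simulations plus planted
sweeps. A hard sweep copies one donor haplotype over a fraction (default 0.9)
of the target haplotypes; a soft sweep copies two distinct donors at half
that fraction each. This reproduces exactly the haplotype-dominance
signatures the statistics target, at trivial cost. Both planters draw the
first donor and then the recipient rows, in that order, so planting a hard
and a soft sweep from the same RNG state yields matched fixtures (same donor,
same recipients) on which H12(soft) ≤ H12(hard) holds deterministically, not
just on average. It does **not** emulate
linked-selection realism: no partial recombination of the swept haplotype,
no new mutation on the swept background, no selection coefficients or sweep
ages. A green sweep-recovery test therefore establishes that the statistics
and the p-value machinery respond to the canonical signatures, not that the
pipeline has a particular power against real sweeps of given strength.

Scaled-down defaults keep the test suite at desk scale: 10% sample sizes
(66/50/50 diploids instead of 661/503/504), 5 kb genes, and 10 kb nSL flanks
(10% of the analysis default). These are stated world choices, fixed up
front; acceptance thresholds are never rescaled. Full-size generation is a
matter of passing the full sample sizes and flanks.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (Ensembl/VCF convention).
* Multiallelic records are dropped, not split; indels are dropped; both are
  counted and reported.
* Missing genotypes: hard error in strict mode (the target data are
  complete), site-drop in lenient mode.
* Empirical p = 0 is stored as 0 and displayed as `< 1/n` to flag the
  resolution limit of the null.
* Null distributions are cached by (statistic, region length, scope): genes
  of equal length share a null, mirroring the study's "sequences of the same
  length" design.
* Seeds: every simulation consumes a seed derived deterministically from the
  run's master seed; identical configurations are bit-identical.
* The site-frequency-spectrum goodness-of-fit test samples one site per
  replicate: sites within a replicate share a genealogy, so pooling all of
  them overdisperses the χ² statistic and rejects a correct simulator.

## Known limitations

* The study's per-gene values (its supplementary tables) are not
  reproducible without the 1000 Genomes download, which is out of scope;
  correctness rests on the oracle, calibration and property suites.
* The exact tail rule behind the study's Tajima's D p-values is not
  recoverable from its text; the two-sided default here is a declared
  choice.
* No standardized (frequency-binned) nSL, no iHS/XP-EHH, no FDR across
  genes, no composite-likelihood sweep localization, no liftover, no
  imputation or phasing.
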