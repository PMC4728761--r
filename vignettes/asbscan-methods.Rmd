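---
title: "Detecting allele-specific transcription factor binding with asbscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific transcription factor binding with asbscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asbscan)
```

## The problem

A heterozygous SNP inside a transcription factor binding site can change how
strongly the factor binds each of the two alleles. In ChIP-seq data from a
diploid sample this shows up as *allelic imbalance*: reads piling up on the
bound allele more often than on the other. A SNP at which this imbalance is
statistically significant is an **AS-SNP** (allele-specific SNP) — a direct,
cell-type-specific candidate for the functional variant behind a GWAS
association, even when the reported lead GWAS SNP itself sits outside any
binding site.

`asbscan` implements the full discovery pipeline: construct a sample-specific
alternative genome, count allele-informative reads at heterozygous sites,
test each site against a symmetric binomial null, control the false discovery
rate, remove candidates in unreliable genomic regions, and link the survivors
to GWAS variants through linkage disequilibrium (LD) proxies.

## The model

At a heterozygous site let $n_{G1}$ and $n_{G2}$ be the read counts
supporting the reference (G1) and alternative (G2) allele. Under no
allele-specific binding and equal amplification of both alleles,

$$ n_{G1} \mid n \sim \mathrm{Binomial}(n, 1/2), \qquad n = n_{G1} + n_{G2}. $$

The two-sided p-value is computed by the minimum-likelihood convention: the
probabilities of all outcomes no more likely than the observed one are
summed,

$$ P = \sum_{i\,:\,\Pr(X=i)\;\le\;\Pr(X=k)\,(1+10^{-7})} \Pr(X = i), $$

with the relative slack guarding against floating-point ties in the density
comparison (this matches the dominant convention for exact binomial tests,
e.g. `stats::binom.test`). P-values across all covered sites are adjusted
with the Benjamini–Hochberg step-up procedure, and sites with $q < \alpha$
(default $\alpha = 0.05$) are selected. Selection is applied *after*
correction; selecting on raw p-values is available (`select_on = "p"`) for
sensitivity analysis only.

The allelic ratio $n_{G1}/n$ is reported G1-based throughout: a ratio above
0.5 means the reference allele is preferentially bound.

## Why two genomes

Aligners map reference-allele reads slightly more successfully than
alternative-allele reads (*reference mapping bias*), which would inflate
$n_{G1}$ systematically. The pipeline therefore works against two genomes:
the reference G1 and an alternative genome G2 obtained by substituting the
alternative allele at every variant site (`build_alternative_genome()`).
Substitution is restricted to SNVs so that G1 and G2 share one coordinate
system; indels are rejected because they would shift coordinates and
silently corrupt per-position counting. A stated reference allele that does
not match the reference sequence aborts the build rather than being skipped:
it indicates a miscoordinated variant set, which would corrupt every
downstream count.

"Mapped specifically to G1 or G2" is operationalized in `count_alleles()` as:
a read qualifies if it maps over the site with mapping quality at or above
the threshold in *at least one* of the two alignments (the dual alignment
acts as a mask against reads mappable in neither), and its allele call is the
base it carries at the SNP — identical in both alignments, since G2 differs
from G1 only at substituted positions. Each fragment votes once: duplicate-
marked and secondary/supplementary records are skipped. Bases below the
base-quality threshold, third alleles and deletions spanning the site count
as `OTHER` and are excluded from testing.

Sites with no informative reads are discarded before testing
(`discard_uncovered()`, default `min_total = 1`). The alternative reading of
the discard rule — requiring coverage on *each* allele — would remove every
monoallelic site, i.e. precisely the strongest allele-specific candidates,
and is therefore not implemented.

## Region filters

Selected AS-SNPs are filtered against three exclusion tracks: assembly gaps
padded ±1 Mb (capturing centromeric/telomeric neighbourhoods), blacklisted
regions padded ±100 bp, and CNV regions unpadded (no padding is specified
for CNVs, and the track is user-supplied). Filtering runs *after* selection:
moving it before the test would change the multiple-testing universe, so the
order is a contract, not an implementation detail (`filter_before_test`
exists for sensitivity analysis). Intervals are handled as `GRanges`
(1-based, closed) with `rtracklayer` converting BED's 0-based half-open
convention exactly once at the file boundary; a SNP whose 0-based position
equals a padded interval's half-open end is *outside* it.

## Allele frequencies and LD proxies

Survivors are intersected with a population allele-frequency table
(`annotate_af()`, dropping absent SNPs by default, mirroring intersect
semantics) and linked to GWAS catalog SNPs by LD (`find_proxies()`). LD is
computed from phased haplotypes as

$$ r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad D = p_{AB} - p_A p_B, $$

with no expectation-maximization reconstruction from unphased genotypes: a
phased panel is a required input, which is the minimal faithful version of
delegating proxy lookup to an external LD service. The proxy threshold is
**inclusive** ($r^2 \ge 0.8$ by default; a strict flag exists) and an AS-SNP
identical to a catalog SNP links with $r^2 = 1$ by definition. Proxy links
are attached to the final report as annotation; the report is not pruned to
linked SNPs, so downstream false-discovery accounting stays interpretable.

## The synthetic-data generator

Every input has a generator with ground truth, making the whole pipeline
testable offline:

* `generate_reference()` / `plant_het_snps()` — random contig and planted
  heterozygous SNVs. Sites are kept one read length from contig ends and at
  least one read length apart; the spacing makes per-site read draws
  independent, so the binomial calibration and power checks have exact
  analytic oracles.
* `simulate_reads()` — per-site depth is Poisson(`mean_depth`) (a standard
  shotgun-coverage assumption that keeps zero-coverage sites possible, so
  the discard rule is exercised); each read overlapping a site carries the
  G1 allele with probability `imbalance[site]`, then per-base errors
  substitute uniformly among the three other bases. Reads are single-end,
  fixed-length, with a simulated strand flag; strand does not affect
  counting because SAM stores reference-strand sequence. The truth table
  records the exact pre-error haplotype of origin of every read.
* `generate_exclusion_tracks()` — short raw intervals over a chosen fraction
  of sites, assigned to the three track labels; membership truth is
  recomputed arithmetically from raw intervals plus padding.
* `generate_haplotype_panel()` — a partner column copies the index column
  with probability $\sqrt{r^2_\mathrm{target}}$ and redraws otherwise, so
  the expected allelic correlation is $\sqrt{r^2_\mathrm{target}}$ and the
  realized $r^2$ converges to the target as the panel grows.

What the generator does **not** emulate: PCR duplicates, GC bias, fragment
length variation, paired ends, indels, genotyping error, true reference
mapping bias (reads are placed, not aligned), or LD structure beyond
pairwise index–partner correlation. Passing tests therefore demonstrate the
pipeline's statistical and bookkeeping correctness under its stated model,
not robustness to those real-data artifacts.

## The standard validation scenario

`simulate_study()` defaults define the package's reference conditions: 500
heterozygous sites on a 120 kb contig, 20 of them with planted imbalance of
magnitude 0.75–0.9 (direction random), Poisson mean depth 60, read length
36, per-base error 0.001 (Illumina-like), about 30 % of sites covered by
exclusion tracks, a 2 000-haplotype panel realizing $r^2 \approx 0.95$
between each planted site and one GWAS catalog partner. Track paddings in
this scenario are scaled to the contig (gap 20 bp, blacklist 10 bp, cnv 0):
the production paddings assume genome-scale coordinates and would blanket a
small contig; the region-filter code path is identical either way, and the
realized masked fraction is recorded in the truth table (padded intervals
can reach neighbouring sites, so it can slightly exceed the request). Depths
and library sizes are not published for the original ChIP-seq runs; these
defaults were chosen once for test power at desk scale.

Problem sizes used by the test-suite oracles: binomial enumeration to
$n \le 200$; 1 000 random vectors for the BH and $r^2$ oracles; 2 000 sites
for the calibration and power checks; 20 seeds of the standard scenario for
end-to-end recovery.

## Numerical choices and edge cases

* The p-value is exactly 1 whenever the observed outcome's density reaches
  the maximum of the null density (within the $1+10^{-7}$ slack), avoiding
  sums drifting below 1 by round-off.
* `alpha = 1` is treated as the vacuous threshold and selects every site
  (the strict comparison `q < 1` would exclude ties at exactly 1).
* $r^2$ groups the per-locus variances before multiplying, so
  `compute_r2(a, b)` and `compute_r2(b, a)` are bit-identical; a
  monomorphic panel column is an error (undefined LD), not a zero.
* Selection sorts by q-value, ties broken by decreasing $|ratio - 0.5|$.
* All randomness flows from one master seed through substreams derived with
  `derive_seeds()`; identical configuration and seed reproduce every output
  byte-for-byte.

## Limitations

The test is a plain per-site binomial: no beta-binomial overdispersion, no
aggregation across sites in a peak, no replicate combination. FDR is
controlled within one counts table; whether correction should pool across
TF experiments is a study-design question the package leaves to the caller.
Haplotype phasing of the sample is not modelled — G2 carries all alternative
alleles — and alignment itself is out of scope: the package consumes
alignments (or simulates placements directly).

## A worked run

```{r, eval = FALSE}
report <- run_pipeline(pipeline_config(simulate = list(), seed = 7))
report
#> AS-SNP discovery run (seed 7 )
#>              stage n_in n_removed n_out
#>              count  500         0   500
#>  discard_uncovered  500         0   500
#>               test  500         0   500
#>             select  500       480    20
#>       af_intersect   20         0    20
#>      region_filter   20         6    14
#> 14 AS-SNP(s) in the final report
#> 14 proxy link(s)
```

Of the 20 planted AS sites, 6 fell inside padded exclusion tracks and were
removed after selection; the 14 survivors each carry their planted GWAS
proxy link.
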