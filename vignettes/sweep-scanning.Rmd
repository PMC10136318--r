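---
title: "Window-based sweep scanning and candidate-variant follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based sweep scanning and candidate-variant follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The model and its assumptions

`sweepscan` looks for hard selective sweeps in a two-population contrast
(group A, the wild or phenotype-positive side; group B, the domestic or
phenotype-negative side). A hard sweep drives a beneficial allele to
(near-)fixation in one population and drags linked variation with it, so
the swept region shows two things at once: strong allele-frequency
differentiation between the populations, and a local collapse of
nucleotide diversity on the swept side. Neither signal alone is specific
— drift and background selection also move single statistics — which is
why the scan requires windows to be jointly extreme in both.

Everything operates on unphased allele dosages (0/1/2 alternate-allele
copies per diploid) from biallelic SNPs. The assumptions are the usual
ones for this family of scans:

- genotypes are called well enough that per-site allele and heterozygote
  counts are trustworthy after a call-rate filter;
- sites are treated independently within windows (no LD modelling in the
  scan itself; LD is only examined descriptively in the follow-up);
- populations are treated as internally unstructured for the purpose of
  the F_ST estimator;
- diversity per bp is comparable across windows because windows have a
  fixed span (a truncated terminal window uses its true span).

### Per-site statistics

F_ST uses the Weir–Cockerham (1984) variance-component estimator for two
populations: from each group's called-diploid count, allele frequency and
observed heterozygosity, the among-population (`a`), among-individual
(`b`) and within-individual (`c`) components are formed and
`theta = a/(a+b+c)`. Per-site estimates are kept as-is, including
negative values: clamping each site at zero before averaging would bias
window means upward, so only the final reported window value is clamped.
A site is undefined when either group has fewer than two called diploids
or when it is monomorphic overall; undefined sites simply drop out of the
window mean.

Per-site diversity is the unbiased expected heterozygosity
`pi = 2p(1-p) * 2n/(2n-1)`, which equals the mean pairwise difference
over all C(2n, 2) allele pairs at the site (the package tests verify this
identity exhaustively for 2n <= 20).

### Windows and outlier calling

Windows are 40 kb sliding by 10 kb — wide enough at typical resequencing
densities (a few SNPs per kb) to average tens of SNPs, and overlapping so
that sweep boundaries are not lost to grid placement. Window F_ST is the
arithmetic mean of defined per-site `theta`; a `ratio_of_sums` switch
provides the weighted variant (`sum(a)/sum(a+b+c)`) for users who prefer
it, but the mean is the default because the window statistic here is
defined as the average of per-SNP values. Window diversity is
`sum(site pi) / span` per group, and the pi ratio is the ratio of those
two window-level diversities. We deliberately do not average per-SNP
ratios: a single near-zero domestic `pi` at one SNP would explode the
window value, whereas window-level `pi` is a stable quantity with a
direct interpretation (diversity per bp).

Outliers are windows at or above the empirical 95th percentile of *both*
statistics. The threshold is an order statistic: the smallest observed
value with at least 95% of windows strictly below it; windows equal to
the threshold are selected. When no value qualifies (e.g. all windows
identical) nothing is selected. Windows where group B has exactly zero
diversity but group A does not are the strongest possible ratio evidence
and are ranked above every finite ratio (`pi_ratio = Inf`); windows where
both diversities are zero carry no ratio information and are excluded.
Windows with fewer than `min_snps = 10` SNPs are excluded from calling —
at 40-kb scale and ~2 SNPs/kb this trims only sparse outliers whose means
would be dominated by a handful of sites.

Selected windows merge when overlapping or book-ended; the merged
region's peak statistics are maxima over members. Genes attach by >= 1 bp
overlap. The candidate ranking takes the top 50 genes by best (maximum
over selected windows) F_ST, then the top 50 by best pi ratio excluding
genes already taken, with ties broken by genomic order so the output is
reproducible.

## Follow-up inside a region

The follow-up chain runs in a fixed order, each stage consuming the
previous stage's survivors:

1. **Allele-frequency differentiation** — a two-sided Fisher exact test
   on the 2x2 table of allele counts (two per called diploid). The test
   is exact at the tiny sample sizes typical of validation panels;
   significance defaults to raw p < 0.05 because this stage is a filter,
   not an inference, and BH-adjusted values are always reported so users
   can tighten.
2. **Genotype differentiation** — each group's modal genotype must reach
   frequency `fix_threshold = 0.8` and the modal genotypes must differ.
   0.8 tolerates a stray heterozygote or miscall in small panels while
   still demanding the near-fixed pattern a hard sweep predicts.
3. **Segregation** — an individual scores "yes" when its genotype is in
   the set expected for its phenotype class. The expected set defaults to
   the modal genotype of each phenotype class within the discovery
   populations; heterozygotes are mismatches unless a class's modal
   genotype is heterozygous. Per-population tallies and their Total row
   are reported; `segregation_from_tallies()` re-scores published
   per-population yes/no tallies through the same code path.
4. **LD grouping** — composite r² (squared Pearson correlation of dosage
   vectors over pairwise-complete individuals), which needs no phasing
   and equals haplotype r² under HWE. Complete-LD groups require all
   pairwise r² >= 1 - 1e-9; the tolerance only absorbs floating-point
   noise, not near-linkage.

## What the simulator emulates — and what it does not

`simulate_two_pop()` draws ancestral frequencies from Beta(0.8, 0.8)
truncated to [0.05, 0.95] (a U-shaped folded site-frequency spectrum,
truncated so every site is polymorphic somewhere), then population
frequencies from the Balding–Nichols model
`p_g ~ Beta(p0(1-F)/F, (1-p0)(1-F)/F)` with `F = 0.1` background
divergence, and genotypes as Binomial(2, p_g) per diploid. SNP positions
are uniform at 2.2 SNPs/kb. This gives direct, analytic control of the
expected background F_ST and runs in seconds where a coalescent
simulation would not, at the cost of realism the window scan does not
need: there is no recombination map, no LD structure (sites are
independent given their frequencies), no demographic history, and no
sequencing-error model. Follow-up fixtures that need linkage construct it
explicitly — a causal SNP's "linked partner" carries a copied dosage
vector, the one LD pattern the scan's claims depend on.

Sweeps are implanted by setting the domestic-side minor-allele frequency
(relative to the ancestral major allele) to
`min(eps, 1 - 0.95) / 10`. The two factors implement the two stated
sweep properties independently: the `min` pushes the major allele to at
least 0.95, and the division guarantees at least a 10-fold reduction of
expected per-site diversity inside the sweep. A frequency cap alone
would not do this — capping at 0.95 leaves expected `2p(1-p)` near
0.095, only ~3-fold below the ~0.3 background of this frequency law —
so the diversity target is enforced directly.

Default sweeps are 40 kb, two per 1-Mb contig, aligned to the 10-kb step
grid. Phenotypes are assigned by group (domestic = case), and the causal
SNP is written as a fixed difference, so at penetrance 1 genotype and
phenotype segregate perfectly; `implant_causal_snp()` with penetrance
`q` forces exactly `round((1-q) n)` contradicting individuals.

Passing tests on this simulator therefore demonstrate that the
*machinery* is correct (the statistics match their oracles, the scan
recovers regions with the designed signature, the follow-up recovers the
designed causal variant). They do not demonstrate robustness to
admixture, uneven coverage, batch-correlated missingness or reference
bias — all properties of real data the generator does not emulate.

## Numerical and design choices

- **Coordinates**: 1-based inclusive in memory and in the window TSV
  (the VCF convention); BED files on disk are 0-based half-open.
- **Missing data**: excluded per site and per statistic; sites below 50%
  call rate in either contrast group are dropped at read time.
- **Multiallelic / non-SNP records**: skipped with a logged count; the
  scan is defined on two-allele frequencies.
- **Quantile ties**: inclusive at the threshold, so a run of equal
  values at the cut is selected together; the selected count is bounded
  by `ceil(0.05 n)` plus ties.
- **Degenerate windows**: zero-SNP windows carry `NA` statistics and are
  excluded; a region list can legitimately be empty and every writer
  emits a header-only file in that case.
- **PCA** (sanity check only): monomorphic sites dropped, missing
  dosages mean-imputed, sites standardized by `sqrt(p(1-p))`, SVD;
  scores are deterministic up to sign.
- **Determinism**: one seed governs all simulator draws; the scan and
  follow-up are deterministic, so identical inputs and parameters
  reproduce outputs byte for byte (manifests record every parameter).

## Validation problem sizes

The shipped tests and the acceptance script validate at sizes a laptop
handles in well under a minute apiece: oracle comparisons on 1,000
random site configurations (F_ST), all allele configurations with
2n <= 20 (pi), and 1,000 random 2x2 tables (Fisher); sweep recovery on a
10-Mb, 20 + 20-diploid genome with twenty implanted 40-kb sweeps
(recall >= 0.8, precision >= 0.6 at the default scan settings); and a
matching neutral genome whose mean window F_ST stays near the simulated
F = 0.1 with no sweep-sized signal. These sizes were chosen as the
smallest at which the window grid, the top-5% rule and the recovery
metrics all operate non-trivially.

## Known limitations

- The Weir–Cockerham estimator is computed per site and averaged; very
  sparse windows (few defined sites) have noisy means, which is what
  `min_snps` guards against.
- The pi ratio is undefined when the domestic window diversity is zero;
  the Inf-ranking policy is a deliberate choice, and users who prefer to
  drop such windows can filter on `ratio_defined`.
- Composite r² equals haplotype r² only under HWE within the pooled
  sample; it is used descriptively, not inferentially.
- The segregation score is descriptive concordance, not a genetic model:
  dominance is expressed only through the expected-genotype sets.
- The scan targets hard sweeps; soft sweeps (standing variation, multiple
  origins) dilute both signals and will be under-called.
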