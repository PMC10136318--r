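# sweepscan

Detecting selective sweeps and following up candidate variants in
two-population resequencing data.

When a population is domesticated (or diverges under any strong
directional pressure), the genomic regions carrying selected alleles show
a characteristic double signature against the wild relative: elevated
allele-frequency differentiation and a collapse of nucleotide diversity
on the selected side. `sweepscan` implements the standard window-scan
recipe for finding such regions from a multi-sample VCF of biallelic
SNPs, plus the descriptive follow-up used to nominate causal variants
inside them. It is written for population geneticists analysing
wild-versus-domestic (or, e.g., broody-versus-non-broody) contrasts in
birds and other diploids, and ships a genotype simulator with known
truth so the whole pipeline can be validated end to end.

## The statistics

For a contrast between group A (wild side) and group B (domestic side):

- **Per-site F_ST** — the Weir & Cockerham (1984) estimator for two
  populations, `theta = a / (a + b + c)`, from the among-population (a),
  among-individual (b) and within-individual (c) variance components
  computed on unphased genotype counts. Negative per-site estimates are
  retained; only the reported window mean is clamped at 0.
- **Per-site diversity** `pi = 2p(1-p) * 2n/(2n-1)`, the unbiased mean
  pairwise difference over the `2n` sampled alleles.
- **Windows** — 40-kb sliding windows, 10-kb step. Window F_ST is the
  arithmetic mean of per-site `theta`; window diversity is the sum of
  per-site `pi` divided by the window span (per-bp); the **pi ratio** is
  `pi_A / pi_B`, large when group B has lost diversity.
- **Divergent regions** — windows in the empirical top 5% of *both*
  window F_ST and pi ratio, merged when overlapping or book-ended. Genes
  overlapping a region by >= 1 bp are attached; candidate genes are
  ranked top-50 by best F_ST then top-50 by best pi ratio without
  overlap.
- **Follow-up** inside a region: two-sided Fisher exact tests on allele
  counts (BH-adjusted values reported alongside), genotype-
  differentiation flags (near-fixed different modal genotypes),
  genotype-phenotype segregation tallies, and composite LD r-squared
  (squared dosage correlation) with complete-LD grouping at r² = 1.

The simulator draws population allele frequencies from the
Balding-Nichols model `p_g ~ Beta(p0(1-F)/F, (1-p0)(1-F)/F)` so the
background F_ST is controlled directly, and implants sweeps by pushing
the domestic-side major allele toward fixation.

## Worked example

Simulate a 2-Mb, 20 + 20 diploid dataset with four implanted 40-kb
sweeps, scan it, and score recovery against the simulator's truth:

```r
library(sweepscan)

cfg <- sim_config(seed = 1, n_contigs = 2, contig_length_bp = 1e6)
sim <- simulate_two_pop(cfg, out_dir = "demo")
print(sim$table)
#> variant_table: 4357 SNPs, 40 samples, 2 contig(s)
#>   missing genotype rate: 0.000

grid <- make_windows(sim$table$contig_lengths)   # 40-kb / 10-kb grid
ws   <- call_outlier_windows(window_stats(sim$table, sim$contrast, grid))
regions <- assign_genes(merge_regions(ws), sim$genes)
regions[, c("contig", "start", "end", "n_windows", "peak_fst", "peak_pi_ratio")]
#>   contig  start    end n_windows  peak_fst peak_pi_ratio
#> 1  ctg01 330001 370000         1 0.2647865      35.84982
#> 2  ctg01 660001 700000         1 0.2230093      30.18498
#> 3  ctg02 320001 380000         3 0.3038547      41.76527
#> 4  ctg02 660001 710000         2 0.2524964      41.96647

evaluate_recovery(regions, sim$truth$sweeps)[c("recall", "precision")]
#> $recall    [1] 1
#> $precision [1] 0.8429703
```

The four called regions sit on the four implanted sweeps (truth starts
330001 and 660001 on each contig): every sweep is recovered and ~84% of
the called span is true sweep. Peak pi ratios of 30–42 against a
genome-wide background near 1 are the expected signature of a 10-fold
diversity loss; peak window F_ST ~0.22–0.30 stands out over the
background differentiation of ~0.08 simulated at F = 0.1.

The same stages are scriptable from a shell via the thin CLI in
`exec/sweepscan` (`simulate`, `scan`, `followup`, `report`
subcommands), which writes window TSVs, region BEDs, gene rankings and
a run manifest.

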