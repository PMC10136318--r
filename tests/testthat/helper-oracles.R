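# Independent oracles used to pin the statistical core.

# Weir & Cockerham (1984) variance components for two populations,
# coded straight off the published equations, one site at a time.
# Inputs: called diploids, alt-allele frequency and observed het
# fraction per group.
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# Per-site pi by exhaustive enumeration of all C(2n, 2) allele pairs.
pi_pair_oracle <- function(n, alt) {
  alleles <- c(rep(1, alt), rep(0, 2 * n - alt))
  pairs <- utils::combn(2 * n, 2)
  diffs <- alleles[pairs[1, ]] != alleles[pairs[2, ]]
  mean(diffs)
}

# Two-sided Fisher exact p by direct enumeration of all 2x2 tables with
# the observed margins; table probabilities via a choose()-product
# (conditional hypergeometric likelihood computed from first principles).
# Tables whose probability is <= the observed one (up to the customary
# 1 + 1e-7 relative tie tolerance) contribute to p.
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  prob_of <- function(x) {
    # x = count in cell [1,1]
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, prob_of, numeric(1))
  p_obs <- prob_of(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A tiny hand-built variant table: dosages given sites x samples for
# readability, transposed into the samples x sites layout.
tiny_table <- function(dosage_by_site, positions = NULL,
                       contig = "chr1", contig_len = NULL) {
  m <- t(dosage_by_site)
  n_site <- ncol(m)
  if (is.null(positions)) positions <- seq(100, by = 100, length.out = n_site)
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  }
  sites <- data.frame(contig = contig, pos = positions,
                      ref = rep("A", n_site), alt = rep("G", n_site),
                      stringsAsFactors = FALSE)
  if (is.null(contig_len)) contig_len <- max(positions) + 100
  variant_table(sites, m, stats::setNames(contig_len, contig))
}

# Contrast splitting the first na samples from the next nb.
tiny_contrast <- function(samples, na, nb, phenotype = NULL) {
  pops <- stats::setNames(
    c(rep("popA", na), rep("popB", nb),
      rep("other", length(samples) - na - nb)), samples)
  contrast_map(pops, "popA", "popB", phenotype = phenotype)
}

# Minimal VCF text fixture writer.
write_vcf_text <- function(path, records, samples,
                           contigs = c(chr1 = 100000)) {
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records
  )
  writeLines(lines, path)
  path
}
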