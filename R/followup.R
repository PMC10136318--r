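#' Exact tests of allele-frequency differentiation
#'
#' For each candidate site, builds the 2x2 allele-count table (contrast
#' group x ref/alt allele, two alleles per called diploid) and computes a
#' two-sided Fisher exact p-value, plus Benjamini-Hochberg adjusted
#' values over the tested set. A site monomorphic for the same allele in
#' both groups has p = 1. Significance follows the raw p-value at
#' `alpha` by default; the BH column lets callers tighten.
#'
#' @param x a [variant_table()].
#' @param contrast a [contrast_map()].
#' @param sites integer site indices to test (default all sites).
#' @param alpha significance level on the raw p-value (default 0.05).
#' @return data.frame, one row per site: `site`, `contig`, `pos`,
#'   `ref_a`, `alt_a`, `ref_b`, `alt_b` (allele counts), `p_value`,
#'   `bh_adjusted_p`, `significant`.
#' @export
allele_freq_test <- function(x, contrast, sites = seq_len(n_sites(x)),
                             alpha = 0.05) {
  ca <- group_counts(x, contrast_samples(contrast, "a"))
  cb <- group_counts(x, contrast_samples(contrast, "b"))
  p <- vapply(sites, function(i) {
    tab <- matrix(c(2 * ca$n[i] - ca$alt[i], ca$alt[i],
                    2 * cb$n[i] - cb$alt[i], cb$alt[i]),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || all(tab[, 2] == 0) || all(tab[, 1] == 0)) {
      return(1)  # a group uncalled, or monomorphic overall
    }
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  bh <- stats::p.adjust(p, method = "BH")
  data.frame(
    site = sites,
    contig = x$sites$contig[sites],
    pos = x$sites$pos[sites],
    ref_a = 2 * ca$n[sites] - ca$alt[sites], alt_a = ca$alt[sites],
    ref_b = 2 * cb$n[sites] - cb$alt[sites], alt_b = cb$alt[sites],
    p_value = p,
    bh_adjusted_p = bh,
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
}

#' Flag genotype-differentiated sites
#'
#' A site is flagged when each contrast group's modal genotype reaches a
#' frequency of at least `fix_threshold` among its called individuals and
#' the two modal genotypes differ — the near-fixed-difference pattern of
#' a hard sweep (e.g. homozygous alternate in the wild group, homozygous
#' reference in every domestic breed).
#'
#' @param x a [variant_table()].
#' @param contrast a [contrast_map()].
#' @param sites integer site indices (default all).
#' @param fix_threshold minimal modal-genotype frequency per group
#'   (default 0.8).
#' @return data.frame `site`, `contig`, `pos`, `modal_a`, `modal_b`,
#'   `freq_a`, `freq_b`, `differentiated`.
#' @export
genotype_differentiation <- function(x, contrast,
                                     sites = seq_len(n_sites(x)),
                                     fix_threshold = 0.8) {
  modal <- function(side, i) {
    d <- x$dosage[contrast_samples(contrast, side), i]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(c(NA_real_, NA_real_))
    tab <- tabulate(d + 1, nbins = 3)
    m <- which.max(tab)  # ties resolved toward the lower dosage
    c(m - 1, tab[m] / length(d))
  }
  res <- t(vapply(sites, function(i) c(modal("a", i), modal("b", i)),
                  numeric(4)))
  data.frame(
    site = sites,
    contig = x$sites$contig[sites],
    pos = x$sites$pos[sites],
    modal_a = res[, 1], freq_a = res[, 2],
    modal_b = res[, 3], freq_b = res[, 4],
    differentiated = !is.na(res[, 1]) & !is.na(res[, 3]) &
      res[, 1] != res[, 3] &
      res[, 2] >= fix_threshold & res[, 4] >= fix_threshold,
    stringsAsFactors = FALSE
  )
}

#' Score genotype-phenotype segregation
#'
#' Counts, per population and in total, how many individuals carry a
#' genotype consistent with their phenotype class under an expected-
#' genotype rule (a "yes") versus inconsistent (a "no"). The rule maps
#' each phenotype class to the set of consistent dosages, typically the
#' modal genotypes of the discovery populations; heterozygotes count as
#' mismatches unless the rule lists dosage 1. Individuals with unknown
#' phenotype or missing genotype are excluded and logged.
#'
#' @param genotypes named numeric vector, sample -> dosage at the
#'   candidate site.
#' @param phenotype named character vector, sample -> `case`/`control`/
#'   `unknown`.
#' @param populations named character vector, sample -> population.
#' @param expected_rule list with elements `case` and `control`, each a
#'   vector of consistent dosages (e.g. `list(case = 2, control = 0)`).
#' @return data.frame, one row per population plus a `Total` row:
#'   `population`, `n`, `yes`, `no`.
#' @export
segregation_score <- function(genotypes, phenotype, populations,
                              expected_rule) {
  stopifnot(all(c("case", "control") %in% names(expected_rule)))
  samples <- intersect(names(genotypes), names(phenotype))
  known <- samples[phenotype[samples] %in% c("case", "control") &
                     !is.na(genotypes[samples])]
  n_excl <- length(samples) - length(known)
  if (n_excl > 0) {
    message("segregation_score: excluded ", n_excl,
            " individual(s) with unknown phenotype or missing genotype")
  }
  ok <- vapply(known, function(s) {
    genotypes[[s]] %in% expected_rule[[phenotype[[s]]]]
  }, logical(1))
  pop <- populations[known]
  pops <- unique(pop)
  rows <- lapply(pops, function(pl) {
    sel <- pop == pl
    data.frame(population = pl, n = sum(sel), yes = sum(ok[sel]),
               no = sum(sel) - sum(ok[sel]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(population = "Total", n = sum(out$n),
                      yes = sum(out$yes), no = sum(out$no),
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Re-score segregation from published per-population tallies
#'
#' Validation panels are often reported only as per-population yes/no
#' tallies per SNP rather than individual-level genotypes. This helper
#' reconstructs a consistent individual-level dataset from such tallies
#' (each "yes" individual carries the genotype its phenotype class
#' expects, each "no" the contradicting one) and pushes it through
#' [segregation_score()], reproducing the per-population rows and the
#' Total row.
#'
#' @param tallies data.frame with columns `breed`, `phenotype`
#'   (`case`/`control`), `n`, `snp_pos`, `yes`, `no`; see
#'   `system.file("extdata", "ext1_knob_segregation.tsv",
#'   package = "sweepscan")` for the expected layout.
#' @param rule expected-genotype rule passed to [segregation_score()]
#'   (default `list(case = 2, control = 0)`).
#' @return named list of segregation tables, one per `snp_pos`.
#' @export
segregation_from_tallies <- function(tallies,
                                     rule = list(case = 2, control = 0)) {
  stopifnot(all(tallies$yes + tallies$no == tallies$n))
  out <- list()
  for (snp in unique(tallies$snp_pos)) {
    rows <- tallies[tallies$snp_pos == snp, , drop = FALSE]
    geno <- numeric(0)
    phen <- character(0)
    pops <- character(0)
    for (i in seq_len(nrow(rows))) {
      ids <- sprintf("%s_%02d", rows$breed[i], seq_len(rows$n[i]))
      cls <- rows$phenotype[i]
      expected <- rule[[cls]][1]
      contra <- rule[[setdiff(c("case", "control"), cls)]][1]
      geno <- c(geno, stats::setNames(
        c(rep(expected, rows$yes[i]), rep(contra, rows$no[i])), ids))
      phen <- c(phen, stats::setNames(rep(cls, rows$n[i]), ids))
      pops <- c(pops, stats::setNames(rep(rows$breed[i], rows$n[i]), ids))
    }
    out[[as.character(snp)]] <- segregation_score(geno, phen, pops, rule)
  }
  out
}

#' Composite linkage-disequilibrium r-squared and complete-LD groups
#'
#' Pairwise r-squared between candidate sites as the squared Pearson
#' correlation of genotype dosages over pairwise-complete individuals
#' (the composite LD measure, valid for unphased data). Zero-variance
#' sites have undefined r-squared and are excluded from grouping.
#' Complete-LD groups are built greedily along the site order: a site
#' joins the first group whose every member has r-squared >= 1 - tol
#' with it, else founds a new group.
#'
#' @param x a [variant_table()].
#' @param sites integer site indices (>= 2).
#' @param tol tolerance below 1 still counted as complete LD
#'   (default 1e-9, absorbing floating-point noise).
#' @return list with `r2` (symmetric matrix, unit diagonal, dimnames
#'   `contig:pos`) and `groups` (list of integer site-index vectors; only
#'   groups of two or more sites are reported).
#' @export
ld_r2 <- function(x, sites, tol = 1e-9) {
  if (length(sites) < 2) stop("LD needs at least two sites")
  d <- x$dosage[, sites, drop = FALSE]
  k <- length(sites)
  lab <- paste0(x$sites$contig[sites], ":", x$sites$pos[sites])
  r2 <- matrix(NA_real_, k, k, dimnames = list(lab, lab))
  diag(r2) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      keep <- !is.na(d[, i]) & !is.na(d[, j])
      if (sum(keep) < 2) next
      vi <- d[keep, i]
      vj <- d[keep, j]
      if (stats::sd(vi) == 0 || stats::sd(vj) == 0) next
      r2[i, j] <- r2[j, i] <- stats::cor(vi, vj)^2
    }
  }
  usable <- which(vapply(seq_len(k), function(i)
    any(!is.na(r2[i, -i])), logical(1)))
  groups <- list()
  for (i in usable) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      mem <- groups[[g]]
      if (all(!is.na(r2[i, mem]) & r2[i, mem] >= 1 - tol)) {
        groups[[g]] <- c(mem, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- i
  }
  groups <- lapply(groups, function(g) sites[sort(g)])
  list(r2 = r2, groups = groups[lengths(groups) >= 2])
}
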